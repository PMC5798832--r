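# End-to-end workflow stages: simulate -> extract -> analyze. Each stage is
# usable on its own so real cohorts can enter at the extract or analyze
# step; the bundled command-line script (inst/cli/ctradiomics.R) is a thin
# wrapper over these functions.

#' Simulate a phantom cohort (workflow stage 1)
#'
#' Thin wrapper over [generate_cohort()] with progress logging.
#'
#' @inheritParams generate_cohort
#' @param quiet suppress per-stage messages.
#' @return The cohort manifest tibble.
#' @export
run_simulate <- function(n_benign = 33L, n_malignant = 42L,
                         out_dir = tempfile("cohort"),
                         benign_template = phantom_spec("benign"),
                         malignant_template = phantom_spec("malignant"),
                         master_seed = 20260101L, quiet = FALSE) {
  manifest <- generate_cohort(n_benign, n_malignant, out_dir,
                              benign_template, malignant_template,
                              master_seed)
  if (!quiet)
    message(sprintf("simulate: wrote %d cases (%d benign, %d malignant) to %s",
                    nrow(manifest), n_benign, n_malignant, out_dir))
  manifest
}

#' Extract features for every case in a manifest (workflow stage 2)
#'
#' Reads each image/mask pair, crops the ROI and computes the full feature
#' vector; one row per case in registry column order. An unreadable case
#' aborts the run with the offending path (no silent skipping).
#'
#' @param manifest cohort manifest tibble or path to a manifest CSV with
#'   columns `case_id`, `image_path`, `mask_path`, `label`.
#' @param out_csv optional path for the feature-table CSV.
#' @param config a [radiomics_config()].
#' @param quiet suppress per-case log lines.
#' @return Feature table tibble: `case_id`, `label`, then the registry
#'   features (750 with defaults).
#' @export
run_extract <- function(manifest, out_csv = NULL,
                        config = radiomics_config(), quiet = FALSE) {
  if (is.character(manifest)) manifest <- tibble::as_tibble(
    read.csv(manifest, stringsAsFactors = FALSE))
  stopifnot(all(c("case_id", "image_path", "mask_path", "label") %in%
                  names(manifest)))
  if (nrow(manifest) == 0L) stop("empty manifest")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    t0 <- Sys.time()
    vol <- read_volume(manifest$image_path[i])
    msk <- read_volume(manifest$mask_path[i])
    patch <- extract_roi(vol, msk)
    fv <- full_feature_vector(patch, config)
    if (!quiet)
      message(sprintf("extract: %s (%d ROI voxels) in %.2fs",
                      manifest$case_id[i], patch$n_voxels,
                      as.numeric(Sys.time() - t0, units = "secs")))
    dplyr::bind_cols(tibble::tibble(case_id = manifest$case_id[i],
                                    label = manifest$label[i]),
                     tibble::as_tibble(as.list(fv)))
  })
  tbl <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) write.csv(tbl, out_csv, row.names = FALSE)
  tbl
}

#' Run the statistical analysis (workflow stage 3)
#'
#' Quantile normalization, Wilcoxon screening, sequential forward
#' selection, LOOCV evaluation of the signature, the all-features and
#' random-signature baselines, and the heatmap export, in that order.
#'
#' @param tbl feature table tibble or path to a feature-table CSV.
#' @param out_dir optional output directory; if given, writes
#'   `report.json`, `heatmap.csv` and `case_order.csv`.
#' @param config a [radiomics_config()].
#' @param seed RNG seed for the random-signature baseline.
#' @param quiet suppress stage messages.
#' @return A list of class `radiomics_report`: `screened`, `signature`,
#'   `evaluation`, `baseline_all`, `baseline_random`, `heatmap`, `config`,
#'   `seed`.
#' @export
run_analyze <- function(tbl, out_dir = NULL, config = radiomics_config(),
                        seed = 1L, quiet = FALSE) {
  if (is.character(tbl)) tbl <- tibble::as_tibble(
    read.csv(tbl, stringsAsFactors = FALSE, check.names = FALSE))
  say <- function(...) if (!quiet) message(sprintf(...))
  norm <- quantile_normalize(tbl)
  screened <- wilcoxon_screen(norm, alpha = config$alpha)
  say("analyze: %d/%d features pass the rank-sum screen at alpha %.2f",
      nrow(screened), attr(screened, "n_tested"), config$alpha)
  if (nrow(screened) < config$signature_size)
    stop("screening kept ", nrow(screened),
         " features, fewer than the signature size")
  signature <- sfs_select(norm, screened$feature,
                          k = config$signature_size, config = config)
  say("analyze: signature = %s", paste(signature$features, collapse = ", "))
  evaluation <- loocv_evaluate(norm, signature$features, config = config)
  baseline_all <- all_features_baseline(norm, screened$feature,
                                        config = config)
  baseline_random <- random_signature_baseline(
    norm, screened$feature, size = config$signature_size,
    n_perm = config$n_perm, seed = seed, config = config)
  say("analyze: signature %.1f%% vs all-features %.1f%% vs random mean %.1f%%",
      100 * evaluation$accuracy, 100 * baseline_all$accuracy,
      100 * baseline_random$mean_accuracy)
  heat_csv <- heat_ord <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    heat_csv <- file.path(out_dir, "heatmap.csv")
    heat_ord <- file.path(out_dir, "case_order.csv")
  }
  heatmap <- heatmap_export(norm, signature$features,
                            out_csv = heat_csv, out_order = heat_ord)
  report <- structure(list(screened = screened, signature = signature,
                           evaluation = evaluation,
                           baseline_all = baseline_all,
                           baseline_random = baseline_random,
                           heatmap = heatmap,
                           config = unclass(config), seed = seed),
                      class = "radiomics_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_list <- function(report) {
  ev <- report$evaluation
  list(seed = report$seed,
       config = report$config,
       screened = list(n = nrow(report$screened),
                       features = report$screened$feature,
                       p_values = report$screened$p_value),
       signature = list(features = report$signature$features,
                        step_accuracy = report$signature$accuracy),
       evaluation = list(tp = ev$tp, fn = ev$fn, tn = ev$tn, fp = ev$fp,
                         accuracy = ev$accuracy,
                         sensitivity = ev$sensitivity,
                         specificity = ev$specificity),
       baseline_all_features = list(
         accuracy = report$baseline_all$accuracy),
       baseline_random_signature = list(
         n_perm = report$baseline_random$n_perm,
         mean_accuracy = report$baseline_random$mean_accuracy))
}

#' @export
print.radiomics_report <- function(x, ...) {
  cat("<radiomics_report>\n")
  cat(sprintf("  screened features : %d\n", nrow(x$screened)))
  cat(sprintf("  signature         : %s\n",
              paste(x$signature$features, collapse = ", ")))
  cat(sprintf("  signature LOOCV   : %.1f%% acc / %.2f%% sens / %.2f%% spec\n",
              100 * x$evaluation$accuracy, 100 * x$evaluation$sensitivity,
              100 * x$evaluation$specificity))
  cat(sprintf("  all-features acc  : %.1f%%\n",
              100 * x$baseline_all$accuracy))
  cat(sprintf("  random mean acc   : %.1f%% (%d draws)\n",
              100 * x$baseline_random$mean_accuracy,
              x$baseline_random$n_perm))
  invisible(x)
}
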