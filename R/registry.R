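#' Pipeline configuration
#'
#' All tunable knobs with the defaults that reproduce the reference
#' configuration: 256 gray levels for the co-occurrence and run-length
#' matrices, 64 for the size-zone and gray-tone difference matrices (denser
#' matrices on small nodules), Laplacian-of-Gaussian scales 1-6 mm, 64
#' histogram bins for the statistic set, screening level alpha = 0.05,
#' 4-feature signature, linear SVM with cost 1, 1000 random-signature
#' permutations.
#'
#' @param glcm_levels,rlm_levels,glszm_levels,ngtdm_levels gray-level counts.
#' @param log_sigmas_mm LoG scales in mm (length 6 for the 750-feature
#'   inventory).
#' @param stat_bins histogram bins for the 16-statistic summary.
#' @param alpha screening significance level.
#' @param signature_size features in the signature (k).
#' @param svm_kernel,svm_cost classifier configuration.
#' @param n_perm random-signature permutation count.
#' @return A named list of class `radiomics_config`.
#' @export
radiomics_config <- function(glcm_levels = 256L, rlm_levels = 256L,
                             glszm_levels = 64L, ngtdm_levels = 64L,
                             log_sigmas_mm = 1:6, stat_bins = 64L,
                             alpha = 0.05, signature_size = 4L,
                             svm_kernel = "linear", svm_cost = 1,
                             n_perm = 1000L) {
  structure(list(glcm_levels = as.integer(glcm_levels),
                 rlm_levels = as.integer(rlm_levels),
                 glszm_levels = as.integer(glszm_levels),
                 ngtdm_levels = as.integer(ngtdm_levels),
                 log_sigmas_mm = log_sigmas_mm,
                 stat_bins = as.integer(stat_bins),
                 alpha = alpha, signature_size = as.integer(signature_size),
                 svm_kernel = svm_kernel, svm_cost = svm_cost,
                 n_perm = as.integer(n_perm)),
            class = "radiomics_config")
}

# feature names per category, in registry (= extraction) order
feature_names_by_category <- function(config = radiomics_config()) {
  sn <- stat_names()
  list(
    intensity_shape = c(paste0("Intensity_", sn),
                        paste0("IVH_", c(paste0("I", c(10, 30, 50, 70, 90)),
                                         paste0("V", c(10, 30, 50, 70, 90)))),
                        paste0("Shape_", c("volume", "surface_area",
                                           "surface_to_volume", "sphericity",
                                           "compactness1", "compactness2",
                                           "max_diameter"))),
    log = as.vector(vapply(config$log_sigmas_mm, function(sg)
      paste0("LoG_s", format(sg), "_", sn), character(16))),
    wavelet = as.vector(vapply(c("LLL", "LLH", "LHL", "LHH",
                                 "HLL", "HLH", "HHL", "HHH"), function(b)
      paste0("Wav_", b, "_", sn), character(16))),
    laws = as.vector(vapply(laws_ids(), function(id)
      paste0("Laws_", id, "_", sn), character(16))),
    glcm = paste0("GLCM_", names(glcm_features(
      structure(list(probabilities = matrix(1), levels = 1L),
                class = "glcm_matrix")))),
    rlm = paste0("RLM_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                           "SRLGE", "SRHGE", "LRLGE", "LRHGE")),
    glszm = paste0("GLSZM_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE",
                               "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE")),
    ngtdm = paste0("NGTDM_", c("coarseness", "contrast", "busyness",
                               "complexity", "strength")),
    fractal = paste0("FD_t", seq(10, 80, by = 10))
  )
}

#' The 750-feature registry
#'
#' Machine-readable inventory mapping every feature name to its category
#' and a short definition, in the exact order features are emitted. With
#' the default configuration the category totals are 33 (intensity &
#' shape), 96 (LoG), 128 (wavelet), 432 (Laws), 26 (co-occurrence), 11
#' (run-length), 11 (size-zone), 5 (gray-tone difference) and 8 (fractal)
#' — 750 in all.
#'
#' @param config a [radiomics_config()].
#' @return A tibble with columns `feature`, `category`, `definition`.
#' @examples
#' reg <- feature_registry()
#' dplyr::count(reg, category)
#' @export
feature_registry <- function(config = radiomics_config()) {
  nm <- feature_names_by_category(config)
  defs <- c(
    intensity_shape = "statistic of raw in-mask intensities / IVH curve / mask morphology",
    log = "statistic of the Laplacian-of-Gaussian response at the named scale (mm)",
    wavelet = "statistic of the named one-level 3D Haar subband",
    laws = "statistic of the named separable Laws L3/E3/S3 kernel response",
    glcm = "descriptor of the 13-direction co-occurrence probability matrix",
    rlm = "descriptor of the 13-direction gray-level run-length matrix",
    glszm = "descriptor of the 26-connected gray-level size-zone matrix",
    ngtdm = "descriptor of the neighbourhood gray-tone difference table",
    fractal = "box-counting dimension of the range-fraction thresholded set")
  tibble::tibble(
    feature = unlist(nm, use.names = FALSE),
    category = rep(names(nm), lengths(nm)),
    definition = rep(defs[names(nm)], lengths(nm)))
}

#' Extract the full 750-feature vector from one nodule
#'
#' Runs every feature block on the ROI patch and concatenates them in
#' registry order: intensity & shape, LoG, wavelet, Laws, co-occurrence,
#' run-length, size-zone, gray-tone difference, fractal.
#'
#' @param patch an [roi_patch()].
#' @param config a [radiomics_config()].
#' @return Named numeric vector whose names equal
#'   `feature_registry(config)$feature` (750 with defaults).
#' @export
full_feature_vector <- function(patch, config = radiomics_config()) {
  stopifnot(inherits(patch, "roi_patch"))
  glcm_f <- glcm_features(glcm(quantize(patch, config$glcm_levels)))
  out <- c(
    intensity_shape_block(patch, bins = config$stat_bins),
    log_block(patch, sigmas_mm = config$log_sigmas_mm,
              bins = config$stat_bins),
    wavelet_block(patch, bins = config$stat_bins),
    laws_block(patch, bins = config$stat_bins),
    setNames(glcm_f, paste0("GLCM_", names(glcm_f))),
    rlm_features(rlm(quantize(patch, config$rlm_levels))),
    glszm_features(glszm(quantize(patch, config$glszm_levels))),
    ngtdm_features(ngtdm(quantize(patch, config$ngtdm_levels))),
    fractal_features(patch))
  expected <- unlist(feature_names_by_category(config), use.names = FALSE)
  stopifnot(length(out) == length(expected))
  # RLM/GLSZM/NGTDM blocks carry bare names; align to registry names
  names(out) <- expected
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(head(names(out)[bad], 5), collapse = ", "))
  out
}
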