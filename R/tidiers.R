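# broom-style tidiers for fitted pipeline objects

#' Tidy a radiomics signature
#'
#' @param x a [sfs_select()] result.
#' @param ... ignored.
#' @return Tibble with `step`, `feature`, `accuracy` (cumulative LOOCV
#'   accuracy after adding the feature).
#' @method tidy radiomics_signature
#' @export
tidy.radiomics_signature <- function(x, ...) {
  tibble::tibble(step = seq_along(x$features), feature = x$features,
                 accuracy = x$accuracy)
}

#' @rdname tidy.radiomics_signature
#' @return For `glance()`: one row with `k`, `accuracy` (final step),
#'   `svm_kernel`, `svm_cost`, `n_candidates`.
#' @method glance radiomics_signature
#' @export
glance.radiomics_signature <- function(x, ...) {
  tibble::tibble(k = x$k, accuracy = x$accuracy[length(x$accuracy)],
                 svm_kernel = x$svm_kernel, svm_cost = x$svm_cost,
                 n_candidates = length(x$candidates))
}

#' Tidy a LOOCV evaluation
#'
#' @param x a [loocv_evaluate()] result.
#' @param ... ignored.
#' @return Per-case predictions tibble (`case_id`, `label`, `predicted`,
#'   `correct`).
#' @method tidy radiomics_eval
#' @export
tidy.radiomics_eval <- function(x, ...) {
  dplyr::mutate(x$predictions, correct = .data$label == .data$predicted)
}

#' @rdname tidy.radiomics_eval
#' @return For `glance()`: one row with the confusion counts and the
#'   three metrics (proportions).
#' @method glance radiomics_eval
#' @export
glance.radiomics_eval <- function(x, ...) {
  tibble::tibble(tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp,
                 accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' @rdname tidy.radiomics_signature
#' @method tidy radiomics_baseline
#' @export
tidy.radiomics_baseline <- function(x, ...) x$accuracies

#' @rdname tidy.radiomics_signature
#' @method glance radiomics_baseline
#' @export
glance.radiomics_baseline <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, size = x$size,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = sd(x$accuracies$accuracy))
}
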