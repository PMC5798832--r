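# Feature-table helpers: tibbles with case_id, label and feature columns
# are the bridge format between the extractor and the statistics stages.

ft_validate <- function(tbl, require_both_classes = TRUE) {
  stopifnot(is.data.frame(tbl))
  if (!all(c("case_id", "label") %in% names(tbl)))
    stop("feature table needs 'case_id' and 'label' columns")
  feats <- setdiff(names(tbl), c("case_id", "label"))
  if (length(feats) == 0L) stop("feature table has no feature columns")
  if (anyDuplicated(feats)) stop("duplicate feature names")
  X <- as.matrix(tbl[feats])
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("feature table contains missing or non-finite values")
  lab <- as.character(tbl$label)
  if (require_both_classes && length(unique(lab)) < 2L)
    stop("both classes must be present")
  list(X = X, case_id = as.character(tbl$case_id), label = lab,
       features = feats)
}

ft_rebuild <- function(ft, X) {
  dplyr::bind_cols(tibble::tibble(case_id = ft$case_id, label = ft$label),
                   tibble::as_tibble(X))
}

#' Quantile-normalize a feature table across cases
#'
#' Makes every case's feature-value distribution identical while
#' preserving within-case ranks: the value at rank r in a case is replaced
#' by the mean over cases of their rank-r values, with ties receiving the
#' average of the tied reference values. Applied across all cases before
#' screening and selection, mirroring the batch-effect correction stage.
#'
#' @param tbl feature table (`case_id`, `label`, feature columns); at
#'   least 2 cases.
#' @return The normalized table, same shape.
#' @examples
#' tbl <- tibble::tibble(case_id = c("a", "b"), label = c("benign", "malignant"),
#'                       f1 = c(1, 4), f2 = c(2, 5), f3 = c(3, 6))
#' quantile_normalize(tbl)  # both cases become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(tbl) {
  ft <- ft_validate(tbl, require_both_classes = FALSE)
  if (nrow(ft$X) < 2L) stop("quantile normalization needs at least 2 cases")
  Xn <- t(limma::normalizeQuantiles(t(ft$X), ties = TRUE))
  dimnames(Xn) <- dimnames(ft$X)
  ft_rebuild(ft, Xn)
}

#' Wilcoxon rank-sum screening of features
#'
#' Tests every feature for a two-sided location difference between the two
#' classes and keeps those with p below `alpha` (no multiple-testing
#' correction, matching the reference procedure). The exact rank-sum
#' distribution is used when both groups have at most 10 cases and there
#' are no ties; otherwise the normal approximation with continuity and tie
#' correction.
#'
#' The screened features are returned ranked by ascending p-value. This
#' ranking is also the candidate ordering consumed by [sfs_select()], whose
#' accuracy ties therefore resolve towards the more significant feature.
#'
#' @param tbl feature table; both classes present with >= 2 cases each.
#' @param alpha significance level (default 0.05).
#' @return Tibble of selected features (`feature`, `p_value`) ranked by
#'   p-value, with attributes `n_tested` and `alpha`.
#' @export
wilcoxon_screen <- function(tbl, alpha = 0.05) {
  ft <- ft_validate(tbl)
  classes <- sort(unique(ft$label))
  g1 <- ft$label == classes[1]; g2 <- ft$label == classes[2]
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("each class needs at least 2 cases")
  pv <- vapply(seq_along(ft$features), function(j) {
    x <- ft$X[g1, j]; y <- ft$X[g2, j]
    if (max(c(x, y)) == min(c(x, y))) return(1)  # constant feature
    use_exact <- length(x) <= 10 && length(y) <= 10 &&
      !anyDuplicated(c(x, y))
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                  correct = TRUE)$p.value)
  }, numeric(1))
  keep <- which(pv < alpha)
  keep <- keep[order(pv[keep])]
  out <- tibble::tibble(feature = ft$features[keep], p_value = pv[keep])
  attr(out, "n_tested") <- length(pv)
  attr(out, "alpha") <- alpha
  out
}
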