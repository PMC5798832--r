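# Signature building: SVM under leave-one-out cross-validation, greedy
# sequential forward selection, and the evaluation/baseline machinery.

# leave-one-out predictions for an SVM on a feature matrix; features are
# standardised per training fold (held-out case never touches the fold's
# centring/scaling parameters)
svm_loocv <- function(X, y, kernel = "linear", cost = 1,
                      keep_fold_params = FALSE) {
  n <- nrow(X)
  y <- factor(y)
  pred <- character(n)
  fold_params <- if (keep_fold_params) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop("degenerate training fold: only one class when case ", i,
           " is held out")
    ctr <- colMeans(tr)
    scl <- apply(tr, 2, sd)
    scl[scl == 0] <- 1
    trs <- sweep(sweep(tr, 2, ctr), 2, scl, `/`)
    tes <- (X[i, ] - ctr) / scl
    fit <- e1071::svm(x = trs, y = ytr, kernel = kernel, cost = cost,
                      scale = FALSE)
    pred[i] <- as.character(predict(fit, matrix(tes, nrow = 1)))
    if (keep_fold_params) fold_params[[i]] <- list(center = ctr, scale = scl)
  }
  list(pred = pred, fold_params = fold_params)
}

loocv_accuracy <- function(X, y, kernel = "linear", cost = 1) {
  mean(svm_loocv(X, y, kernel, cost)$pred == as.character(y))
}

#' Evaluate a feature set by leave-one-out cross-validation
#'
#' For each case, an SVM is trained on all remaining cases (feature
#' standardisation fitted on the training fold only) and the held-out case
#' is predicted; the per-case predictions are aggregated into confusion
#' counts and accuracy, sensitivity and specificity.
#'
#' @param tbl feature table.
#' @param features character vector of feature columns to use (>= 1).
#' @param positive_class label counted as positive for
#'   sensitivity/specificity (default `"malignant"`).
#' @param config a [radiomics_config()] (SVM kernel and cost).
#' @return An object of class `radiomics_eval`: confusion counts `tp`,
#'   `fn`, `tn`, `fp`; `accuracy`, `sensitivity`, `specificity`
#'   (proportions); `predictions` tibble; `fold_params` (per-fold
#'   standardisation, for leakage audits).
#' @export
loocv_evaluate <- function(tbl, features, positive_class = "malignant",
                           config = radiomics_config()) {
  ft <- ft_validate(tbl)
  if (length(features) < 1L) stop("need at least one feature")
  missing_f <- setdiff(features, ft$features)
  if (length(missing_f) > 0)
    stop("unknown feature(s): ", paste(head(missing_f, 3), collapse = ", "))
  X <- ft$X[, features, drop = FALSE]
  cv <- svm_loocv(X, ft$label, config$svm_kernel, config$svm_cost,
                  keep_fold_params = TRUE)
  pos <- ft$label == positive_class
  tp <- sum(pos & cv$pred == positive_class)
  fn <- sum(pos & cv$pred != positive_class)
  tn <- sum(!pos & cv$pred != positive_class)
  fp <- sum(!pos & cv$pred == positive_class)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 positive_class = positive_class,
                 features = features,
                 predictions = tibble::tibble(case_id = ft$case_id,
                                              label = ft$label,
                                              predicted = cv$pred),
                 fold_params = cv$fold_params),
            class = "radiomics_eval")
}

#' @export
print.radiomics_eval <- function(x, ...) {
  cat(sprintf(paste0("<radiomics_eval> %d features, %d cases\n",
                     "  accuracy %.1f%%  sensitivity %.2f%%  ",
                     "specificity %.2f%%\n"),
              length(x$features), nrow(x$predictions),
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity and specificity (in percent) from true/false
#' positive/negative counts, e.g. 39/42 correct malignant and 24/33
#' correct benign give 84% / 92.857% / 72.727%.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return Tibble with `accuracy`, `sensitivity`, `specificity` (percent).
#' @examples
#' classification_metrics(tp = 39, fn = 3, tn = 24, fp = 9)
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  tibble::tibble(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp))
}

#' Sequential forward selection of a feature signature
#'
#' Greedy wrapper selection: starting from the empty set, each step adds
#' the screened candidate that maximises the leave-one-out
#' cross-validation accuracy of the SVM on the current set plus that
#' candidate, stopping at `k` features. Accuracy ties are broken towards
#' the earlier candidate in the supplied ordering (stable and
#' deterministic).
#'
#' @param tbl feature table.
#' @param candidates character vector of screened feature names (the
#'   search pool), non-empty; `k <= length(candidates)`.
#' @param k signature size (default 4).
#' @param config a [radiomics_config()].
#' @return An object of class `radiomics_signature`: ordered `features`,
#'   per-step `accuracy`, `k`, classifier config.
#' @export
sfs_select <- function(tbl, candidates, k = 4L, config = radiomics_config()) {
  ft <- ft_validate(tbl)
  if (k < 1L) stop("parameter error: k must be >= 1")
  if (length(candidates) == 0L) stop("no candidate features")
  missing_f <- setdiff(candidates, ft$features)
  if (length(missing_f) > 0)
    stop("unknown candidate(s): ", paste(head(missing_f, 3), collapse = ", "))
  if (k > length(candidates)) stop("k exceeds number of candidates")
  selected <- character(0)
  step_acc <- numeric(0)
  remaining <- candidates
  for (step in seq_len(k)) {
    accs <- vapply(remaining, function(f) {
      loocv_accuracy(ft$X[, c(selected, f), drop = FALSE], ft$label,
                     config$svm_kernel, config$svm_cost)
    }, numeric(1))
    best <- remaining[which.max(accs)]   # first max: earlier candidate wins
    selected <- c(selected, best)
    step_acc <- c(step_acc, max(accs))
    remaining <- setdiff(remaining, best)
  }
  structure(list(features = selected, accuracy = step_acc, k = k,
                 svm_kernel = config$svm_kernel, svm_cost = config$svm_cost,
                 candidates = candidates),
            class = "radiomics_signature")
}

#' @export
print.radiomics_signature <- function(x, ...) {
  cat("<radiomics_signature>\n")
  for (i in seq_along(x$features))
    cat(sprintf("  %d. %-24s LOOCV accuracy %.1f%%\n", i, x$features[i],
                100 * x$accuracy[i]))
  invisible(x)
}

#' Random-signature permutation baseline
#'
#' Reference distribution for the selected signature: `n_perm` uniformly
#' random size-`size` subsets of the screened candidates, each evaluated
#' by SVM LOOCV accuracy. Reproducible under `seed`; the caller's RNG
#' state is untouched.
#'
#' @param tbl feature table.
#' @param candidates screened feature names; at least `size`.
#' @param size signature size drawn (default 4).
#' @param n_perm number of random signatures (reference analysis uses
#'   1000).
#' @param seed RNG seed.
#' @param config a [radiomics_config()].
#' @return List of class `radiomics_baseline`: `mean_accuracy`,
#'   `accuracies` tibble (`draw`, `accuracy`), `size`, `n_perm`.
#' @export
random_signature_baseline <- function(tbl, candidates, size = 4L,
                                      n_perm = 1000L, seed = 1L,
                                      config = radiomics_config()) {
  ft <- ft_validate(tbl)
  if (length(candidates) < size) stop("fewer candidates than signature size")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  acc <- vapply(seq_len(n_perm), function(i) {
    f <- sample(candidates, size)
    loocv_accuracy(ft$X[, f, drop = FALSE], ft$label,
                   config$svm_kernel, config$svm_cost)
  }, numeric(1))
  structure(list(mean_accuracy = mean(acc),
                 accuracies = tibble::tibble(draw = seq_len(n_perm),
                                             accuracy = acc),
                 size = size, n_perm = n_perm, seed = seed),
            class = "radiomics_baseline")
}

#' @export
print.radiomics_baseline <- function(x, ...) {
  cat(sprintf("<radiomics_baseline> %d random %d-feature signatures, mean accuracy %.1f%%\n",
              x$n_perm, x$size, 100 * x$mean_accuracy))
  invisible(x)
}

#' All-screened-features baseline
#'
#' LOOCV evaluation using every screened feature at once, the
#' no-selection reference.
#'
#' @param tbl feature table.
#' @param candidates screened feature names.
#' @param config a [radiomics_config()].
#' @return A `radiomics_eval` (see [loocv_evaluate()]).
#' @export
all_features_baseline <- function(tbl, candidates,
                                  config = radiomics_config()) {
  loocv_evaluate(tbl, candidates, config = config)
}
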