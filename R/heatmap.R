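#' Z-score heatmap matrix with clustered case ordering
#'
#' Standardises each selected feature to zero mean and unit variance
#' across cases (zero-variance features map to all-zero rows) and orders
#' the cases by agglomerative hierarchical clustering (average linkage,
#' Euclidean distance) of their z-scored signature vectors — the data
#' behind the classic signature expression heatmap.
#'
#' @param tbl feature table.
#' @param features feature names to include (>= 1).
#' @param out_csv optional path: writes the z-score matrix (features x
#'   cases) as CSV.
#' @param out_order optional path: writes the case ordering as CSV.
#' @return An object of class `radiomics_heatmap`: `z` (features x cases
#'   matrix), `case_order` (case ids, clustering order), `case_labels`
#'   (named by case id), `hclust`.
#' @export
heatmap_export <- function(tbl, features, out_csv = NULL, out_order = NULL) {
  ft <- ft_validate(tbl, require_both_classes = FALSE)
  if (length(features) < 1L) stop("need at least one feature")
  missing_f <- setdiff(features, ft$features)
  if (length(missing_f) > 0)
    stop("unknown feature(s): ", paste(head(missing_f, 3), collapse = ", "))
  X <- ft$X[, features, drop = FALSE]
  Z <- apply(X, 2, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  Z <- matrix(Z, nrow = nrow(X),
              dimnames = list(ft$case_id, features))
  hc <- hclust(dist(Z), method = "average")
  ord <- ft$case_id[hc$order]
  zt <- t(Z)   # features x cases
  if (!is.null(out_csv))
    write.csv(data.frame(feature = rownames(zt), zt, check.names = FALSE),
              out_csv, row.names = FALSE)
  if (!is.null(out_order))
    write.csv(data.frame(position = seq_along(ord), case_id = ord,
                         label = ft$label[match(ord, ft$case_id)]),
              out_order, row.names = FALSE)
  structure(list(z = zt, case_order = ord,
                 case_labels = setNames(ft$label, ft$case_id),
                 hclust = hc),
            class = "radiomics_heatmap")
}

#' @export
print.radiomics_heatmap <- function(x, ...) {
  cat(sprintf("<radiomics_heatmap> %d features x %d cases\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Plot a signature z-score heatmap
#'
#' Tile plot of the z-score matrix with cases in clustering order,
#' annotated by class label.
#'
#' @param object a [heatmap_export()] result.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot radiomics_heatmap
#' @export
autoplot.radiomics_heatmap <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object$z, rownames = "feature")),
    -"feature", names_to = "case_id", values_to = "z")
  df$case_id <- factor(df$case_id, levels = object$case_order)
  df$label <- object$case_labels[as.character(df$case_id)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$case_id, y = .data$feature,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::facet_grid(. ~ label, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "case (clustered)", y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Accuracy distribution plot for the random-signature baseline
#'
#' Histogram of the permutation accuracies with the mean marked.
#'
#' @param object a [random_signature_baseline()] result.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot radiomics_baseline
#' @export
autoplot.radiomics_baseline <- function(object, ...) {
  ggplot2::ggplot(object$accuracies, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_accuracy,
                        colour = "firebrick") +
    ggplot2::labs(x = "LOOCV accuracy of random signature", y = "count") +
    ggplot2::theme_minimal()
}
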