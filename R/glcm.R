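#' The 13 unique 3D co-occurrence directions
#'
#' Unique non-antipodal voxel offsets with components in \{-1, 0, 1\}: the
#' 3 face, 6 edge and 4 corner neighbour directions used by the
#' co-occurrence and run-length constructions.
#'
#' @return A 13 x 3 integer matrix of offsets.
#' @export
offsets_13 <- function() {
  o <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(o) <- "integer"
  o
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at a fixed voxel distance over the
#' 13 unique 3D directions (symmetrised, so each pair is counted in both
#' orders), sums the counts over directions and normalises to a joint
#' probability matrix. Pairs with an out-of-mask member are skipped, never
#' bridged.
#'
#' @param q a [quantize()]d patch.
#' @param distance offset magnitude in voxels (default 1).
#' @param directions offset matrix; defaults to [offsets_13()]. A subset can
#'   be supplied for direction-resolved matrices.
#' @return An object of class `glcm_matrix`: list with `probabilities`
#'   (levels x levels, sums to 1), `levels`, `distance`, `n_directions`,
#'   `n_pairs`.
#' @export
glcm <- function(q, distance = 1L, directions = offsets_13()) {
  stopifnot(inherits(q, "quantized_patch"))
  L <- q$levels
  codes <- array(as.double(q$codes), dim(q$codes))  # NA outside mask
  counts <- matrix(0, L, L)
  total <- 0L
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ] * as.integer(distance)
    b <- shift_array(codes, o)
    ok <- !is.na(codes) & !is.na(b)
    if (!any(ok)) next
    ci <- codes[ok]; cj <- b[ok]
    tab <- tabulate(ci * L + cj + 1, nbins = L * L)
    counts <- counts + matrix(tab, L, L, byrow = TRUE)
    total <- total + sum(ok)
  }
  if (total == 0L) stop("degenerate ROI: no valid voxel pair in any direction")
  counts <- counts + t(counts)   # symmetrise: both orders
  structure(list(probabilities = counts / sum(counts), levels = L,
                 distance = as.integer(distance),
                 n_directions = nrow(directions), n_pairs = total),
            class = "glcm_matrix")
}

#' Haralick-style co-occurrence features
#'
#' The 26 scalar descriptors of a co-occurrence probability matrix kept in
#' the package feature registry. Gray-level values enter the formulas
#' 1-based; logarithms are base 2 with the 0 log 0 = 0 convention.
#' Degenerate guards: correlation of a zero-variance matrix is 1 (perfect
#' dependence limit) and the information measures fall back to 0 when the
#' marginal entropy vanishes.
#'
#' @param m a [glcm()] result.
#' @return Named numeric vector of 26 features.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  p <- m$probabilities
  L <- m$levels
  lev <- seq_len(L)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px)); sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  IM <- matrix(lev, L, L); JM <- t(IM)
  ad <- abs(IM - JM); sq <- (IM - JM)^2
  # sum (i+j) and difference |i-j| marginal distributions
  ps <- as.vector(rowsum(as.vector(p), group = as.vector(IM + JM)))
  ks <- sort(unique(as.vector(IM + JM)))
  pd <- as.vector(rowsum(as.vector(p), group = as.vector(ad)))
  kd <- sort(unique(as.vector(ad)))
  log2z <- function(x) ifelse(x > 0, log2(x), 0)
  ent <- -sum(p * log2z(p))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  pxy_ind <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxy_ind))
  hxy2 <- -sum(pxy_ind * log2z(pxy_ind))
  da <- sum(kd * pd)
  sa <- sum(ks * ps)
  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(IM * JM * p) - mu_x * mu_y) / (sd_x * sd_y) else 1
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  offdiag <- ad > 0
  c(autocorrelation = sum(IM * JM * p),
    joint_average = mu_x,
    cluster_prominence = sum((IM + JM - mu_x - mu_y)^4 * p),
    cluster_shade = sum((IM + JM - mu_x - mu_y)^3 * p),
    cluster_tendency = sum((IM + JM - mu_x - mu_y)^2 * p),
    contrast = sum(sq * p),
    correlation = corr,
    difference_average = da,
    difference_energy = sum(pd^2),
    difference_entropy = -sum(pd * log2z(pd)),
    difference_variance = sum((kd - da)^2 * pd),
    dissimilarity = sum(ad * p),
    energy = sum(p^2),
    entropy = ent,
    homogeneity = sum(p / (1 + ad)),
    inverse_difference_moment = sum(p / (1 + sq)),
    inverse_difference_normalized = sum(p / (1 + ad / L)),
    inverse_difference_moment_normalized = sum(p / (1 + sq / L^2)),
    inverse_variance = sum(p[offdiag] / sq[offdiag]),
    imc1 = imc1,
    imc2 = imc2,
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = -sum(ps * log2z(ps)),
    sum_variance = sum((ks - sa)^2 * ps),
    joint_variance = sum((IM - mu_x)^2 * p))
}
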