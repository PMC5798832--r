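#' Names of the 16 summary statistics
#'
#' The statistic suffixes applied to the raw ROI and to every filter
#' response: order statistics, histogram statistics (64 bins by default),
#' moment statistics, and a co-occurrence contrast/homogeneity pair computed
#' on the patch re-quantised to 32 levels.
#'
#' @return Character vector of length 16.
#' @export
stat_names <- function() {
  c("min", "max", "median", "peak", "mean", "sd", "coeff_var", "rms",
    "skewness", "kurtosis", "energy", "entropy", "uniformity", "range",
    "contrast", "lcl_homo")
}

#' Sixteen-statistic summary of an intensity sample
#'
#' Computes the shared statistic set used for every feature block: min, max,
#' median, histogram peak (mode), mean, standard deviation, coefficient of
#' variation, root mean square, skewness, excess kurtosis, energy (sum of
#' squares), histogram entropy (log base 2), uniformity, range, and the
#' co-occurrence contrast and local homogeneity of the patch at 32 gray
#' levels (distance 1, averaged over the 13 directions).
#'
#' Degenerate limits are defined so every statistic stays finite: a
#' zero-variance sample has skewness = kurtosis = 0, entropy = 0 and
#' uniformity = 1; a zero mean gives coefficient of variation 0; a patch
#' with no valid voxel pair gets contrast 0 and homogeneity 1.
#'
#' @param x 3D numeric array (a patch or filter response), or a plain
#'   numeric vector (treated as a 1 x 1 x n patch).
#' @param mask logical array like `x` selecting ROI voxels; default all.
#' @param bins histogram bin count for peak/entropy/uniformity (>= 2).
#' @param glcm_levels gray levels for the contrast/homogeneity pair.
#' @return Named numeric vector of length 16 (see [stat_names()]).
#' @examples
#' stat_set(c(1, 2, 3, 4))[c("mean", "rms", "energy")]
#' @export
stat_set <- function(x, mask = NULL, bins = 64L, glcm_levels = 32L) {
  if (is.null(dim(x))) x <- array(as.numeric(x), c(1L, 1L, length(x)))
  if (is.null(mask)) mask <- array(TRUE, dim(x))
  if (bins < 2L) stop("parameter error: 'bins' must be >= 2")
  v <- x[mask]
  if (length(v) == 0L) stop("empty input: no in-mask values")
  if (any(!is.finite(v))) stop("non-finite values in statistic input")
  n <- length(v)
  mn <- min(v); mx <- max(v); rng <- mx - mn
  mu <- mean(v)
  s <- if (n >= 2L) sd(v) else 0
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 - 3 else 0
  # histogram over [min, max] in equal-width bins
  if (rng > 0) {
    cd <- pmin(floor((v - mn) / (rng / bins)), bins - 1)
    cnt <- tabulate(cd + 1, nbins = bins)
    prob <- cnt / n
    peak <- mn + (which.max(cnt) - 0.5) * (rng / bins)
  } else {
    prob <- 1
    peak <- mn
  }
  pz <- prob[prob > 0]
  gl <- stat_set_glcm_pair(x, mask, glcm_levels)
  c(min = mn, max = mx, median = median(v), peak = peak, mean = mu,
    sd = s, coeff_var = if (mu != 0) s / mu else 0,
    rms = sqrt(mean(v^2)), skewness = skew, kurtosis = kurt,
    energy = sum(v^2), entropy = -sum(pz * log2(pz)),
    uniformity = sum(pz^2), range = rng,
    contrast = gl[1], lcl_homo = gl[2])
}

# contrast/homogeneity of the 32-level GLCM of the patch; degenerate
# patches (single voxel, no neighbour pair) fall back to the constant-image
# limit contrast 0 / homogeneity 1
stat_set_glcm_pair <- function(x, mask, levels) {
  out <- tryCatch({
    p <- roi_patch_internal(x, mask)
    f <- glcm_features(glcm(quantize(p, levels)))
    c(f[["contrast"]], f[["homogeneity"]])
  }, error = function(e) c(0, 1))
  out
}

# roi_patch without the tight-crop requirement (filter responses keep the
# original box); crops internally so glcm sees a tight patch
roi_patch_internal <- function(x, mask) {
  bb <- mask_bbox(mask)
  ix <- bb[1, 1]:bb[2, 1]; iy <- bb[1, 2]:bb[2, 2]; iz <- bb[1, 3]:bb[2, 3]
  roi_patch(x[ix, iy, iz, drop = FALSE], mask[ix, iy, iz, drop = FALSE])
}
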