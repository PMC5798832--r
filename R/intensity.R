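#' Intensity-volume histogram features
#'
#' Cumulative intensity-volume descriptors, the imaging analogue of a
#' dose-volume histogram. `Ix` is the highest intensity such that at least
#' x% of the ROI volume has that intensity or higher; `Vx` is the fraction
#' of the ROI volume at or above the intensity x% of the way from the
#' in-mask minimum to the maximum. Both are evaluated on the decile grid
#' \{10, 30, 50, 70, 90\}.
#'
#' @param patch an [roi_patch()].
#' @return Named numeric vector: `I10 ... I90` then `V10 ... V90`.
#' @examples
#' p <- roi_patch(array(1:10, c(10, 1, 1)), array(TRUE, c(10, 1, 1)))
#' ivh_features(p)[["I30"]]  # 8: voxels {8,9,10} are exactly 30%
#' @export
ivh_features <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  v <- patch$voxels[patch$mask]
  n <- length(v)
  dec <- c(10, 30, 50, 70, 90)
  sv <- sort(v, decreasing = TRUE)
  ix <- sv[pmin(n, ceiling(n * dec / 100))]
  mn <- min(v); rng <- max(v) - mn
  vx <- vapply(dec, function(x) mean(v >= mn + rng * x / 100), numeric(1))
  setNames(c(ix, vx), c(paste0("I", dec), paste0("V", dec)))
}

#' Morphological features of the ROI mask
#'
#' Volume, surface area and derived compactness descriptors of the binary
#' mask in physical units. Surface area is estimated mesh-free via the
#' coarea formula: the mask indicator is smoothed with a half-voxel
#' Gaussian and the gradient magnitude is integrated over the volume,
#' which is accurate to a few percent on digitised convex bodies (erring
#' on the overestimate side, so sphericity respects its upper bound).
#' Maximum diameter is the largest pairwise distance between surface voxel
#' centres.
#'
#' @param patch an [roi_patch()].
#' @return Named numeric vector: `volume`, `surface_area`,
#'   `surface_to_volume`, `sphericity`, `compactness1`, `compactness2`,
#'   `max_diameter`. Units mm^3, mm^2, 1/mm, unitless x3, mm.
#' @export
shape_features <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  sp <- patch$spacing
  vol <- patch$n_voxels * prod(sp)
  A <- mask_surface_area(patch$mask, sp)
  # capped at 1: voxelised volume/area conventions can nudge a digitised
  # sphere past the continuum isoperimetric bound
  sph <- min(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / A)
  surf <- surface_voxels(patch$mask)
  coords <- sweep(surf - 1, 2, sp, `*`)
  maxd <- if (nrow(coords) > 1L) max(dist(coords)) else max(sp)
  maxd <- max(maxd, max(sp))
  c(volume = vol, surface_area = A, surface_to_volume = A / vol,
    sphericity = sph,
    compactness1 = vol / (sqrt(pi) * A^1.5),
    compactness2 = sph^3,   # algebraically 36*pi*vol^2/A^3 under the cap
    max_diameter = maxd)
}

# indicator-gradient surface area estimate (coarea formula); the mask is
# zero-padded so faces on the patch boundary are counted
mask_surface_area <- function(mask, spacing) {
  pad <- 4L
  d <- dim(mask) + 2L * pad
  ind <- array(0, d)
  ind[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
      pad + seq_len(dim(mask)[3])] <- as.numeric(mask)
  sm <- ind
  for (a in 1:3) {
    sigma_vox <- 0.5  # half a voxel: slight overestimate on digitised bodies
    sm <- conv_axis(sm, gaussian_kernel_1d(sigma_vox), a)
  }
  gsq <- array(0, d)
  for (a in 1:3) {
    fwd <- shift_vec <- rep(0L, 3); shift_vec[a] <- 1L
    plus <- shift_array(sm, shift_vec)
    minus <- shift_array(sm, -shift_vec)
    g <- (plus - minus) / (2 * spacing[a])
    g[is.na(g)] <- 0
    gsq <- gsq + g^2
  }
  sum(sqrt(gsq)) * prod(spacing)
}

# voxel indices (1-based, rows) of mask voxels with an exposed 6-face
surface_voxels <- function(mask) {
  exposed <- array(FALSE, dim(mask))
  for (a in 1:3) for (s in c(-1L, 1L)) {
    o <- rep(0L, 3); o[a] <- s
    nb <- shift_array(array(as.numeric(mask), dim(mask)), o)
    exposed <- exposed | (mask & (is.na(nb) | nb == 0))
  }
  which(exposed, arr.ind = TRUE)
}

#' The 33 intensity and shape features
#'
#' Concatenates the 16-statistic summary of the raw in-mask intensities
#' (prefix `Intensity_`), the 10 intensity-volume histogram features
#' (prefix `IVH_`) and the 7 shape features (prefix `Shape_`).
#'
#' @param patch an [roi_patch()].
#' @param bins histogram bins for the statistic set.
#' @return Named numeric vector of length 33.
#' @export
intensity_shape_block <- function(patch, bins = 64L) {
  stopifnot(inherits(patch, "roi_patch"))
  s <- stat_set(patch$voxels, patch$mask, bins = bins)
  iv <- ivh_features(patch)
  sh <- shape_features(patch)
  setNames(c(s, iv, sh),
           c(paste0("Intensity_", names(s)), paste0("IVH_", names(iv)),
             paste0("Shape_", names(sh))))
}
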