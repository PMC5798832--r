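# Laws texture-energy, one-level Haar wavelet, and Laplacian-of-Gaussian
# filter banks. Each bank produces per-voxel responses on the ROI patch
# (out-of-mask voxels infilled with the nearest in-mask value first, mirror
# boundary conditions) which are then summarised in-mask by stat_set().

laws_1d <- list(L = c(1, 2, 1),    # level (local average)
                E = c(-1, 0, 1),   # edge  (first difference)
                S = c(-1, 2, -1))  # spot  (second difference)

#' Laws 3D kernel identifiers
#'
#' The 27 three-letter combinations over \{L, E, S\} (level, edge, spot).
#' Letter k of the id names the 1D kernel applied along axis k.
#'
#' @return Character vector of 27 ids, `"LLL"` first.
#' @export
laws_ids <- function() {
  lt <- c("L", "E", "S")
  as.vector(vapply(lt, function(a)
    vapply(lt, function(b) paste0(a, b, lt), character(3)), character(9)))
}

#' Apply a Laws 3D texture-energy filter
#'
#' Convolves the patch with the separable outer product of the length-3
#' Laws kernels L3 = (1,2,1), E3 = (-1,0,1), S3 = (-1,2,-1), one per axis in
#' id order. Out-of-mask voxels are infilled with the nearest in-mask value
#' before filtering; borders are mirror-padded.
#'
#' @param patch an [roi_patch()].
#' @param id one of [laws_ids()], e.g. `"LSL"`.
#' @return A `filter_response`: list with `filter_id`, `voxels` (response,
#'   same geometry), `mask`, `spacing`.
#' @export
laws_filter <- function(patch, id) {
  stopifnot(inherits(patch, "roi_patch"))
  letters3 <- strsplit(id, "")[[1]]
  if (length(letters3) != 3L || !all(letters3 %in% names(laws_1d)))
    stop("unknown Laws kernel id: ", id)
  arr <- infill_nearest(patch$voxels, patch$mask)
  resp <- separable_conv3(arr, laws_1d[[letters3[1]]],
                          laws_1d[[letters3[2]]], laws_1d[[letters3[3]]])
  filter_response(paste0("Laws_", id), resp, patch)
}

filter_response <- function(id, voxels, patch) {
  structure(list(filter_id = id, voxels = voxels, mask = patch$mask,
                 spacing = patch$spacing),
            class = "filter_response")
}

#' @export
print.filter_response <- function(x, ...) {
  cat(sprintf("<filter_response> %s, %s box\n", x$filter_id,
              paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' The 432 Laws texture features
#'
#' The 16-statistic summary of the in-mask response of each of the 27 Laws
#' kernels; names `Laws_<id>_<stat>`, including the four signature features
#' `Laws_LSL_min`, `Laws_SLL_energy`, `Laws_SSL_skewness`,
#' `Laws_EEL_uniformity`.
#'
#' @param patch an [roi_patch()].
#' @param bins histogram bins for the statistic set.
#' @return Named numeric vector of length 432 (27 x 16).
#' @export
laws_block <- function(patch, bins = 64L) {
  out <- lapply(laws_ids(), function(id) {
    r <- laws_filter(patch, id)
    s <- stat_set(r$voxels, r$mask, bins = bins)
    setNames(s, paste0("Laws_", id, "_", names(s)))
  })
  unlist(out)
}

# --- one-level 3D Haar wavelet ---------------------------------------------

# single-axis Haar analysis followed by nearest-coefficient upsampling back
# to the original length, so subbands keep the patch geometry and the ROI
# mask stays applicable
haar_axis <- function(arr, axis, highpass) {
  d <- dim(arr)
  n <- d[axis]
  i1 <- seq(1L, n, by = 2L)
  i2 <- mirror_idx(i1 + 1L, n)      # odd length: mirror the last pair
  pick <- function(idx) switch(axis,
                               arr[idx, , , drop = FALSE],
                               arr[, idx, , drop = FALSE],
                               arr[, , idx, drop = FALSE])
  a <- pick(i1); b <- pick(i2)
  coef <- if (highpass) (a - b) / sqrt(2) else (a + b) / sqrt(2)
  up <- rep(seq_along(i1), each = 2L)[seq_len(n)]
  switch(axis,
         coef[up, , , drop = FALSE],
         coef[, up, , drop = FALSE],
         coef[, , up, drop = FALSE])
}

#' One-level 3D Haar wavelet subbands
#'
#' Separable one-level discrete wavelet decomposition (orthonormal Haar)
#' along the three axes; the eight subbands are named by the per-axis
#' low/high filter (`LLL` ... `HHH`, letter k = axis k) and mapped back to
#' the patch geometry by nearest-coefficient upsampling so the ROI mask
#' applies. A constant patch of value c yields an `LLL` subband constant at
#' c * 2^(3/2) (the Haar scaling gain sqrt(2) per axis) and exact zeros in
#' every subband with at least one high-pass axis.
#'
#' @param patch an [roi_patch()].
#' @return Named list of eight `filter_response` objects.
#' @export
wavelet_subbands <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  arr <- infill_nearest(patch$voxels, patch$mask)
  bands <- list()
  for (bx in c("L", "H")) {
    ax <- haar_axis(arr, 1L, bx == "H")
    for (by in c("L", "H")) {
      axy <- haar_axis(ax, 2L, by == "H")
      for (bz in c("L", "H")) {
        nm <- paste0(bx, by, bz)
        bands[[nm]] <- filter_response(paste0("Wav_", nm),
                                       haar_axis(axy, 3L, bz == "H"), patch)
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' The 128 wavelet features
#'
#' The 16-statistic summary of each of the 8 Haar subbands; names
#' `Wav_<band>_<stat>` (e.g. `Wav_LLH_min`, `Wav_HHL_lcl_homo`).
#'
#' @param patch an [roi_patch()].
#' @param bins histogram bins for the statistic set.
#' @return Named numeric vector of length 128 (8 x 16).
#' @export
wavelet_block <- function(patch, bins = 64L) {
  bands <- wavelet_subbands(patch)
  out <- lapply(names(bands), function(nm) {
    r <- bands[[nm]]
    s <- stat_set(r$voxels, r$mask, bins = bins)
    setNames(s, paste0("Wav_", nm, "_", names(s)))
  })
  unlist(out)
}

# --- Laplacian of Gaussian -------------------------------------------------

#' Laplacian-of-Gaussian filter at a physical scale
#'
#' Band-pass blob filter: the image is convolved with the Laplacian of a 3D
#' Gaussian of standard deviation `sigma_mm`, computed in physical units
#' (the scale is converted to voxels per axis through the spacing) as the
#' sum of three separable second-derivative terms. Kernels are sampled to a
#' 3-sigma radius and corrected to zero sum, so constant and linear-ramp
#' images respond exactly zero away from borders.
#'
#' @param patch an [roi_patch()].
#' @param sigma_mm Gaussian scale in mm, > 0.
#' @return A `filter_response`.
#' @export
log_filter <- function(patch, sigma_mm) {
  stopifnot(inherits(patch, "roi_patch"))
  if (!is.finite(sigma_mm) || sigma_mm <= 0)
    stop("parameter error: sigma_mm must be > 0")
  sig <- sigma_mm / patch$spacing
  if (all(ceiling(3 * sig) < 1))
    stop("parameter error: sigma ", sigma_mm,
         " mm has sub-voxel support on every axis")
  arr <- infill_nearest(patch$voxels, patch$mask)
  g <- lapply(sig, gaussian_kernel_1d)
  resp <- array(0, dim(arr))
  for (a in 1:3) {
    k <- g
    k[[a]] <- gaussian_d2_kernel_1d(sig[a])
    resp <- resp + separable_conv3(arr, k[[1]], k[[2]], k[[3]]) /
      patch$spacing[a]^2
  }
  filter_response(paste0("LoG_s", format(sigma_mm)), resp, patch)
}

#' The 96 Laplacian-of-Gaussian features
#'
#' The 16-statistic summary of the LoG response at each scale; names
#' `LoG_s<sigma>_<stat>`. Default scales 1-6 mm span fine to coarse
#' blob structure.
#'
#' @param patch an [roi_patch()].
#' @param sigmas_mm numeric vector of scales (default `1:6` mm).
#' @param bins histogram bins for the statistic set.
#' @return Named numeric vector of length `16 * length(sigmas_mm)` (96 by
#'   default).
#' @export
log_block <- function(patch, sigmas_mm = 1:6, bins = 64L) {
  out <- lapply(sigmas_mm, function(sg) {
    r <- log_filter(patch, sg)
    s <- stat_set(r$voxels, r$mask, bins = bins)
    setNames(s, paste0("LoG_s", format(sg), "_", names(s)))
  })
  unlist(out)
}
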