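#' Image volume container
#'
#' A minimal in-memory representation of a 3D scalar image: a rank-3 array of
#' intensities (Hounsfield-unit-like values for CT) plus the physical voxel
#' spacing and origin in millimetres. Arrays are indexed `[x, y, z]`.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel pitch (dx, dy, dz) in mm; all
#'   strictly positive and finite.
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `image_volume`: a list with elements `voxels`,
#'   `spacing`, `origin`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 5))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("geometry error: 'voxels' must be a rank-3 array, got rank ",
         length(dim(voxels)))
  }
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels))) {
    stop("load error: volume contains non-finite intensities (NaN/Inf)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("geometry error: spacing must be three strictly positive finite values")
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing (%s) mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Region-of-interest patch
#'
#' A tight bounding-box crop of a volume together with the binary nodule mask
#' restricted to the same box. All feature computations consume this type and
#' use only in-mask voxels; out-of-mask voxels inside the box are never
#' bridged by voxel pairs, runs or zones.
#'
#' @param voxels 3D intensity array (the crop).
#' @param mask 3D logical array, same shape; at least one `TRUE` voxel, and
#'   the mask's bounding box must touch every face of the patch.
#' @param spacing voxel pitch in mm.
#' @return An object of class `roi_patch`: list with `voxels`, `mask`,
#'   `spacing`, `n_voxels`.
#' @seealso [extract_roi()]
#' @export
roi_patch <- function(voxels, mask, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("geometry error: patch voxels must be a rank-3 array")
  mask <- array(as.logical(mask), dim(voxels))
  if (!identical(dim(mask), dim(voxels)))
    stop("geometry error: mask shape must equal voxel shape")
  n <- sum(mask)
  if (n < 1L) stop("empty ROI")
  bb <- mask_bbox(mask)
  d <- dim(mask)
  if (any(bb[1, ] != 1L) || any(bb[2, ] != d))
    stop("geometry error: mask bounding box must touch every face (tight crop)")
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels[mask])))
    stop("load error: non-finite intensities inside the ROI")
  structure(list(voxels = voxels, mask = mask,
                 spacing = as.numeric(spacing), n_voxels = as.integer(n)),
            class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch> %s box, %d ROI voxels, spacing (%s) mm\n",
              paste(dim(x$voxels), collapse = "x"), x$n_voxels,
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

# bounding box of TRUE voxels: 2x3 matrix (min row, max row), 1-based
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  rbind(apply(idx, 2, min), apply(idx, 2, max))
}

#' Crop a volume to the mask bounding box
#'
#' Extracts the tight axis-aligned bounding box of the `TRUE` voxels of
#' `mask` from `volume`, carrying the binary mask along, so that downstream
#' feature computations see only the nodule and its immediate box.
#'
#' @param volume an [image_volume()].
#' @param mask an [image_volume()] or 3D array, same shape as `volume`;
#'   voxels with value > 0.5 are inside the ROI.
#' @return An [roi_patch()].
#' @examples
#' v <- image_volume(array(rnorm(8000), c(20, 20, 20)))
#' m <- array(FALSE, c(20, 20, 20)); m[8:12, 9:11, 10] <- TRUE
#' p <- extract_roi(v, m)
#' p$n_voxels
#' @export
extract_roi <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"))
  if (inherits(mask, "image_volume")) mask <- mask$voxels
  if (!identical(dim(mask), dim(volume$voxels)))
    stop("geometry error: mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume shape ",
         paste(dim(volume$voxels), collapse = "x"))
  mask <- array(as.numeric(mask) > 0.5, dim(mask))
  if (!any(mask)) stop("empty ROI")
  bb <- mask_bbox(mask)
  ix <- bb[1, 1]:bb[2, 1]; iy <- bb[1, 2]:bb[2, 2]; iz <- bb[1, 3]:bb[2, 3]
  roi_patch(volume$voxels[ix, iy, iz, drop = FALSE],
            mask[ix, iy, iz, drop = FALSE],
            volume$spacing)
}

#' Quantize ROI intensities to discrete gray levels
#'
#' Equal-width binning of in-mask intensities over their observed min-max
#' range into `levels` gray levels, the discretisation used by the
#' matrix-based texture features. Codes are 0-based (`0 .. levels-1`);
#' out-of-mask voxels carry `NA` as sentinel. A constant patch maps wholly
#' to code 0.
#'
#' @param patch an [roi_patch()].
#' @param levels integer number of gray levels, at least 2 (co-occurrence
#'   features default to 256).
#' @return An object of class `quantized_patch`: list with integer array
#'   `codes` (`NA` outside the mask), `mask`, `levels`, `level_edges`,
#'   `spacing`, `n_voxels`.
#' @examples
#' p <- roi_patch(array(1:27, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
#' q <- quantize(p, 4)
#' table(q$codes)
#' @export
quantize <- function(patch, levels = 256L) {
  stopifnot(inherits(patch, "roi_patch"))
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("parameter error: 'levels' must be an integer >= 2")
  v <- patch$voxels[patch$mask]
  lo <- min(v); hi <- max(v)
  codes <- array(NA_integer_, dim(patch$voxels))
  if (hi > lo) {
    width <- (hi - lo) / levels
    cd <- as.integer(floor((v - lo) / width))
    cd[cd >= levels] <- levels - 1L   # v == hi lands in the top bin
    codes[patch$mask] <- cd
    edges <- lo + width * (0:levels)
  } else {
    codes[patch$mask] <- 0L
    edges <- c(lo, hi)
  }
  structure(list(codes = codes, mask = patch$mask, levels = levels,
                 level_edges = edges, spacing = patch$spacing,
                 n_voxels = patch$n_voxels),
            class = "quantized_patch")
}

#' @export
print.quantized_patch <- function(x, ...) {
  cat(sprintf("<quantized_patch> %s box, %d levels, %d ROI voxels\n",
              paste(dim(x$codes), collapse = "x"), x$levels, x$n_voxels))
  invisible(x)
}
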