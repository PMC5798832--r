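# Separable 3D convolution with mirror boundary handling, plus the
# nearest-neighbour infill applied to out-of-mask voxels before filtering.
# These primitives back the Laws, wavelet and LoG banks.

# fold indices into [1, n] by mirror reflection without edge duplication
mirror_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  hi <- p >= n
  p[hi] <- 2L * n - 2L - p[hi]
  p + 1L
}

# correlate `arr` along `axis` with a centred 1D kernel (odd length);
# for symmetric kernels correlation equals convolution
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  k <- length(kernel)
  r <- (k - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (t in seq_len(k)) {
    if (kernel[t] == 0) next
    idx <- mirror_idx(base + (t - 1L - r), n)
    out <- out + kernel[t] * switch(axis,
                                    arr[idx, , , drop = FALSE],
                                    arr[, idx, , drop = FALSE],
                                    arr[, , idx, drop = FALSE])
  }
  out
}

separable_conv3 <- function(arr, kx, ky, kz) {
  conv_axis(conv_axis(conv_axis(arr, kx, 1L), ky, 2L), kz, 3L)
}

# shift array by integer offset, padding with NA
shift_array <- function(arr, o) {
  d <- dim(arr)
  out <- array(NA_real_, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    len <- d[a] - abs(o[a])
    if (len <= 0L) return(out)
    if (o[a] >= 0) {
      dst[[a]] <- seq_len(len)
      src[[a]] <- dst[[a]] + o[a]
    } else {
      dst[[a]] <- seq_len(len) - o[a]
      src[[a]] <- seq_len(len)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# replace out-of-mask voxels by values propagated from the mask boundary
# (iterative 6-neighbour mean propagation, a grassfire approximation to
# nearest-in-mask infill); keeps background air out of the filter responses
infill_nearest <- function(voxels, mask) {
  vals <- voxels
  vals[!mask] <- NA_real_
  if (all(mask)) return(vals)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  it_max <- sum(dim(voxels))
  for (it in seq_len(it_max)) {
    unk <- is.na(vals)
    if (!any(unk)) break
    acc <- array(0, dim(vals))
    cnt <- array(0, dim(vals))
    for (r in seq_len(nrow(offs))) {
      sh <- shift_array(vals, offs[r, ])
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + sh[ok]
      cnt <- cnt + ok
    }
    fill <- unk & cnt > 0
    vals[fill] <- acc[fill] / cnt[fill]
  }
  vals
}

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# second derivative of a Gaussian, sampled and corrected to zero sum so
# constants are annihilated exactly
gaussian_d2_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
  k - mean(k)
}
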