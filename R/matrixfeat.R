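# Run-length, size-zone, gray-tone difference and fractal features.
# All constructions exclude out-of-mask voxels: runs and zones never bridge
# a gap, and neighbourhood means use only in-mask neighbours.

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along each of the 13 unique 3D
#' directions, sums the counts over directions and normalises by the total
#' run count. Out-of-mask voxels terminate runs.
#'
#' @param q a [quantize()]d patch.
#' @param directions offset matrix, default [offsets_13()].
#' @return An object of class `rlm_matrix`: list with `counts`
#'   (levels x max-run-length), `p` (normalised), `n_runs`, `levels`,
#'   `n_directions`, `n_voxels`.
#' @export
rlm <- function(q, directions = offsets_13()) {
  stopifnot(inherits(q, "quantized_patch"))
  L <- q$levels
  d <- dim(q$codes)
  runs_lvl <- integer(0); runs_len <- integer(0)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    ch <- direction_chains(q$codes, o)
    rl <- rle(as.vector(ch))
    keep <- !is.na(rl$values)
    runs_lvl <- c(runs_lvl, rl$values[keep])
    runs_len <- c(runs_len, rl$lengths[keep])
  }
  rmax <- max(runs_len, 1L)
  counts <- matrix(0, L, rmax)
  tab <- tabulate(runs_lvl * rmax + runs_len, nbins = L * rmax)
  counts <- matrix(tab, L, rmax, byrow = TRUE)
  n_runs <- sum(counts)
  structure(list(counts = counts, p = counts / n_runs, n_runs = n_runs,
                 levels = L, n_directions = nrow(directions),
                 n_voxels = q$n_voxels),
            class = "rlm_matrix")
}

# stack all maximal voxel chains along offset `o` into a matrix with an NA
# separator row, so a single rle() pass yields within-chain runs only
direction_chains <- function(codes, o) {
  d <- dim(codes)
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3])))
  prev <- sweep(grid, 2, o, `-`)
  is_start <- prev[, 1] < 1 | prev[, 1] > d[1] |
    prev[, 2] < 1 | prev[, 2] > d[2] | prev[, 3] < 1 | prev[, 3] > d[3]
  cur <- grid[is_start, , drop = FALSE]
  max_len <- sum(abs(o) * (d - 1)) + 1L
  out <- matrix(NA_real_, max_len + 1L, nrow(cur))
  for (s in seq_len(max_len)) {
    inb <- cur[, 1] >= 1 & cur[, 1] <= d[1] & cur[, 2] >= 1 &
      cur[, 2] <= d[2] & cur[, 3] >= 1 & cur[, 3] <= d[3]
    if (!any(inb)) break
    lin <- cur[inb, 1] + (cur[inb, 2] - 1L) * d[1] +
      (cur[inb, 3] - 1L) * d[1] * d[2]
    out[s, inb] <- codes[lin]
    cur <- sweep(cur, 2, o, `+`)
  }
  out
}

#' Run-length features
#'
#' The 11 Galloway-family descriptors: SRE, LRE, GLN, RLN, RP, LGRE, HGRE,
#' SRLGE, SRHGE, LRLGE, LRHGE. Gray levels enter the emphasis weights
#' 1-based; run percentage is the run count over the number of voxels
#' scanned across all directions.
#'
#' @param m an [rlm()] result.
#' @return Named numeric vector of 11 features.
#' @export
rlm_features <- function(m) {
  stopifnot(inherits(m, "rlm_matrix"))
  p <- m$p
  iv <- seq_len(nrow(p))          # gray level value (1-based)
  jv <- seq_len(ncol(p))          # run length
  ri <- rowSums(p); cj <- colSums(p)
  I2 <- matrix(iv^2, nrow(p), ncol(p))
  J2 <- matrix(jv^2, nrow(p), ncol(p), byrow = TRUE)
  c(SRE = sum(p / J2),
    LRE = sum(p * J2),
    GLN = sum(ri^2) * m$n_runs,      # = sum(counts rowsums^2)/n_runs
    RLN = sum(cj^2) * m$n_runs,
    RP = m$n_runs / (m$n_directions * m$n_voxels),
    LGRE = sum(p / I2),
    HGRE = sum(p * I2),
    SRLGE = sum(p / (I2 * J2)),
    SRHGE = sum(p * I2 / J2),
    LRLGE = sum(p * J2 / I2),
    LRHGE = sum(p * I2 * J2))
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' the matrix counts zones by gray level and zone size.
#'
#' @param q a [quantize()]d patch.
#' @return An object of class `glszm_matrix`: list with `counts`
#'   (levels x max zone size), `p`, `n_zones`, `levels`, `n_voxels`.
#' @export
glszm <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  L <- q$levels
  d <- dim(q$codes)
  inmask <- which(!is.na(q$codes))
  node <- integer(prod(d)); node[inmask] <- seq_along(inmask)
  codes <- array(as.double(q$codes), d)
  edges <- list()
  offs <- offsets_13()
  for (r in seq_len(nrow(offs))) {
    b <- shift_array(codes, offs[r, ])
    ok <- !is.na(codes) & !is.na(b) & codes == b
    if (!any(ok)) next
    ia <- which(ok)
    o <- offs[r, ]
    ib <- ia + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    edges[[length(edges) + 1L]] <- cbind(node[ia], node[ib])
  }
  g <- igraph::make_empty_graph(n = length(inmask), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_level <- codes[inmask][match(seq_len(comp$no), comp$membership)]
  zmax <- max(zone_size)
  counts <- matrix(0, L, zmax)
  tab <- tabulate(zone_level * zmax + zone_size, nbins = L * zmax)
  counts <- matrix(tab, L, zmax, byrow = TRUE)
  structure(list(counts = counts, p = counts / sum(counts),
                 n_zones = sum(counts), levels = L, n_voxels = q$n_voxels),
            class = "glszm_matrix")
}

#' Size-zone features
#'
#' The 11 size-zone analogues of the run-length descriptors: SZE, LZE, GLN,
#' ZSN, ZP, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE.
#'
#' @param m a [glszm()] result.
#' @return Named numeric vector of 11 features.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "glszm_matrix"))
  p <- m$p
  iv <- seq_len(nrow(p)); jv <- seq_len(ncol(p))
  ri <- rowSums(p); cj <- colSums(p)
  I2 <- matrix(iv^2, nrow(p), ncol(p))
  J2 <- matrix(jv^2, nrow(p), ncol(p), byrow = TRUE)
  c(SZE = sum(p / J2),
    LZE = sum(p * J2),
    GLN = sum(ri^2) * m$n_zones,
    ZSN = sum(cj^2) * m$n_zones,
    ZP = m$n_zones / m$n_voxels,
    LGZE = sum(p / I2),
    HGZE = sum(p * I2),
    SZLGE = sum(p / (I2 * J2)),
    SZHGE = sum(p * I2 / J2),
    LZLGE = sum(p * J2 / I2),
    LZHGE = sum(p * I2 * J2))
}

#' Neighbourhood gray-tone difference table
#'
#' For each gray level, the occurrence probability and the summed absolute
#' deviation of its voxels from the mean of their 26-neighbourhood
#' (in-mask neighbours only; voxels without any in-mask neighbour are
#' excluded).
#'
#' @param q a [quantize()]d patch.
#' @return An object of class `ngtdm_table`: list with `level` (1-based
#'   value), `p`, `s`, `n_valid`.
#' @export
ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  L <- q$levels
  d <- dim(q$codes)
  codes <- array(as.double(q$codes), d)
  filled <- codes; filled[is.na(filled)] <- 0
  msk <- array(as.double(!is.na(codes)), d)
  ssum <- array(0, d); scnt <- array(0, d)
  offs <- rbind(offsets_13(), -offsets_13())
  for (r in seq_len(nrow(offs))) {
    sv <- shift_array(filled, offs[r, ]); sv[is.na(sv)] <- 0
    sm <- shift_array(msk, offs[r, ]); sm[is.na(sm)] <- 0
    ssum <- ssum + sv; scnt <- scnt + sm
  }
  valid <- !is.na(codes) & scnt > 0
  dev <- abs(codes[valid] - ssum[valid] / scnt[valid])
  lv <- codes[valid] + 1          # 1-based level value
  n_i <- tabulate(lv, nbins = L)
  s_i <- as.vector(tapply(dev, factor(lv, levels = seq_len(L)), sum))
  s_i[is.na(s_i)] <- 0
  structure(list(level = seq_len(L), p = n_i / sum(n_i), s = s_i,
                 n_valid = sum(n_i)),
            class = "ngtdm_table")
}

#' Gray-tone difference features
#'
#' The five Amadasun-King regional texture descriptors: coarseness,
#' contrast, busyness, complexity, strength. The coarseness denominator is
#' guarded by epsilon = 1e-6, capping the constant-image singularity at
#' 1e6; busyness and strength are 0 in the same limit.
#'
#' @param t an [ngtdm()] result.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(t) {
  stopifnot(inherits(t, "ngtdm_table"))
  eps <- 1e-6
  act <- t$p > 0
  i <- t$level[act]; p <- t$p[act]; s <- t$s[act]
  N <- t$n_valid; Ng <- length(i)
  ps <- sum(p * s)
  coarseness <- min(1 / max(ps, eps), 1 / eps)
  if (Ng > 1) {
    DI <- outer(i, i, `-`)
    PP <- outer(p, p)
    contrast <- sum(PP * DI^2) / (Ng * (Ng - 1)) * sum(s) / N
    ip <- i * p
    denom_b <- sum(abs(outer(ip, ip, `-`)))
    busyness <- if (denom_b > 0) ps / denom_b else 0
    PSi <- outer(p * s, p * s, `+`)
    Psum <- outer(p, p, `+`)
    complexity <- sum(abs(DI) * PSi / Psum) / N
    strength <- sum(Psum * DI^2) / (eps + sum(s))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Box-counting fractal-dimension features
#'
#' Thresholds the in-mask intensities at eight fractions (10% ... 80%) of
#' the intensity range and estimates the box-counting dimension of each
#' binary set from a least-squares fit of log N(eps) against log(1/eps)
#' over box sizes \{2, 4, 8, 16\} voxels (clipped to the patch size; the
#' patch is zero-padded to at least 4 voxels per axis). An empty
#' thresholded set has dimension 0 by convention.
#'
#' @param patch an [roi_patch()].
#' @return Named numeric vector `FD_t10` ... `FD_t80`.
#' @export
fractal_features <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  v <- patch$voxels[patch$mask]
  mn <- min(v); rng <- max(v) - mn
  d0 <- dim(patch$mask)
  d <- pmax(d0, 4L)
  sizes <- c(2L, 4L, 8L, 16L)
  sizes <- sizes[sizes <= max(d)]
  fracs <- seq(0.1, 0.8, by = 0.1)
  out <- vapply(fracs, function(f) {
    thr <- mn + f * rng
    set <- array(FALSE, d)
    set[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <-
      patch$mask & patch$voxels >= thr
    idx <- which(set, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(0)
    counts <- vapply(sizes, function(eps) {
      box <- floor((idx - 1L) / eps)
      nrow(unique(box))
    }, numeric(1))
    fit <- lm(log(counts) ~ log(1 / sizes))
    max(0, unname(coef(fit)[2]))
  }, numeric(1))
  setNames(out, paste0("FD_t", round(fracs * 100)))
}
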