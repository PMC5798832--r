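# Independent brute-force oracles. Deliberately written as plain triple
# loops / flood fills, sharing no code path with the package internals.

# mirror-reflected index (no edge duplication), scalar
o_mirror <- function(i, n) {
  if (n == 1L) return(1L)
  p <- (i - 1L) %% (2L * n - 2L)
  if (p >= n) p <- 2L * n - 2L - p
  p + 1L
}

# full 3D correlation with an explicit kernel array, mirror boundary
oracle_conv3 <- function(arr, k3d) {
  d <- dim(arr)
  kd <- dim(k3d)
  r <- (kd - 1L) %/% 2L
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    s <- 0
    for (a in seq_len(kd[1])) for (b in seq_len(kd[2])) for (cc in seq_len(kd[3])) {
      s <- s + k3d[a, b, cc] *
        arr[o_mirror(x + a - 1L - r[1], d[1]),
            o_mirror(y + b - 1L - r[2], d[2]),
            o_mirror(z + cc - 1L - r[3], d[3])]
    }
    out[x, y, z] <- s
  }
  out
}

in_bounds <- function(v, d) all(v >= 1L) && all(v <= d)

# symmetrised pair-count GLCM over the given offsets
oracle_glcm <- function(codes, levels, offsets = offsets_13(), distance = 1L) {
  d <- dim(codes)
  M <- matrix(0, levels, levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    ci <- codes[x, y, z]
    if (is.na(ci)) next
    for (r in seq_len(nrow(offsets))) {
      u <- c(x, y, z) + offsets[r, ] * distance
      if (!in_bounds(u, d)) next
      cj <- codes[u[1], u[2], u[3]]
      if (is.na(cj)) next
      M[ci + 1, cj + 1] <- M[ci + 1, cj + 1] + 1
      M[cj + 1, ci + 1] <- M[cj + 1, ci + 1] + 1
    }
  }
  M / sum(M)
}

# run-length counts by walking every maximal line voxel by voxel
oracle_rlm <- function(codes, levels, offsets = offsets_13()) {
  d <- dim(codes)
  runs <- list()
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (in_bounds(c(x, y, z) - o, d)) next   # not a line start
      pos <- c(x, y, z)
      cur <- NA; len <- 0L
      while (in_bounds(pos, d)) {
        cd <- codes[pos[1], pos[2], pos[3]]
        if (!is.na(cd) && !is.na(cur) && cd == cur) {
          len <- len + 1L
        } else {
          if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
          cur <- cd; len <- if (is.na(cd)) 0L else 1L
        }
        pos <- pos + o
      }
      if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
    }
  }
  rm_mat <- do.call(rbind, runs)
  rmax <- max(rm_mat[, 2])
  counts <- matrix(0, levels, rmax)
  for (i in seq_len(nrow(rm_mat)))
    counts[rm_mat[i, 1] + 1, rm_mat[i, 2]] <-
      counts[rm_mat[i, 1] + 1, rm_mat[i, 2]] + 1
  counts
}

# 26-connected equal-code zones by breadth-first flood fill
oracle_zones <- function(codes) {
  d <- dim(codes)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nz <- 0L
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(codes[x, y, z]) || lab[x, y, z] > 0L) next
    nz <- nz + 1L
    queue <- list(c(x, y, z))
    lab[x, y, z] <- nz
    size <- 0L
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (r in seq_len(nrow(nb))) {
        u <- v + nb[r, ]
        if (!in_bounds(u, d)) next
        if (is.na(codes[u[1], u[2], u[3]]) || lab[u[1], u[2], u[3]] > 0L) next
        if (codes[u[1], u[2], u[3]] != codes[x, y, z]) next
        lab[u[1], u[2], u[3]] <- nz
        queue[[length(queue) + 1L]] <- u
      }
    }
    zones[[nz]] <- c(level = codes[x, y, z], size = size)
  }
  do.call(rbind, zones)
}

# per-level occurrence probability and summed 26-neighbourhood deviation
oracle_ngtdm <- function(codes, levels) {
  d <- dim(codes)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  n_i <- numeric(levels); s_i <- numeric(levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    ci <- codes[x, y, z]
    if (is.na(ci)) next
    vals <- c()
    for (r in seq_len(nrow(nb))) {
      u <- c(x, y, z) + nb[r, ]
      if (!in_bounds(u, d)) next
      cu <- codes[u[1], u[2], u[3]]
      if (!is.na(cu)) vals <- c(vals, cu)
    }
    if (length(vals) == 0L) next
    n_i[ci + 1] <- n_i[ci + 1] + 1
    s_i[ci + 1] <- s_i[ci + 1] + abs(ci - mean(vals))
  }
  list(p = n_i / sum(n_i), s = s_i, n_valid = sum(n_i))
}

# per-voxel equal-width binning, written with cut() rather than floor()
oracle_quantize <- function(v, lo, hi, levels) {
  if (hi <= lo) return(rep(0L, length(v)))
  br <- seq(lo, hi, length.out = levels + 1)
  as.integer(cut(v, breaks = br, include.lowest = TRUE, right = FALSE)) - 1L
}

# greedy forward selection re-implemented with its own LOOCV loop
oracle_greedy_sfs <- function(X, y, candidates, k) {
  loo <- function(cols) {
    hits <- 0L
    for (i in seq_len(nrow(X))) {
      tr <- X[-i, cols, drop = FALSE]
      mu <- colMeans(tr); sg <- apply(tr, 2, stats::sd); sg[sg == 0] <- 1
      fit <- e1071::svm(x = scale(tr, mu, sg), y = factor(y[-i]),
                        kernel = "linear", cost = 1, scale = FALSE)
      pr <- predict(fit, matrix((X[i, cols] - mu) / sg, nrow = 1))
      if (as.character(pr) == y[i]) hits <- hits + 1L
    }
    hits / nrow(X)
  }
  sel <- character(0)
  for (s in seq_len(k)) {
    pool <- setdiff(candidates, sel)
    accs <- sapply(pool, function(f) loo(c(sel, f)))
    sel <- c(sel, pool[which.max(accs)])
  }
  sel
}

# small random patch with an irregular mask (always >= 2 in-mask voxels)
random_patch <- function(dim3, p_mask = 0.85, seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(dim3)), dim3)
  repeat {
    m <- array(runif(prod(dim3)) < p_mask, dim3)
    if (sum(m) >= max(2, prod(dim3) * 0.3)) break
  }
  # tighten the box so roi_patch accepts it
  idx <- which(m, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  v <- v[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
         drop = FALSE]
  m <- m[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
         drop = FALSE]
  roi_patch(v, m)
}
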