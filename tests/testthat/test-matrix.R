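fixture_q <- function(name, levels) {
  fx <- fixture_microvolumes()[[name]]
  quantize(roi_patch(fx$voxels, fx$mask), levels)
}

test_that("micro-fixtures match their documented definitions", {
  fx <- fixture_microvolumes()
  expect_equal(fx$constant4$voxels, array(5, c(4, 4, 4)))
  expect_equal(dim(fx$checker221$voxels), c(2, 2, 1))
  expect_equal(fx$checker221$voxels[, , 1], rbind(c(0, 1), c(1, 0)))
  expect_equal(fx$run331$voxels[, 2, 1], c(1, 1, 1))
  expect_equal(sum(!fx$masked333$mask), 2)
})

test_that("GLCM on fixtures equals brute-force pair counting", {
  # constant cube: all mass at P(0,0)
  qc <- fixture_q("constant4", 4)
  mc <- glcm(qc)
  expect_equal(mc$probabilities[1, 1], 1)
  expect_equal(sum(mc$probabilities), 1)
  # checkerboard, in-plane axis directions only: pure off-diagonal mass
  qk <- fixture_q("checker221", 2)
  mk <- glcm(qk, directions = rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(mk$probabilities,
               rbind(c(0, 0.5), c(0.5, 0)))
  # all 13 directions vs oracle, on every fixture and a random patch
  for (nm in c("checker221", "run331", "masked333")) {
    q <- fixture_q(nm, 4)
    expect_equal(glcm(q)$probabilities, oracle_glcm(q$codes, 4), info = nm)
  }
  pr <- random_patch(c(4, 4, 4), seed = 21)
  qr <- quantize(pr, 5)
  expect_equal(glcm(qr)$probabilities, oracle_glcm(qr$codes, 5))
  # degenerate: single voxel has no pair
  p1 <- roi_patch(array(1, c(1, 1, 1)), array(TRUE, c(1, 1, 1)))
  expect_error(glcm(quantize(p1, 2)), "degenerate ROI")
})

test_that("GLCM features match direct summation formulas", {
  # identity-like matrix: perfect diagonal
  L <- 4
  m_id <- structure(list(probabilities = diag(L) / L, levels = L),
                    class = "glcm_matrix")
  f_id <- glcm_features(m_id)
  expect_equal(f_id[["contrast"]], 0)
  expect_equal(f_id[["homogeneity"]], 1)
  expect_equal(f_id[["energy"]], 1 / L)
  expect_equal(f_id[["entropy"]], log2(L))
  # single entry
  m1 <- structure(list(probabilities = matrix(c(1, 0, 0, 0), 2, 2),
                       levels = 2L), class = "glcm_matrix")
  f1 <- glcm_features(m1)
  expect_equal(f1[["energy"]], 1)
  expect_equal(f1[["entropy"]], 0)
  expect_equal(f1[["maximum_probability"]], 1)
  # random probability matrix vs naive double loops
  set.seed(3)
  P <- matrix(runif(16), 4, 4); P <- (P + t(P)); P <- P / sum(P)
  f <- glcm_features(structure(list(probabilities = P, levels = 4L),
                               class = "glcm_matrix"))
  cont <- diss <- auto <- 0
  for (i in 1:4) for (j in 1:4) {
    cont <- cont + (i - j)^2 * P[i, j]
    diss <- diss + abs(i - j) * P[i, j]
    auto <- auto + i * j * P[i, j]
  }
  expect_equal(f[["contrast"]], cont)
  expect_equal(f[["dissimilarity"]], diss)
  expect_equal(f[["autocorrelation"]], auto)
  mu <- sum((1:4) * rowSums(P))
  expect_equal(f[["joint_average"]], mu)
  expect_equal(f[["joint_variance"]],
               sum(outer((1:4 - mu)^2, rep(1, 4)) * P))
  expect_length(f, 26)
})

test_that("run-length matrix equals the line-walking oracle", {
  # a 1x1x3 constant line: one run of 3 along the z direction
  pz <- roi_patch(array(2, c(1, 1, 3)), array(TRUE, c(1, 1, 3)))
  qz <- quantize(pz, 2)
  mz <- rlm(qz, directions = rbind(c(0, 0, 1)))
  expect_equal(mz$counts[1, 3], 1)
  expect_equal(mz$n_runs, 1)
  # all-distinct codes: every run has length 1
  pd <- roi_patch(array(1:8, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  qd <- quantize(pd, 8)
  fd <- rlm_features(rlm(qd))
  expect_equal(fd[["SRE"]], 1)
  # oracle equivalence on fixtures and random patches
  for (nm in c("checker221", "run331", "masked333")) {
    q <- fixture_q(nm, 4)
    o <- oracle_rlm(q$codes, 4)
    m <- rlm(q)
    expect_equal(m$counts, o, info = nm)
  }
  qr <- quantize(random_patch(c(4, 3, 4), seed = 31), 4)
  expect_equal(rlm(qr)$counts, oracle_rlm(qr$codes, 4))
})

test_that("reversing gray-level order row-reverses the RLM and swaps emphases", {
  qr <- quantize(random_patch(c(4, 4, 3), seed = 32), 6)
  L <- qr$levels
  rev_codes <- (L - 1L) - qr$codes
  q2 <- qr; q2$codes <- rev_codes
  m1 <- rlm(qr); m2 <- rlm(q2)
  expect_equal(m2$counts, m1$counts[L:1, , drop = FALSE])
  # the reflected matrix reproduces the emphasis pair computed directly
  f2 <- rlm_features(m2)
  p1 <- m1$p
  w_rev <- (L - seq_len(L) + 1L)^2
  expect_equal(f2[["LGRE"]], sum(sweep(p1, 1, w_rev, `/`)))
  expect_equal(f2[["HGRE"]], sum(sweep(p1, 1, w_rev, `*`)))
})

test_that("size zones are 26-connected equal-code components", {
  # constant patch: a single zone of n_voxels
  qc <- fixture_q("constant4", 4)
  mc <- glszm(qc)
  expect_equal(mc$n_zones, 1)
  expect_equal(mc$counts[1, 64], 1)
  # two disjoint same-code blobs
  v <- array(0, c(5, 1, 1)); v[c(1, 2, 5)] <- 9
  p <- roi_patch(v, array(TRUE, c(5, 1, 1)))
  q <- quantize(p, 2)
  m <- glszm(q)
  expect_equal(m$counts[2, 2], 1)  # blob {1,2}
  expect_equal(m$counts[2, 1], 1)  # blob {5}
  expect_equal(m$counts[1, 2], 1)  # gap {3,4}
  # conservation + oracle on fixtures and random patches
  for (nm in c("checker221", "run331", "masked333")) {
    q <- fixture_q(nm, 4)
    m <- glszm(q)
    o <- oracle_zones(q$codes)
    expect_equal(sum(m$counts %*% seq_len(ncol(m$counts))), q$n_voxels)
    expect_equal(m$n_zones, nrow(o), info = nm)
    for (r in seq_len(nrow(o)))
      expect_gte(m$counts[o[r, "level"] + 1, o[r, "size"]], 1)
  }
  qr <- quantize(random_patch(c(4, 4, 4), seed = 33), 3)
  mr <- glszm(qr)
  or <- oracle_zones(qr$codes)
  oc <- matrix(0, qr$levels, max(or[, "size"]))
  for (r in seq_len(nrow(or)))
    oc[or[r, "level"] + 1, or[r, "size"]] <- oc[or[r, "level"] + 1,
                                                or[r, "size"]] + 1
  expect_equal(mr$counts, oc)
  expect_equal(sum(mr$counts %*% seq_len(ncol(mr$counts))), qr$n_voxels)
})

test_that("gray-tone difference table matches the neighbourhood oracle", {
  # constant patch: zero deviations, capped coarseness, zero busyness
  qc <- fixture_q("constant4", 4)
  fc <- ngtdm_features(ngtdm(qc))
  expect_equal(fc[["coarseness"]], 1e6)
  expect_equal(fc[["busyness"]], 0)
  expect_length(fc, 5)
  # one deviant voxel in a constant cube: hand-computable deviation
  v <- array(0, c(3, 3, 3)); v[2, 2, 2] <- 10
  p <- roi_patch(v, array(TRUE, c(3, 3, 3)))
  q <- quantize(p, 2)
  t1 <- ngtdm(q)
  # centre voxel: 26 neighbours all 0 -> deviation 1; corner/edge voxels
  # include the deviant centre
  o <- oracle_ngtdm(q$codes, 2)
  expect_equal(t1$p, o$p)
  expect_equal(t1$s, o$s)
  expect_equal(t1$s[2], 1)  # the deviant voxel deviates by exactly its code
  # oracle equivalence on fixtures and a random patch
  for (nm in c("checker221", "run331", "masked333")) {
    q <- fixture_q(nm, 4)
    tt <- ngtdm(q); oo <- oracle_ngtdm(q$codes, 4)
    expect_equal(tt$p, oo$p, info = nm)
    expect_equal(tt$s, oo$s, info = nm)
  }
  qr <- quantize(random_patch(c(4, 4, 3), seed = 34), 4)
  tr <- ngtdm(qr); orc <- oracle_ngtdm(qr$codes, 4)
  expect_equal(tr$p, orc$p)
  expect_equal(tr$s, orc$s)
  expect_equal(sum(tr$p), 1)
})

test_that("box-counting dimension is near 3 for solid sets, 8 features total", {
  # solid cube: every thresholded set at or below the minimum keeps all voxels
  p <- roi_patch(array(rnorm(16^3, 100, 1), c(16, 16, 16)),
                 array(TRUE, c(16, 16, 16)))
  fd <- fractal_features(p)
  expect_length(fd, 8)
  expect_named(fd, paste0("FD_t", seq(10, 80, by = 10)))
  # low thresholds keep nearly the full cube: dimension close to 3
  expect_gt(fd[["FD_t10"]], 2.8)
  expect_lt(fd[["FD_t10"]], 3.2)
  expect_true(all(is.finite(fd)))
})

test_that("full feature vector matches the registry inventory", {
  p <- random_patch(c(6, 6, 6), seed = 41)
  cfg <- radiomics_config()
  fv <- full_feature_vector(p, cfg)
  reg <- feature_registry(cfg)
  expect_length(fv, 750)
  expect_identical(names(fv), reg$feature)
  counts <- table(reg$category)
  expect_equal(unname(counts[c("intensity_shape", "log", "wavelet", "laws",
                               "glcm", "rlm", "glszm", "ngtdm", "fractal")]),
               structure(c(33L, 96L, 128L, 432L, 26L, 11L, 11L, 5L, 8L),
                         class = "table"), ignore_attr = TRUE)
  # constant patch: every degenerate-limit convention keeps features finite
  pc <- roi_patch(array(7, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  fvc <- full_feature_vector(pc, cfg)
  expect_true(all(is.finite(fvc)))
  expect_length(fvc, 750)
})
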