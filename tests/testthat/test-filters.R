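const_patch <- function(value = 3, d = c(4, 4, 4)) {
  roi_patch(array(value, d), array(TRUE, d))
}

test_that("Laws kernels annihilate or amplify constants as expected", {
  pc <- const_patch(3)
  for (id in c("ELL", "SLS", "EES", "LSE")) {
    r <- laws_filter(pc, id)
    expect_equal(max(abs(r$voxels)), 0, info = id)
  }
  rl <- laws_filter(pc, "LLL")
  expect_equal(as.vector(rl$voxels), rep(3 * 64, 64))  # (sum L3)^3 = 4^3
  expect_error(laws_filter(pc, "LXQ"), "unknown Laws kernel")
})

test_that("Laws responses equal the explicit triple-loop convolution", {
  k1 <- list(L = c(1, 2, 1), E = c(-1, 0, 1), S = c(-1, 2, -1))
  set.seed(5)
  arr <- array(rnorm(125), c(5, 5, 5))
  p <- roi_patch(arr, array(TRUE, c(5, 5, 5)))
  for (id in c("LLL", "LSL", "EEL", "SSS", "ESL")) {
    lt <- strsplit(id, "")[[1]]
    k3d <- outer(outer(k1[[lt[1]]], k1[[lt[2]]]), k1[[lt[3]]])
    expect_equal(laws_filter(p, id)$voxels, oracle_conv3(arr, k3d),
                 tolerance = 1e-12, info = id)
  }
})

test_that("axis permutation of patch and kernel id commute", {
  set.seed(6)
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  p <- roi_patch(arr, array(TRUE, c(4, 5, 6)))
  # swap axes 1 and 3: id letters swap the same way
  arr2 <- aperm(arr, c(3, 2, 1))
  p2 <- roi_patch(arr2, array(TRUE, dim(arr2)))
  s1 <- stat_set(laws_filter(p, "LSE")$voxels, p$mask)
  s2 <- stat_set(laws_filter(p2, "ESL")$voxels, p2$mask)
  expect_equal(s1, s2)
})

test_that("laws_block yields the 432 named features with signature names", {
  p <- random_patch(c(5, 5, 5), seed = 7)
  b <- laws_block(p)
  expect_length(b, 432)
  expect_true(all(c("Laws_LSL_min", "Laws_SLL_energy", "Laws_SSL_skewness",
                    "Laws_EEL_uniformity") %in% names(b)))
  # constant patch: EEL response is identically zero, so uniformity is 1
  expect_equal(laws_block(const_patch())[["Laws_EEL_uniformity"]], 1)
})

test_that("Haar subbands: high-pass kills constants, LLL carries the gain", {
  pc <- const_patch(2, c(4, 4, 4))
  sb <- wavelet_subbands(pc)
  expect_named(sb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_equal(max(abs(sb$HHH$voxels)), 0)
  expect_equal(max(abs(sb$LHL$voxels)), 0)
  expect_equal(as.vector(sb$LLL$voxels), rep(2 * 2^(3 / 2), 64))
  # orthonormal Haar on a hand-computed 2x1x1 pair: the x pair combines as
  # (a+-b)/sqrt(2); each singleton axis contributes the sqrt(2) scaling gain
  p2 <- roi_patch(array(c(3, 1), c(2, 1, 1)), array(TRUE, c(2, 1, 1)))
  sb2 <- wavelet_subbands(p2)
  expect_equal(as.vector(sb2$LLL$voxels), rep((3 + 1) / sqrt(2) * 2, 2))
  expect_equal(as.vector(sb2$HLL$voxels), rep((3 - 1) / sqrt(2) * 2, 2))
})

test_that("wavelet_block yields 128 features with subband-statistic names", {
  p <- random_patch(c(4, 4, 4), seed = 8)
  b <- wavelet_block(p)
  expect_length(b, 128)
  expect_true(all(c("Wav_LLH_min", "Wav_HHL_lcl_homo") %in% names(b)))
})

test_that("LoG responds zero to constants and affine ramps", {
  pc <- const_patch(5, c(7, 7, 7))
  r <- log_filter(pc, 1.5)
  expect_lt(max(abs(r$voxels)), 1e-10)
  ramp <- array(rep(seq_len(9), each = 1), c(9, 9, 9))
  ramp <- aperm(ramp, c(1, 2, 3)) + 0  # x-ramp
  pr <- roi_patch(ramp, array(TRUE, c(9, 9, 9)))
  rr <- log_filter(pr, 1)
  core <- rr$voxels[4:6, 4:6, 4:6]
  expect_lt(max(abs(core)), 1e-8)
  expect_error(log_filter(pc, -1), "parameter error")
})

test_that("LoG equals direct convolution with the sampled kernel", {
  set.seed(9)
  arr <- array(rnorm(343), c(7, 7, 7))
  p <- roi_patch(arr, array(TRUE, c(7, 7, 7)), spacing = c(1, 1, 1))
  sigma <- 1.2
  g <- exp(-(-4:4)^2 / (2 * sigma^2)); g <- g / sum(g)
  d2 <- ((-4:4)^2 - sigma^2) / sigma^4 * g; d2 <- d2 - mean(d2)
  k3d <- outer(outer(d2, g), g) + outer(outer(g, d2), g) +
    outer(outer(g, g), d2)
  expect_equal(log_filter(p, sigma)$voxels, oracle_conv3(arr, k3d),
               tolerance = 1e-6)
})

test_that("log_block yields 96 features over the six default scales", {
  p <- random_patch(c(5, 5, 5), seed = 10)
  b <- log_block(p)
  expect_length(b, 96)
  expect_true(all(c("LoG_s1_min", "LoG_s6_lcl_homo") %in% names(b)))
  # determinism
  expect_identical(b, log_block(random_patch(c(5, 5, 5), seed = 10)))
})

test_that("phantom heterogeneity raises Laws spot-edge energy (rank test)", {
  energy_ees <- function(amp, seed) {
    sp <- phantom_spec(if (amp > 0) "malignant" else "benign",
                       diameter_mm = 12, spacing_mm = c(1.5, 1.5, 1.5),
                       noise_sd = 5, heterogeneity_amp = amp, seed = seed)
    ph <- generate_phantom(sp)
    p <- extract_roi(ph$volume, ph$mask)
    r <- laws_filter(p, "EES")
    sum(r$voxels[r$mask]^2)
  }
  e0 <- vapply(1:20, function(s) energy_ees(0, 100 + s), numeric(1))
  e1 <- vapply(1:20, function(s) energy_ees(30, 200 + s), numeric(1))
  e2 <- vapply(1:20, function(s) energy_ees(60, 300 + s), numeric(1))
  expect_lt(median(e0), median(e1))
  expect_lt(median(e1), median(e2))
  expect_lt(wilcox.test(e0, e2, alternative = "less")$p.value, 0.05)
})
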