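sep_table <- function(n_per_class = 6, n_noise = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  tibble::tibble(case_id = paste0("c", seq_len(n)),
                 label = rep(c("benign", "malignant"), each = n_per_class)) |>
    dplyr::bind_cols(tibble::as_tibble(
      matrix(rnorm(n * n_noise), n,
             dimnames = list(NULL, paste0("noise_", seq_len(n_noise)))))) |>
    dplyr::mutate(strong = rep(c(0, 10), each = n_per_class) + rnorm(n, sd = 0.1))
}

test_that("a perfectly predictive feature is selected first", {
  tbl <- sep_table(seed = 2)
  sig <- sfs_select(tbl, c(paste0("noise_", 1:4), "strong"), k = 2)
  expect_equal(sig$features[1], "strong")
  expect_equal(sig$accuracy[1], 1)
  expect_length(sig$features, 2)
  expect_error(sfs_select(tbl, character(0), k = 1), "no candidate")
  expect_error(sfs_select(tbl, "strong", k = 0), "parameter error")
  expect_error(sfs_select(tbl, "strong", k = 3), "exceeds")
})

test_that("greedy selection path matches an independent frontier oracle", {
  tbl <- simulate_feature_table(n_per_class = 6, n_signal = 2, n_noise = 4,
                                effect = 1.5, seed = 13)
  ftv <- setdiff(names(tbl), c("case_id", "label"))
  X <- as.matrix(tbl[ftv])
  sig <- sfs_select(tbl, ftv, k = 3)
  oracle <- oracle_greedy_sfs(X, tbl$label, ftv, k = 3)
  expect_identical(sig$features, oracle)
})

test_that("LOOCV evaluation aggregates confusion counts correctly", {
  tbl <- sep_table(seed = 3)
  ev <- loocv_evaluate(tbl, "strong")
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$tp + ev$tn + ev$fp + ev$fn, nrow(tbl))
  g <- glance(ev)
  expect_equal(g$accuracy, (g$tp + g$tn) / nrow(tbl))
  td <- tidy(ev)
  expect_true(all(td$correct))
  # the worked metric arithmetic: 39/42 and 24/33 correct
  m <- classification_metrics(tp = 39, fn = 3, tn = 24, fp = 9)
  expect_equal(m$accuracy, 84)
  expect_equal(m$sensitivity, 92.857, tolerance = 1e-4)
  expect_equal(m$specificity, 72.727, tolerance = 1e-4)
})

test_that("label shuffling drives accuracy to the majority-class rate", {
  set.seed(4)
  accs <- vapply(1:10, function(i) {
    n <- 16
    tbl <- tibble::tibble(case_id = paste0("c", 1:n),
                          label = sample(rep(c("benign", "malignant"), n / 2)),
                          f = rnorm(n))
    loocv_evaluate(tbl, "f")$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("held-out cases never influence their own fold parameters", {
  tbl <- sep_table(seed = 5)
  ev1 <- loocv_evaluate(tbl, c("strong", "noise_1"))
  tbl2 <- tbl
  tbl2$strong[3] <- tbl2$strong[3] + 50   # perturb one case only
  tbl2$noise_1[3] <- -99
  ev2 <- loocv_evaluate(tbl2, c("strong", "noise_1"))
  # fold 3 trains without case 3: its standardisation must be unchanged
  expect_identical(ev1$fold_params[[3]], ev2$fold_params[[3]])
  # other folds do see case 3
  expect_false(identical(ev1$fold_params[[1]], ev2$fold_params[[1]]))
})

test_that("random-signature baseline is seeded and near chance on noise", {
  tbl <- simulate_feature_table(n_per_class = 8, n_signal = 0, n_noise = 12,
                                effect = 0, seed = 21)
  cand <- paste0("noise_", 1:12)
  b1 <- random_signature_baseline(tbl, cand, size = 4, n_perm = 5, seed = 77)
  b2 <- random_signature_baseline(tbl, cand, size = 4, n_perm = 5, seed = 77)
  expect_identical(b1$accuracies, b2$accuracies)
  expect_equal(nrow(tidy(b1)), 5)
  b3 <- random_signature_baseline(tbl, cand, size = 4, n_perm = 1, seed = 3)
  expect_length(b3$accuracies$accuracy, 1)
  # pure-noise candidates, balanced classes: mean accuracy near 50%
  tbl2 <- simulate_feature_table(n_per_class = 10, n_signal = 0,
                                 n_noise = 20, effect = 0, seed = 31)
  bl <- random_signature_baseline(tbl2, paste0("noise_", 1:20), size = 4,
                                  n_perm = 50, seed = 1)
  expect_lt(abs(bl$mean_accuracy - 0.5), 0.12)
  expect_error(random_signature_baseline(tbl2, "noise_1"), "fewer candidates")
})

test_that("all-features baseline reports a full evaluation", {
  tbl <- sep_table(seed = 6)
  ev <- all_features_baseline(tbl, c("strong", paste0("noise_", 1:4)))
  expect_s3_class(ev, "radiomics_eval")
  expect_equal(ev$tp + ev$tn + ev$fp + ev$fn, nrow(tbl))
})

test_that("signature tidiers expose steps and configuration", {
  tbl <- sep_table(seed = 7)
  sig <- sfs_select(tbl, c("strong", paste0("noise_", 1:3)), k = 2)
  td <- tidy(sig)
  expect_equal(td$step, 1:2)
  expect_equal(td$feature, sig$features)
  g <- glance(sig)
  expect_equal(g$k, 2L)
  expect_equal(g$svm_kernel, "linear")
})
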