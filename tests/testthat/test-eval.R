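test_that("Cohen's kappa matches its closed forms", {
  y <- rep(c("L", "R"), each = 50)
  expect_equal(cohen_kappa(y, y), 1)

  # balanced binary with symmetric errors: kappa = 2a - 1
  n <- 7000
  y_true <- rep(c("L", "R"), each = n / 2)
  n_err <- round((1 - 0.9571) * n / 2)   # same errors in each class
  y_pred <- y_true
  y_pred[seq_len(n_err)] <- "R"
  y_pred[n / 2 + seq_len(n_err)] <- "L"
  a <- mean(y_true == y_pred)
  expect_equal(a, 0.9571, tolerance = 1e-4)
  expect_equal(cohen_kappa(y_true, y_pred), 2 * a - 1, tolerance = 1e-12)
  expect_equal(cohen_kappa(y_true, y_pred), 0.9142, tolerance = 5e-4)

  # anti-correlated predictions on balanced data
  y_anti <- ifelse(y == "L", "R", "L")
  expect_equal(cohen_kappa(y, y_anti), -1)

  # constant classifier on balanced data: chance agreement, kappa 0
  expect_equal(cohen_kappa(y, rep("L", 100)), 0)

  expect_error(cohen_kappa(rep("L", 10), rep("L", 10)), "undefined")
  expect_error(cohen_kappa(y, y[1:10]), "length")
})

test_that("the paired t-test matches a permutation oracle", {
  set.seed(25)
  a <- rnorm(10, mean = 0.85, sd = 0.05)
  b <- a - rnorm(10, mean = 0.03, sd = 0.04)
  res <- paired_ttest(a, b)
  expect_length(res$t, 1)
  expect_true(res$p > 0 && res$p < 1)

  # sign-flip permutation oracle on the differences
  d <- a - b
  t_obs <- mean(d) / (sd(d) / sqrt(length(d)))
  n_perm <- 10000
  set.seed(26)
  t_perm <- replicate(n_perm, {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    ds <- d * s
    mean(ds) / (sd(ds) / sqrt(length(ds)))
  })
  p_perm <- mean(abs(t_perm) >= abs(t_obs))
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / n_perm) + 2 / n_perm
  expect_lt(abs(res$p - p_perm), max(mc_err, 0.02))

  # constant difference with tiny jitter: p tends to zero
  set.seed(27)
  a2 <- rnorm(8); b2 <- a2 + 0.5 + rnorm(8, sd = 1e-4)
  expect_lt(paired_ttest(a2, b2)$p, 1e-10)

  expect_error(paired_ttest(a, a), "zero variance")
  expect_error(paired_ttest(a, b[1:3]), "length")
})

test_that("cross-validation is deterministic and leakage-free in structure", {
  ts <- quick_dataset(n_per_class = 8, seed = 9)
  cfg <- quick_config()
  dc <- mi_decompose(ts, cfg)

  cv1 <- cross_validate(ts, cfg, k = 4, repeats = 2, seed = 3,
                        decompositions = dc)
  cv2 <- cross_validate(ts, cfg, k = 4, repeats = 2, seed = 3,
                        decompositions = dc)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(dim(cv1$accuracy), c(4, 2))
  expect_true(all(cv1$accuracy >= 0 & cv1$accuracy <= 1))

  expect_error(cross_validate(ts, cfg, k = 10), "fewer trials")
})

test_that("the concatenation baseline uses the summed feature dimension", {
  ts <- quick_dataset(n_per_class = 6, seed = 10)
  cfg <- quick_config()
  fit <- mi_decoder(ts, cfg, method = "fdm")
  # 3 branches x 2 pairs x 2 = 12 concatenated features
  expect_equal(ncol(fit$fdm_model$svm$SV), 12)
  pr <- predict(fit, ts)
  expect_true(all(pr$decision %in% c("L", "R")))
  expect_gt(mean(pr$decision == as.character(ts$labels)), 0.5)
})
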