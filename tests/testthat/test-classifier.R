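sep_data <- function(n = 40, gap = 8, seed = 19) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n), n, 2)
  y <- factor(rep(c("L", "R"), each = n / 2), levels = c("L", "R"))
  X[y == "L", 1] <- X[y == "L", 1] + gap
  list(X = X, y = y)
}

test_that("the calibrated SVM separates, reproduces and calibrates", {
  d <- sep_data()
  m <- train_prob_svm(d$X, d$y, kernel = "linear", seed = 3)
  p <- predict_prob(m, d$X)
  expect_equal(mean(ifelse(p[, "P_L"] >= 0.5, "L", "R") == d$y), 1)
  expect_lt(m$N_sv, m$l / 2)   # few support vectors on separable data

  # determinism: identical sigmoid and support count across runs
  m2 <- train_prob_svm(d$X, d$y, kernel = "linear", seed = 3)
  expect_identical(c(m$A, m$B, m$N_sv), c(m2$A, m2$B, m2$N_sv))

  # Monte-Carlo calibration oracle: known class posterior 0.8
  set.seed(20)
  n <- 500
  x <- sample(c(-1, 1), n, replace = TRUE)
  lab <- factor(ifelse(runif(n) < ifelse(x > 0, 0.8, 0.2), "L", "R"),
                levels = c("L", "R"))
  X <- cbind(x + rnorm(n, sd = 0.1), rnorm(n))
  mc <- train_prob_svm(X, lab, seed = 4)
  pc <- predict_prob(mc, X)
  expect_lt(abs(mean(pc[x > 0, "P_L"]) - 0.8), 0.1)
  expect_lt(abs(mean(pc[x < 0, "P_L"]) - 0.2), 0.1)

  expect_error(train_prob_svm(d$X, factor(rep("L", 40),
                                          levels = c("L", "R"))),
               "2 samples per class")
})

test_that("probabilities complement and follow the fitted sigmoid", {
  d <- sep_data()
  m <- train_prob_svm(d$X, d$y, kernel = "linear", seed = 5)

  # far on the L side of a separable linear margin: saturated probability
  far <- matrix(c(30, 0), 1)
  expect_gt(predict_prob(m, far)[, "P_L"], 0.99)

  # closed-form consistency: P_L = plogis(B + A * decision value)
  dv <- mifuse:::oriented_dv(m$svm, d$X)
  expect_equal(unname(predict_prob(m, d$X)[, "P_L"]),
               unname(pmin(pmax(plogis(m$B + m$A * dv), 1e-7), 1 - 1e-7)),
               tolerance = 1e-12)

  set.seed(21)
  Xr <- matrix(rnorm(2000), 1000, 2)
  p <- predict_prob(m, Xr)
  expect_equal(unname(p[, "P_L"] + p[, "P_R"]), rep(1, 1000),
               tolerance = 1e-12)
})

test_that("basic probability assignments discount by the support ratio", {
  # direct substitution
  m <- bpa_from_prob(0.5, 0.5, 2, 10)
  expect_equal(mass_to_vec(m), c(L = 0.4, R = 0.4, Theta = 0.2))

  # certain class, fully supported model
  m1 <- bpa_from_prob(1, 0, 1, 1e9)
  expect_equal(mass_to_vec(m1), c(L = 1, R = 0, Theta = 0), tolerance = 1e-8)

  # algebraic inversion oracle: recover a published-style BPA row exactly
  u <- 0.1188
  p_l <- 0.5985 / (1 - u)
  m2 <- bpa_from_prob(p_l, 1 - p_l, u * 1e4, 1e4)
  expect_equal(unname(mass_to_vec(m2)), c(0.5985, 0.2827, 0.1188),
               tolerance = 1e-12)

  # normalization is exact and Theta is monotone in N_sv / l
  set.seed(22)
  thetas <- c()
  for (i in 1:50) {
    p <- runif(1)
    nsv <- sample(1:99, 1)
    mm <- bpa_from_prob(p, 1 - p, nsv, 100)
    expect_equal(sum(mass_to_vec(mm)), 1)
    expect_equal(mm$m_l / max(mm$m_r, 1e-300), p / max(1 - p, 1e-300),
                 tolerance = 1e-9)
  }
  u_grid <- seq(0.05, 0.95, by = 0.05)
  th <- vapply(u_grid, function(u)
    bpa_from_prob(0.6, 0.4, round(u * 1e4), 1e4)$m_theta, 0)
  expect_true(all(diff(th) > 0))

  expect_warning(mf <- bpa_from_prob(0.7, 0.3, 10, 10), "uninformative")
  expect_equal(mf$m_theta, 1)
  expect_error(bpa_from_prob(0.7, 0.3, 11, 10), "exceeds")
  expect_error(bpa_from_prob(0.7, 0.2, 1, 10), "equal 1")
})
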