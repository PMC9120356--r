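test_that("class covariances are symmetric PSD averages", {
  set.seed(14)
  data <- array(rnorm(6 * 4 * 50), c(6, 4, 50))
  labels <- factor(rep(c("L", "R"), 3), levels = c("L", "R"))

  cv <- class_covariances(data, labels)
  for (C in cv) {
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }

  # single trial per class: covariance equals the trial's (normalized) XX'
  d1 <- data[1:2, , , drop = FALSE]
  cv1 <- class_covariances(d1, factor(c("L", "R"), levels = c("L", "R")),
                           trace_norm = FALSE)
  X <- d1[1, , ]; X <- X - rowMeans(X)
  expect_equal(cv1$C1, tcrossprod(X), tolerance = 1e-12)

  # literal vs trace-normalized mode differ by per-trial scalars only:
  # recompute the normalized average directly
  cvn <- class_covariances(data, labels, trace_norm = TRUE)
  direct <- matrix(0, 4, 4)
  for (i in which(labels == "L")) {
    X <- data[i, , ]; X <- X - rowMeans(X)
    C <- tcrossprod(X)
    direct <- direct + C / sum(diag(C))
  }
  expect_equal(cvn$C1, direct / 3, tolerance = 1e-12)

  expect_error(class_covariances(data, factor(rep("L", 6),
                                              levels = c("L", "R"))),
               "both classes")
})

test_that("CSP filters solve the generalized eigenproblem", {
  # indistinguishable classes: all eigenvalues 1
  I4 <- diag(4)
  f_id <- fit_csp(I4, I4, m_pairs = 2)
  expect_equal(f_id$eigvals, rep(1, 4), tolerance = 1e-10)

  # diagonal pencil closed form
  f_d <- fit_csp(diag(c(2, 1)), diag(c(1, 2)), m_pairs = 1)
  expect_equal(sort(f_d$eigvals), c(0.5, 2), tolerance = 1e-10)
  expect_equal(abs(f_d$W), diag(2)[, c(1, 2)], tolerance = 1e-8)

  # random SPD pair: simultaneous diagonalization oracle
  set.seed(15)
  C1 <- random_spd(8); C2 <- random_spd(8)
  f <- fit_csp(C1, C2, m_pairs = 2)
  expect_equal(unname(colSums(f$W^2)), rep(1, 4), tolerance = 1e-12)
  for (C in list(C1, C2)) {
    M <- t(f$W) %*% C %*% f$W
    offdiag <- M - diag(diag(M))
    expect_lt(max(abs(offdiag)), 1e-8 * max(abs(M)))
  }
  # the full-eigendecomposition oracle agrees on the eigenvalues
  lam_oracle <- sort(Re(eigen(solve(C2, C1))$values))
  expect_equal(sort(f$eigvals),
               lam_oracle[c(1, 2, 7, 8)], tolerance = 1e-8)

  # label swap inverts the spectrum
  f_sw <- fit_csp(C2, C1, m_pairs = 2)
  expect_equal(sort(f_sw$eigvals), sort(1 / f$eigvals), tolerance = 1e-8)

  expect_error(fit_csp(C1, C2, m_pairs = 5), "exceeds")
})

test_that("projection is linear and features are scale-free", {
  set.seed(16)
  W <- fit_csp(random_spd(5), random_spd(5), m_pairs = 2)
  X <- matrix(rnorm(5 * 40), 5); Y <- matrix(rnorm(5 * 40), 5)

  # selection filter reproduces a channel
  sel <- matrix(0, 5, 1); sel[3, 1] <- 1
  expect_equal(apply_csp(X, sel), X[3, , drop = FALSE] * 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_equal(apply_csp(2 * X + 3 * Y, W),
               2 * apply_csp(X, W) + 3 * apply_csp(Y, W), tolerance = 1e-10)
  expect_error(apply_csp(X[1:3, ], W), "channels")

  Z <- apply_csp(X, W)
  f <- csp_features(Z)
  expect_length(f, 4)
  expect_equal(sum(exp(f)), 1, tolerance = 1e-9)
  expect_equal(csp_features(7 * Z), f, tolerance = 1e-9)

  # equal row variances: all features log(1/2m)
  Zeq <- matrix(rep(rnorm(100), 4), nrow = 4, byrow = TRUE)
  expect_equal(csp_features(Zeq), rep(log(1 / 4), 4), tolerance = 1e-9)
})

test_that("projected variances order with the eigenvalues on matched data", {
  set.seed(17)
  p <- 6
  A1 <- diag(c(4, 3, 1, 1, 0.5, 0.25)); A2 <- diag(rev(diag(A1)))
  gen <- function(A, n) {
    X <- array(0, c(n, p, 80))
    for (i in 1:n) X[i, , ] <- t(chol(A)) %*% matrix(rnorm(p * 80), p)
    X
  }
  XL <- gen(A1, 30); XR <- gen(A2, 30)
  data <- array(0, c(60, p, 80))
  data[1:30, , ] <- XL; data[31:60, , ] <- XR
  labels <- factor(rep(c("L", "R"), each = 30), levels = c("L", "R"))
  cv <- class_covariances(data, labels, trace_norm = FALSE)
  f <- fit_csp(cv$C1, cv$C2, m_pairs = 1)
  # first filter maximizes L-variance ratio, last minimizes it
  vl <- apply(apply_csp(data[1, , ], f), 1, var)
  vr <- apply(apply_csp(data[31, , ], f), 1, var)
  expect_gt(vl[1] / vr[1], 1)
  expect_lt(vl[2] / vr[2], 1)
})

test_that("Fisher scores measure separation and ignore affine shifts", {
  set.seed(18)
  f_l <- matrix(rnorm(200), 100); f_r <- matrix(rnorm(200), 100)
  labels <- factor(rep(c("L", "R"), each = 100), levels = c("L", "R"))

  # identical distributions: score near 0 (exactly 0 for identical samples)
  same <- rbind(f_l, f_l)
  expect_equal(fisher_score(same, labels)$aggregate, 0)

  # exact closed form: unit variances, means 0 and 1 -> FS = 0.5
  z <- as.numeric(scale(rnorm(100)))   # sample mean 0, sd 1 exactly
  feat <- matrix(c(z, z + 1), ncol = 1)
  expect_equal(fisher_score(feat, labels)$per_feature[[1]], 0.5,
               tolerance = 1e-12)

  # common affine transform cancels
  both <- rbind(f_l, f_r)
  fs1 <- fisher_score(both, labels)$per_feature
  fs2 <- fisher_score(3 * both + 5, labels)$per_feature
  expect_equal(fs1, fs2, tolerance = 1e-10)

  expect_error(fisher_score(rbind(f_l * 0, f_l * 0), labels), "degenerate")
})
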