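test_that("EMD reconstructs additively and resolves constructed mixtures", {
  fs <- 250
  set.seed(7)
  x <- tone(10, fs, 4) + 0.5 * tone(2, fs, 4) + 0.1 * rnorm(1000)
  e <- emd(x)
  recon <- colSums(e$imfs) + e$residual
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-10)

  # single-mode signal: first IMF is the signal
  p <- tone(10, fs, 2)
  expect_gt(cor(emd(p)$imfs[1, ], p), 0.99)

  # constructed two-tone mixture with known truth
  hi <- tone(20, fs, 4); lo <- tone(2, fs, 4)
  e2 <- emd(hi + lo)
  expect_gt(cor(e2$imfs[1, ], hi), 0.95)
  expect_gt(cor(e2$imfs[2, ], lo), 0.95)

  # monotone input: no IMFs, identity residual
  m <- emd(seq(0, 1, length.out = 100))
  expect_equal(nrow(m$imfs), 0)
  expect_equal(m$residual, seq(0, 1, length.out = 100))
})

test_that("IMFs satisfy the mode criteria", {
  # clean two-mode mixture: the mode criteria are exact properties of
  # well-resolved IMFs (the noise-dominated first IMF of a noisy signal only
  # satisfies them approximately under the standard sifting stop)
  x <- tone(18, 250, 4) + 0.7 * tone(6, 250, 4)
  e <- emd(x)
  expect_gt(nrow(e$imfs), 1)
  for (k in 1:2) {
    imf <- e$imfs[k, ]
    zc <- sum(abs(diff(sign(imf))) == 2)            # strict zero crossings
    ds <- sign(diff(imf)); ds <- ds[ds != 0]
    n_ext <- sum(diff(ds) != 0)                     # turning points
    expect_lte(abs(zc - n_ext), 2)

    # local mean near zero relative to the IMF amplitude
    up <- spline(which(diff(sign(diff(imf))) < 0) + 1,
                 imf[which(diff(sign(diff(imf))) < 0) + 1],
                 xout = seq_along(imf))$y
    lo <- spline(which(diff(sign(diff(imf))) > 0) + 1,
                 imf[which(diff(sign(diff(imf))) > 0) + 1],
                 xout = seq_along(imf))$y
    core <- 50:(length(imf) - 50)
    expect_lt(mean(abs((up + lo)[core] / 2)), 0.25 * sd(imf))
  }
  # ordered from high to low characteristic frequency
  zcr <- apply(e$imfs, 1, function(v) mean(abs(diff(sign(v))) > 0))
  expect_true(all(diff(zcr[1:min(3, length(zcr))]) <= 0.01))
})

test_that("ensemble EMD degenerates, averages and reproduces", {
  set.seed(9)
  x <- tone(10, 250, 2) + 0.2 * rnorm(500)

  # noiseless single-member ensemble is plain EMD
  e0 <- feemd(x, noise_coeff = 0, n_ensembles = 1)
  e1 <- emd(x)
  expect_identical(e0$imfs, e1$imfs)

  # bit-identical under a fixed seed
  a <- feemd(x, 0.2, 8, seed = 4)
  b <- feemd(x, 0.2, 8, seed = 4)
  expect_identical(a, b)

  # each realization reconstructs x + added noise exactly, so the ensemble
  # reconstruction error is the mean of the noise: sd = coeff * sd(x) / sqrt(E)
  for (ne in c(5, 20)) {
    fe <- feemd(x, 0.2, ne, seed = 5)
    err <- colSums(fe$imfs) + fe$residual - x
    expect_lt(sd(err), 2 * 0.2 * sd(x) / sqrt(ne))
    expect_gt(sd(err), 0.2 * 0.2 * sd(x) / sqrt(ne))
  }
  expect_error(feemd(x, noise_coeff = -0.1), "noise_coeff")
})

test_that("IMF selection keeps the leading modes", {
  imfs <- matrix(rnorm(50), nrow = 10)
  expect_equal(select_imfs(imfs, 3), imfs[1:3, ])
  expect_warning(out <- select_imfs(imfs, 0), "no IMFs")
  expect_equal(nrow(out), 0)
  expect_error(select_imfs(imfs[1:2, ], 3), "available")
})
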