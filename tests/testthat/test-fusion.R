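test_that("Dempster combination matches brute-force enumeration", {
  a <- mass_function(0.6, 0.2, 0.2)
  ab <- ds_combine(a, a)
  oracle <- brute_force_ds(mass_to_vec(a), mass_to_vec(a))
  expect_equal(mass_to_vec(ab), oracle, tolerance = 1e-12)

  # exhaustive 0.05 mass grid for two masses
  grid <- seq(0, 1, by = 0.05)
  for (l1 in grid) for (r1 in grid[grid <= 1 - l1 + 1e-12]) {
    m1 <- mass_function(l1, min(r1, 1 - l1))
    for (l2 in c(0.15, 0.6)) {
      m2 <- mass_function(l2, 0.25)
      v1 <- mass_to_vec(m1); v2 <- mass_to_vec(m2)
      k <- 1 - (v1[["L"]] * v2[["R"]] + v1[["R"]] * v2[["L"]])
      if (k <= 0) next
      expect_equal(mass_to_vec(ds_combine(m1, m2)),
                   brute_force_ds(v1, v2), tolerance = 1e-12)
    }
  }
})

test_that("the vacuous mass is neutral and total conflict is an error", {
  vac <- mass_function(0, 0, 1)
  m <- mass_function(0.55, 0.25, 0.2)
  expect_equal(mass_to_vec(ds_combine(vac, m)), mass_to_vec(m),
               tolerance = 1e-12)
  expect_error(ds_combine(mass_function(1, 0, 0), mass_function(0, 1, 0)),
               "total conflict")
})

test_that("three-way fusion sharpens the winner and shrinks uncertainty", {
  s <- list(mass_function(0.4999, 0.0501, 0.4500),
            mass_function(0.5985, 0.2827, 0.1188),
            mass_function(0.4578, 0.2109, 0.3313))
  fr <- ds_combine_all(s)
  expect_equal(round(mass_to_vec(fr$fused), 4),
               c(L = 0.8269, R = 0.1450, Theta = 0.0282))
  expect_identical(fr$decision, "L")
  expect_true(fr$confident)

  # an input trio that mis-sums has Theta recompleted, and fusion can
  # overturn a 2-of-3 vote
  expect_warning(m1 <- mass_function(0.4617, 0.0883, 0.045), "completing")
  s2 <- list(m1, mass_function(0.3918, 0.4894),
             mass_function(0.2927, 0.3761))
  fr2 <- ds_combine_all(s2)
  expect_equal(round(mass_to_vec(fr2$fused), 4),
               c(L = 0.5408, R = 0.4241, Theta = 0.0351))
  expect_identical(fr2$decision, "L")
  expect_true(fr2$confident)

  # order invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    fp <- ds_combine_all(s[perm])
    expect_equal(mass_to_vec(fp$fused), mass_to_vec(fr$fused),
                 tolerance = 1e-12)
  }
})

test_that("decision rules accept only confident, low-uncertainty winners", {
  # rounded (4-decimal) fused masses mis-sum by 1e-4 and are recompleted
  d1 <- decide(suppressWarnings(mass_function(0.8269, 0.1450, 0.0282)))
  expect_identical(d1$decision, "L"); expect_true(d1$confident)

  d2 <- decide(suppressWarnings(mass_function(0.5408, 0.4241, 0.0351)))
  expect_identical(d2$decision, "L"); expect_true(d2$confident)

  # rule 3 violated: Theta mass at or above eps2
  d3 <- decide(mass_function(0.45, 0.35, 0.20))
  expect_identical(d3$decision, "L"); expect_false(d3$confident)

  # tie falls back to L, not confident at eps1 = 0
  d4 <- decide(mass_function(0.45, 0.45, 0.10))
  expect_identical(d4$decision, "L"); expect_false(d4$confident)
})

test_that("fusion never increases the Theta mass (random masses)", {
  set.seed(23)
  n_bad <- 0
  for (i in 1:10000) {
    v <- runif(3); v <- v / sum(v)
    w <- runif(3); w <- w / sum(w)
    ma <- mass_function(v[1], v[2], v[3])
    mb <- mass_function(w[1], w[2], w[3])
    mc <- ds_combine(ma, mb)
    expect_equal(sum(mass_to_vec(mc)), 1, tolerance = 1e-12)
    if (mc$m_theta > min(ma$m_theta, mb$m_theta) + 1e-12) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("classifier BPAs always satisfy the fusion preconditions", {
  set.seed(24)
  for (i in 1:200) {
    p <- runif(1, 1e-6, 1 - 1e-6)
    m <- bpa_from_prob(p, 1 - p, sample(1:49, 1), 50)
    v <- mass_to_vec(m)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1)
    d <- decide(m)
    expect_true(d$decision %in% c("L", "R"))
  }
})
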