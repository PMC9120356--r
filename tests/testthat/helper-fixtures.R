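# shared fixtures: all data is generated in code at test time

tone <- function(freq, fs, dur, phase = 0) {
  sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

# a light configuration for pipeline-level tests: small EMD ensemble and a
# short delay search keep individual tests fast without changing the
# pipeline's structure
quick_config <- function(...) {
  mi_config(feemd_ensembles = 4, max_tau = 8, ...)
}

quick_dataset <- function(n_per_class = 10, seed = 2, erd_depth = 0.6,
                          snr_db = 0) {
  generate_mi_dataset(n_per_class = n_per_class, fs = 128, duration_s = 2,
                      erd_depth = erd_depth, snr_db = snr_db, seed = seed)
}

# random symmetric positive definite matrix
random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.1
}

# independent brute-force Dempster combination for the 2-singleton frame:
# enumerate all 9 intersection products
brute_force_ds <- function(a, b) {
  sets <- list(L = "L", R = "R", Theta = c("L", "R"))
  out <- c(L = 0, R = 0, Theta = 0)
  conflict <- 0
  for (i in names(sets)) for (j in names(sets)) {
    inter <- intersect(sets[[i]], sets[[j]])
    w <- a[[i]] * b[[j]]
    if (length(inter) == 0) conflict <- conflict + w
    else if (length(inter) == 2) out[["Theta"]] <- out[["Theta"]] + w
    else out[[inter]] <- out[[inter]] + w
  }
  out / (1 - conflict)
}

mass_to_vec <- function(m) c(L = m$m_l, R = m$m_r, Theta = m$m_theta)
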