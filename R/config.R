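#' Decoding pipeline configuration
#'
#' Collects every tunable parameter of the decoding pipeline. Defaults follow
#' the standard few-channel motor-imagery configuration: 8-30 Hz 5th-order
#' Butterworth band-pass; db4 wavelet packets at depth 3 (sampling rates up to
#' 160 Hz) or 4 (above), keeping the 4 highest-energy in-band nodes per
#' channel; ensemble EMD with noise coefficient 0.2, 40 ensemble members and
#' up to 10 IMFs, keeping the first 3; local mean decomposition keeping the
#' first 2 product functions; embedding dimensions 2/2/3 for the WPT/EEMD/LMD
#' branches with the delay chosen by the C-C method on training trials; 2 CSP
#' filter pairs per branch; RBF-SVM with C = 1; and fusion decision thresholds
#' `eps1 = 0`, `eps2 = 0.1`.
#'
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order.
#' @param apply_filter band-pass the trials inside [mi_decoder()]; set to
#'   `FALSE` for data that is already band-limited to `band`.
#' @param wavelet wavelet name for the WPT branch.
#' @param wpt_depth decomposition depth, or `NULL` to choose 3/4 by sampling
#'   rate.
#' @param wpt_k wavelet packet nodes kept per channel.
#' @param feemd_noise,feemd_ensembles,feemd_max_imfs ensemble-EMD parameters.
#' @param n_imfs IMFs kept per channel.
#' @param n_pfs product functions kept per channel.
#' @param pf_corr_floor diagnostic correlation floor for kept PFs.
#' @param d named embedding dimensions per branch.
#' @param max_tau largest delay examined by the C-C method.
#' @param tau_trials,tau_channels caps on the training trials / component
#'   channels entering the per-branch delay estimate (median over channels).
#' @param m_pairs CSP filter pairs per branch.
#' @param trace_norm trace-normalize per-trial covariances.
#' @param svm_cost,svm_gamma SVM hyperparameters (`NULL` gamma = heuristic
#'   `1/(n_features * mean feature variance)`).
#' @param calib_folds folds for sigmoid calibration.
#' @param eps1,eps2 fusion decision thresholds.
#' @param seed base seed for all stochastic steps (ensemble noise, fold
#'   assignment).
#' @return object of class `mi_config`.
#' @export
mi_config <- function(band = c(8, 30), filter_order = 5, apply_filter = TRUE,
                      wavelet = "db4", wpt_depth = NULL, wpt_k = 4,
                      feemd_noise = 0.2, feemd_ensembles = 40,
                      feemd_max_imfs = 10, n_imfs = 3, n_pfs = 2,
                      pf_corr_floor = 0.1,
                      d = c(wpt = 2, feemd = 2, lmd = 3),
                      max_tau = 20, tau_trials = 2, tau_channels = 6,
                      m_pairs = 2, trace_norm = TRUE,
                      svm_cost = 1, svm_gamma = NULL, calib_folds = 5,
                      eps1 = 0, eps2 = 0.1, seed = 1) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            filter_order >= 1, wpt_k >= 1, feemd_noise >= 0,
            feemd_ensembles >= 1, n_imfs >= 1, n_pfs >= 1,
            all(c("wpt", "feemd", "lmd") %in% names(d)),
            max_tau >= 1, m_pairs >= 1, svm_cost > 0,
            eps1 >= 0, eps2 > 0)
  structure(as.list(environment()), class = "mi_config")
}

#' @export
print.mi_config <- function(x, ...) {
  cat("<mi_config>\n")
  cat("  band-pass:", x$band[1], "-", x$band[2], "Hz, order", x$filter_order,
      if (x$apply_filter) "(applied)" else "(assumed done)", "\n")
  cat("  WPT:", x$wavelet, "depth",
      if (is.null(x$wpt_depth)) "auto(3/4)" else x$wpt_depth,
      "keep", x$wpt_k, "| FEEMD:", x$feemd_noise, "x", x$feemd_ensembles,
      "keep", x$n_imfs, "| LMD keep", x$n_pfs, "\n")
  cat("  embedding d:", paste(names(x$d), x$d, sep = "=", collapse = " "),
      " max_tau:", x$max_tau, "\n")
  cat("  CSP pairs:", x$m_pairs, "| SVM C:", x$svm_cost,
      "| fusion eps1:", x$eps1, "eps2:", x$eps2, "| seed:", x$seed, "\n")
  invisible(x)
}

# serialize / restore a configuration (lossless JSON round trip)
#' @rdname mi_config
#' @param path file path for the JSON configuration.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, "mi_config"))
  v <- unclass(x)
  v$d <- as.list(v$d)   # keep branch names through JSON
  jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname mi_config
#' @export
read_config <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  v$d <- unlist(v$d)
  do.call(mi_config, v)
}

wpt_depth_for <- function(cfg, fs) {
  if (!is.null(cfg$wpt_depth)) cfg$wpt_depth else if (fs <= 160) 3L else 4L
}
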