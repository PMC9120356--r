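#' Decompose every trial of a set along the three time-frequency branches
#'
#' Applies the configured band-pass filter and then, per trial and channel,
#' the wavelet packet transform (all terminal nodes, with energy ratios kept
#' for later node selection), ensemble EMD (first `n_imfs` IMFs) and local
#' mean decomposition (first `n_pfs` product functions). Decomposition is a
#' per-trial operation independent of labels or of other trials, so the result
#' can be computed once and reused across cross-validation folds without
#' information leakage; the ensemble-EMD noise seed is derived from the
#' configuration seed and the trial/channel index, making the cache
#' deterministic.
#'
#' @param ts a [trial_set()].
#' @param cfg an [mi_config()].
#' @return object of class `mi_decomp` holding per-branch component tensors.
#' @export
mi_decompose <- function(ts, cfg = mi_config()) {
  stopifnot(inherits(ts, "trial_set"), inherits(cfg, "mi_config"))
  if (cfg$apply_filter)
    ts <- bandpass_trials(ts, filter_spec(cfg$band[1], cfg$band[2],
                                          cfg$filter_order))
  nt <- n_trials(ts)
  nc <- length(ts$channels)
  n <- dim(ts$data)[3]
  depth <- wpt_depth_for(cfg, ts$fs)
  nnodes <- 2^depth

  wpt_data <- array(0, c(nt, nc * nnodes, n))
  wpt_energy <- array(0, c(nt, nc, nnodes))
  feemd_data <- array(0, c(nt, nc * cfg$n_imfs, n))
  lmd_data <- array(0, c(nt, nc * cfg$n_pfs, n))
  lmd_corr <- matrix(NA_real_, nt, nc * cfg$n_pfs)
  bands <- NULL
  n_short_lmd <- 0L

  for (i in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      x <- ts$data[i, ch, ]
      w <- wpt_decompose(x, ts$fs, cfg$wavelet, depth)
      bands <- w$bands
      for (j in seq_len(nnodes))
        wpt_data[i, (ch - 1) * nnodes + j, ] <- w$nodes[[j]]
      wpt_energy[i, ch, ] <- w$energy_ratio

      fe <- feemd(x, cfg$feemd_noise, cfg$feemd_ensembles, cfg$feemd_max_imfs,
                  seed = cfg$seed + 101L * i + ch)
      imfs <- select_imfs(fe$imfs, cfg$n_imfs)
      for (j in seq_len(cfg$n_imfs))
        feemd_data[i, (ch - 1) * cfg$n_imfs + j, ] <- imfs[j, ]

      lm <- lmd(x)
      if (nrow(lm$pfs) < cfg$n_pfs) {
        # rare degenerate trial: pad with the residual so shapes stay fixed
        n_short_lmd <- n_short_lmd + 1L
        lm$pfs <- rbind(lm$pfs,
                        matrix(rep(lm$residual, cfg$n_pfs - nrow(lm$pfs)),
                               ncol = n, byrow = TRUE))
      }
      pfs <- lm$pfs[seq_len(cfg$n_pfs), , drop = FALSE]
      for (j in seq_len(cfg$n_pfs)) {
        lmd_data[i, (ch - 1) * cfg$n_pfs + j, ] <- pfs[j, ]
        lmd_corr[i, (ch - 1) * cfg$n_pfs + j] <-
          if (sd(pfs[j, ]) > 1e-300) cor(pfs[j, ], x) else 0
      }
    }
  }
  if (n_short_lmd > 0)
    warning(n_short_lmd, " trial-channel(s) yielded fewer than ", cfg$n_pfs,
            " product functions; padded with the residual")
  low_corr <- mean(abs(lmd_corr) < cfg$pf_corr_floor, na.rm = TRUE)
  structure(list(
    fs = ts$fs, n_trials = nt, n_samples = n, channels = ts$channels,
    labels = ts$labels, depth = depth,
    wpt = list(data = wpt_data, energy = wpt_energy, bands = bands,
               nnodes = nnodes),
    feemd = list(data = feemd_data, per_channel = cfg$n_imfs),
    lmd = list(data = lmd_data, per_channel = cfg$n_pfs, corr = lmd_corr,
               low_corr_frac = low_corr)),
    class = "mi_decomp")
}

#' @export
print.mi_decomp <- function(x, ...) {
  cat("<mi_decomp> ", x$n_trials, " trials @ ", x$fs, " Hz\n", sep = "")
  cat("  WPT: ", dim(x$wpt$data)[2], " node signals (depth ", x$depth,
      "), FEEMD: ", dim(x$feemd$data)[2], " IMFs, LMD: ",
      dim(x$lmd$data)[2], " PFs\n", sep = "")
  invisible(x)
}

# subset a decomposition cache by trial index
decomp_subset <- function(dc, idx) {
  out <- dc
  out$wpt$data <- dc$wpt$data[idx, , , drop = FALSE]
  out$wpt$energy <- dc$wpt$energy[idx, , , drop = FALSE]
  out$feemd$data <- dc$feemd$data[idx, , , drop = FALSE]
  out$lmd$data <- dc$lmd$data[idx, , , drop = FALSE]
  out$lmd$corr <- dc$lmd$corr[idx, , drop = FALSE]
  out$labels <- if (!is.null(dc$labels)) dc$labels[idx] else NULL
  out$n_trials <- length(idx)
  out
}

# component tensor of one branch after node selection (trials x comps x n)
branch_tensor <- function(dc, branch, wpt_sel = NULL) {
  if (branch == "wpt") {
    stopifnot(!is.null(wpt_sel))
    dc$wpt$data[, wpt_sel, , drop = FALSE]
  } else dc[[branch]]$data
}

# per-channel WPT node choice from mean training energy ratios; returns
# column indices into the stacked node tensor
select_wpt_channels <- function(dc, cfg) {
  nn <- dc$wpt$nnodes
  sel <- integer(0)
  for (ch in seq_along(dc$channels)) {
    ratios <- apply(dc$wpt$energy[, ch, , drop = FALSE], 3, mean)
    keep <- select_wpt_index(dc$wpt$bands, ratios, cfg$band, cfg$wpt_k,
                             extend = TRUE)
    sel <- c(sel, (ch - 1L) * nn + keep)
  }
  sel
}
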