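BRANCHES <- c("wpt", "feemd", "lmd")

# median C-C delay over a capped set of training trials and component
# channels of one branch tensor
estimate_branch_tau <- function(arr, cfg) {
  nt <- dim(arr)[1]; ncomp <- dim(arr)[2]; n <- dim(arr)[3]
  max_tau <- min(cfg$max_tau, floor(n / 10))
  if (max_tau < 2) return(1L)
  tr_idx <- unique(round(seq(1, nt, length.out = min(cfg$tau_trials, nt))))
  ch_idx <- unique(round(seq(1, ncomp, length.out = min(cfg$tau_channels,
                                                        ncomp))))
  taus <- c()
  for (i in tr_idx)
    for (j in ch_idx) {
      p <- tryCatch(
        suppressWarnings(cc_method(arr[i, j, ], max_tau = max_tau)),
        error = function(e) NULL)
      if (!is.null(p)) taus <- c(taus, p$tau)
    }
  if (!length(taus)) 1L else as.integer(round(median(taus)))
}

# log-variance CSP features for every trial of an embedded tensor
tensor_features <- function(emb, filters) {
  t(vapply(seq_len(dim(emb)[1]),
           function(i) csp_features(apply_csp(emb[i, , ], filters)),
           numeric(ncol(filters$W))))
}

# fit the branch machinery (selection, delay, CSP) and return features
fit_branches <- function(dc, cfg) {
  wpt_sel <- select_wpt_channels(dc, cfg)
  branches <- list()
  for (br in BRANCHES) {
    arr <- branch_tensor(dc, br, wpt_sel)
    tau <- estimate_branch_tau(arr, cfg)
    params <- embedding_params(tau, cfg$d[[br]])
    emb <- expand_bundle(arr, params)
    covs <- class_covariances(emb, dc$labels, cfg$trace_norm)
    filters <- fit_csp(covs$C1, covs$C2, cfg$m_pairs)
    branches[[br]] <- list(
      tau = tau, params = params, filters = filters, wpt_sel = wpt_sel,
      n_components = dim(arr)[2], n_embedded = dim(emb)[2],
      features = tensor_features(emb, filters))
  }
  branches
}

branch_features_newdata <- function(fit, dc) {
  lapply(stats::setNames(BRANCHES, BRANCHES), function(br) {
    b <- fit$branches[[br]]
    arr <- branch_tensor(dc, br, b$wpt_sel)
    emb <- expand_bundle(arr, b$params)
    tensor_features(emb, b$filters)
  })
}

#' Fit a few-channel motor-imagery decoder
#'
#' Trains the full decoding pipeline on a labeled [trial_set()]: band-pass
#' filtering; three parallel time-frequency decompositions (wavelet packets,
#' ensemble EMD, local mean decomposition) that expand the 3 recording
#' channels into 12 / 9 / 6 component channels; delay-coordinate phase-space
#' embedding (dimensions 2 / 2 / 3, delay chosen by the C-C method on
#' training trials) expanding those to 24 / 18 / 18 channels; common spatial
#' pattern filtering with log-variance features per branch; and one calibrated
#' RBF-SVM per branch. With `method = "ds"` (the default) each branch SVM
#' emits a basic probability assignment whose uncertainty mass is the model's
#' support-vector ratio, and test trials are classified by Dempster-Shafer
#' fusion of the three branch opinions; with `method = "fdm"` the branch
#' features are concatenated into a single calibrated SVM (the
#' feature-domain-merge baseline).
#'
#' @param x a labeled [trial_set()] with both classes present.
#' @param config an [mi_config()].
#' @param method `"ds"` (decision-level evidential fusion) or `"fdm"`
#'   (feature-level concatenation baseline).
#' @param decompositions optional precomputed [mi_decompose()] cache for `x`
#'   (labels are taken from `x`).
#' @return object of class `mi_decoder` with `print()`, `summary()`,
#'   `predict()`, `coef()` and `plot()` methods. `coef()` returns the CSP
#'   projection matrices per branch.
#' @examples
#' \donttest{
#' ts <- generate_mi_dataset(n_per_class = 12, fs = 128, duration_s = 2,
#'                           seed = 2)
#' cfg <- mi_config(feemd_ensembles = 4, max_tau = 8)
#' fit <- mi_decoder(ts, cfg)
#' fit
#' predict(fit, ts[1:4])
#' }
#' @export
mi_decoder <- function(x, config = mi_config(), method = c("ds", "fdm"),
                       decompositions = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(x, "trial_set"))
  if (is.null(x$labels)) stop("training requires labels")
  if (any(table(x$labels) < 2)) stop("need both classes with >= 2 trials")
  dc <- if (is.null(decompositions)) mi_decompose(x, config) else decompositions
  dc$labels <- x$labels
  fit <- fit_from_decomp(dc, config, method)
  fit$call <- match.call()
  fit
}

fit_from_decomp <- function(dc, config, method = "ds") {
  branches <- fit_branches(dc, config)
  models <- NULL; fdm_model <- NULL
  if (method == "ds") {
    models <- lapply(branches, function(b)
      train_prob_svm(b$features, dc$labels, cost = config$svm_cost,
                     gamma = config$svm_gamma,
                     calib_folds = config$calib_folds, seed = config$seed))
  } else {
    feat <- do.call(cbind, lapply(branches, `[[`, "features"))
    fdm_model <- train_prob_svm(feat, dc$labels, cost = config$svm_cost,
                                gamma = config$svm_gamma,
                                calib_folds = config$calib_folds,
                                seed = config$seed)
  }
  structure(list(method = method, config = config, branches = branches,
                 models = models, fdm_model = fdm_model, fs = dc$fs,
                 n_train = dc$n_trials, labels = dc$labels,
                 label_table = table(dc$labels)),
            class = "mi_decoder")
}

#' Predict motor-imagery class for new trials
#'
#' @param object a fitted [mi_decoder()].
#' @param newdata a [trial_set()] with matching channel count and sampling
#'   rate, or a precomputed [mi_decompose()] cache of one.
#' @param ... unused.
#' @return data.frame with one row per trial: `decision`, `confident`, the
#'   fused masses `m_L`, `m_R`, `m_Theta`, the discarded `conflict` mass and
#'   per-branch class-L probabilities (for `method = "fdm"`: the single
#'   model's probabilities and an argmax decision).
#' @export
predict.mi_decoder <- function(object, newdata, ...) {
  dc <- if (inherits(newdata, "mi_decomp")) newdata
        else mi_decompose(newdata, object$config)
  if (dc$fs != object$fs)
    stop("sampling rate mismatch: model ", object$fs, " Hz, data ", dc$fs)
  predict_from_decomp(object, dc)
}

predict_from_decomp <- function(object, dc) {
  feats <- branch_features_newdata(object, dc)
  nt <- dc$n_trials
  if (object$method == "fdm") {
    p <- predict_prob(object$fdm_model, do.call(cbind, feats))
    return(data.frame(decision = ifelse(p[, "P_L"] >= 0.5, "L", "R"),
                      confident = NA, m_L = p[, "P_L"], m_R = p[, "P_R"],
                      m_Theta = 0, conflict = 0))
  }
  probs <- lapply(BRANCHES, function(br)
    predict_prob(object$models[[br]], feats[[br]]))
  names(probs) <- BRANCHES
  out <- data.frame(decision = character(nt), confident = logical(nt),
                    m_L = numeric(nt), m_R = numeric(nt),
                    m_Theta = numeric(nt), conflict = numeric(nt))
  for (br in BRANCHES) out[[paste0("p_L_", br)]] <- probs[[br]][, "P_L"]
  for (i in seq_len(nt)) {
    masses <- lapply(BRANCHES, function(br) {
      m <- object$models[[br]]
      bpa_from_prob(probs[[br]][i, "P_L"], probs[[br]][i, "P_R"],
                    m$N_sv, m$l)
    })
    fr <- ds_combine_all(masses, object$config$eps1, object$config$eps2)
    out$decision[i] <- fr$decision
    out$confident[i] <- fr$confident
    out$m_L[i] <- fr$fused$m_l
    out$m_R[i] <- fr$fused$m_r
    out$m_Theta[i] <- fr$fused$m_theta
    out$conflict[i] <- fr$conflict
  }
  out
}

#' @export
print.mi_decoder <- function(x, ...) {
  cat("<mi_decoder> ", if (x$method == "ds") "evidential fusion"
      else "concatenated-feature baseline", ", trained on ", x$n_train,
      " trials (", paste(names(x$label_table), x$label_table, sep = "=",
                         collapse = ", "), ") @ ", x$fs, " Hz\n", sep = "")
  for (br in BRANCHES) {
    b <- x$branches[[br]]
    cat(sprintf("  %-5s %2d components -> %2d embedded channels (tau = %d, d = %d), %d CSP features\n",
                toupper(br), b$n_components, b$n_embedded, b$tau,
                b$params$d, ncol(b$filters$W)))
  }
  if (x$method == "ds")
    for (br in BRANCHES)
      cat(sprintf("  %-5s SVM: N_sv/l = %d/%d\n", toupper(br),
                  x$models[[br]]$N_sv, x$models[[br]]$l))
  invisible(x)
}

#' @export
summary.mi_decoder <- function(object, ...) {
  print(object)
  cat("training-feature Fisher scores (aggregate per branch):\n")
  for (br in BRANCHES) {
    fs <- fisher_score(object$branches[[br]]$features, object$labels)
    cat(sprintf("  %-5s %.4f\n", toupper(br), fs$aggregate))
  }
  invisible(object)
}

#' @export
coef.mi_decoder <- function(object, ...) {
  lapply(object$branches, function(b) b$filters$W)
}

#' Eigenvalue spectra of the fitted spatial filters
#'
#' Plots the retained generalized eigenvalues of each branch's CSP filter
#' bank; values far from 1 indicate discriminative variance ratios.
#'
#' @param x a fitted [mi_decoder()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.mi_decoder <- function(x, ...) {
  ev <- lapply(x$branches, function(b) b$filters$eigvals)
  graphics::plot(rep(seq_along(BRANCHES), each = length(ev[[1]])),
                 unlist(ev), log = "y", xaxt = "n",
                 xlab = "branch", ylab = "generalized eigenvalue", ...)
  graphics::axis(1, at = seq_along(BRANCHES), labels = toupper(BRANCHES))
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
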