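#' Cohen's kappa for binary agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` computed from the marginal label frequencies. On balanced
#' binary data this reduces to `2 * accuracy - 1`.
#'
#' @param y_true,y_pred equal-length label vectors in `{"L","R"}`.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c("L", "R"))) stop("labels must be L or R")
  po <- mean(y_true == y_pred)
  pe <- sum(vapply(c("L", "R"), function(cl)
    mean(y_true == cl) * mean(y_pred == cl), 0))
  if (abs(1 - pe) < 1e-12)
    stop("undefined kappa: a single class in both truth and prediction")
  (po - pe) / (1 - pe)
}

#' Paired t-test on per-subject performance
#'
#' Two-sided paired t-test (wrapping [stats::t.test()]) with an explicit guard
#' against zero variance of the differences, for comparing two methods'
#' per-subject accuracies.
#'
#' @param acc_a,acc_b equal-length numeric vectors (one entry per subject).
#' @return list with `t` and `p`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("length mismatch")
  if (length(acc_a) < 2) stop("need at least 2 pairs")
  d <- acc_a - acc_b
  if (sd(d) < 1e-15) stop("zero variance of paired differences")
  ht <- t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Repeated stratified cross-validation of the decoding pipeline
#'
#' Runs `repeats` rounds of stratified `k`-fold cross-validation (default the
#' 5 x 5 scheme). Every data-dependent stage — wavelet-node choice, the C-C
#' embedding delay, CSP filters and the calibrated SVMs — is re-estimated
#' inside each training fold; only the per-trial, label-free time-frequency
#' decomposition is computed once and shared across folds, which cannot leak
#' information because it never sees more than one trial at a time.
#'
#' @param ts a labeled [trial_set()].
#' @param config an [mi_config()].
#' @param k folds per repeat.
#' @param repeats repeats with reshuffled fold assignment.
#' @param seed seed for fold shuffling.
#' @param method `"ds"` or `"fdm"`, see [mi_decoder()].
#' @param decompositions optional precomputed [mi_decompose()] cache.
#' @param verbose print one line per repeat.
#' @return object of class `mi_cv`: per-fold accuracies (`k x repeats`), their
#'   mean and standard deviation, per-repeat pooled kappa values and their
#'   mean, and the pooled predictions.
#' @export
cross_validate <- function(ts, config = mi_config(), k = 5, repeats = 5,
                           seed = 1, method = c("ds", "fdm"),
                           decompositions = NULL, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(ts$labels)) stop("cross-validation requires labels")
  if (any(table(ts$labels) < k)) stop("a class has fewer trials than folds")
  dc <- if (is.null(decompositions)) mi_decompose(ts, config)
        else decompositions
  dc$labels <- ts$labels
  acc <- matrix(NA_real_, k, repeats)
  kappas <- numeric(repeats)
  pooled <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(ts$labels, k, seed + r - 1L)
    preds <- character(n_trials(ts))
    for (f in seq_len(k)) {
      tr <- which(folds != f); te <- which(folds == f)
      fit <- fit_from_decomp(decomp_subset(dc, tr), config, method)
      pr <- predict_from_decomp(fit, decomp_subset(dc, te))
      preds[te] <- pr$decision
      acc[f, r] <- mean(pr$decision == as.character(ts$labels[te]))
    }
    kappas[r] <- tryCatch(cohen_kappa(as.character(ts$labels), preds),
                          error = function(e) NA_real_)
    pooled[[r]] <- preds
    if (verbose)
      message("repeat ", r, ": accuracy ", round(mean(acc[, r]), 4),
              ", kappa ", round(kappas[r], 4))
  }
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = sd(as.vector(acc)), kappa = kappas,
                 mean_kappa = mean(kappas, na.rm = TRUE), k = k,
                 repeats = repeats, method = method,
                 labels = as.character(ts$labels), predictions = pooled),
            class = "mi_cv")
}

#' @export
print.mi_cv <- function(x, ...) {
  cat("<mi_cv> ", x$k, " x ", x$repeats, " cross-validation (",
      if (x$method == "ds") "evidential fusion" else "feature concatenation",
      ")\n", sep = "")
  cat(sprintf("  accuracy: %.2f%% +/- %.2f%%   kappa: %.3f\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy, x$mean_kappa))
  invisible(x)
}

#' Concatenated-feature fusion baseline
#'
#' Cross-validates the feature-domain-merge pipeline: the CSP feature vectors
#' of the three time-frequency branches are concatenated (4 + 4 + 4 features
#' at the default 2 filter pairs) and classified by a single calibrated SVM,
#' instead of fusing three per-branch classifier opinions. Serves as the
#' comparison arm for decision-level evidential fusion.
#'
#' @inheritParams cross_validate
#' @return an `mi_cv` object (`method = "fdm"`).
#' @export
fdm_baseline <- function(ts, config = mi_config(), k = 5, repeats = 5,
                         seed = 1, decompositions = NULL, verbose = FALSE) {
  cross_validate(ts, config, k, repeats, seed, method = "fdm",
                 decompositions = decompositions, verbose = verbose)
}
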