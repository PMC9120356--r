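# decision values oriented so that positive favours class "L" (libsvm signs
# them by order of label appearance in the training subset, not by level)
oriented_dv <- function(model, X) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (colnames(dv)[1] == "R/L") -as.numeric(dv) else as.numeric(dv)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Train a support vector machine with sigmoid probability calibration
#'
#' Fits an SVM margin classifier (via \pkg{e1071}/libsvm) and a Platt-type
#' sigmoid mapping decision values to class probabilities. To avoid the
#' optimistic calibration of in-sample decision values, the sigmoid is fitted
#' by logistic regression on decision values obtained from a deterministic
#' stratified k-fold cross-validation within the training set. The
#' support-vector count `N_sv` and the training size `l` are recorded for
#' basic-probability-assignment construction (see [bpa_from_prob()]).
#'
#' @param features trials x features numeric matrix.
#' @param labels factor (or character) of labels in `{"L","R"}`, both present.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; default `1 / (ncol * mean feature variance)`.
#' @param kernel kernel name passed to [e1071::svm()].
#' @param calib_folds folds for the calibration cross-validation.
#' @param seed seed for the fold assignment (calibration is deterministic
#'   given `seed` and the data).
#' @return object of class `prob_svm`: the fitted classifier, sigmoid
#'   coefficients `A` (slope) and `B` (intercept) of
#'   `P(L | f) = plogis(A * f + B)`, `N_sv`, and `l`.
#' @export
train_prob_svm <- function(features, labels, cost = 1, gamma = NULL,
                           kernel = "radial", calib_folds = 5, seed = 1) {
  features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features))) stop("non-finite features")
  labels <- factor(as.character(labels), levels = c("L", "R"))
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  if (is.null(gamma)) {
    fv <- mean(apply(features, 2, var))
    gamma <- if (fv > 0) 1 / (ncol(features) * fv) else 1 / ncol(features)
  }
  k <- min(calib_folds, min(table(labels)))
  folds <- stratified_folds(labels, k, seed)
  dv <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- e1071::svm(features[tr, , drop = FALSE], labels[tr], cost = cost,
                    gamma = gamma, kernel = kernel, scale = FALSE)
    dv[!tr] <- oriented_dv(m, features[!tr, , drop = FALSE])
  }
  y <- as.integer(labels == "L")
  sig <- suppressWarnings(glm(y ~ dv, family = binomial()))
  model <- e1071::svm(features, labels, cost = cost, gamma = gamma,
                      kernel = kernel, scale = FALSE)
  structure(list(svm = model, A = unname(coef(sig)[2]),
                 B = unname(coef(sig)[1]), N_sv = model$tot.nSV,
                 l = nrow(features), gamma = gamma, cost = cost),
            class = "prob_svm")
}

#' @export
print.prob_svm <- function(x, ...) {
  cat("<prob_svm> l =", x$l, " N_sv =", x$N_sv,
      " sigmoid: P(L) = plogis(", format(x$A, digits = 4), "* f +",
      format(x$B, digits = 4), ")\n")
  invisible(x)
}

#' Class probabilities from a calibrated SVM
#'
#' Maps the SVM decision value of each trial through the fitted sigmoid;
#' probabilities are clamped away from 0 and 1 (by 1e-7) and satisfy
#' `P_L + P_R = 1` exactly.
#'
#' @param model a [train_prob_svm()] fit.
#' @param features trial feature matrix (or a single feature vector).
#' @return two-column matrix with columns `P_L` and `P_R`.
#' @export
predict_prob <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  f <- oriented_dv(model$svm, features)
  p_l <- pmin(pmax(plogis(model$B + model$A * f), 1e-7), 1 - 1e-7)
  cbind(P_L = p_l, P_R = 1 - p_l)
}

#' Basic probability assignment from calibrated class probabilities
#'
#' Discounts the class probabilities by the model's support-vector ratio: with
#' `u = N_sv / l`, the masses are `m_L = P_L (1 - u)`, `m_R = P_R (1 - u)` and
#' `m_Theta = u`. The mass on the whole frame encodes how uncertain the
#' classifier itself is: a model where every training point is a support
#' vector (`u = 1`) contributes a vacuous, fully uncertain opinion.
#'
#' @param p_l,p_r class probabilities, `p_l + p_r = 1`.
#' @param n_sv support-vector count.
#' @param l training-sample count.
#' @return a [mass_function()].
#' @export
bpa_from_prob <- function(p_l, p_r, n_sv, l) {
  if (abs(p_l + p_r - 1) > 1e-9) stop("P_L + P_R must equal 1")
  if (n_sv <= 0 || l <= 0) stop("need n_sv > 0 and l > 0")
  u <- n_sv / l
  if (u > 1) stop("N_sv exceeds the training size")
  if (u == 1)
    warning("N_sv = l: model is uninformative, all mass on Theta")
  mass_function(p_l * (1 - u), p_r * (1 - u), u)
}
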