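#' Class covariance matrices for common spatial patterns
#'
#' Computes the spatial covariance of each class as the average over trials of
#' `X X'` with channels centered per trial. With `trace_norm = TRUE` (the
#' default) each trial covariance is divided by its trace first, which removes
#' per-trial amplitude differences; `trace_norm = FALSE` gives the literal
#' unnormalized average, which differs from the normalized form only by
#' per-trial scalar factors.
#'
#' @param data trials x channels x samples array.
#' @param labels factor of per-trial labels with levels `c("L","R")`.
#' @param trace_norm divide each trial covariance by its trace.
#' @return list with symmetric positive semi-definite matrices `C1` (class L)
#'   and `C2` (class R).
#' @export
class_covariances <- function(data, labels, trace_norm = TRUE) {
  labels <- factor(as.character(labels), levels = c("L", "R"))
  if (any(table(labels) == 0)) stop("both classes must be present")
  p <- dim(data)[2]
  acc <- list(L = matrix(0, p, p), R = matrix(0, p, p))
  for (i in seq_len(dim(data)[1])) {
    X <- data[i, , ]
    X <- X - rowMeans(X)
    C <- tcrossprod(X)
    if (trace_norm) C <- C / sum(diag(C))
    cls <- as.character(labels[i])
    acc[[cls]] <- acc[[cls]] + C
  }
  n <- table(labels)
  list(C1 = (acc$L + t(acc$L)) / (2 * n[["L"]]),
       C2 = (acc$R + t(acc$R)) / (2 * n[["R"]]))
}

#' Fit common spatial pattern filters
#'
#' Solves the generalized eigenvalue problem `C1 w = lambda C2 w` (via
#' whitening with the Cholesky factor of `C2`) and keeps the `m_pairs`
#' eigenvectors with the largest and the `m_pairs` with the smallest
#' generalized eigenvalues: the filters that maximize the class-L/class-R
#' variance ratio and its reciprocal. Filter columns are scaled to unit
#' Euclidean norm. When the pencil is ill-conditioned a ridge of
#' `1e-8 * trace / channels` is added to both covariances.
#'
#' @param C1,C2 class covariance matrices from [class_covariances()].
#' @param m_pairs number of filter pairs to retain (`2 * m_pairs` filters).
#' @return object of class `csp_filters`: list with `W` (channels x
#'   `2 * m_pairs` filters), `eigvals` (matching generalized eigenvalues,
#'   largest `m_pairs` first, smallest last) and `m_pairs`.
#' @export
fit_csp <- function(C1, C2, m_pairs = 2) {
  p <- nrow(C1)
  if (2 * m_pairs > p) stop("2 * m_pairs exceeds the channel count")
  Cs <- C1 + C2
  if (rcond(Cs) < 1e-10) {
    ridge <- 1e-8 * sum(diag(Cs)) / p
    C1 <- C1 + ridge * diag(p)
    C2 <- C2 + ridge * diag(p)
  }
  R <- chol(C2)                       # C2 = R'R
  Rinv <- backsolve(R, diag(p))
  A <- t(Rinv) %*% C1 %*% Rinv        # symmetric whitened pencil
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)   # eigenvalues descending
  W_all <- Rinv %*% eg$vectors
  sel <- c(seq_len(m_pairs), p - m_pairs + seq_len(m_pairs))
  W <- W_all[, sel, drop = FALSE]
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  structure(list(W = W, eigvals = eg$values[sel], m_pairs = m_pairs),
            class = "csp_filters")
}

#' @export
print.csp_filters <- function(x, ...) {
  cat("<csp_filters> ", nrow(x$W), " channels -> ", ncol(x$W),
      " filters (", x$m_pairs, " pairs)\n", sep = "")
  cat("  eigenvalues:", format(x$eigvals, digits = 4), "\n")
  invisible(x)
}

#' Project a trial through CSP filters
#'
#' @param X channels x samples matrix (one trial).
#' @param filters a [fit_csp()] result (or a plain projection matrix).
#' @return `2 * m_pairs` x samples projected signal `Z = W' X`.
#' @export
apply_csp <- function(X, filters) {
  W <- if (inherits(filters, "csp_filters")) filters$W else filters
  if (nrow(X) != nrow(W))
    stop("trial has ", nrow(X), " channels but filters expect ", nrow(W))
  t(W) %*% X
}

#' Normalized log-variance CSP features
#'
#' The standard CSP readout: `f_j = log(var(z_j) / sum_k var(z_k))`. Invariant
#' under a common scaling of the projected trial; `sum(exp(f)) = 1`.
#'
#' @param Z projected trial from [apply_csp()].
#' @return numeric feature vector of length `nrow(Z)`.
#' @export
csp_features <- function(Z) {
  v <- apply(Z, 1, var)
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance in projected trial")
  log(v / tot)
}

#' Fisher score of feature separability
#'
#' Per feature, `FS = (mu_L - mu_R)^2 / (var_L + var_R)`; the aggregate score
#' is the mean over features. Invariant under a common affine transform of
#' both classes.
#'
#' @param features trials x features matrix.
#' @param labels factor of per-trial labels in `{"L","R"}`.
#' @return list with `per_feature` scores and the `aggregate` mean.
#' @export
fisher_score <- function(features, labels) {
  labels <- factor(as.character(labels), levels = c("L", "R"))
  if (any(table(labels) == 0)) stop("both classes must be present")
  fl <- features[labels == "L", , drop = FALSE]
  fr <- features[labels == "R", , drop = FALSE]
  num <- (colMeans(fl) - colMeans(fr))^2
  den <- apply(fl, 2, var) + apply(fr, 2, var)
  if (any(den <= 0)) stop("degenerate (zero-variance) feature")
  fs <- num / den
  list(per_feature = fs, aggregate = mean(fs))
}
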