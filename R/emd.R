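#' Empirical mode decomposition
#'
#' Sifts the signal into intrinsic mode functions (IMFs) ordered from highest
#' to lowest characteristic frequency, plus a residual. Envelopes are natural
#' cubic splines through the local extrema with two extrema mirrored beyond
#' each boundary; sifting stops when the normalized squared change between
#' consecutive sifts drops below `sd_tol` or after `max_sifts` sifts.
#' A monotone (or otherwise extrema-poor) input yields zero IMFs and is
#' returned whole as the residual.
#'
#' @param x numeric signal.
#' @param max_imfs maximum number of IMFs to extract.
#' @param max_sifts maximum sifting iterations per IMF.
#' @param sd_tol sifting stop tolerance (Cauchy-type criterion).
#' @return list with `imfs` (matrix, one IMF per row; 0 rows if none) and
#'   `residual`. `x` equals `colSums(imfs) + residual` to machine precision.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 1 / 250))
#' e <- emd(x)
#' cor(e$imfs[1, ], x)
#' @export
emd <- function(x, max_imfs = 10, max_sifts = 10, sd_tol = 0.2) {
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite samples in input")
  .emd_c(as.numeric(x), as.integer(max_imfs), as.integer(max_sifts), sd_tol)
}

#' Ensemble empirical mode decomposition
#'
#' Averages EMD over an ensemble of noise-perturbed copies of the signal:
#' `IMF_k` is the ensemble mean of the k-th IMF of `x + noise_coeff * sd(x) *
#' w` with `w` white Gaussian noise. Averaging cancels the added noise at rate
#' `1/sqrt(n_ensembles)` while stabilizing the dyadic filter-bank behaviour of
#' EMD against mode mixing. Defaults follow the decoding pipeline
#' configuration: noise amplitude coefficient 0.2, 40 ensemble members, up to
#' 10 IMFs. With `noise_coeff = 0` and a single ensemble member the result is
#' exactly [emd()].
#'
#' @param x numeric signal.
#' @param noise_coeff white-noise amplitude as a fraction of `sd(x)`.
#' @param n_ensembles ensemble size.
#' @param max_imfs maximum IMFs per realization (short realizations are
#'   zero-padded to this count before averaging).
#' @param seed integer seed making the ensemble reproducible; the caller's RNG
#'   state is left untouched.
#' @inheritParams emd
#' @return list with `imfs` (`max_imfs` x n matrix; trailing all-zero rows are
#'   dropped) and `residual` (ensemble mean).
#' @export
feemd <- function(x, noise_coeff = 0.2, n_ensembles = 40, max_imfs = 10,
                  max_sifts = 10, sd_tol = 0.2, seed = NULL) {
  if (noise_coeff < 0) stop("`noise_coeff` must be >= 0")
  if (n_ensembles < 1) stop("`n_ensembles` must be >= 1")
  if (noise_coeff == 0 && n_ensembles == 1) return(emd(x, max_imfs, max_sifts, sd_tol))
  n <- length(x)
  amp <- noise_coeff * sd(x)
  acc <- matrix(0, max_imfs, n)
  res <- numeric(n)
  runner <- function() {
    for (e in seq_len(n_ensembles)) {
      xe <- x + amp * rnorm(n)
      de <- .emd_c(xe, max_imfs, max_sifts, sd_tol)
      k <- nrow(de$imfs)
      if (k > 0) acc[seq_len(k), ] <<- acc[seq_len(k), , drop = FALSE] + de$imfs
      res <<- res + de$residual
    }
  }
  if (!is.null(seed)) with_seed(seed, runner()) else runner()
  acc <- acc / n_ensembles
  res <- res / n_ensembles
  nz <- which(rowSums(acc != 0) > 0)
  keep <- if (length(nz)) seq_len(max(nz)) else integer(0)
  list(imfs = acc[keep, , drop = FALSE], residual = res)
}

#' Keep the leading intrinsic mode functions
#'
#' The first IMFs carry the highest-frequency content; for 8-30 Hz band-passed
#' motor-imagery EEG the informative mu/beta activity concentrates in the
#' first three, which is the pipeline default.
#'
#' @param imfs IMF matrix (one IMF per row).
#' @param n_keep number of leading IMFs to keep.
#' @return matrix of the first `n_keep` rows.
#' @export
select_imfs <- function(imfs, n_keep = 3) {
  if (n_keep == 0) {
    warning("n_keep = 0: no IMFs selected")
    return(imfs[integer(0), , drop = FALSE])
  }
  if (nrow(imfs) < n_keep)
    stop("only ", nrow(imfs), " IMFs available, need ", n_keep)
  imfs[seq_len(n_keep), , drop = FALSE]
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
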