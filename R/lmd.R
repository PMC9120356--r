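# local extrema indices (both kinds, ascending), endpoints included as knots
lmd_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  s <- sign(dx)
  # carry sign through flat runs so plateaus do not hide turning points
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0) + 1L
  unique(c(1L, idx, n))
}

# moving-average smoothing of a step function; window odd, edges padded by
# repetition; iterated until no two adjacent samples are equal (or cap).
lmd_smooth <- function(y, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(y)
  for (it in 1:30) {
    yp <- c(rep(y[1], half), y, rep(y[n], half))
    y <- as.numeric(stats::filter(yp, rep(1 / w, w), sides = 2))[(half + 1):(half + n)]
    if (!any(diff(y) == 0)) break
  }
  y
}

#' Local mean decomposition
#'
#' Iteratively separates the signal into product functions (PFs), each the
#' product of a slowly varying positive envelope and a pure
#' frequency-modulated carrier, ordered from highest to lowest characteristic
#' frequency. The local mean and local magnitude are piecewise-constant
#' functions over successive extrema, smoothed by an iterated moving average
#' whose window is a third of the mean extrema spacing; demodulation repeats
#' until the residual envelope is within `purity_tol` of unity. The residual
#' is defined as `x - rowSums(PFs)`, so the additive reconstruction is exact.
#' A near-constant input (fewer than 3 extrema) yields zero PFs.
#'
#' @param x numeric signal.
#' @param max_pfs maximum number of product functions.
#' @param max_demod maximum demodulation iterations per PF.
#' @param purity_tol envelope-purity stop tolerance.
#' @return list with `pfs` (matrix, one PF per row), `envelopes` (matching
#'   instantaneous-amplitude rows) and `residual`.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' x <- (1 + 0.5 * cos(2 * pi * t)) * cos(2 * pi * 15 * t)
#' l <- lmd(x)
#' cor(l$pfs[1, ], x)
#' @export
lmd <- function(x, max_pfs = 6, max_demod = 12, purity_tol = 1e-3) {
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite samples in input")
  n <- length(x)
  r <- x
  pfs <- list(); envs <- list()
  for (p in seq_len(max_pfs)) {
    ext <- lmd_extrema(r)
    # stop on extrema-poor or energetically negligible residual
    if (length(ext) < 5 || sd(r) < 1e-4 * (sd(x) + 1e-300)) break
    s <- r
    a_acc <- rep(1, n)
    ok <- FALSE
    for (it in seq_len(max_demod)) {
      ext <- lmd_extrema(s)
      if (length(ext) < 5) break
      ev <- s[ext]
      nseg <- length(ext) - 1L
      m_step <- numeric(n); a_step <- numeric(n)
      for (k in seq_len(nseg)) {
        i0 <- ext[k]; i1 <- ext[k + 1L]
        m_step[i0:i1] <- (ev[k] + ev[k + 1L]) / 2
        a_step[i0:i1] <- abs(ev[k] - ev[k + 1L]) / 2
      }
      w <- max(3, round(mean(diff(ext)) / 3))
      m_t <- lmd_smooth(m_step, w)
      a_t <- pmax(lmd_smooth(a_step, w), 1e-12)
      s <- (s - m_t) / a_t
      a_acc <- a_acc * a_t
      if (max(abs(a_t - 1)) < purity_tol) { ok <- TRUE; break }
      ok <- TRUE  # at least one successful demodulation pass
    }
    if (!ok) break
    pf <- a_acc * s
    # a PF cannot carry more energy than its source: divergence guard
    if (sd(pf) > 2 * sd(r)) break
    pfs[[p]] <- pf
    envs[[p]] <- a_acc
    r <- r - pf
  }
  k <- length(pfs)
  list(pfs = if (k) do.call(rbind, pfs) else matrix(0, 0, n),
       envelopes = if (k) do.call(rbind, envs) else matrix(0, 0, n),
       residual = x - if (k) colSums(do.call(rbind, pfs)) else 0)
}

#' Select leading product functions
#'
#' Keeps the first `n_keep` PFs (highest characteristic frequencies). Each
#' kept PF is checked against a Pearson-correlation floor with the original
#' signal; a PF below the floor is still kept by order but flagged with a
#' warning, since the floor is a diagnostic for uninformative components, not
#' a hard selection rule.
#'
#' @param x_original the signal that was decomposed.
#' @param pfs PF matrix from [lmd()].
#' @param n_keep number of PFs to keep (pipeline default 2).
#' @param min_abs_corr absolute-correlation diagnostic floor.
#' @return matrix of the first `n_keep` PFs, with attribute `"corr"` holding
#'   the per-PF correlations with `x_original`.
#' @export
select_pfs <- function(x_original, pfs, n_keep = 2, min_abs_corr = 0.1) {
  if (nrow(pfs) < n_keep)
    stop("only ", nrow(pfs), " PFs available, need ", n_keep)
  keep <- pfs[seq_len(n_keep), , drop = FALSE]
  r <- apply(keep, 1, function(p)
    if (sd(p) < 1e-300) 0 else cor(p, x_original))
  low <- which(abs(r) < min_abs_corr)
  if (length(low))
    warning("PF", paste(low, collapse = ","),
            " below the |r| >= ", min_abs_corr,
            " diagnostic floor; kept by order")
  attr(keep, "corr") <- r
  keep
}
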