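#' Delay-embedding parameters
#'
#' @param tau delay in samples (`>= 1`).
#' @param d embedding dimension (`>= 1`). The decoding pipeline uses d = 2 for
#'   the wavelet-packet and ensemble-EMD branches and d = 3 for the
#'   local-mean-decomposition branch.
#' @return object of class `embedding_params`.
#' @export
embedding_params <- function(tau, d) {
  if (tau < 1 || d < 1) stop("need tau >= 1 and d >= 1")
  structure(list(tau = as.integer(tau), d = as.integer(d)),
            class = "embedding_params")
}

# S(m, r, t) of the C-C method for all m in `ms` at once: the series is split
# into t disjoint sub-series (every t-th sample); within each, correlation
# integrals of the delay-1 m-dimensional embeddings (maximum-norm metric) are
# computed on one shared, deterministic subsample of vectors, and the
# deviation from the independence factorization C(1,r)^m is averaged over
# sub-series. Returns a length(ms) x length(radii) matrix.
cc_statistic <- function(x, ms, t, radii, n_sub = 150) {
  m_max <- max(ms)
  acc <- matrix(0, length(ms), length(radii))
  used <- 0L
  cap <- max(25, round(n_sub / sqrt(t)))
  for (s in seq_len(t)) {
    xs <- x[seq(s, length(x), by = t)]
    L <- length(xs) - (m_max - 1)
    if (L < 10) next
    idx <- unique(round(seq(1, L, length.out = min(cap, L))))
    D <- matrix(0, length(idx), length(idx))
    Cs <- matrix(0, m_max, length(radii))  # C(m, r) for m = 1..m_max
    for (k in 0:(m_max - 1)) {
      v <- xs[idx + k]
      D <- pmax(D, abs(outer(v, v, "-")))
      du <- D[upper.tri(D)]
      Cs[k + 1, ] <- vapply(radii, function(r) mean(du < r), 0)
    }
    for (j in seq_along(ms))
      acc[j, ] <- acc[j, ] + (Cs[ms[j], ] - Cs[1, ]^ms[j])
    used <- used + 1L
  }
  if (used == 0L) return(matrix(NA_real_, length(ms), length(radii)))
  acc / used
}

#' Joint delay/dimension selection by the C-C method
#'
#' Computes the correlation-integral statistic
#' `S(m, r, t) = C(m, r, t) - C(1, r, t)^m` over radii `r = j * sd(x) / 2`,
#' `j = 1..4`, on disjoint sub-series with a deterministic subsample of delay
#' vectors. The delay is chosen from the pairwise (`m = 2`) statistic averaged
#' over radii, which for an oscillation with period `P` crosses zero at the
#' quarter period, in agreement with the first zero of the autocorrelation:
#' `tau` is the first zero crossing of `S2(t)`, or the first local minimum of
#' `S2(t)` when it never crosses zero. A series with no serial dependence at
#' lag 1 (e.g. white noise, whose correlation integrals factorize at every
#' delay, leaving `S ~ 0` throughout) has no pronounced structure and falls
#' back to `tau = 1` with a warning. The embedding dimension is the smallest
#' candidate at which the `m = 2..5` statistic at the chosen delay stabilizes
#' (relative change below 5%), falling back to the first candidate (the
#' caller's branch default) when inconclusive.
#'
#' @param x numeric signal, `length(x) >= 10 * max_tau`.
#' @param max_tau largest delay examined.
#' @param d_candidates candidate embedding dimensions, first = fallback.
#' @return an [embedding_params()] with attributes `s_bar` (the `S2(t)`
#'   curve), `delta_s` (its radius spread) and `pronounced`.
#' @export
cc_method <- function(x, max_tau = 20, d_candidates = 2:5) {
  n <- length(x)
  if (n < 10 * max_tau) stop("signal too short for max_tau = ", max_tau)
  sx <- sd(x)
  if (sx < 1e-300) stop("degenerate (constant) signal")
  radii <- (1:4) * sx / 2
  s2 <- numeric(max_tau)
  d2 <- numeric(max_tau)
  for (t in seq_len(max_tau)) {
    S <- cc_statistic(x, 2, t, radii)
    s2[t] <- mean(S)
    d2[t] <- max(S) - min(S)
  }
  pronounced <- s2[1] > 0.05   # serial dependence at lag 1 at all?
  tau <- 1L
  if (pronounced && max_tau > 1) {
    tol <- 0.025 * s2[1]          # "effectively decorrelated" threshold
    zc <- which(s2 <= tol)
    if (length(zc)) {
      tau <- zc[1]
    } else {
      # no crossing in range: first material local minimum, else argmin
      lmin <- NA_integer_
      if (max_tau >= 3)
        for (t in 2:(max_tau - 1))
          if (s2[t] < s2[t - 1] - tol && s2[t] <= s2[t + 1]) { lmin <- t; break }
      tau <- if (!is.na(lmin)) lmin else which.min(s2)
    }
  } else if (!pronounced && max_tau > 1) {
    warning("no pronounced structure in the C-C statistic; tau = 1")
  }
  # dimension: stabilization of the mean statistic across m at the chosen tau
  ms <- 2:5
  s_at_tau <- rowMeans(cc_statistic(x, ms, as.integer(tau), radii))
  d <- d_candidates[1]
  for (j in seq_len(length(ms) - 1)) {
    rel <- abs(s_at_tau[j + 1] - s_at_tau[j]) / max(abs(s_at_tau[j]), 1e-12)
    if (rel < 0.05 && ms[j] %in% d_candidates) { d <- ms[j]; break }
  }
  out <- embedding_params(tau, d)
  attr(out, "s_bar") <- s2
  attr(out, "delta_s") <- d2
  attr(out, "pronounced") <- pronounced
  out
}

#' Delay-coordinate embedding of a scalar series
#'
#' Coordinate `k` (`k = 0..d-1`) is the input shifted left by `k * tau`
#' samples; all coordinates are truncated to the common length
#' `n - (d - 1) * tau`, so early (cue-proximal) samples are kept.
#'
#' @param x numeric series of length `n`.
#' @param params an [embedding_params()].
#' @return `d` x `(n - (d-1) * tau)` matrix, one coordinate per row.
#' @examples
#' delay_embed(1:10, embedding_params(tau = 2, d = 3))
#' @export
delay_embed <- function(x, params) {
  tau <- params$tau; d <- params$d
  n <- length(x)
  L <- n - (d - 1) * tau
  if (L < 1) stop("series too short: n = ", n, ", (d-1)*tau = ", (d - 1) * tau)
  out <- matrix(0, d, L)
  for (k in 0:(d - 1)) out[k + 1, ] <- x[(1 + k * tau):(L + k * tau)]
  out
}

# expand a trials x components x samples array into
# trials x (components * d) x embedded-length, coordinates adjacent per
# component (component-major, coordinate-minor)
expand_bundle <- function(arr, params) {
  d <- params$d; tau <- params$tau
  dm <- dim(arr)
  L <- dm[3] - (d - 1) * tau
  if (L < 1) stop("embedded length would be < 1")
  out <- array(0, c(dm[1], dm[2] * d, L))
  for (cc in seq_len(dm[2]))
    for (k in 0:(d - 1))
      out[, (cc - 1) * d + k + 1, ] <- arr[, cc, (1 + k * tau):(L + k * tau)]
  out
}
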