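#' Mass function over the left/right frame of discernment
#'
#' A basic probability assignment over the frame `{{L}, {R}, Theta}` where
#' `Theta = {L, R}` carries the unassigned (uncertain) mass. Masses must be
#' nonnegative and sum to one. If `m_theta` is omitted it is completed as
#' `1 - m_l - m_r`; if a supplied trio mis-sums by more than 1e-6 the Theta
#' mass is recompleted from the singleton masses with a warning.
#'
#' @param m_l,m_r,m_theta masses for `{L}`, `{R}` and the frame.
#' @return object of class `mass_function`.
#' @examples
#' mass_function(0.6, 0.2, 0.2)
#' mass_function(0.4999, 0.0501)  # Theta completed to 0.45
#' @export
mass_function <- function(m_l, m_r, m_theta = NULL) {
  if (m_l < -1e-12 || m_r < -1e-12) stop("negative mass")
  if (m_l + m_r > 1 + 1e-9) stop("singleton masses exceed 1")
  if (is.null(m_theta)) {
    m_theta <- 1 - m_l - m_r
  } else if (abs(m_l + m_r + m_theta - 1) > 1e-6) {
    warning("masses sum to ", format(m_l + m_r + m_theta, digits = 6),
            "; completing Theta as 1 - m(L) - m(R)")
    m_theta <- 1 - m_l - m_r
  } else {
    # absorb sub-tolerance rounding into Theta so the sum is exactly 1
    m_theta <- 1 - m_l - m_r
  }
  if (m_theta < -1e-12) stop("negative Theta mass")
  structure(list(m_l = max(m_l, 0), m_r = max(m_r, 0),
                 m_theta = max(m_theta, 0)), class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat(sprintf("<mass_function> m(L) = %.4f  m(R) = %.4f  m(Theta) = %.4f\n",
              x$m_l, x$m_r, x$m_theta))
  invisible(x)
}

mass_vec <- function(x) c(L = x$m_l, R = x$m_r, Theta = x$m_theta)

# unnormalized conjunctive combination; mass on the empty set is dropped,
# so sum(result) = K, the non-conflicting mass
ds_conjunct <- function(a, b) {
  c(L = a[["L"]] * b[["L"]] + a[["L"]] * b[["Theta"]] + a[["Theta"]] * b[["L"]],
    R = a[["R"]] * b[["R"]] + a[["R"]] * b[["Theta"]] + a[["Theta"]] * b[["R"]],
    Theta = a[["Theta"]] * b[["Theta"]])
}

#' Combine two mass functions by Dempster's rule
#'
#' Conjunctive combination with renormalization over non-conflicting
#' intersections: `m(A) = (1/K) sum over B, C with B intersect C = A of
#' m_a(B) m_b(C)`, where `K` is the total non-conflicting mass. The vacuous
#' mass `(0, 0, 1)` is the neutral element; two opposed certainties
#' (`K = 0`) cannot be combined.
#'
#' @param m_a,m_b [mass_function()] objects.
#' @return the combined [mass_function()], with attribute `conflict`
#'   (`1 - K`, the conflicting mass discarded by normalization).
#' @export
ds_combine <- function(m_a, m_b) {
  stopifnot(inherits(m_a, "mass_function"), inherits(m_b, "mass_function"))
  u <- ds_conjunct(mass_vec(m_a), mass_vec(m_b))
  K <- sum(u)
  if (K <= 0) stop("total conflict (K = 0): opposed certain masses")
  out <- mass_function(u[["L"]] / K, u[["R"]] / K, u[["Theta"]] / K)
  attr(out, "conflict") <- 1 - K
  out
}

#' Fuse several mass functions and decide
#'
#' Combines all mass functions with Dempster's rule (associative and
#' commutative, so the input order is irrelevant) and applies the decision
#' rules of [decide()]. The reported conflict is the total conflicting mass of
#' the joint combination, `1 - K` with `K` the mass surviving on non-empty
#' intersections.
#'
#' @param masses list of [mass_function()] objects (at least one).
#' @param eps1,eps2 decision thresholds, see [decide()].
#' @return object of class `fusion_result`: list with `fused` (the combined
#'   [mass_function()]), `conflict`, `decision` (`"L"` or `"R"`) and
#'   `confident` (logical).
#' @examples
#' m <- list(mass_function(0.4999, 0.0501, 0.4500),
#'           mass_function(0.5985, 0.2827, 0.1188),
#'           mass_function(0.4578, 0.2109, 0.3313))
#' ds_combine_all(m)
#' @export
ds_combine_all <- function(masses, eps1 = 0, eps2 = 0.1) {
  if (!length(masses)) stop("need at least one mass function")
  stopifnot(all(vapply(masses, inherits, TRUE, "mass_function")))
  u <- mass_vec(masses[[1]])
  for (m in masses[-1]) u <- ds_conjunct(u, mass_vec(m))
  K <- sum(u)
  if (K <= 0) stop("total conflict (K = 0): opposed certain masses")
  fused <- mass_function(u[["L"]] / K, u[["R"]] / K, u[["Theta"]] / K)
  dec <- decide(fused, eps1, eps2)
  structure(list(fused = fused, conflict = 1 - K, decision = dec$decision,
                 confident = dec$confident), class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_result> fused m(L) = %.4f, m(R) = %.4f, m(Theta) = %.4f\n",
    x$fused$m_l, x$fused$m_r, x$fused$m_theta))
  cat(sprintf("  decision: {%s}%s   conflict: %.4f\n", x$decision,
              if (x$confident) "" else " (fallback, rules not satisfied)",
              x$conflict))
  invisible(x)
}

#' Decision rules on a fused mass function
#'
#' A class `W` in `{L, R}` is accepted when (1) its fused mass is the maximum
#' of the three masses, (2) it exceeds the other singleton mass by more than
#' `eps1`, and (3) the residual uncertainty `m(Theta)` is below `eps2`
#' (defaults 0 and 0.1). When the rules fail, the decision falls back to the
#' larger singleton mass (ties to `"L"`) with `confident = FALSE`, since a
#' binary decoder must always emit a class.
#'
#' @param fused a [mass_function()].
#' @param eps1 minimum margin between the two singleton masses.
#' @param eps2 maximum tolerated Theta mass.
#' @return list with `decision` (`"L"` or `"R"`) and `confident` (logical).
#' @export
decide <- function(fused, eps1 = 0, eps2 = 0.1) {
  stopifnot(inherits(fused, "mass_function"))
  m <- mass_vec(fused)
  best <- if (m[["L"]] >= m[["R"]]) "L" else "R"
  other <- setdiff(c("L", "R"), best)
  confident <- m[[best]] == max(m) &&
    (m[[best]] - m[[other]]) > eps1 &&
    m[["Theta"]] < eps2
  list(decision = best, confident = confident)
}

#' Worked fusion demonstration
#'
#' Fuses two sets of three single-branch basic probability assignments (one
#' per time-frequency branch) for two test trials and prints the fused masses
#' and decisions, illustrating how evidential fusion sharpens the winning
#' class mass and shrinks the uncertainty, and how it can overturn a 2-of-3
#' majority vote when the dissenting branch is the more certain one.
#'
#' @return (invisibly) a list of the two [ds_combine_all()] results.
#' @export
fuse_demo <- function() {
  sets <- list(
    trial1 = list(mass_function(0.4999, 0.0501, 0.4500),
                  mass_function(0.5985, 0.2827, 0.1188),
                  mass_function(0.4578, 0.2109, 0.3313)),
    trial2 = list(mass_function(0.4617, 0.0883),
                  mass_function(0.3918, 0.4894),
                  mass_function(0.2927, 0.3761)))
  out <- lapply(sets, ds_combine_all)
  for (nm in names(out)) {
    cat(nm, "branch masses:\n")
    for (m in sets[[nm]])
      cat(sprintf("   (%.4f, %.4f, %.4f)\n", m$m_l, m$m_r, m$m_theta))
    print(out[[nm]])
  }
  invisible(out)
}
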