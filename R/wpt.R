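# Orthonormal Daubechies-4 (8-tap) analysis low-pass filter.
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)

# one periodized analysis stage: x (length N even) -> list(a, d), each N/2
wpt_analysis_stage <- function(x, h) {
  N <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # QMF high-pass
  k2 <- 2 * (0:(N / 2 - 1))
  a <- numeric(N / 2); d <- numeric(N / 2)
  for (m in seq_along(h)) {
    idx <- (k2 + m - 1) %% N + 1
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

# one periodized synthesis stage from a single child (bit 0 = low, 1 = high)
wpt_synthesis_stage <- function(c_child, bit, h) {
  N <- 2 * length(c_child)
  f <- if (bit == 0) h else rev(h) * (-1)^(seq_along(h) - 1)
  x <- numeric(N)
  k2 <- 2 * (seq_along(c_child) - 1)
  for (m in seq_along(f)) {
    idx <- (k2 + m - 1) %% N + 1   # distinct for fixed m
    x[idx] <- x[idx] + f[m] * c_child
  }
  x
}

# frequency (sequency) position of each Paley-ordered leaf at given depth:
# a high-pass split reverses the frequency orientation of its children.
wpt_freq_order <- function(depth) {
  pos <- 0L
  for (lev in seq_len(depth)) {
    newpos <- integer(2L * length(pos))
    for (i in seq_along(pos)) {
      p <- pos[i]
      children <- if (p %% 2L == 0L) c(2L * p, 2L * p + 1L)
                  else c(2L * p + 1L, 2L * p)
      newpos[2L * i - 1L] <- children[1L]
      newpos[2L * i] <- children[2L]
    }
    pos <- newpos
  }
  pos  # pos[paley_index + 1] = frequency slot (0-based)
}

#' Wavelet packet decomposition into frequency-ordered node signals
#'
#' Fully decomposes a signal to the requested depth with a periodized
#' orthonormal db4 filter bank and reconstructs each of the `2^depth` terminal
#' nodes back to signal length, so the node signals sum exactly to the input.
#' Nodes are returned in ascending nominal frequency order; node `j`
#' (0-based) nominally covers `[j, j+1] * fs / 2^(depth+1)` Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz (used only for band labeling).
#' @param wavelet wavelet name; only `"db4"` is shipped.
#' @param depth decomposition depth (3 gives 8 nodes of width `fs/16` Hz).
#' @return list with `nodes` (list of node signals, each `length(x)`),
#'   `bands` (2-column matrix of nominal band edges in Hz) and
#'   `energy_ratio` (node energy / total, sums to 1).
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 12 * seq(0, 2, by = 1 / fs))
#' w <- wpt_decompose(x, fs, depth = 3)
#' w$bands[which.max(w$energy_ratio), ]  # 8-16 Hz node dominates
#' @export
wpt_decompose <- function(x, fs, wavelet = "db4", depth = 3) {
  if (!identical(wavelet, "db4")) stop("unknown wavelet: ", wavelet)
  if (depth < 1) stop("`depth` must be >= 1")
  n <- length(x)
  if (n < 2^depth) stop("signal shorter than 2^depth")
  h <- DB4_H
  blk <- 2^depth
  npad <- (blk - n %% blk) %% blk
  xp <- if (npad > 0) c(x, x[seq_len(npad)]) else x  # periodic pad

  # full packet tree, Paley order
  coefs <- list(xp)
  for (lev in seq_len(depth)) {
    nxt <- vector("list", 2L * length(coefs))
    for (i in seq_along(coefs)) {
      st <- wpt_analysis_stage(coefs[[i]], h)
      nxt[[2L * i - 1L]] <- st$a
      nxt[[2L * i]] <- st$d
    }
    coefs <- nxt
  }

  # reconstruct each leaf independently
  nodes_paley <- vector("list", length(coefs))
  for (i in seq_along(coefs)) {
    bits <- as.integer(intToBits(i - 1L))[depth:1]  # path from root
    y <- coefs[[i]]
    for (lev in depth:1) y <- wpt_synthesis_stage(y, bits[lev], h)
    nodes_paley[[i]] <- y[seq_len(n)]
  }

  fo <- wpt_freq_order(depth)
  nodes <- vector("list", length(coefs))
  for (i in seq_along(coefs)) nodes[[fo[i] + 1L]] <- nodes_paley[[i]]

  width <- (fs / 2) / 2^depth
  bands <- cbind(low = (seq_along(nodes) - 1) * width,
                 high = seq_along(nodes) * width)
  en <- vapply(nodes, function(v) sum(v^2), 0)
  list(nodes = nodes, bands = bands, energy_ratio = en / sum(en))
}

#' Select wavelet packet nodes by in-band energy
#'
#' Keeps the `k` nodes with the highest energy ratio among nodes whose nominal
#' band intersects `band_hz` (closed intervals, so a node touching a band edge
#' counts). Ties are broken toward the lower band edge. With `extend = TRUE`,
#' when fewer than `k` nodes intersect the band, the candidate set is widened
#' deterministically to the nearest remaining nodes by band distance instead
#' of failing; the decoding pipeline uses this so that narrow node grids still
#' yield the configured channel expansion.
#'
#' @param nodes,bands,energy_ratio as returned by [wpt_decompose()].
#' @param band_hz target frequency band, default `c(8, 30)`.
#' @param k number of nodes to keep.
#' @param extend widen the candidate set instead of erroring when fewer than
#'   `k` nodes overlap `band_hz`.
#' @return list with `nodes` (kept signals, ascending band order), `index`
#'   (0-based frequency-order node indices) and `bands`.
#' @export
select_wpt_nodes <- function(nodes, bands, energy_ratio, band_hz = c(8, 30),
                             k = 4, extend = FALSE) {
  keep <- select_wpt_index(bands, energy_ratio, band_hz, k, extend)
  list(nodes = nodes[keep], index = keep - 1L,
       bands = bands[keep, , drop = FALSE])
}

# selection on band/ratio metadata alone (1-based node rows)
select_wpt_index <- function(bands, energy_ratio, band_hz, k, extend) {
  if (k > nrow(bands)) stop("k exceeds the number of nodes")
  overlap <- bands[, 2] >= band_hz[1] & bands[, 1] <= band_hz[2]
  cand <- which(overlap)
  if (length(cand) < k) {
    if (!extend)
      stop("only ", length(cand), " nodes overlap [", band_hz[1], ", ",
           band_hz[2], "] Hz; k = ", k)
    rest <- setdiff(seq_len(nrow(bands)), cand)
    dist <- pmax(band_hz[1] - bands[rest, 2], bands[rest, 1] - band_hz[2], 0)
    rest <- rest[order(dist, bands[rest, 1])]
    cand <- c(cand, rest[seq_len(k - length(cand))])
  }
  ord <- cand[order(-energy_ratio[cand], bands[cand, 1])]
  sort(ord[seq_len(k)])
}
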