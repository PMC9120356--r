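# one trial of 1/f (pink) background noise, unit variance before scaling
pink_noise <- function(n) {
  half <- (n - 1) %/% 2                     # strictly positive, non-Nyquist
  amp <- 1 / sqrt(seq_len(half))
  pos <- complex(modulus = amp, argument = runif(half, 0, 2 * pi))
  nyq <- if (n %% 2 == 0)
    complex(real = cos(runif(1, 0, 2 * pi)) / sqrt(n / 2)) else NULL
  full <- c(0, pos, nyq, Conj(rev(pos)))
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

# power in [lo, hi] Hz from the raw periodogram
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi & f <= fs / 2
  2 * sum(sp[sel])
}

#' Generate synthetic motor-imagery EEG with lateralized ERD
#'
#' Emulates three bipolar sensorimotor channels (C3, Cz, C4) during left- vs
#' right-hand motor imagery. Each trial is pink (1/f) background noise plus mu
#' (10 Hz) and beta (20 Hz) oscillations with per-trial random phase and
#' amplitude jitter (plus/minus 10%). Event-related desynchronization
#' attenuates the oscillations contralateral to the imagined hand: for a left
#' trial the C4 oscillation amplitude is scaled by `1 - erd_depth` and Cz by
#' `1 - erd_depth / 2`; for a right trial the roles of C3 and C4 swap. The
#' background is scaled per channel so that its 8-30 Hz band power is
#' `-snr_db` dB relative to the unattenuated oscillation power.
#'
#' @param n_per_class trials per class (labels are balanced, classes
#'   interleaved).
#' @param fs sampling rate in Hz (128 and 250 are the typical few-channel
#'   montage rates).
#' @param duration_s trial length in seconds.
#' @param erd_depth attenuation fraction in `[0, 1]`; 0 makes the classes
#'   identically distributed.
#' @param snr_db oscillation-to-background power ratio in the 8-30 Hz band.
#' @param seed integer seed; the same seed reproduces the data set bit for
#'   bit, and the caller's RNG state is untouched.
#' @return a [trial_set()] with `2 * n_per_class` trials.
#' @examples
#' ts <- generate_mi_dataset(n_per_class = 4, fs = 128, duration_s = 2,
#'                           seed = 7)
#' ts
#' @export
generate_mi_dataset <- function(n_per_class = 60, fs = 250, duration_s = 4,
                                erd_depth = 0.6, snr_db = 0, seed = 1) {
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must be in [0, 1]")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  n <- round(fs * duration_s)
  n_tr <- 2L * n_per_class
  labels <- rep(c("L", "R"), n_per_class)
  tvec <- (seq_len(n) - 1) / fs
  a_mu <- 1; a_beta <- 0.5
  p_osc <- (a_mu^2 + a_beta^2) / 2           # unattenuated oscillation power
  data <- array(0, c(n_tr, 3, n))
  with_seed(seed, {
    for (i in seq_len(n_tr)) {
      # contralateral attenuation: left MI suppresses C4, right suppresses C3
      gain <- if (labels[i] == "L") c(1, 1 - erd_depth / 2, 1 - erd_depth)
              else c(1 - erd_depth, 1 - erd_depth / 2, 1)
      for (ch in 1:3) {
        jit <- 1 + runif(1, -0.1, 0.1)
        osc <- gain[ch] * jit *
          (a_mu * sin(2 * pi * 10 * tvec + runif(1, 0, 2 * pi)) +
           a_beta * sin(2 * pi * 20 * tvec + runif(1, 0, 2 * pi)))
        bg <- pink_noise(n)
        bg <- bg * sqrt(p_osc / band_power(bg, fs, 8, 30) / 10^(snr_db / 10))
        data[i, ch, ] <- osc + bg
      }
    }
  })
  trial_set(data, labels, fs)
}
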