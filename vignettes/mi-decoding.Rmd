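---
title: "Decoding few-channel motor imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding few-channel motor imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifuse)
```

## The problem

Common spatial patterns (CSP) is the workhorse feature extractor for
motor-imagery brain-computer interfaces, but it needs spatial structure to
work with: it finds linear channel combinations whose variance discriminates
the two classes. A practical three-channel montage (bipolar C3, Cz, C4) gives
it almost nothing to combine, and plain CSP on three channels can perform
worse than simple band-power features. `mifuse` implements a channel-expansion
strategy: manufacture many surrogate channels from the three recorded ones,
carrying time-frequency and temporal-lag structure that CSP can then exploit,
and combine three differently-expanded views of the data at the decision
level.

The pipeline, per branch:

1. **Band-pass** 8-30 Hz (5th-order Butterworth), covering the mu (8-12 Hz)
   and beta (18-26 Hz) rhythms whose contralateral event-related
   desynchronization (ERD) distinguishes left- from right-hand imagery.
2. **Time-frequency decomposition** of each channel into components —
   wavelet packets (WPT, keep 4 in-band nodes per channel: 12 components),
   ensemble empirical mode decomposition (keep IMF1-IMF3: 9), or local mean
   decomposition (keep PF1-PF2: 6).
3. **Phase-space reconstruction**: each component is delay-embedded
   (`y_i = {x_i, x_{i+tau}, ..., x_{i+(d-1)tau}}`) with dimension d = 2, 2, 3
   per branch, giving 24 / 18 / 18 channels; the delay comes from the C-C
   method on training trials.
4. **CSP** per branch: the generalized eigenproblem `C1 w = lambda C2 w` on
   the class covariances of the expanded tensor; 2 filter pairs, normalized
   log-variance features.
5. **Calibrated SVM** per branch: RBF SVM with a Platt-type sigmoid fitted on
   cross-validated decision values, emitting `P(L)` and `P(R)`.
6. **Evidential fusion**: each branch's probabilities become a basic
   probability assignment (BPA) over `{{L}, {R}, Theta}` with
   `m(Theta) = N_sv / l` (the support-vector ratio — an SVM that needed every
   training point as a support vector is maximally uncertain about its own
   opinion). The three BPAs are combined with Dempster's rule and the fused
   mass decides the class when it is maximal, exceeds the runner-up by
   `eps1 = 0`, and the fused uncertainty is below `eps2 = 0.1`; otherwise the
   decoder falls back to the larger singleton mass (a binary decoder must
   always answer; the fallback is flagged `confident = FALSE`).

The feature-domain-merge baseline (`fdm_baseline()`, `method = "fdm"`)
concatenates the three branches' CSP features into one SVM instead; comparing
it against decision-level fusion is the point of the evaluation harness.

## Worked fusion example

```{r}
fuse_demo()
```

Two things are worth noting. Fusion sharpens: the largest single-branch mass
for the first trial is 0.5985, the fused mass 0.8269, and the uncertainty
drops from a minimum of 0.1188 to 0.0282. Fusion also weighs certainty, not
votes: in the second trial two of three branches prefer {R}, but the
dissenting branch is far more decided, and the fused decision is {L}.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `band`, `filter_order` | 8-30 Hz, 5 | sensorimotor rhythm band; zero-phase application doubles the effective order |
| `wpt_depth` | 3 (fs <= 160) / 4 | node width fs/16 or fs/32 Hz |
| `wpt_k` | 4 | nodes kept per channel (3 x 4 = 12 components) |
| `feemd_noise`, `feemd_ensembles` | 0.2, 40 | white-noise coefficient (fraction of signal SD) and ensemble size |
| `n_imfs`, `n_pfs` | 3, 2 | leading components kept per channel |
| `d` | 2 / 2 / 3 | embedding dimension per branch |
| `max_tau` | 20 samples | upper bound of the C-C delay search |
| `m_pairs` | 2 | CSP filter pairs (4 features per branch) |
| `svm_cost`, `svm_gamma` | 1, `1/(p * var)` | RBF SVM hyperparameters |
| `eps1`, `eps2` | 0, 0.1 | decision margin and uncertainty ceiling |

## Design decisions in detail

**Filtering.** Zero-phase (forward-backward) filtering preserves cue-locked
latencies at the price of doubling the effective order; epochs are extended
by odd reflection (`min(n-1, max(3 * order, fs))` samples) before filtering
because a 15-sample reflection is too short to absorb the transient of a
5th-order band-pass at these rates. Filtering is applied per epoch; for
continuous recordings, filter first and epoch with `extract_epoch()`
afterwards.

**WPT node selection.** Nodes are re-ordered to natural frequency order
(the Paley order of the tree interleaves bands) before band labeling. The
selection rule is "highest energy among nodes whose nominal band intersects
8-30 Hz", with closed-interval overlap so a node touching a band edge
qualifies. At 250 Hz with depth 4 the node grid (7.8125-Hz widths) places
only three nodes inside 8-30 Hz; the pipeline then widens the candidate set
deterministically to the nearest bands so that `wpt_k = 4` nodes per channel
are always produced — the fourth node sits at a band edge and, on band-passed
data, carries transition-band energy. The strict error-on-shortfall contract
is still available via `select_wpt_nodes(..., extend = FALSE)`.

**EMD internals.** Envelopes are natural cubic splines through the local
extrema with two extrema mirrored beyond each boundary; sifting stops on a
Cauchy-type criterion (normalized squared change < 0.2) or after 10 sifts.
The ensemble variant adds Gaussian white noise scaled to `0.2 * sd(x)`,
averages 40 realizations, and is seeded per trial and channel so the
decomposition cache is reproducible. Because every realization reconstructs
its own noisy input exactly, the ensemble reconstruction error is exactly the
mean of the added noise — standard deviation `0.2 * sd(x) / sqrt(40)` — which
the test suite checks.

**LMD internals.** Local means and magnitudes are step functions over
successive extrema, smoothed by an iterated moving average with window a
third of the mean extrema spacing; demodulation stops when the envelope is
within `1e-3` of unity. Extraction stops on extrema-poor or energetically
negligible residuals, and a divergence guard discards any "component" whose
energy exceeds twice its source's (demodulating numerical-noise residuals can
otherwise manufacture energy). The residual is defined as the input minus the
sum of product functions, so additive reconstruction is exact by
construction. The first two PFs are kept by count; the correlation floor
(|r| >= 0.1 with the undecomposed signal) is a logged diagnostic rather than
a selection rule, because a dual frequency-range/correlation criterion does
not pin down an algorithm.

**Delay selection.** The C-C method computes
`S(m, r, t) = C(m, r, t) - C(1, r, t)^m` on disjoint subsampled sub-series
with radii `r = j sd(x)/2`. For the delay we use the pairwise (`m = 2`)
statistic averaged over radii: its first zero crossing (tolerance 2.5% of the
lag-1 value) sits at the quarter period of rhythmic signals, matching the
first zero of the autocorrelation; the higher-dimensional statistics place
their minima near `P/m` instead (the delay that spreads m points evenly on
the cycle), which is why they are not used for the delay. Embedding
dimensions are fixed at the branch defaults (2/2/3); the `m = 2..5`
stabilization rule in `cc_method()` is available but the pipeline does not
let it override the branch dimension. White-noise-like series, whose
correlation integrals factorize at every delay, fall back to `tau = 1` with
a warning. The pipeline estimates one delay per branch as the median of
per-channel estimates over a small cap of training trials and component
channels (2 trials x 6 channels by default) — the estimates are strongly
concentrated because all components live in the same 8-30 Hz band, so a
larger sample buys nothing.

**CSP numerics.** Per-trial covariances are trace-normalized by default
(amplitude invariance); the literal unnormalized form is available with
`trace_norm = FALSE`, and the two differ only by per-trial scalar weights.
The pencil is whitened with the Cholesky factor of `C2`; a ridge of
`1e-8 * trace/p` enters only when the reciprocal condition number drops below
`1e-10`. Filters are unit-norm; the log-variance readout is the standard CSP
feature (the projection alone is not yet a feature vector).

**Calibration.** The Platt sigmoid is fitted by logistic regression on
decision values from a deterministic stratified 5-fold split of the training
set, not on in-sample decision values (which saturate on separable folds) —
and not by libsvm's built-in probability machinery, whose internal fold
randomization is not seedable from R and would break the package's
reproducibility contract. `N_sv` counts all support vectors of the final
model, bounded and unbounded alike.

**Fusion edge cases.** A supplied mass trio that mis-sums by more than 1e-6
has its Theta mass recompleted as `1 - m(L) - m(R)` with a warning (published
tables sometimes round or typo the uncertainty column; completion from the
singleton masses is the only consistent repair). Total conflict (`K = 0`) is
an error — it requires two opposed certainties, which calibrated BPAs with
positive support-vector ratios cannot produce.

## The synthetic generator

`generate_mi_dataset()` emulates what the decoder is built to detect: trials
of pink (1/f) background — the canonical EEG spectral shape — plus 10 Hz mu
and 20 Hz beta oscillations with per-trial random phase and ±10% amplitude
jitter. Left-hand trials attenuate the C4 oscillations by `1 - erd_depth`
(contralateral ERD), right-hand trials attenuate C3, and Cz is attenuated
half-depth in both. `snr_db` fixes the oscillation-to-background power ratio
in the 8-30 Hz band. The benchmark conditions used by the acceptance tests
are 60 trials per class, 250 Hz, 4-s trials, `erd_depth = 0.6`, `snr_db = 0`.

What the generator does *not* emulate: volume-conduction mixing between
channels (each channel's background is independent), artifacts (blinks, EMG),
nonstationarity across a session, and subject variability. Passing the
synthetic benchmark therefore shows that the pipeline recovers lateralized
band-power structure through its full decomposition-embedding-CSP-fusion
stack — it does not predict competition-grade accuracy on real recordings,
which require the original data sets.

## Evaluation protocol

`cross_validate()` runs repeated stratified k-fold cross-validation (5 x 5 by
default). Everything data-dependent — node choice, the C-C delay, CSP
filters, SVMs and their calibration — is re-fitted inside each training fold.
The per-trial decompositions themselves are label-free functions of one trial
at a time, so they are computed once and shared across folds; this is a pure
speed optimization with no leakage path. Controls worth running (the
acceptance tests do): shuffled labels and `erd_depth = 0`, both of which must
collapse to chance.

Problem sizes were chosen to keep the default suite brisk: unit tests use
128 Hz / 2-s trials with a reduced EMD ensemble, while the acceptance
benchmark runs the full 250 Hz / 4-s / 40-ensemble configuration on 120
trials (a few minutes of compute, dominated by the ensemble EMD).

## Known limitations

- The decomposition layer is univariate per channel; no multivariate EMD or
  leadfield-aware variant is provided.
- The frame of discernment is binary; multi-class imagery would need a
  different BPA construction and combination bookkeeping.
- `cc_method()` assumes an oscillatory (band-limited) signal; on broadband
  data its fallback is `tau = 1`.
- On-disk support covers the package's own text container only; EDF/GDF
  recordings should be epoched with their own tooling and imported as arrays.
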