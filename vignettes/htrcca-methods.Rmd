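---
title: "H-TRCCA: model, design choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{H-TRCCA: model, design choices, and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htrcca)
```

## The recognition model

An SSVEP speller presents `Nf` targets flickering at distinct frequencies
`f_n`; a short multi-channel EEG window `X ∈ R^{Nc×Ns}` recorded over
occipital cortex contains an oscillation at the attended frequency and its
harmonics. Recognition reduces to asking which stimulus model explains `X`
best.

The package implements five recognizers over a shared front end:

* **CCA** (calibration-free): score each stimulus by the first canonical
  correlation between `X` and the sine–cosine reference
  `Y_n = [sin(2πf_n t); cos(2πf_n t); … ; sin(2πN_h f_n t); cos(2πN_h f_n t)]`,
  evaluated on the one-based time grid `t = 1/fs, …, Ns/fs`. That grid is a
  deliberate convention: it fixes the phase origin of every reference, and
  the simulator uses the same grid so latency-corrected epochs align with
  their references exactly.
* **TRCA**: per stimulus, a spatial filter `w_t` maximizes the Rayleigh
  quotient `w'Sw / w'Qw` where `S` sums the cross-covariances of distinct
  training-trial pairs and `Q` pools the covariance of all trials. Scoring
  correlates the `w_t`-projected test epoch with the projected template
  (the trial average `X̄_n`).
* **eTRCA**: the same, but both signals are projected through the matrix
  `W = [w_t1 … w_tNf]` of all per-stimulus filters and compared by the
  correlation of the flattened projections.
* **H-TRCCA**: the hybrid two-stage recognizer described next.
* **eH-TRCCA**: H-TRCCA with the stage-2 projection through the full
  ensemble `W` rather than the candidates' filters only.

### The hybrid two-stage test phase

Stage 1 computes, for every stimulus, five correlation features: the plain
canonical correlation with `Y_n`, and four Pearson correlations between
projections of the test epoch (`X'w_a`, `X'w_c`) and projections of the
template (`X̄_n'w_a`, `X̄_n'w_c`) or reference (`Y_n'w_b`, `Y_n'w_d`). The
filters come from two CCA problems solved at training time: template
vs. reference (`w_a, w_b`) and concatenated-trials vs. tiled reference
(`w_c, w_d`). The rationale for the redundancy is that the five features
fail in different ways — the calibration-free feature survives bad
templates, the template features survive noisy single trials — and a
stimulus that is truly attended scores well on all five.

The `Nf × 5` feature matrix is then clustered. A Gaussian-mixture model
(full covariance) is fit for each candidate cluster count `h`, the
hard-assigned partition is scored by the Davies–Bouldin index, and the
best `h` seeds a k-means++ partition. The cluster whose member rows have
the highest mean feature value is kept as the candidate set. The point of
this stage is suppression: far-from-target stimuli stop competing in stage
2, which empirically removes most spurious peaks when spatial filters are
weak (few training trials).

Stage 2 scores each candidate `k` by `C_k = T_k + D_k`, where `T_k` is the
sum of its five fused features and `D_k` correlates the test epoch with the
candidate's template after both are projected through the concatenated
TRCA filters of the candidate set. The prediction is `argmax C_k`.

### Filter-bank fusion

All EEG epochs pass a Chebyshev Type-I filter bank (lower passband edges
6/14/22/30/38 Hz, common 90 Hz upper passband, 100 Hz stopband) before any
correlation is computed; references are analytic sinusoids and are not
filtered. Every raw correlation `r_b` from sub-band `b` is fused by

`ρ = Σ_b (b^{-1.25} + 0.25) · r_b²`

Fusion is applied **per feature component, before clustering** — one of
the genuinely open design points in this architecture. The alternative
(cluster per band, fuse later) would require reconciling `Nb` different
candidate sets; fusing first keeps stage 1 a single well-defined clustering
problem, and makes `T` and `D` commensurable since both are fused the same
way. A consequence worth knowing: fused features are squared, so the sign
of a raw correlation never influences clustering or `T`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `Nh` (reference harmonics) | 5 | — | standard for the 8–15.8 Hz paradigm; 5·15.8 Hz stays below Nyquist at 250 Hz |
| `Nb` (sub-bands) | 5 | — | the conventional five-band SSVEP bank; only five lower edges are defined |
| window `Tw` | 1.0 | s | typical operating point; sweeps go down to 0.2 s |
| latency | 0.14 | s | visual-pathway delay used when windowing epochs from stimulus onset |
| channels | 9 (Pz…O2) | — | the parieto-occipital montage SSVEP decoding conventionally uses |
| `h_range` (cluster counts) | 2–8 | — | capped far below `Nf = 40` so the winning cluster stays a small candidate set |
| filter order selection | 3 dB / 40 dB | dB | minimal Chebyshev order for the stated edges |
| realized passband ripple | 0.5 | dB | forward–backward filtering doubles passband loss in dB; 0.5 dB keeps in-band tones within 1 dB after the double pass |
| ridge (CCA / TRCA solves) | 1e−10·tr/p, 1e−9·tr/Nc | — | relative regularization engaged only for rank-deficient covariance |

## Numerical choices

* **CCA solver**: SVD of the whitened cross-covariance
  `Cxx^{-1/2} Cxy Cyy^{-1/2}`, with covariance normalized by `1/Ns`
  (population form). The population divisor is load-bearing: it makes
  weights *exactly* invariant to tiling the data along time, which the
  template-filter training exploits (tiling `Nt` copies changes nothing).
* **Sign conventions**: every weight vector is scaled so its
  largest-magnitude entry is positive. Canonical weights are
  sign-ambiguous; several features use signed correlations of projections,
  so reproducibility requires fixing signs.
* **TRCA eigen solve**: Cholesky/eigen whitening of `Q` (with relative
  ridge when singular), then a symmetric eigendecomposition; only the
  leading eigenvector is kept, unit-norm. Trials are mean-centered per
  channel before covariance computation. Two identical trials make
  `S ∝ Q`; the solve still returns a vector but warns about the
  degeneracy.
* **Matrix correlation**: the correlation of two equally shaped projected
  matrices is defined as the Pearson correlation of their flattened
  entries. This is stated prominently because ensemble-filter scoring is
  often written as `ρ(X'W, X̄'W)` without definition.
* **Zero-phase filtering**: forward–backward IIR filtering with
  odd-reflection padding of length three times the coefficient count;
  epochs shorter than the padding are rejected rather than silently
  filtered with transients.
* **Rounding of fractional sample offsets**: round-half-to-even
  (`0.13 s × 250 Hz = 32.5 → sample 32`). Any fixed rule works; this one
  is bias-free and matches IEC 60559.
* **Tie-breaks**: argmax ties resolve to the lowest stimulus index;
  cluster-mean ties to the smaller cluster, then the lower label;
  Davies–Bouldin ties across `h` to the smallest `h`. All are documented
  so a full run is bit-reproducible under one seed.
* **Degenerate inputs**: zero-variance projections contribute a 0 feature
  (with a warning) instead of `NA`; coincident cluster centroids give an
  infinite Davies–Bouldin contribution; GMM fits that fail or collapse
  skip that `h`, and if every `h` fails the cluster count falls back to 2;
  an empty k-means cluster is re-seeded at the farthest point. With fewer
  than three stimuli, clustering is skipped and all stimuli are
  candidates.
* **Singleton candidate sets** short-circuit stage 2: a one-column
  projection correlation cannot change an argmax over one element.

## The synthetic generator

`simulate_epochset()` emulates the geometry of the public 40-target
benchmarks: 40 frequencies (8–15.8 Hz, 0.2 Hz steps), 250 Hz sampling,
block structure with one trial per (block, stimulus), nine channels, and a
0.14 s visual latency. The clean component of a trial is
`Σ_h a_h sin(2πh f_n (t − latency) + hφ_n)` with geometric harmonic decay
`a_h = 1/h` and a linear per-stimulus phase progression `φ_n = 0.35πn`
(phases are stable per stimulus — the structural assumption TRCA needs).
Harmonics are mixed into channels through a seeded random matrix whose
occipital channels get 3× gain, so channel-count sweeps behave
qualitatively like real montages. Noise is `1/f` pink (α = 1) plus a 10%
white floor, independent per channel and trial, scaled so the SNR measured
in the 6–90 Hz analysis band hits the configured target; −10 dB is used as
the "moderate noise" operating point, in the range commonly quoted for
in-band SSVEP recordings.

What the generator does **not** emulate: real cross-channel noise
correlation (volume conduction makes EEG noise strongly spatially
correlated; here it is independent per channel), eye-blink and EMG
artifacts, latency jitter across trials, inter-block non-stationarity, and
subject variability. Passing tests on this data therefore demonstrate
algorithmic correctness and the *direction* of effects (e.g. the hybrid
recognizer's low-trial advantage over TRCA), not the absolute accuracy
levels achievable on recorded EEG — synthetic accuracies here run higher
than real-data figures because the noise model is kinder.

## Evaluation protocol

Leave-one-block-out cross-validation: each of `B` blocks is held out once,
a fresh model bank is trained on the remaining blocks (optionally the
first `Nt` of them, deterministically, to emulate reduced calibration),
and accuracy plus ITR are computed per fold. ITR uses the analysis window
as the selection time with a configurable additive gaze-shift term
(default 0 s, matching the bare formula; published SSVEP ITRs often add
0.5 s). Note that a mean of per-fold ITRs is not the ITR of the mean
accuracy (Jensen gap), so published per-subject ITR tables cannot be
reproduced from accuracy summaries alone — the harness reports both
per-fold values and means.

Test-suite problem sizes are deliberately desk-scale: fixtures use 3
blocks of 8 or 40 stimuli at 0.5–1.0 s windows, the directional
H-TRCCA-vs-TRCA comparison runs 10 seeded replicates of a 40-class,
two-training-trial, 0.6 s configuration, and Monte-Carlo property checks
use 20–100 seeds. These sizes keep the full suite in the minutes range
while leaving every contrast far from its decision boundary.

## Known limitations

* The GMM stage inherits `mclust`'s full-covariance fit; on highly
  degenerate feature matrices (noise-free data produces nearly collinear
  rows) every `h` can fail and the fallback `h = 2` path runs instead.
  This is benign — with degenerate features the top cluster is obvious —
  but means the selected `h` is not meaningful there.
* Ensemble variants concatenate only TRCA filters; the CCA-derived filters
  are per-stimulus by construction (each is tied to its own reference) and
  are not ensembled.
* The container format is a versioned RDS file, readable only from R; the
  import adapter accepts the `[Nc × Ns × Nf × B]` array layout of the
  public benchmarks but deliberately does not download or parse their MAT
  files.
* No artifact rejection or re-referencing is provided: epochs are assumed
  to arrive notch-filtered and clean, as the public benchmark recordings
  do.
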