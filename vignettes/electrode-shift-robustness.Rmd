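---
title: "Electrode-shift robustness of SSVEP frequency decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode-shift robustness of SSVEP frequency decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepShift)
```

## The problem

Steady-state visual evoked potential (SSVEP) brain-computer interfaces
decode which flickering stimulus a user attends by detecting the stimulus
frequency (and its harmonics) in occipital EEG. The standard montage
records from O1, Oz and O2, but in daily use electrodes rarely land exactly
on those positions: caps are re-seated, and head-mounted displays push
electrodes around by roughly a centimeter. `ssvepShift` quantifies how much
decoding accuracy suffers under such displacements, and which algorithm and
channel-count choices are most robust to them.

The displacement model is a dense 3 × 7 occipital grid with 1.3 cm pitch,
centered on Oz (channel 11), with O1 and O2 at channels 5 and 17. Each of
the three nominal electrodes may shift to any position of its 9-channel
neighborhood group (left = channels 1–9, middle = 7–15, right = 13–21; the
groups overlap in channels 7–9 and 13–15). Enumerating independent shifts
gives 9 single-channel, 81 = 9 × 9 two-channel and 675 = 9³ − 54
three-channel configurations (tuples that would use the same physical
channel twice are excluded).

Channel numbering is column-major: channel = (col − 1) · 3 + row. The grid
description itself does not pin the numbering down, but this is the unique
3 × 7 numbering for which the stated groups are contiguous column bands
with the stated overlaps and the anchors land on the middle row — we treat
it as an inference, not a given.

## Classifiers

Five training-free scorers share one interface: score every candidate
frequency, pick the argmax (ties, possible only for degenerate inputs, go
to the lowest frequency index).

* **CCA** — the maximal canonical correlation ρ between the windowed EEG
  `X` (N × M) and a harmonic reference `Y` (2·Nh × M) whose rows are
  sin/cos pairs of the first Nh harmonics of the candidate frequency.
* **ECCA** — CCA after augmenting the EEG with a circularly delayed copy
  (`delayEmbed`, τ = 1 sample): the final τ samples move to the front.
  The reference is unchanged.
* **FBCCA** — the EEG is decomposed into Nsb = 5 sub-bands (4–52, 8–52,
  12–52, 16–52, 20–52 Hz, 3rd-order zero-phase Butterworth band-passes),
  each sub-band scored by CCA, and the squared correlations combined with
  weights w(n) = n^−1.25 + 0.25. Sub-band edges are applied literally, so
  a 6 Hz fundamental contributes to the 8–52 Hz band only through its
  harmonics.
* **MSI** — the multivariate synchronization index (S-estimator): from the
  joint correlation matrix of `X` and `Y` (blocks C11 = XX′/M,
  C22 = YY′/M, C12 = XY′/M, C21 = C12′), the diagonal blocks are whitened
  by their symmetric inverse square roots; the P = N + 2·Nh eigenvalues of
  the whitened matrix, normalized to sum to one, give
  S = 1 + Σ λ′ log λ′ / log P. S is 0 for independent signals and 1 for
  complete synchronization.
* **EMSI** — MSI on the delay-embedded EEG.

Numerical conventions, chosen where the definitions are silent:

* Rows of `X` and `Y` are mean-centered per window (correlation rather
  than raw-moment semantics; the 4 Hz high-pass has already removed DC).
* Inverse square roots use symmetric eigendecompositions with eigenvalues
  floored at `eigFloor` (default 1e−12 of the largest), so rank-deficient
  covariances (all-zero channels, duplicated channels, very short windows)
  degrade gracefully instead of crashing.
* The joint correlation matrix is made symmetric via C21 = C12′. (Writing
  C21 = C12 would be dimensionally inconsistent whenever N ≠ 2·Nh.)
* Natural logarithms in the entropy; any common base gives the same S.
  0 · log 0 is taken as 0.
* Nh = 4 harmonics for every algorithm and frequency; with the 10 Hz
  stimulus the highest harmonic (40 Hz) stays inside the 4–52 Hz band.

`ccaCoefficient` and `msiIndex` are validated against brute-force
definitional oracles (direct generalized-eigenproblem solution of the CCA
problem; element-by-element assembly of the S-estimator) on random small
instances to 1e−8, and both are invariant under invertible channel mixing
and channel scaling — which is also why the microvolt unit convention can
never silently change a decision.

For per-combination evaluation the package computes the full 21-channel
cross-covariances once per trial and frequency and subsets them per
channel combination; this fast path is tested for exact agreement with
direct per-combination classification.

## Preprocessing

Mirrors a conventional SSVEP pipeline: decimation to 256 Hz (zero-phase
anti-alias low-pass, then stride selection), a 3rd-order zero-phase
Butterworth band-pass at 4–52 Hz (forward–backward application: 6th-order
magnitude, zero phase), and extraction of analysis windows of 2–5 s in
0.5 s steps from stimulus onset (no visual-latency offset is applied).
Zero-phase filtering uses odd-reflection edge padding of three filter
lengths, so 2 s windows show no visible transients.

## Robustness measures and statistics

For one subject, algorithm, channel count and window length, the
per-combination accuracies (all trials pooled across sessions) are
summarized by

* **ACA** — their mean, and
* **RES = 1 − CV** — one minus the coefficient of variation
  (sd/mean, sample sd with n − 1; a `sd = "population"` option exists).

The statistical layer is a fully within-subject two-way ANOVA (channels ×
algorithm, per window length, no sphericity correction: a 21 × 3 × 5
design reports df (2, 40), (4, 80) and (8, 160)) plus two-sided paired
t-tests with Bonferroni correction, the family being all level pairs of
one factor per window length (3 pairs for channels, 10 for algorithms).
Zero-variance pairs are flagged `degenerate` and reported non-significant
rather than erroring, so constant synthetic data never aborts a pipeline.
A sign-of-difference column accompanies the unsigned corrected p-values.

`shiftDirectionMap` models a rigidly displaced montage: all three anchors
move together by one grid step in each of the nine directions (including
no shift); mean accuracies across subjects are min–max normalized per map.
An all-equal map (possible on ceiling-level synthetic data) normalizes to
zeros with a warning. Normalization is per window length; pooling across
window lengths would mix accuracy scales that differ systematically.

## The synthetic generator

Real deposited recordings are not required anywhere: `simulateRecording`
produces epoched 21-channel data with the structure the analysis assumes.

* **Stimuli**: four frequencies stored as exact rationals of the 60 Hz
  monitor refresh — 60/10, 60/9, 60/8, 60/6 Hz — with four harmonics whose
  amplitudes decay as k^−γ (γ = 1). Trials are 5 s; labels are
  counterbalanced in randomized blocks of four; 25 trials per frequency
  per subject mirror 20 trials × 5 sessions.
* **Spatial gain**: the SSVEP amplitude at each electrode follows an
  isotropic Gaussian of physical distance from a focus cell (default Oz),
  `gainSigma` = 4 cm, putting O1/O2 at ~81 % of the Oz amplitude and the
  outer grid columns at ~60 % — a broad occipital response with a clear
  falloff, so displaced electrodes genuinely see lower SNR.
* **Phase topography**: the response latency grows by 10 ms per cm of
  distance from the focus (`latencyGradient`), on top of a per-trial
  random phase shared by all channels and harmonics. Scalp SSVEPs are not
  phase-locked across sites; this inter-channel phase diversity is
  precisely what gives multichannel synchronization measures (MSI/EMSI)
  their edge. With a perfectly phase-locked (spatially rank-1) response
  the extra canonical correlations of MSI carry only estimation noise and
  multichannel MSI cannot beat a single good electrode — we verified this
  and therefore model the latency topography explicitly.
* **Background**: 1/f^β noise (β = 1) in three parts — a small number
  (4) of spatially coherent sources with smooth random per-subject
  topographies, a uniform common-mode term (weight 0.3), and
  channel-independent sensor noise. The coherent-plus-common share is
  `structuredNoiseFraction` = 0.5 of the background power at the focus
  channel. A single high-weight uniform common mode is deliberately
  avoided as the dominant structure: it is rank-1 and spatially aligned
  with the (smooth) signal topography, so a filter canceling it cancels
  signal too — an artifact, not physiology.
* **SNR**: `snrDb` is total SSVEP power over total background power at
  the focus channel; default −20 dB. This is a broadband figure — with
  narrowband matched references and 5 s windows, −20 dB still yields
  ~70 % single-trial accuracy at the focus, i.e. the mid-range regime the
  robustness comparisons need; at −10 dB and above accuracy saturates.
* **No alpha by default**: a spontaneous 10 Hz oscillator would alias
  into the 10 Hz stimulus class and confound chance-level checks;
  `alphaWeight` enables it for stress tests.
* **Reproducibility**: one integer seed; each subject draws an
  independent substream, so enlarging a study never perturbs earlier
  subjects' data.

What the generator does **not** emulate: eye blinks and EMG artifacts,
electrode-impedance drift, inter-trial nonstationarity of the SSVEP
amplitude, realistic alpha reactivity, or volume-conduction physics beyond
smooth spatial mixing. Passing tests on this generator therefore
demonstrate correctness of the algorithms and the qualitative geometry of
shift robustness — not clinical-grade performance figures.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run scaled-down studies chosen to
exercise every code path at stable Monte-Carlo margins: chance level uses
400 pure-noise trials; signal recovery 100 trials at +20 dB; the
multichannel ordering 15 subjects × 40 trials at 3 s windows with the
single-channel grid complete (9 combinations) and the three-channel grid
down-sampled deterministically to 25 of 675 combinations (`maxCombos`);
the reported ACA/RES study uses 8 subjects. The full 675 × 5 × 7 grid at
25 trials per frequency is available through `runExperiment` defaults.

## A worked example

```{r example, eval = FALSE}
grid <- electrodeGrid()
cfg <- simulationConfig(nSubjects = 3, trialsPerFrequency = 10, seed = 1)
recs <- lapply(simulateStudy(cfg), function(r)
    extractWindow(bandpassRecording(r), 3))

emsi <- classifierConfig("EMSI")
res3 <- lapply(recs, evaluateRobustness, grid = grid, config = emsi,
               nChannels = 3, maxCombos = 25)
measureTable(res3)
```

## Known limitations

* The deposited-dataset loader is not included; the container format
  (raw float64 payload + JSON sidecar) covers simulated and user-supplied
  epoched data.
* Single-channel MSI decisions coincide with CCA decisions (both are
  monotone in the one canonical correlation), so algorithm contrasts are
  meaningful only for multichannel configurations — as in the real study.
* RES is undefined for an all-zero accuracy vector (zero mean); the
  package raises an error rather than guessing.
* Degrees of freedom assume the complete balanced crossing; incomplete
  tables are rejected rather than approximated.
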