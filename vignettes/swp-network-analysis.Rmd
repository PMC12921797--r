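---
title: "Small-world propensity analysis of EEG phase-coupling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world propensity analysis of EEG phase-coupling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swpnet)
```

## What the package computes

`swpnet` implements a sensor-space EEG functional-network pipeline for
two-group, two-condition auditory designs, together with a synthetic-cohort
generator that lets every stage be validated by parameter recovery:

1. **Preprocessing** — zero-phase Butterworth band filtering into seven
   canonical bands (delta 1.5–4, theta 4–8, alpha 8–13, beta1 13–20,
   beta2 20–30, gamma1 30–48, gamma2 52–70 Hz), onset-locked 800 ms
   epoching at 250 Hz, and three-stage trial rejection (±200 µV amplitude,
   evoked signal-to-noise, behavioral correctness) followed by epoch-count
   balancing across groups.
2. **Connectivity** — the weighted Phase Lag Index (wPLI) between every
   sensor pair. For analytic signals $z_a, z_b$ with cross-spectral samples
   $S_k = z_{a,k}\,\overline{z_{b,k}}$,
   $$\mathrm{wPLI} = \frac{\lvert\, \mathbb{E}[\operatorname{Im} S]\,\rvert}
                          {\mathbb{E}[\lvert \operatorname{Im} S\rvert]},$$
   which lies in $[0,1]$, is symmetric, and discards zero-lag coupling —
   the property that suppresses volume-conduction artifacts.
3. **Graph analysis** — Onnela weighted clustering, characteristic path
   length on $1/w$ edge costs, node strength, node and edge betweenness
   (Brandes), and the Small-World Propensity
   $$\Delta C = \frac{C_{latt}-C_{obs}}{C_{latt}-C_{rand}},\qquad
     \Delta L = \frac{L_{obs}-L_{rand}}{L_{latt}-L_{rand}},\qquad
     \phi = 1-\sqrt{\tfrac{\Delta C^2+\Delta L^2}{2}},$$
   with $\Delta C,\Delta L$ clamped to $[0,1]$. The lattice null places
   the observed weights onto a ring lattice, largest weights at the
   smallest ring distances; the random null averages 100 (configurable)
   degree-preserving rewirings with reshuffled weights.
4. **Statistics** — Kruskal–Wallis tests for behavior, 1000-permutation
   label-exchange tests for the global measures (Bonferroni at
   $\alpha/3 \approx 0.0167$ across $\phi, \Delta C, \Delta L$;
   Benjamini–Hochberg FDR across families), cluster-mass permutation tests
   on the Delaunay sensor-neighborhood graph for node metrics
   ($\alpha/2 = 0.025$), hub detection by the one-standard-deviation rule,
   hemispheric median comparisons, and robust (Huber, $k = 1.345$)
   regressions of the behavioral Inverse Efficiency Score
   ($\mathrm{IES} = \overline{RT}_{correct}/p_{correct}$) on $\phi$.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
without reproducing any particular dataset (the clinical recordings such
studies use are typically restricted). Its defaults encode the study
design: a control group of 20 and a dyslexia ("dd") group of 24 subjects,
word and pseudoword conditions, 800 ms epochs at 250 Hz on a 40-channel
10-10/10-20 montage, clean-epoch counts of 32 ± 5 (control) and 21 ± 7
(dd) per subject and condition, and 40 behavioral trials per condition.

**Ground truth.** Each subject and band receives a Watts–Strogatz-style
weighted network: ring lattice of degree 4, rewired edge-wise with
probability 0.1 (control) or 0.5 (dd), weights uniform(0.5, 1), and a
fixed phase lag per edge drawn from $\pm[\pi/8, 3\pi/8]$. Lags are never 0
or $\pi$, where a phase-lag-based estimator is blind by construction.
Expressing the group difference through rewiring makes clustering — hence
$\Delta C$ — the manipulated quantity.

**Signals.** Per band, every channel carries a sinusoid at the band centre
whose phase adds an Ornstein–Uhlenbeck drift (rate 8 s⁻¹, diffusion
6 rad/√s), so uncoupled channels decorrelate while staying narrowband.
A coupled pair shares signal: each endpoint receives the other's
oscillator shifted by the edge lag, with mixing gain `0.8 × weight` and
per-trial von Mises jitter whose concentration grows with the weight
(stronger edges are more phase-stable). A stimulus-locked evoked response
(damped 5 Hz oscillation, ~15 µV peak, fixed per-channel gains) is added
identically to every trial: it gives the epochs a realistic cross-trial
mean — without it the evoked-SNR rejection rule has nothing to measure —
and, being common and instantaneous, it is also a built-in probe of the
estimator's zero-lag insensitivity. Clean signals sit near ±50 µV;
injected artifact transients reach ±400 µV so the ±200 µV rule bites; a
10% artifact rate is the default. Gaussian sensor noise has a 5 µV
standard deviation. Everything is reproducible bit-for-bit from one seed.

**Behavior.** Accuracy follows a logistic link in the subject's
ground-truth small-world propensity $\phi$; correct-trial reaction times
are lognormal around a mean chosen so that $\mathbb{E}[\mathrm{IES}] =
2600 - 2000\,\phi$ ms — a planted negative efficiency relationship of the
magnitude such studies report (slopes of order $-1600$ to $-2500$ ms per
unit $\phi$).

**What the generator does not emulate.** Volume conduction beyond an
optional instantaneous mixing switch, 1/f background spectra, non-
stationary artifacts (drifts, electrode pops), condition-specific network
differences, and any acoustic stimulus structure. Passing recovery tests
therefore demonstrates the correctness and calibration of the estimators
and inference machinery on data satisfying the model's assumptions — not
that those assumptions hold in any given recording.

## Numerical and design choices

- **Filtering.** 4th-order Butterworth band-pass applied forward and
  backward (zero phase). Epochs are reflection-padded by half an epoch per
  side before filtering and re-cropped, standard practice for short
  epochs. The broadband stage is 1–70 Hz with a 48–52 Hz band-stop notch.
  All filters run as matrix-vectorized `stats::filter` passes, verified
  against `signal::filtfilt`.
- **Evoked SNR.** Per sensor, noise is the standard deviation of a
  trial's residual after subtracting the cross-trial mean; SNR is the mean
  signal's peak-to-peak amplitude over twice that noise. The formula has
  no canonical cut-off; the default `snr_min = 1` (signal at least as
  large as noise) is exposed in the configuration. Rejection order is
  amplitude → SNR → correctness, so the SNR reference mean is computed on
  amplitude-clean trials only. The amplitude rule is applied on any
  channel; the SNR rule rejects trials, not sensors.
- **wPLI observation set.** The estimator needs an expectation. The
  package supports three modes: single-trial matrices over within-trial
  samples (`"trials"`, the default unit of analysis, with the first and
  last 10% of samples excluded as Hilbert edge effects), their
  across-trial average (`"average"`), and one estimate over the pooled
  samples of all clean trials (`"pooled"`). For 800 ms epochs the
  narrowband coherence time allows only ~2–3 independent phase
  observations per trial in theta, so single-trial estimates carry a noise
  floor of ~0.5–0.65 regardless of true coupling; the pooled mode is the
  appropriate estimator at that epoch length and is what the package's
  own recovery analyses use. A debiased variant of the estimator is
  available (`debias = TRUE`). Subtracting the cross-trial mean before
  phase extraction (`subtract_evoked = TRUE`) restricts the estimate to
  induced activity; with a strong evoked component this markedly improves
  sensitivity, because evoked energy inflates the wPLI denominator
  without contributing consistent non-zero-lag phase.
- **Graphs are fully weighted.** No proportional thresholding is applied
  (none is part of the analysis the package mirrors). Path costs are
  $1/w$. Disconnected pairs are excluded from $L$ and counted; more than
  50% unreachable pairs is an error. The lattice surrogate fills slots in
  a fixed order (ring distance, then row, then column), making it a
  deterministic idempotent map. Degenerate nulls ($C_{latt} = C_{rand}$)
  produce a clamped deviation with a warning.
- **Hubs.** Strength and betweenness are normalized per subject by their
  across-node mean before group averaging; a node (or edge) is a hub
  (important) when its group average exceeds the across-node mean by at
  least one sample standard deviation.
- **Sensor adjacency.** Delaunay triangulation of the 2-D montage
  positions, pruned at 1.5× the median triangulation edge length; any
  isolated sensor is re-attached to its nearest neighbour so the cluster
  search covers the whole cap.
- **Cluster-forming statistic.** The per-node statistic is the
  tie-corrected normal approximation of the Wilcoxon rank-sum, two-sided
  at 0.05, for coherence with the rank-based global tests; clusters are
  sign-consistent connected components, and the corrected p-value comes
  from the permutation distribution of the maximum cluster mass
  (add-one Monte-Carlo estimator, never exactly zero).
- **Regression direction.** $\phi$ predicts IES (both directions are a
  one-line swap); the reported $R^2$ is computed on the final Huber
  weights and adjusted as $1-(1-R^2)(n-1)/(n-2)$.

## Problem sizes used in the validation suite

The automated checks run at desk scale, chosen to keep the full suite
within minutes while leaving the Monte-Carlo error small relative to every
asserted margin: null-model counts of 10–50 where the reference procedure
uses 100 (the acceptance script's cohort run uses 20; the clustering-only
recovery runs use 12 surrogates because only $\Delta C$ is scored there);
500–1000 permutations per test; 500–1000 simulations for the calibration
checks; 50 replicate cohorts of 12 + 12 subjects with 20 clean epochs for
end-to-end recovery, simulated over a delta–theta–alpha background
(multiband context at a fraction of the full-set cost) and analyzed in
theta.

## A known limitation: $\Delta C$ on dense wPLI matrices

A fully weighted wPLI matrix is dense: every pair gets a positive value,
coupled pairs (~0.45 here) and an estimation floor (~0.15) alike. On such
matrices the Onnela clustering of the lattice and random surrogates
differ only a little — rearranging weights moves a small fraction of the
total triangle mass — so the $\Delta C$ denominator is small and
subject-level $\Delta C$ is noisy and prone to saturate at its clamps.
In the package's recovery experiments the planted topology difference
(rewiring 0.1 vs 0.5) is therefore only weakly visible in $\Delta C$ at
n = 12 + 12, and the direction that does emerge is the one the deviation
formula dictates: the *more rewired* group sits closer to its random null
and shows the *higher* $\Delta C$. Note the sign convention: because
$\Delta C$ measures the shortfall from the lattice, a group with a genuine
clustering deficit has a larger $\Delta C$, not a smaller one —
interpretations that equate "smaller $\Delta C$" with "less clustering"
invert the metric. Sparsifying the matrices before graph analysis would
sharpen the null contrast considerably, but is deliberately not part of
the default pipeline, which analyzes fully weighted graphs.

## Reproducibility

Every stochastic stage (network draw, epoch simulation, behavior,
subsampling, null models, permutations) flows from explicit seeds; a
pipeline run is a pure function of its configuration, and re-running
`run_pipeline()` with the same `run_config()` reproduces every output
byte for byte. Configurations round-trip through YAML; ground truth can
be saved as JSON for external recovery checks; epoch sets can be
exchanged as delimited text or minimal EDF.
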