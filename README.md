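# swpnet — small-world propensity analysis of EEG phase-coupling networks

`swpnet` is an R package for sensor-space EEG functional network analysis
in two-group, two-condition designs (e.g. clinical group vs. controls
listening to words and pseudowords). It turns band-limited, onset-locked
epochs into weighted Phase Lag Index (wPLI) connectivity matrices, scores
each subject's network with the Small-World Propensity against lattice and
random null models, locates hubs by strength and betweenness centrality,
tests group differences with permutation and cluster-mass statistics under
Bonferroni and Benjamini–Hochberg control, and links network topology to
behavioral efficiency with robust regression.

Because the raw clinical recordings behind such studies are typically
restricted, the package ships a first-class synthetic-cohort generator:
phase-coupled oscillator epochs over ground-truth Watts–Strogatz networks
with planted group differences, injected artifacts, and behavior tied to
network efficiency. Every stage of the pipeline can be validated by
recovering what was planted.

## The quantities at the core

For analytic signals $z_a, z_b$ and cross-spectral samples
$S_k = z_{a,k}\overline{z_{b,k}}$:

$$\mathrm{wPLI}(a,b) = \frac{|\mathbb{E}[\mathrm{Im}\,S]|}{\mathbb{E}[|\mathrm{Im}\,S|]} \in [0,1]$$

wPLI ignores zero-lag coupling, suppressing volume-conduction artifacts.
The resulting weighted adjacency is scored with the Small-World Propensity

$$\Delta C = \frac{C_{latt}-C_{obs}}{C_{latt}-C_{rand}},\quad
  \Delta L = \frac{L_{obs}-L_{rand}}{L_{latt}-L_{rand}},\quad
  \phi = 1-\sqrt{\frac{\Delta C^2+\Delta L^2}{2}}$$

using Onnela weighted clustering, Dijkstra path lengths on $1/w$ costs, a
sorted-weight ring-lattice surrogate and degree-preserving random
surrogates. Behavioral efficiency is the Inverse Efficiency Score,
$\mathrm{IES} = \overline{RT}_{\mathrm{correct}} / p_{\mathrm{correct}}$
(ms), regressed on $\phi$ with Huber M-estimation.

## Worked example

```r
library(swpnet)

cfg <- run_config(
  cohort = default_cohort_config(
    n_subjects = c(control = 6, dd = 6),
    bands = c("theta", "beta1"),
    epochs_per_subject = list(control = c(mean = 12, sd = 2),
                              dd = c(mean = 12, sd = 2)),
    phi_null_models = 10, seed = 7),
  connectivity_mode = "pooled", subtract_evoked = TRUE,
  n_random = 20, n_perm = 500, seed = 7)

bundle <- run_pipeline(cfg)        # or run_pipeline(cfg, out_dir = "results/")
cat(write_report(bundle)[1:12], sep = "\n")
```

```
==== Small-world propensity network analysis ====

-- Global measures, condition: word --
band     measure                 control                     dd   p_perm   bonf  fdr
theta    phi          0.5177 +/- 0.0475       0.4301 +/- 0.0417     0.1856
theta    delta_c      0.6816 +/- 0.0672       0.8055 +/- 0.0589     0.2275
theta    delta_l      0.0229 +/- 0.0032       0.0253 +/- 0.0059     0.7864
beta1    phi          0.3926 +/- 0.0372       0.3876 +/- 0.0432     0.9481
beta1    delta_c      0.8586 +/- 0.0528       0.8658 +/- 0.0612     0.9361
beta1    delta_l      0.0175 +/- 0.0077       0.0178 +/- 0.0053     0.9721
```

Each row gives the group mean ± standard error of a global network
measure per band, the two-sided label-permutation p-value, and whether it
survives Bonferroni (α/3 ≈ 0.0167 over the three dependent measures) and
FDR control. Here the "dd" group — whose ground-truth networks are rewired
at p = 0.5 instead of 0.1, i.e. have degraded clustering — shows the
higher θ-band ΔC (clustering further from the lattice null) and lower φ,
though at 6 + 6 subjects the permutation test does not reach significance.
The same bundle carries per-subject metrics, hub tables, cluster-mass
results, hemisphere comparisons, IES values (here: word-condition mean
1281.8 ms for controls vs. 1795.0 ms for dd, reflecting the planted
negative IES–φ link) and the robust efficiency regressions; with
`out_dir` everything is written as tidy TSV plus a JSON summary and a
provenance log, and reruns with the same config are byte-identical.

Continuous recordings can also be read from delimited text or EDF
(`read_delimited_recording()`, `read_edf()`), segmented with
`segment_epochs()`, and pushed through the same stage functions.

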