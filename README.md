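# aecnet

Frequency-resolved resting-state network analysis for band-limited neural
(MEG-style) parcel time series, from raw-ish signals to corrected
developmental-trajectory statistics.

## Who this is for

Groups studying how functional brain networks reorganize (e.g. between
childhood and adulthood) from electrophysiological recordings, where
connectivity must be estimated per frequency band and where instantaneous
field spread ("leakage") makes naive amplitude correlations untrustworthy.
The package also ships a seeded synthetic-cohort generator with planted
ground truth, so the whole pipeline can be exercised and validated without
access to gated patient data.

## What it computes

The connectivity core is the **orthogonalized amplitude-envelope
correlation**.  For band-limited analytic signals
X̂(t) = x(t) + i·H[x(t)] and Ŷ(t):

    |Ŷ⊥X(t)| = |Im(Ŷ(t) X̂†(t))| / |X̂(t)|
    C⊥(X̂, Ŷ) = [Corr(|X̂|, |Ŷ⊥X|) + Corr(|Ŷ|, |X̂⊥Y|)] / 2

computed over 30-s sliding windows (stride 1/8 of the window; windows
touching rejected samples are excluded) and collapsed by the median.  Around
it:

* **cleaning** — 5σ amplitude spikes, 3 SD peaks of the 31–80 Hz EOG
  envelope (REOG), 1-s head-motion blocks above 1.7 mm/s;
* **spectral** — SVD sign-aligned label averaging, zero-phase FIR band-pass
  with a 60 Hz notch, decimation keeping fs > 3·f_hi, analytic-signal
  envelopes;
* **graphs** — proportional-cost binary adjacency (cost grid 5–30%), path
  length, degree, clustering, global/local efficiency, betweenness;
* **resilience** — targeted (degree- or score-ranked) and random node
  removal with normalized global efficiency, and a per-removal age
  correlation scan;
* **stats** — Spearman correlations corrected by maximum-statistics
  permutation (p_c = 2(n+1)/(n_p+1), n_p = 10,000 by default), bootstrap-CI
  confirmation, nested bootstrap clouds (1,024 realizations), LOESS with
  10-fold cross-validated bandwidth over 0.01–0.99.

## Worked example

A 60-subject synthetic cohort (ages 7–29, 64 parcels) with planted positive
age slopes on beta-band local efficiency and gamma-band global efficiency:

```r
library(aecnet)
cfg <- cohort_config(
  n_subjects = 60, n_nodes = 64,
  bands = list(beta = band_definition("beta", 13, 30),
               gamma = band_definition("gamma", 31, 80)),
  fs = 600, age_effect_local = 0.01, age_effect_global = 0.01, seed = 1)
run <- run_pipeline(pipeline_config(cfg, file.path(tempdir(), "demo"),
                                    n_p = 2000, max_remove = 20, seed = 1))
print(run$correlations)
```

```
<corrected_correlation> 24 cell(s), n_p = 2000 (min attainable p_c = 0.001)
  corrected-significant cells:
                         cell    rho p_raw   p_c
   beta|0.1|global_efficiency -0.479 5e-04 0.006
    beta|0.1|local_efficiency  0.626 5e-04 0.001
  beta|0.15|global_efficiency -0.654 5e-04 0.001
   beta|0.15|local_efficiency  0.738 5e-04 0.001
    beta|0.2|local_efficiency  0.494 5e-04 0.004
    beta|0.3|local_efficiency  0.445 1e-03 0.011
 gamma|0.15|global_efficiency  0.417 3e-03 0.023
  gamma|0.15|local_efficiency -0.512 5e-04 0.001
```

Each cell is one band × cost × metric combination; `rho` is the Spearman
correlation of the metric with age and `p_c` its family-wise-corrected
p-value over all 24 cells.  The planted effects are recovered with their
planted signs — beta local efficiency rises with age, gamma global
efficiency rises with age — and each carries the opposite-signed echo in the
complementary metric that a lattice↔shortcut topology trade-off implies.
The run directory receives `metrics.csv`, `correlations.csv`,
`resilience.csv` and a `manifest.json` with the config hash and file
checksums.

```r
print(run$resilience)
```

```
<resilience_scan> 40 cell(s), snapshot(s):
  band   term k node_removed    rho  p_raw   p_c
  beta degree 4           26 -0.427 0.0015 0.021
 gamma degree 6           14  0.374 0.0050 0.067
```

The scan removes hub nodes in one fixed group-level order for every subject
and correlates each removal count's normalized global efficiency with age;
the snapshot rows mark the removal count with the strongest age effect per
band.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline run from scratch: it generates the
planted synthetic cohort for that seed, executes the full pipeline
(connectivity → cost-thresholded graphs → corrected trajectory statistics →
resilience scan) at the analysis defaults, logs a summary to stderr, and
writes the result object to `--out`.
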