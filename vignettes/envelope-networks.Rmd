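---
title: "Frequency-resolved envelope-correlation networks: methods and design"
author: "aecnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved envelope-correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aecnet)
```

# The problem

Resting-state functional networks in the developing brain reorganize between
childhood and adulthood, and they do so differently depending on the cortical
rhythm that mediates the coupling: networks carried by the beta band
(13-30 Hz) tend to become more locally clustered with maturation, while
gamma-band networks (31-80 Hz) prioritize long-range integration.  Testing
such claims requires a pipeline that goes from band-limited parcel time
series all the way to corrected developmental-trajectory statistics:

1. artifact cleaning by fixed threshold rules,
2. sign-aligned label averaging, band-pass filtering and analytic-signal
   envelopes,
3. leakage-insensitive orthogonalized envelope correlation over sliding
   windows, collapsed by the median,
4. proportional-cost binary graphs and their metrics,
5. targeted-attack resilience, optionally ranked by external per-node score
   maps (e.g. meta-analytic association z-scores),
6. Spearman age correlations corrected by maximum statistics over the whole
   comparison space, confirmed by bootstrap, and visualized with
   cross-validated LOESS and a nested bootstrap cloud.

`aecnet` implements every stage as a tested, reusable component, plus a
synthetic-cohort generator that plants known structure so each stage can be
validated end to end.  Real recordings of this kind are typically gated by
data-sharing agreements; the generator is therefore a first-class module,
not a test shim.

# The estimator at the core

For two band-limited analytic signals $\hat{X}(t)$, $\hat{Y}(t)$ (series plus
$i$ times their Hilbert transforms), instantaneous field spread produces
spurious zero-lag correlation.  The orthogonalized envelope correlation
removes the component of $\hat{Y}$ collinear with $\hat{X}$ at each sample,

$$|\hat{Y}_{\perp X}(t)| = \frac{|\mathrm{Im}(\hat{Y}(t)\,
\hat{X}^\dagger(t))|}{|\hat{X}(t)|},$$

and correlates envelopes in both directions, averaging:

$$C_\perp(\hat X,\hat Y)=\tfrac12\left[\mathrm{Corr}(|\hat X|,
|\hat Y_{\perp X}|)+\mathrm{Corr}(|\hat Y|,|\hat X_{\perp Y}|)\right].$$

$C_\perp$ is exactly zero for $\hat Y = c\hat X$ (real $c$), invariant to
positive rescaling of either input, and computed over 30-s windows with a
stride of 1/8 of the window so that each window spans several slow envelope
cycles.  Windows overlapping any rejected sample are excluded whole; the
per-pair median over valid windows gives the connectivity matrix.

## Known residual bias

Pairwise orthogonalization is not a complete leakage correction: the
*reference* envelope $|\hat X|$ of a mixed signal still contains a share of
the other source's envelope, so mixed-but-independent pairs retain a small
positive residual.  With the generator's default modulation depth and a
pairwise mixing weight of 0.4 we measure a median residual of about
0.04-0.05, against a naive envelope correlation of about 0.45 for the same
pairs.  Conclusions should therefore rest on the relative pattern of
$C_\perp$, not on its absolute zero point - one reason the graph stage
thresholds at fixed cost rather than at a fixed correlation value.

# Graph stage conventions

Connectivity matrices are binarized by *proportional cost*: the strongest
`round(cost * N(N-1)/2)` entries become edges (ties broken by value, then
row-major pair index, so the graph is reproducible).  Fixing cost equates
edge counts across subjects, the precondition for comparing metrics across
ages.  Because no single cost is privileged, metrics are evaluated over
5-30% in 5% steps by default (`default_costs()`).

Metric conventions on possibly-disconnected binary graphs:

* distances are BFS hop counts; unreachable pairs are `Inf`;
* average path length is taken over reachable ordered pairs only, with the
  reachable fraction reported alongside;
* global efficiency uses $1/\infty = 0$, so it is defined for any graph;
* local efficiency of a node is the global efficiency of the subgraph
  induced on its neighbours (zero below degree 2) - note this differs from
  the neighbourhood definition used by `igraph::local_efficiency()`;
* clustering is triangle density of the neighbourhood, zero below degree 2;
* betweenness sums over unordered pairs, endpoints excluded, unnormalized.

Shortest-path kernels are compiled (Rcpp BFS) because the simulation-based
tests evaluate hundreds of thousands of graphs; every metric is checked
exhaustively against matrix-power / walk-count oracles on all labelled
graphs up to 6 nodes and on random graphs up to 12 nodes.

The "small-world index" is deliberately not exposed as a named metric: it is
discussed qualitatively in this literature as the relative strength of local
and global efficiency but has no single printed formula; both efficiencies
are reported instead.

# Resilience

A targeted attack removes nodes in a stated order (descending degree, or an
external per-node score map averaged from vertex-level z-scores); after each
removal the remaining graph's global efficiency is recomputed and divided by
the intact value, giving the curve $r_0 = 1, r_1, \dots$.  Removed nodes
leave the graph entirely (remaining-node convention; the reference
formulation does not state the alternative fixed-denominator convention, and
the ratio form makes the two nearly equivalent in practice).  The
score-ranked variant applies *one* fixed order to every subject, so
between-subject differences in the curve reflect topology, not ranking.

The per-removal age scan correlates each removal count's normalized
efficiency with age and corrects over the full declared space (bands x
removals x terms) by maximum statistics.  The removal count maximizing
$|\rho|$ is reported as the "snapshot", but the whole curve is always
emitted.

# Trajectory statistics

* **Spearman correlation** on average ranks.
* **Maximum-statistics correction**: each of $n_p$ permutations shuffles the
  ages *once* and recomputes the correlation for every cell of the
  comparison grid with that same shuffle (reusing one shuffle across cells
  is required for the validity of the max-statistic); the maximum and
  minimum over the grid form the null record.  For an observed positive
  (negative) $\rho$, $n$ counts null maxima above it (minima below it) and
  $p_c = 2(n+1)/(n_p+1)$, capped at 1.  The attainable minimum is exactly
  $2/(n_p+1)$, and $p_c$ is monotone in $|\rho|$ within a fixed null record.
  Default $n_p = 10000$.
* **Robust confirmation**: corrected-significant cells are re-tested by a
  percentile bootstrap CI of the Spearman correlation over subject
  resamples; "confirmed" means the 95% CI excludes zero.  Only this
  bootstrap-CI check is implemented, not a full robust-correlation toolbox.
* **Nested bootstrap** (1024 realizations): the joint (age, metric)
  distribution is visualized by drawing an age anchor, resampling with
  replacement among the `m = max(5, n/10)` nearest-age subjects, and
  recording that draw's (mean age, mean metric).  The exact resampling
  scheme behind published density maps of this kind is under-specified;
  the local-neighbourhood scheme above reproduces their qualitative
  behaviour (clouds that span the age axis and tighten where data are
  dense), and a plain pooled bootstrap is available via
  `scheme = "pooled"`.
* **LOESS**: local linear regression with tricube weights (the method name
  alone does not fix kernel and degree; degree-1/tricube is the standard
  choice, and degree 1 makes the fit exact on linear data).  The bandwidth -
  the fraction of points per local fit - is selected from 0.01 to 0.99 in
  0.01 steps by 10-fold cross-validation on summed out-of-fold squared
  error; infeasible candidates (local neighbourhoods under 3 points) are
  skipped and logged; ties go to the smallest bandwidth.

# The synthetic cohort

`cohort_config()` defaults describe the emulated population: 131 subjects
aged 7-29 (uniform), 448 parcels, five bands (delta 1-4, theta 4-8, alpha
8-12, beta 13-30, gamma 31-80 Hz; the 31 Hz gamma floor follows the methods
convention over the 30 Hz one sometimes quoted), 5-minute recordings at
600 Hz with the sampling rule $f_s > 3 f_{hi}$ enforced.

**Signals.**  Each node is a band-passed Gaussian carrier (broadband-in-band,
so envelopes are non-degenerate) multiplied by a slow positive modulator
$1 + |z(t)|$, where $z$ is unit-variance Gaussian low-passed below 0.5 Hz -
several modulator cycles fit in every 30-s window.  Planted coupling sets
the correlation of the underlying $z$ processes; leakage is an instantaneous
row-normalized mixing toward ring neighbours.  The additive-baseline
modulator form matters: a purely rectified modulator lets envelopes collapse
toward zero, which inflates the orthogonalization residual through the
$1/|\hat X|$ factor.

**Topology and age effects.**  Age effects are planted at the graph level
(edge placement), not the signal level, so downstream metric recovery is
interpretable.  Nodes sit on a ring; each band's planted edges are a
lattice/shortcut mixture: short-range pairs build triangles (local
efficiency), long-range pairs build shortcuts (global efficiency), and one
mixing fraction interpolates between the two, Watts-Strogatz style.  The
local band's short-range fraction and the global band's long-range fraction
shift by 0.01/year by default (the slope also used in the recovery
simulations); a one-parameter mixture necessarily gives each planted effect
an opposite-signed echo in the other metric, which is itself realistic.
A fixed slice of strong edges is forced onto designated hub nodes (10% of
nodes by default), and `age_effect_hub` (default 0) lets hub dependence
decline with age for resilience-recovery experiments.  Strong edges get
weights in (0.5, 0.9) against a (0, 0.3) background, so proportional
thresholding at or below the planted density (0.15) recovers planted edges.

**Artifacts.**  Auxiliary channels are generated at an acquisition-style
rate (at least 200 Hz): a broadband reference trace with 8-sigma spikes;
HEOG/VEOG modelled as slow (< 5 Hz) ocular signal plus weak broadband
instrument noise, with 31-80 Hz bursts injected - the quiet saccade-band
baseline is what makes the whole-series 3 SD REOG threshold a reliable
burst detector; and a head-speed trace with 1-s excursions at 2.5 mm/s
against a ~0.5 mm/s baseline.  Default rates (1 spike, 2 bursts,
0.5 excursions per minute) represent *residual* artifacts after upstream
projection-based cleaning, which keeps total data loss well under 10%.
Counts are deterministic (rate x minutes); positions are seeded and logged
as ground truth.

**Reproducibility.**  One global seed expands into per-subject substreams
drawn from the master stream, so cohorts are bit-identical across runs and
subjects are independent.

## What a green test does and does not establish

The generator realizes the statistical structure the analysis assumes:
stationary carriers, a single shared modulator timescale, instantaneous
(zero-lag) leakage, uniform ages, and graph-level age effects that are
linear in expectation.  Real recordings violate most of these in detail
(non-stationarity, 1/f spectra, lagged and distributed leakage, sampling
biases), so green tests establish the *correctness of the computations and
the statistical calibration of the corrections* - not that the pipeline
would recover any particular effect from real data.

# Numerical choices

* Zero-phase filtering uses odd-length windowed-sinc (Hamming) FIR kernels
  applied centred with reflection padding, so envelope timing never shifts
  between nodes; samples within one filter half-width of an edge are marked
  invalid.  The 60 Hz notch (1 Hz wide, applied only when 60 Hz lies inside
  the band) uses its own, longer kernel so that the transition fits inside
  the stop band; measured attenuation at the line frequency exceeds 20 dB.
* Decimation keeps the largest integer factor with $f_{s,out} > 3 f_{hi}$.
* The analytic signal is assembled as `x + 1i * Im(hilbert(x))`, making the
  real-part contract exact.
* Orthogonalization guards divisions where $|\hat X|$ is below $10^{-12}$ of
  its peak (samples marked invalid) and floors envelopes below $10^{-10}$ of
  the peak of $|\hat Y|$ to exact zero, so real multiples orthogonalize to
  an identical zero rather than to float noise.
* Windows are tiled from $t = 0$; a trailing partial window is discarded;
  windowed Pearson correlations are computed from cumulative sums.
* Edge-count rounding is round-half-up; thresholding ties break by (value
  descending, row-major index ascending).
* Cells with zero metric variance get `NA` correlations and are treated as
  zero inside the permutation null.

# Design decisions that were genuinely open

* **Spike rule scope**: whether the 5-sigma rule applies per channel or per
  source series is unstated in the reference description; it is applied to
  whichever series it is given (per input series).
* **SD conventions**: spike and REOG thresholds use mean and SD over the
  whole time course, artifacts included - the literal reading; robust
  variants are out of scope.  Masked samples are excluded, never
  interpolated.
* **Disconnected graphs**: the printed metric formulas assume connectivity;
  the reachable-pairs convention for $L$ and $1/\infty = 0$ for efficiency
  are the standard resolutions, and the resilience procedure (which
  disconnects graphs on purpose) only depends on the efficiency convention.
* **Efficiency after removal** is computed over remaining-node pairs.
* **Signed max/min null** with the factor-2 formula implements the
  two-tailed reading of the corrected p-value; whether the original used
  $|\rho|$ instead is not fully explicit.
* **30 valid samples** is the floor for a window correlation ("enough
  independent samples" is otherwise unquantified).
* **The cohort container** is a plain-text directory (CSV matrices +
  JSON sidecars) rather than HDF5: no HDF5-capable R package is available
  in the supported environment, and desk-scale cohorts do not need one.

# Scaling of the simulation-based tests

The family-wise error simulation runs 200 null cohorts at $n_p = 1000$
permutations (reduced from the analysis default of 10000) on 32-node
cohorts; trajectory recovery runs 50 replicate 64-node cohorts.  These
scales keep the full suite within a single-CPU test budget while leaving
the Monte-Carlo error of the checked rates well inside the asserted bands.

# Limitations

* Pairwise orthogonalization leaves a small positive residual under strong
  mixing (see above); multivariate leakage correction is out of scope.
* Phase-based connectivity (coherence, PLV), wavelet/multitaper spectra,
  and source modelling are out of scope; the pipeline starts at parcel
  time series.
* Weighted-graph metric variants and community detection are not provided.
* The nested-bootstrap neighbourhood size `m` is a visualization choice;
  inference never depends on it.
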