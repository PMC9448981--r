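---
title: "Screening virtual driving test telemetry for HIV-associated neurocognitive disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening virtual driving test telemetry for HIV-associated neurocognitive disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdthand)
```

## The problem

HIV-associated neurocognitive disorders (HAND) are common among people with
HIV, but the milder forms are hard to detect with brief clinic screeners. A
self-directed virtual driving test (VDT) records rich telemetry — a 10 Hz
multichannel time series with route-zone annotations and discrete error
events — while probing exactly the abilities HAND degrades: sustained
attention, executive control, fine motor control. The statistical difficulty
is scale: one short drive yields thousands of derived performance variables
for a cohort of only a few dozen participants, so naive univariate testing
drowns in false positives and multivariable models cannot be fit at all.

`vdthand` implements the complete analysis chain for this setting: reference
labels from neuropsychological testing, telemetry featurization, a
resampling-based univariate screen with a consensus rule across splits,
stability diagnostics for the resulting ranked lists, and secondary
domain-association statistics. Because clinical VDT datasets are generally
proprietary, the package also ships a synthetic cohort generator with planted
group effects, so every stage is exercised and validated end to end in code.

## Reference labels: deficit scores and the GDS

Each participant completes a neuropsychological battery covering seven
cognitive domains with at least two tests per domain (`cnpa_domains()`).
Demographically adjusted T-scores (mean 50, SD 10 in a seronegative
reference population) are mapped to deficit scores by a step function:
no deficit at T ≥ 40, then one point per 5-point band down to a maximum of 5
below T = 20. Averaging deficit scores within a domain gives the domain
deficit; averaging the seven domain deficits gives the Global Deficit Score
(GDS). Two inclusive cutoffs produce the binary labels the screen needs:

* **HAND present**: GDS ≥ 0.5;
* **domain impaired**: domain deficit ≥ 1.

The bin boundaries and both cutoffs are arguments of
`summarize_deficits()`; the defaults are the standard published values. The
deficit mapping is monotone by construction — lowering any single T-score can
never lower a deficit, a domain deficit, or the GDS — and the test suite
asserts this as a property. A three-level severity category derived from the
GDS is reported for completeness but plays no role in the screen. Missing
test scores are an error by default; an optional policy averages over the
tests available within a domain, which we do not recommend for confirmatory
use.

## Featurization of replay files

A replay file is parsed into seven core channels (speed, posted speed, lane
offset, signed center offset, heading, road heading, steering fraction) plus
any extra channels present (eye-gaze summaries, for instance, are treated as
generic channels). `derive_channels()` adds forward acceleration and jerk
(forward first differences scaled by the sample rate, in mph/s and mph/s²),
speed relative to the posted limit, absolute lane deviation, heading
misalignment with the road direction (wrapped into [0°, 180°]), and
indicator channels for driving at least 10 or 15 mph below the posted limit.

Each continuous channel is summarized by five statistics — min, max, mean,
median, standard deviation (n − 1 denominator) — over the **global** scope
(the whole drive) and over each route **zone** (membership is per-sample via
the zone track). Indicator channels contribute a percent-time column per
scope, and each of the eight higher-order error types contributes count
columns per scope. The composite **VDT Error Score** is a linear combination
of the eight global error counts. The production weights of the commercial
platform are not public, so `default_error_weights()` ships an explicit,
overridable stand-in that weights collisions heaviest; all results that
depend only on the ranks of positive-weighted sums are insensitive to the
exact choice, and the weights are recorded in the run configuration.

Columns that are constant across the cohort are removed (a fixed route makes
many zonal columns structurally constant — no pedestrian collisions in a
zone without pedestrians) and logged. Each surviving column keeps its
original column index; that index is the documented tie-break of the ranking
stage, so column order is part of the contract and is asserted stable by the
tests.

## The split-consensus screen

With labels $y_i \in \{0, 1\}$ and feature matrix columns $x_{ij}$, the
screen proceeds in two stages.

**Stage 1 — per-split ranking.** The cohort is partitioned into $S = 5$
stratified folds (class counts per fold within one of proportional); the
training set of split $s$ is the complement of fold $s$. On each training
set, every variable receives the Kruskal–Wallis statistic

$$H = \frac{\frac{12}{n(n+1)} \sum_g n_g \left(\bar R_g - \tfrac{n+1}{2}\right)^2}
  {1 - \sum_t (t^3 - t) / (n^3 - n)},$$

computed from mid-ranks with the standard tie correction (count variables
guarantee ties; a constant variable is assigned $H = 0$ rather than an
error). Variables are ranked by descending $H$, ties broken in favour of the
smaller original column index. Two-group $p$-values use the $\chi^2_1$ upper
tail (`h_to_p()`).

**Stage 2 — consensus.** Fix a list length $k$ and intersect the $S$ top-$k$
prefixes. The consensus (possibly empty) is ranked by the median $H$ across
all $S$ splits — the median over five splits reflects how strongly a variable
is associated in at least three of them. `mean_topk_curve()` exposes the
mean top-$k$ $H$ as a function of $k$, and `elbow_k()` estimates its knee
with a kneedle-style detector (normalize to the unit square, flip the
decreasing curve to the concave-increasing orientation, take the first
threshold-beating local maximum of $y - x$; a straight line has no knee and
returns `NA`). The elbow is advisory: the pipeline's $k$ is a configuration
constant, default 100, because a conservative fixed $k$ keeps the
intermediate lists comparable across splits.

We wrote the kneedle detector in-package; it supports both the convex
configuration (fast drop, then flat — the shape of the mean top-$k$ $H$
curve) and the concave configuration (flat, then drop), selected by the
`curve` argument.

### What the consensus does and does not control

The motivation for intersecting five lists is false-positive control without
per-test correction: under independent lists, a variable has probability
$(k/M)^S$ of appearing in all five by chance
(`null_selection_probability()`; about $8.4 \times 10^{-8}$ at $k = 100$,
$M = 2601$, $S = 5$). It is important to be explicit that this independence
heuristic does **not** describe the splitting scheme itself: training sets
that are complements of five folds share three of their four folds, so
per-split $H$ values are strongly correlated and the realized null consensus
is typically non-empty. The acceptance script computes this directly
(`null_consensus_median_size`): with no planted effects, a cohort of 62 and
$M > 1000$ variables, the $k = 100$ consensus contains on the order of a
dozen variables. Consensus membership alone is therefore a screening
shortlist, not a significance statement; the stability diagnostics and the
reported median $H$/$p$ are part of the interpretation, and any downstream
use should validate on independent data.

## Stability diagnostics

`stability_report()` compares all pairs of top-$k$ lists with two metrics:

* **Jaccard similarity** of the top-$k$ sets, $|A \cap B| / |A \cup B|$;
* **normalized top-$k$ Kendall distance** with penalty parameter $p$
  (default 0.5, the neutral choice), following the standard case analysis
  for partial lists: discordant shared pairs and contradictory
  present/absent pairs cost 1, pairs whose relative order is undetermined
  (both elements confined to one list) cost $p$. The total is divided by the
  distance between two disjoint lists, $k^2 + 2p\binom{k}{2}$, so the value
  is exactly 0 for identical lists and 1 for disjoint lists at every $p$.

Although the quantity is sometimes loosely called a correlation, it is a
*distance*: small values mean similar lists. One subtlety of the
normalization: because the disjoint-list constant itself grows with $p$, the
normalized value need not be monotone in $p$ (the raw penalized total is);
we kept the normalization because an exact [0, 1] range is more useful for
reporting.

## Secondary statistics

`spearman_domain_matrix()` computes Spearman correlations between each
consensus variable and the seven binary domain-impairment flags, reporting
two significance tiers: raw ($p < \alpha$) and Bonferroni
($p < \alpha / m$). The family size $m$ is all tested cells,
$|\text{consensus}| \times 7$ — the most conservative reading — and is
configurable. Cells with a constant variable or a constant flag are reported
as undefined rather than erroring. Prevalence contrasts use the two-sided
Fisher exact test (`exact_test_2x2()`); the drug-use-by-HAND style contrast
uses the uncorrected Pearson chi-square (`chi_square_2x2()`), whose closed
form $n(ad - bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ is the only variant
consistent with vanishing statistics on near-independent tables; rank-sum
comparisons use the Mann–Whitney $W$ with a tie-corrected normal
approximation (`rank_sum_w()`).

One documentation note: impairment-prevalence tables are sometimes headed
"domain deficit score > 0" while the operative rule is the inclusive cutoff
≥ 1. The package follows the ≥ 1 rule and exposes the threshold
(`domain_cutoff`) so either convention can be reproduced explicitly.

## The synthetic cohort generator

`cohort_spec()` defaults encode the study conditions the package targets: 62
participants, 57% HAND prevalence (the positive count is
`round(n * prevalence)`, giving 35), a fixed route sampled at 10 Hz for 600
s. Telemetry scale defaults to a reduced inventory (10 extra channels, 5
zones, roughly 600 retained variables) so that examples and tests run at
desk scale; raising `n_zones` toward 22 and `n_channels` toward 30
approaches the full ~2,600-variable scale, which remains route-dependent and
is never asserted as an exact count.

Generation choices, and why:

* **Channels are stationary location-scale draws per zone** (per-zone route
  location + a participant-level random offset + noise), not a vehicle
  dynamics simulation. The screen consumes only summary statistics, and a
  location-scale model keeps planted effects interpretable: shifting a
  channel's location in a zone by `effect_size` noise-scale units shifts the
  zonal median (and mean, min, max) by the same amount. The ground truth
  bookkeeps the `<channel>|median|zone:<z>` column of each planted cell; the
  other location statistics of that cell shift too, which mimics the
  multi-collinearity of real telemetry variables.
* **Labels first, T-scores conditional on label.** HAND profiles impair 2–5
  whole domains (T-scores 22–32, domain deficits ≥ 2, hence GDS ≥ 4/7);
  non-HAND profiles stay in the normal range, with occasional single
  sub-threshold tests that keep the GDS below 0.25. GDS scoring therefore
  reproduces the generated labels exactly, which gives the scoring module an
  exact oracle; `misclassification_rate` (default 0) flips a controllable
  fraction for robustness tests.
* **Error events are negative binomial** (size 2) per type with
  group-specific means, defaults chosen so the HAND group's composite error
  score is roughly twice the other group's with a long right tail, matching
  the skewed, wide-IQR behaviour such scores show in practice.
* **An optional AR(1) coefficient** (`ar1`, default 0) adds within-session
  autocorrelation. No reference value exists for it, so the default is
  none; summary statistics of stationary AR(1) noise differ from iid mainly
  in the effective sample size per zone, which does not change any
  rank-based conclusion in our tests.

What the generator deliberately does **not** emulate: vehicle dynamics and
route geometry, gaze acquisition, non-stationary within-zone behaviour
(approach/brake profiles), learning effects across the drive, and
demographic structure in the T-scores. Passing tests on synthetic cohorts
therefore validate the *statistical machinery* — scoring arithmetic, rank
computations, consensus logic, stability metrics, determinism — not the
clinical claim that telemetry separates HAND in any particular population.

## Numerical and reproducibility choices

* Quantiles (medians, IQR = Q3 − Q1) use linear interpolation (R type 7),
  matching the dominant convention of the surrounding numeric ecosystem.
* Standard deviations use the n − 1 denominator.
* Zone membership is per-sample; derived difference channels anchor each
  difference to its leading sample's zone.
* Replay JSON serialization rounds channel values to 4 decimals so that
  write → parse → write round-trips are byte-identical; all generator
  randomness flows from the spec seed, and `stratified_training_sets()` is
  deterministic given its seed (the contract is determinism-given-seed, not
  bit-compatibility with any other library's fold assignment).
* The absolute percent median difference is
  $|m_\text{HAND} - m_\text{no}| / |m_\text{HAND}| \times 100$, reported as
  `UNDEF` when the HAND-group median is zero — the only convention that
  reproduces a full published-style distribution table including its
  undefined rows.
* Degenerate inputs are contracts, not crashes: constant variables get
  $H = 0$; empty consensuses are valid results; undefined association cells
  are flagged, not thrown.

## Problem sizes used by the test suite

The suite validates the heavy properties at deliberately reduced scale: null
calibration uses 20 cohorts of 62 participants with ~1,250 retained
variables and 60 s sessions; parameter recovery uses 10 cohorts of 200
participants with ~600 variables and 20 planted shifts of 1.5 noise-scale
units; oracle equivalence uses 200 random instances with n ≤ 30. These sizes
were chosen as the smallest at which the respective statistical claims are
meaningful.

## Known limitations

* The consensus' false-positive behaviour depends on the fold-overlap
  structure; the analytic $(k/M)^S$ bound applies only to independent lists
  (see above) and should not be quoted as the realized null rate.
* The error-score weights are a documented stand-in, not the commercial
  platform's weights.
* The generator's per-zone stationarity understates within-zone dynamics;
  acceleration/jerk variables on synthetic data are noise-dominated and
  should not be interpreted clinically.
* No multivariable or predictive modelling is included by design; the
  output is a screened, ranked shortlist with stability diagnostics.
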