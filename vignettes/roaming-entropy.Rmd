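---
title: "Roaming entropy, repeatability and resting metabolic rate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Roaming entropy, repeatability and resting metabolic rate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roamr)
```

`roamr` analyzes long-term RFID monitoring of mouse colonies in large
multi-level enclosures. This vignette explains the models and procedures
the package implements, the parameters that matter and their defaults, the
numerical choices made where the design was genuinely open, and what the
bundled simulator does and does not emulate.

## From antenna reads to roaming entropy

The raw observational unit is a detection event: a ring antenna reads a
mouse's subcutaneous transponder and stores `(timestamp, antenna_id,
animal_id)`. `parse_event_log()` validates and stably sorts these records;
`deduplicate_events()` optionally collapses re-reads of a stationary
animal at the same antenna within a refractory window (default 1 s when
enabled). Whether contact probabilities should be computed from raw reads
or debounced contacts is not settled by any definition of "contact", so
both modes are first-class: `refractory_s = 0` reproduces raw counting and
any positive window gives debounced counting. All results in the package's
examples use raw reads.

Nightly analysis windows come from a light schedule of dated regimes
(e.g. summertime lights 08:00–20:00, wintertime 07:00–19:00). All
intervals are half-open `[start, end)` and a *night* is labeled by its
lights-off date, spanning lights-off to the next day's lights-on — an
unambiguous partition of the recording into dark phases and light-phase
remainders. Regime switches take effect per calendar date; timestamps are
naive local clock time throughout, appropriate for a single-site recording
and avoiding daylight-saving arithmetic. Dark phases are the analysis unit
because colony disturbance (caretakers, experiments) concentrates in the
light phase.

For animal $i$ on night $t$, the contact distribution is
$p_{i,j,t} = c_{i,j,t} / \sum_j c_{i,j,t}$ over the $k$ installed
antennas, and the roaming entropy is

$$\mathrm{RE}_{i,t} = -\sum_{j=1}^{k} p_{i,j,t}\,\log p_{i,j,t} \,/\, \log k,$$

with $0\log 0 := 0$. Design choices here:

- $k$ is the number of *installed* antennas from the layout (27 in the
  reference system), not the number the animal happened to contact — RE
  values are then comparable across animals and nights.
- Natural logarithm internally; RE is base-free because numerator and
  denominator share the base (property-tested).
- A night with zero contacts has no defined entropy: RE is missing,
  excluded from group means, and contributes 0 to the cumulative sum
  $\mathrm{cRE} = \sum_t \mathrm{RE}_{i,t}$ (a plain sum has no other
  sensible treatment of an undefined term). Missing nights are flagged so
  the analyst can distinguish "home all night" (RE = 0) from "not
  detected" (RE missing).

Group results are reported as mean ± sample sd (n − 1) with the
coefficient of variation $100\,\mathrm{sd}/\mathrm{mean}$ in percent,
maximum, minimum and n — CV only rounded at presentation.

## Activity binning

An animal is *active* in a clock-aligned quarter-hour bin when it
contacted **two different antennas** within that bin; repeated reads at
one antenna (grooming next to an antenna, sleeping in a nest box) never
count. Bins are half-open and anchored at 00:00, 96 per day, because the
day-long raster display this feeds assumes wall-clock alignment. The rule
is monotone — adding events can only switch bins from inactive to active —
and insensitive to deduplication, so raw events are used. Column sums of
the boolean animal × day × bin array give the colony heatmap counts.

## Sliding-window repeatability

Stability of individual differences is quantified by the intraclass
correlation of nightly RE in overlapping 4-week windows advancing by one
week (week 1–4, 2–5, ...; a 20-week series gives 17 windows). Weeks are
anchored to the first night of the series and a trailing partial week is
dropped, the bookkeeping that makes the window count exact.

Within a window, animals are groups in a one-way ANOVA:

$$R = \frac{\hat\sigma^2_{\mathrm{among}}}{\hat\sigma^2_{\mathrm{among}} + \hat\sigma^2_{\mathrm{within}}},\qquad
\hat\sigma^2_{\mathrm{among}} = \frac{MS_A - MS_W}{n_0},\qquad
n_0 = \frac{N - \sum_i n_i^2/N}{a - 1},$$

with negative among-group estimates truncated to 0 so $R \in [0, 1]$. The
classical closed-form estimator was chosen over a likelihood-fit mixed
model because it is exactly testable against a brute-force
variance-components computation (and against `lme4` on balanced designs,
where REML coincides with it — both cross-checks are in the test suite).

Uncertainty comes from a **cluster bootstrap**: whole animals are resampled
with replacement (animals are the exchangeable units for a between-animal
variance ratio) and the 2.5%/97.5% percentiles of the re-estimated $R$
form the interval (default 500 replicates). With colony-sized cluster
counts (~19 animals) percentile intervals are known to undercover
somewhat relative to their nominal 95%; the package reports them as the
conventional summary they are, and the test suite documents the measured
coverage. Significance uses a permutation test (default 100 shuffles of
observations across animals, group sizes preserved) with the add-one
correction $p = (1 + \#\{R_{perm} \ge R_{obs}\})/(1 + n_{perm})$, which
avoids reporting an impossible $p = 0$. Every resampling function requires
an explicit seed; nothing reads or mutates the global RNG stream.

The trend of $R$ across windows — does individual behavior stabilize? —
is a simple OLS of $R$ on window index (`repeatability_trend()`).

## Resting metabolic rate

Indirect calorimetry yields a V̇O₂ series (mL min⁻¹ kg⁻¹; absolute flow
traces are converted with the animal's body mass). The resting regime is
delimited on the cumulative-frequency curve: distinct V̇O₂ values on the
x-axis against the percentage of samples at or below them (ties share the
highest rank's percentage). A continuous two-segment model

$$y = \beta_0 + \beta_1 x + \beta_2 (x - \psi)_+$$

is fitted by exhaustive grid search over 200 breakpoint candidates between
the 2nd and 98th percentile of $x$ (at least 3 points required on each
side), followed by golden-section refinement between the neighbouring
grid candidates; ties prefer the smaller $\psi$. Grid-plus-refinement was
chosen over iterative linearization because it is deterministic, immune to
poor starting values, and agrees with iterative estimators whenever the
breakpoint is well separated — the regime for which the procedure is
intended. The fit is flagged "no material breakpoint" when the two-segment
RSS improves on the best single line by less than 1% (also covering
numerically-zero RSS on exactly linear input), and the RMR is then
undefined rather than spurious.

The RMR itself is the arithmetic mean of all samples strictly below
$\psi$ — the mean matches the convention in which resting metabolism is
reported as mean ± sd. On two-state synthetic traces with modes ≥ 4
within-mode sd apart, the recovered RMR stays within 2% of the
generator's resting-state mean (tested over replicated runs).

## The synthetic colony

No public corpus of multi-month colony RFID recordings exists at this
granularity, so the package generates its own test bed with known ground
truth. `simulate_colony()` emulates:

- **Layout**: 27 antennas on 5 levels; within a level antennas form a
  ring, consecutive levels are joined by single tube edges. This is a
  plausible connected topology at the reference scale, not a
  reconstruction of a specific enclosure; any adjacency matrix can be
  supplied.
- **Event times**: an inhomogeneous Poisson process per mouse with
  piecewise-constant hourly rate
  $\lambda = \text{base}_i \cdot \text{circadian}(h) \cdot \text{aging}^{d} \cdot \text{night}_{i,d}$.
  The default circadian profile has dark:light ≈ 6:1 with peaks in the
  first and last dark hour and a small anticipatory ramp before
  lights-off. RFID reads are asynchronous, so generation is in continuous
  time rather than fixed ticks.
- **Space use**: each event moves the mouse one step on the antenna graph,
  choosing among the current antenna and its neighbours with probability
  proportional to the mouse's preference vector. Preferences concentrate
  weight `home_weight` on a random home antenna. The default
  `home_weight_mean = 0.75` was set by eigen-analysis of the induced walk:
  it puts the stationary-law ("asymptotic") RE near 0.08 ± 0.015, the
  first-night scale reported for aged mice in such enclosures. Empirical
  nightly RE runs below the asymptotic value (typically 0.04–0.06 at the
  defaults) because a night's contacts are temporally correlated — the
  walk lingers near home — which is itself realistic.
- **Aging**: the decline multiplier scales both the event rate and the
  odds of choosing non-home antennas. A rate-only decline would lower
  measured RE only through finite-sample entropy bias, a fragile artifact;
  shrinking the exploration odds makes roaming breadth genuinely narrow
  with age, which is the phenomenon of interest (mean nightly RE then
  falls over days, and the cross-animal cRE variance grows when
  preference heterogeneity `home_weight_sd` is configured).
- **Ground truth** exported per mouse: profile parameters, the walk's
  stationary distribution (by eigen-decomposition) and its implied
  asymptotic RE, and the generating variance components; plus a YAML
  sidecar with config and seed for provenance.

What the simulator deliberately does **not** emulate: social interaction,
dominance, nesting and feeding dynamics, body-mass trajectories, antenna
failures, or clock drift. Tests passing on this simulator therefore
demonstrate the *estimators'* correctness and the pipeline's contracts,
not that real colonies satisfy the generator's independence assumptions.

For ICC parameter-recovery testing the mechanistic simulator is the wrong
tool (its realized ICC is an emergent quantity); `simulate_re_series()`
generates nightly RE directly from the Gaussian variance-components model
with an exact target ICC. At the reference scale of 19 animals × 28
nights, the ANOVA estimator recovers targets 0.2/0.5/0.8 within ±0.05 in
mean over 200 replicates, and the permutation test holds its nominal size
(checked in the acceptance tests). `simulate_vo2()` provides the matching
calorimetry test bed: a two-state Markov chain (stationary resting
probability `p_rest`, mean resting dwell 30 samples) with Gaussian
within-state noise, exporting the realized resting-state mean as the
recovery target.

## Problem sizes and determinism

The shipped tests run the statistical checks at the scales stated above —
200-replicate Monte Carlo for ICC, breakpoint and permutation-size checks;
10,000-distribution entropy stress suites; colony simulations of 2–30 days
and 2–20 mice — sizes at which every documented tolerance is comfortably
resolved while the whole suite completes in well under a minute of compute
per file. All stochastic outputs are reproducible: the same configuration
and seed yield byte-identical event logs and pipeline artifacts (the run
log keeps wall-clock timestamps off disk for exactly this reason).

## Known limitations

- RE treats antennas as unordered categories: no spatial smoothing, dwell
  times or trajectory reconstruction between antennas, so two animals
  using different but equally many antennas are indistinguishable by RE.
- The repeatability model is the unadjusted one-way ANOVA ICC; no
  covariate-conditional (adjusted) repeatability, no GLMM link-scale
  variant, and mixed-model comparisons are intentionally out of scope.
- The RMR threshold assumes an essentially bimodal V̇O₂ distribution;
  traces dominated by transitions (no plateau in the cumulative-frequency
  curve) yield an honest "no material breakpoint" rather than a number.
- Pairwise correlation reports are exploratory: raw p-values with a
  cautionary flag, no multiple-testing correction — interpret accordingly.
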