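# roamr

Long-term home-cage monitoring of group-housed mice with RFID antennas
produces a continuous stream of `(timestamp, antenna, animal)` detections.
`roamr` turns such event streams into the quantities used to study
behavioral individuality and its stability in large, semi-naturalistic
enclosures:

- **Roaming entropy (RE)** — the normalized Shannon entropy of an animal's
  antenna-contact distribution over one nightly dark phase,

  RE<sub>i,t</sub> = −Σ<sub>j=1..k</sub> p<sub>i,j,t</sub> log p<sub>i,j,t</sub> / log k,

  where p<sub>i,j,t</sub> is the probability that animal *i* was detected
  at antenna *j* during period *t* and *k* is the number of installed
  antennas. RE is 0 when all contacts fall on one antenna and 1 when all
  *k* antennas are used uniformly.
- **Cumulative roaming entropy (cRE)** — the running sum
  cRE = RE<sub>t1</sub> + RE<sub>t2</sub> + …; its slope reflects
  sustained spatial activity, its cross-animal spread behavioral
  individuality.
- **Activity binning** — an animal is *active* in a clock-aligned 15-minute
  bin when it contacted at least two different antennas within that bin;
  counting active animals per bin yields the colony activity heatmap.
- **Repeatability (ICC)** — one-way ANOVA variance-components estimate of
  R = σ²<sub>among</sub>/(σ²<sub>among</sub> + σ²<sub>within</sub>) of
  nightly RE in sliding 4-week windows advancing by 1 week, with cluster
  (animal-level) bootstrap confidence intervals and permutation p-values.
- **Resting metabolic rate (RMR)** — from an indirect-calorimetry V̇O₂
  trace, the cumulative-frequency percentage is regressed on V̇O₂ with a
  continuous two-segment ("broken-line") model; the breakpoint ψ separates
  resting from active metabolism and RMR is the mean of all samples below
  it.

Because raw RFID recordings of this kind are rarely shareable, the package
ships a colony simulator (`simulate_colony()`): a continuous-time,
circadian-modulated random walk on an antenna graph with individual
antenna preferences, night-to-night variability and age-related decline,
exporting its ground truth for parameter-recovery testing. A matching
two-state generator (`simulate_vo2()`) produces calorimetry traces with a
known resting mean.

Intended users are behavioral phenotyping and animal-welfare researchers
running RFID-instrumented group housing, and anyone needing a tested
reference implementation of roaming entropy, sliding-window repeatability
or the cumulative-frequency RMR threshold.

## Worked example

```r
library(roamr)

# a 20-mouse colony on the default 27-antenna, 5-level layout, 14 days
sim <- simulate_colony(sim_config(n_mice = 20, n_days = 14, seed = 1))
n_events(sim$log)
#> [1] 175197

rs <- roaming_series(sim$log, sim$config$schedule)
group_summary(rs$re[rs$date == min(rs$date)])   # first-night RE across mice
#>     mean     sd cv_percent    max    min     n
#> 1 0.0390 0.0134       34.2 0.0652 0.0149    20
group_summary(rs$cre[rs$date == max(rs$date)])  # final cumulative RE
#>    mean    sd cv_percent   max   min     n
#> 1 0.628 0.277       44.2  1.14 0.203    20

# resting metabolic rate from a two-state calorimetry trace
vo2 <- simulate_vo2(rest_mean = 40, active_mean = 80, sd_within = 2,
                    p_rest = 0.8, n = 600, seed = 2)
resting_metabolic_rate(vo2$trace)
#> RMR = 39.88 mL/min/kg (threshold 43.10, 411 samples below)
round(vo2$truth$rest_mean_realized, 2)  # generator's rest-state truth
#> [1] 40.18
```

The first-night RE of ~0.04 ± 0.013 says each mouse concentrated its
nightly contacts on a handful of the 27 antennas; the spread of the final
cRE across animals is the individuality signal the repeatability analysis
quantifies. The estimated RMR (39.88 mL min⁻¹ kg⁻¹) recovers the
generator's resting-state mean (40.18) well within 2%: the segmented
threshold at 43.1 cleanly separates the resting mode from activity bouts.

Sliding-window repeatability on a nightly RE table:

```r
rw <- repeatability_windows(rs, n_boot = 500, n_perm = 100, seed = 3)
repeatability_trend(rw)   # OLS of R on window index
```

A thin command-line front end over the same functions lives in
`inst/cli/roamr.R` (subcommands `simulate`, `compute-re`,
`activity-heatmap`, `repeatability`, `rmr`, `correlate`, `run-all`).

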