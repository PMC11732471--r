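# hdcurve

Empirical sample-size determination for task-related fMRI
region-of-interest (ROI) effects, using Bayesian updating on existing
participant-level data.

## The problem

Task-related fMRI studies need enough participants to estimate their effects
of interest with useful precision, but classical power analysis requires a
population effect size that is rarely known and, when taken from the
literature, is usually inflated by publication bias. `hdcurve` takes the
alternative route: it uses an *existing* dataset from a similar task and
region to estimate, empirically, how large a new sample must be before the
95% highest-density credible interval (HDCI) for the effect reliably
excludes zero. It is aimed at researchers planning or pre-registering a new
ROI study, and at labs that want to monitor precision while data collection
is ongoing.

## The method

The input is a table with one row per participant: a mean ROI activation
value for each of two task conditions (GLM parameter estimates, e.g.
learning vs. application), and optionally a covariate such as age.

Two effect sizes are supported, each with a flat prior so that the HDCI
endpoints coincide numerically with the classical interval:

* **Paired Cohen's d** — by default the `dz` variant,
  `d = mean(x − y) / SD(x − y)`. Its 95% HDCI is bootstrap-based: the data
  are resampled `B = 100` times (whole participants, pairs intact), and the
  interval is `mean(d*) ± 1.96 · SD(d*)` over the resampled values.
* **Pearson's r** between the per-participant condition difference and the
  covariate. Its HDCI is the Fisher interval
  `tanh(atanh(r) ± 1.96 / √(n − 3))`.

To ask "what if we had stopped at n participants?", the engine permutes the
participant order `k = 1000` times; within each permutation the first `n`
records form the subsample at size `n`, for every `n` on a grid (by default
`n_min = 20`, then fifths of the remaining range up to `N`). Per grid size it
reports the average of the `k` HDCIs and the **proportion of intervals
excluding zero** — the empirical analogue of power. A sequential
`monitor_update()` mode recomputes the single current-data HDCI as new
participants accrue, stopping when the interval excludes zero or the maximum
feasible sample is reached.

`simulate_ci_updating()` shows why the credible-interval framing matters: a
researcher who computes a classical 95% confidence interval at n = 20 per
group and adds 10 more per group only when the interval contains zero
inflates the two-look type-I error from 5% to about 7.8% (leaving effective
92.2% intervals). HDCIs summarise the data at hand and carry no such
repeated-sampling accounting.

## Worked example

Synthetic datasets shaped like four typical developmental ROI studies ship
as seeded generators (no download needed). The self-evaluation-like fixture
has N = 149 and population d = 0.46:

```r
library(hdcurve)
ds <- fixture_suite(seed = 1)$self_evaluations_mpfc
curve <- run_curve(ds, engine_config(k = 1000, seed = 1234))
summary_table(curve)
#>       n label                      mean_point mean_lower mean_upper prop_excluding_zero
#>   1  20 0.43 (-0.06, 0.92), n = 20      0.429    -0.0630      0.920               0.366
#>   2  46 0.4 (0.09, 0.71), n = 46        0.403     0.0938      0.711               0.753
#>   3  72 0.39 (0.15, 0.64), n = 72       0.393     0.150       0.637               0.957
#>   4  98 0.39 (0.18, 0.6), n = 98        0.389     0.181       0.598               0.999
#>   5 149 0.39 (0.22, 0.56), n = 149      0.388     0.219       0.556               1
```

Read: with 20 participants the average interval still contains zero and only
37% of accrual orders would have excluded it; from about 72 participants
onward nearly every interval excludes zero, so a new study of this effect
should plan for roughly that many participants. `plot_intervals(curve)` and
`plot_proportions(curve)` draw the corresponding figures.

The optional-stopping demonstration:

```r
simulate_ci_updating(reps = 100000, seed = 1)
#> Sequential CI updating (100000 reps, looks at n = 20, 30 per group, true effect 0):
#>   first-look rejection rate:        0.0498
#>   conditional second-look rate:     0.0291
#>   cumulative rejection rate:        0.0775
#>   effective interval coverage:      0.9225
```

A command-line launcher is installed as `exec/hdcurve`:

```sh
hdcurve estim-diff --input feedback.csv --var-a mfg_learning \
  --var-b mfg_application --k 1000 --seed 1234 --name "Feedback DLPFC" \
  --out-dir results/feedback
hdcurve simulate-updating --reps 100000 --seed 7 --out-dir results/sim
```

Each run writes a summary CSV, a per-cell CSV, figures and a log of every
effective setting.

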