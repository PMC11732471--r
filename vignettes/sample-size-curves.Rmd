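---
title: "How hdcurve determines sample sizes: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How hdcurve determines sample sizes: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdcurve)
```

## The estimation problem

A planned task-related fMRI study will summarise each participant's response
in a region of interest (ROI) by one GLM parameter estimate per condition.
The scientific questions are typically "is the condition effect non-zero?"
(paired Cohen's d) and "does the effect change with age?" (Pearson's r
between the condition difference and age). `hdcurve` answers the planning
question — how many participants until these effects are estimated precisely
enough that the interval excludes zero? — empirically, from an existing
dataset of the same kind, instead of from an assumed population effect size.

Precision is expressed as a 95% highest-density credible interval (HDCI):
the narrowest interval believed to contain the parameter with probability
0.95. All analyses use a flat prior, with two consequences that the package
relies on throughout: the HDCI is determined by the data alone, and its
endpoints coincide numerically with the endpoints of the classical
confidence interval. Unlike a confidence interval, however, an HDCI
describes the data at hand and may be recomputed as data accrue without any
repeated-sampling error accounting — the point the sequential simulation
below makes quantitative.

## Interval constructions

**Paired Cohen's d.** The default standardiser is `dz`,
$d = \bar{x - y} / \mathrm{SD}(x - y)$, with the $n-1$ sample SD; `dav`
(mean difference over the average of the two condition SDs) is available as
an option. The HDCI is built by nonparametric bootstrap: `B = 100` resamples
of whole participants (condition pairs are never broken, since the statistic
is defined on the pairing), the statistic computed on each, and the interval
taken as $\bar{d^*} \pm z \cdot \mathrm{SD}(d^*)$. The reported point
estimate is the bootstrap mean $\bar{d^*}$, matching the interval's centre.
The multiplier is the exact normal quantile for the configured level
(1.959964 at 0.95, i.e. the conventional 1.96 to two decimals), so
non-default levels remain consistent. A resample on which the statistic is
undefined (zero variance of the resampled differences) is redrawn, with a
cap of $10B$ total draws beyond which the data are reported as degenerate —
redrawing keeps exactly `B` comparable values in every interval.

**Pearson's r.** Under the flat prior the HDCI equals the classical Fisher
interval, $\tanh(\mathrm{atanh}(r) \pm z/\sqrt{n-3})$, which is closed-form
and order-invariant; a bootstrap variant (`bootstrap_hdci_r()`) exists for
sensitivity checks. The Fisher interval's 95% coverage at moderate n is one
of the package's acceptance properties.

## The permutation-subsampling curve

An existing dataset of size $N$ is, for planning purposes, one arbitrary
accrual order of $N$ participants. To estimate what an interval at sample
size $n < N$ would look like, `run_curve()` draws `k = 1000` uniform random
permutations of the participants; within one permutation the subset at size
$n$ is the *first n records of that same shuffled order* for every grid
size, mirroring sequential accrual (an independent-draws mode is available
via `nested = FALSE`). At $n = N$ all permutations contain the same records.
Per grid size the k intervals are averaged element-wise, and the proportion
whose bounds both lie strictly on one side of zero is recorded — the
empirical analogue of power. A zero-width interval exactly at zero counts as
containing zero; the case has measure zero and the strict rule makes the
proportion conservative.

**The grid.** By default five sizes: `n_min = 20`, then steps of one fifth
of the remaining range, $s = \mathrm{round}((N - n_{\min})/5)$ with
half-away-from-zero rounding, ending at $N$ (so 20, 70, 120, 170, 271 for
$N = 271$). Twenty participants is the smallest sample at which a first
impression of the effect is not dominated by sampling fluctuation or
outliers; a dense grid can be supplied explicitly via `grid =`.

**Seeding.** One master seed spawns three independent substreams — the
permutations, the per-cell bootstraps, and the display selection — so that
cosmetic options (e.g. `display_count`, the 10 individual intervals drawn
per size in `plot_intervals()`) cannot perturb the estimates. Identical
configurations give bit-identical results, a tested invariant.

**Degenerate cells.** A subset on which the estimator is undefined (zero
variance, constant covariate) flags its cell rather than failing the run;
flagged cells are excluded from the per-size averages and counted in the
log. The exclusion proportion keeps `k` as its denominator, so degenerate
cells never count as excluding zero.

## Monitoring during data collection

`monitor_update()` implements the sequential use: append newly collected
participants, recompute the single current-data HDCI (no permutation), and
stop when the interval excludes zero or the configured maximum achievable
sample size is reached. Because the intervals are credible intervals under a
flat prior, this repeated looking needs no multiplicity correction. For
contrast, `simulate_ci_updating()` quantifies what the same behaviour does
to *confidence* intervals: with two groups of 20 from a null population and
a pooled-variance 95% t interval, about 5% of first looks reject; among the
survivors, adding 10 per group and recomputing rejects about another 2.8%,
for a cumulative two-look type-I error near 7.8% and effective 92.2%
intervals. The pooled t interval is the standard choice at 20 per group;
the simulation is vectorised and chunked, and the three rates are tested
against their analytic or simulated values within three Monte-Carlo
standard errors.

## The synthetic-data generators

The generators exist so every pipeline stage is testable without any data
download, and they define the study conditions the test suite runs under.
`gen_paired()` draws condition pairs from a bivariate normal with
configurable SDs and between-condition correlation (`rho_ab = 0.5` by
default — repeated measures of the same region are typically positively
correlated, which is what makes the paired design efficient) and shifts the
condition-A mean by `d_true` population difference-SDs, so the population
`dz` is exact by construction. `gen_with_covariate()` adds a covariate that
is marginally uniform on a configurable range (ages drawn evenly across a
developmental window) through a Gaussian copula: a latent standard normal
mixes the population-standardised condition difference with independent
noise at latent correlation $r_{\mathrm{true}}\sqrt{\pi/3}$, the factor that
undoes the attenuation of the normal-to-uniform transform, so the population
correlation with the condition difference equals `r_true` exactly
(attainable up to $\sqrt{3/\pi} \approx 0.977$). `fixture_suite()` bundles
four datasets with sample sizes 271, 221, 149 and 156 and population effects
(d, r) of (1.87, 0.38), (0.73, −0.04), (0.46, 0.06) and (0.57, −0.17) —
the scale of real feedback-learning, gambling-reward, self-evaluation and
vicarious-reward effects in the developmental literature.

What the generators deliberately do not emulate: non-normal or
heavy-tailed activation values, outlying participants, motion-related
heteroskedasticity, site or session effects, and nonlinear age
relationships. Tests passing on these fixtures therefore certify the
estimation machinery — interval construction, permutation accounting,
calibration under the null, parameter recovery — not robustness of the
bootstrap to pathological real-world ROI distributions.

## Numerical and formatting choices

* Strict inequalities define "excludes zero"; means are exact arithmetic
  means of cell values (tested against brute-force recomputation).
* Table labels round to two decimals, half away from zero, with trailing
  zeros dropped (`0.80` prints `0.8`); CSV outputs keep full precision so
  rounding never contaminates downstream computation.
* Listwise deletion with a logged count is the missing-data policy: rows
  incomplete for the columns an analysis needs are dropped by
  `read_roi_table()` / `validate_covariate()`, and never silently.
* Input files are comma-separated with a header row and `.` decimals; ids
  are synthesised `1..N` in file order when absent. Row order is preserved
  by I/O — only the engine permutes.

## Problem sizes in the test suite

The shipped tests scale the Monte-Carlo work to what the checks actually
need: `k` between 15 and 200 for curve tests (k affects only the Monte-Carlo
error of the curve aggregates, not their meaning), 100,000 replicates for
the sequential simulation, 2,000 simulations for Fisher coverage, and the
null-calibration property averages exclusion proportions over 40 independent
null datasets of N = 500 at k = 50 — cells within one dataset are
correlated (at n = N they share all records), so the Monte-Carlo standard
error is taken across datasets rather than across cells. Full-scale runs
(k = 1000) are what the CLI defaults to.

## Known limitations

* The bootstrap interval is the symmetric mean-±-SD construction; it does
  not correct skew the way BCa intervals would, and at very small n (near
  the 20 floor) bootstrap SDs of d are themselves noisy.
* The correlation analysis models linear association only; developmental
  effects that are nonlinear in age need a different effect-size measure.
* A sample-size estimate transfers to a new study only insofar as task,
  region, population and acquisition resemble the existing data; the curve
  quantifies precision in the data at hand, not generalisation error.
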