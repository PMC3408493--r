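---
title: "Methods: sectioned Bernoulli scan for seasonality of conception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sectioned Bernoulli scan for seasonality of conception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

seasonscan asks whether conceptions of children later diagnosed with a
condition (the motivating application is sole autism in a 1990s California
birth cohort) cluster at particular times of year, and whether any such
seasonal excess persists across years. This vignette is the package's own
account of the statistical machinery, the choices behind its defaults, and
what the accompanying synthetic-data tests do and do not establish.

## The model

Each conception is a Bernoulli trial: among the $N$ conceptions of a study
window, $C$ are cases. Under the null hypothesis every conception has the
same case probability $C/N$ regardless of date. The alternative is a single
contiguous interval of days with a higher in-window probability.

For a candidate window containing $n_z$ conceptions and $c$ cases, the test
statistic is the log likelihood ratio of the maximized two-rate model over
the maximized one-rate model,

$$
\mathrm{LLR} = c\log\frac{c}{n_z} + (n_z-c)\log\Big(1-\frac{c}{n_z}\Big)
 + (C-c)\log\frac{C-c}{N-n_z}
 + (N-n_z-C+c)\log\Big(1-\frac{C-c}{N-n_z}\Big)
 - C\log\frac{C}{N} - (N-C)\log\Big(1-\frac{C}{N}\Big),
$$

with $0\log 0 \equiv 0$, clamped to zero whenever the in-window rate does
not exceed the out-of-window rate (the statistic is one-sided: only excess
risk counts). The *most likely cluster* is the window maximizing the LLR
over all contiguous day runs of length 1 to `max_len_days`. Two summaries
accompany it: the null expectation $E = n_z C/N$ and the relative risk
$\mathrm{RR} = (c/n_z)\,/\,((C-c)/(N-n_z))$, the in-window case rate over
the out-of-window rate.

Because the maximum over tens of thousands of overlapping windows has no
usable closed-form null distribution, inference is by random permutation:
each replicate redistributes the $C$ case labels uniformly at random among
the $N$ conceptions — holding the daily conception totals fixed, which
makes the redistribution a multivariate hypergeometric draw over days —
and rescans. With $b$ of $R$ replicate maxima at or above the observed
maximum, $p = (1+b)/(1+R)$. The window enumeration and the permutation
loop are compiled (Rcpp); the exported `bernoulli_llr()` is the reference
R implementation of the same formula, and the test suite checks the
compiled scan against an exhaustive R-level enumeration and the formula
against directly evaluated binomial log-likelihoods.

## Sections, trend, and multiple testing

Case incidence in the target cohort rises several-fold across the study
period. The scan handles this not by detrending — the drivers of the trend
are unknown, and removing an assumed trend can manufacture spurious
periodicity — but by dividing March 1992 to March 2000 into six
overlapping three-year sections stepped by one year, each scanned
conditionally on its *own* totals $N$ and $C$. March cutpoints are used
because, under a prenatal-exposure hypothesis, March is the least likely
month for an excess; `cut_month` is configurable for robustness runs
(e.g. December), and `span_years = 4` gives the four-year sensitivity
variant. Across the six section-level tests the Holm–Bonferroni step-down
controls the family-wise error rate at `alpha = 0.05`: p-values are sorted
and the $i$-th smallest is rejected while $p_{(i)} \le \alpha/(m-i+1)$.

Sectioning absorbs the trend only *between* sections. Within a section the
trend still tilts the daily rates, and a scan window placed over the
steepest-trend days competes with any genuine seasonal excess. Two
practical consequences, both visible in the synthetic experiments: the
detected window tends to extend from an implanted cluster into adjacent
trend-elevated days (so its dates cover the implant but are wider than
it), and with wide `max_len_days` a strongly trended but implant-free
stretch can itself reach significance. This is a property of the method on
trended data, not an artifact of the implementation.

## Tunable parameters

* `max_len_days` (default 90): longest candidate window, in days. The
  seasonality question is sub-quarterly and reported clusters are about a
  month long; 90 days leaves room to detect broader excesses while keeping
  enumeration fast. Narrower maxima (e.g. 60) tighten detected windows on
  trended series.
* `reps` (default 999): permutation replicates, so the smallest attainable
  p-value is 0.001. Calibration tests use 199 to keep 500-scan experiments
  fast; published p-values as small as $10^{-4}$ imply more replicates
  than the default.
* `alpha` (default 0.05): family-wise level of the Holm step-down.
* `span_years`/`step_years`/`cut_month` (3/1/March): the section grid.
* `seed`: one master seed; section $i$ permutes with `seed + 1000*i`, and
  stratified runs offset by a further $10^6$ per stratum, giving
  independent, reproducible permutation streams.

## The synthetic cohort generator

The real case registry/birth-file linkage is restricted, so every stage is
exercised against `generate_cohort()`, which emulates the structure the
analysis assumes:

* **Volume and trend.** Year-specific daily conception means and baseline
  case probabilities are calibrated from the published per-year birth and
  case counts (about 1,100–1,450 conceptions/day; case risk rising from
  roughly 0.6 to 3.2 per 1,000). Published counts are by calendar year, so
  by default the yearly case rates are treated as mid-year anchors joined
  piecewise-linearly into a daily risk curve. Holding each year's rate
  constant (`trend_mode = "step"`) is also available, but it plants
  artificial risk jumps at January 1 that a day-resolution scan duly
  reports as clusters — a feature real incidence data do not have, which
  is why interpolation is the default.
* **Implants.** Three high-risk windows copy the published cluster dates
  (Nov 7–Dec 2 1994, Nov 9–Dec 7 1995, Nov 7–Dec 6 1996) with in-window
  case probabilities equal to the published in-window case fractions
  (e.g. 82/35,323 for 1994). An implant can be confined to one geographic
  stratum for stratified-scan tests.
* **Covariates.** Sex, Medi-Cal, race/ethnicity, parental ages and
  education are drawn from marginals approximating the published cohort
  description (51% male, ~41% Medi-Cal, five race categories with
  non-Hispanic white at 36%, ~9% missing father's age). Gestational age is
  generated so that 11% of cases and 1.3% of all births are preterm
  (< 37 weeks), the published figures; birth weight follows gestational
  age with low birth weight (< 2.5 kg) emerging from the distribution.
  Covariates are independent of cluster membership unless a *confounding
  hook* (`cluster_covariate_or`, `cluster_outcome_or`) implants a known
  odds ratio — the device used to verify that the composition and outcome
  regressions recover known effects.
* **Strata.** 80% metro and 67% south, reflecting a predominantly
  metropolitan cohort with the majority of cases in the south of the
  state.
* **Siblings.** A configurable fraction of families (default 30%) gets one
  linked sibling. In `independent` mode the sibling conception is offset
  by a gamma-distributed spacing (mean 900, sd 350 days — typical two-to-
  three-year spacing) with random sign, so sibling day-of-year is
  unrelated to the index child's; in `assortative` mode the sibling is
  conceived a whole number of years away within ±6 days of the index
  day-of-year, emulating temporally consistent family planning.
* **Daily totals** are Poisson around the daily means (an `exact_n`
  multinomial mode exists for worked examples); the Bernoulli scan
  conditions on totals either way. Within-year conception seasonality is
  uniform by default, with an optional sinusoidal modulation
  (`seasonal_amplitude`), since the real within-year pattern is not
  described in the source material.

What the generator does **not** emulate: diagnosis and ascertainment
processes, record-linkage error, real geographic structure (strata are
labels, not places), within-year conception seasonality, or correlation
between covariates. Passing tests therefore show that the *pipeline*
detects what it is supposed to detect and nothing else under its own
model; they cannot show that the real data's clusters were correctly
characterized.

## Numerical and coding conventions

* Dates: conception date = last menses + 14 days. Analysis intervals are
  half-open `[start, end)` so adjacent sections compose without overlap;
  detected *cluster* dates are reported and consumed inclusive of both
  endpoints, as printed in the source tables.
* Covariate codings: preterm = gestational age < 37 weeks; low birth
  weight = birth weight < 2,500 g; mean parental age (mother-only when the
  father's is missing) dichotomized at ≥ 35; mean parental education
  binned < 12, [12, 16], > 16 years (inclusive middle); race reference
  non-Hispanic white; records missing both parental ages are dropped with
  a logged count. Records missing gestational age or birth weight are
  kept for scanning and excluded only from the corresponding outcome
  regression.
* Scan ties (equal LLR) resolve to the earliest start, then the shortest
  window, making results deterministic.
* The sibling test measures circular day-of-year distance
  $\min(|a-b|,\,365-|a-b|)$ with February 29 mapped to February 28;
  fractional timeframes (22.5) compare as `distance <= t` on the real
  line. The 2×2 chi-square is computed without continuity correction by
  default (`correct = TRUE` is available). Sibling pairs enter the test
  when the index child — case or control — was conceived during a
  detected cluster period; the sibling itself may be conceived anywhere
  in the sibling observation span.
* Logistic regressions report Wald 95% intervals; constant covariates are
  dropped with a warning rather than fit.

## Known inconsistency in the source worked examples

The published 1995 cluster row (109 cases among 38,602 conceptions,
expected 62.91, printed RR 1.72) is internally inconsistent: with section
totals consistent with its expected count, the in/out-rate definition
gives 1.77 and the in/overall-rate definition gives 1.73. The package does
not force agreement; its tests reproduce that row's expected count only
and document that both standard definitions give at least 1.73.

## Problem sizes in the test suite

The suite runs the full pipeline once at study scale (about 3.8M synthetic
records, 199 permutations per section), verifies the compiled scan against
brute-force enumeration on 1,000 random series of up to 50 days and 500
events, calibrates the permutation test on 500 null series of 80 days and
5,000 conceptions at 199 replicates, and checks regression recovery with
one $n = 10^5$ fit plus 200 replicates at $n = 4{,}000$. These sizes are
the package's chosen balance between statistical resolution and a test run
of a couple of minutes; the acceptance script's implant experiment uses
the published three-year scale (1,480,000 conceptions, 999 permutations).

## Limitations

* Within-section trend is not modeled; see above for the two consequences
  (widened detected windows; possible trend-driven significance at wide
  `max_len_days`). Interpreting a detected cluster on trended data should
  include a look at the daily series.
* With 999 permutations the p-value floor is 0.001; Holm-corrected
  decisions at $m = 6$ are unaffected, but published p-values smaller
  than that cannot be reproduced exactly.
* Only the single most likely cluster per section is reported; secondary
  clusters are out of scope.
* The generator's covariates are mutually independent by construction, so
  the composition regressions on default synthetic data test the null
  path only; implanted-OR runs exercise the signal path one covariate at
  a time.
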