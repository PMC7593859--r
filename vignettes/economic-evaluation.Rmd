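---
title: "Methods: incremental cost-effectiveness of a community mHealth program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental cost-effectiveness of a community mHealth program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceapipe)
```

## The evaluation problem

`ceapipe` implements the economic evaluation of a mobile-health (mHealth)
job aid delivered through village-level frontline health workers (ASHAs,
roughly one per 1000 population) in a two-arm cluster-randomized design:
11 primary health centers per arm, with prospective surveillance of all
pregnancies, live births, and infant survival to one year. The question it
answers is the standard one of program economics: what does one year of
running the intervention cost beyond routine care, and what does that buy
in infant deaths averted and life-years saved?

The package takes a **program perspective** with **incremental costing**:
only resources that differ between the intervention and control arms are
counted, and household or government health-system input costs are out of
scope. All amounts are carried at a single price year (default label
"2016-2017"); mixed price years in a comparison are surfaced as a warning
rather than silently combined.

## Costing model

A cost ledger is a set of line items, each with a category, a phase
(start-up vs implementation), an arm, and an amount. Recurrent items carry
an annual outlay and pass through unchanged. Capital items (software
build, vehicles, handsets, IT equipment, one-time orientation training)
carry a one-time outlay that is converted to an equivalent annual cost by
dividing by the annuity-in-arrears factor

$$AF(r, n) = \sum_{t=1}^{n} (1+r)^{-t} = \frac{1 - (1+r)^{-n}}{r},$$

with $AF = n$ in the zero-discount limit. This is the standard
health-economics annualization convention (Drummond et al.); the default
discount rate is 3% per year. Default useful lives, overridable per item
or per category: software development and four-wheelers 10 years,
two-wheelers 7, IT equipment 5, mobile handsets 3, orientation training 3.
Refresher training is deliberately *not* a capital item: it recurs, so it
stays an annual cost.

Numerically, the factor is computed as `-expm1(-n * log1p(r)) / r`, which
is algebraically the closed form but remains accurate as $r \to 0$, where
the naive expression loses all precision to cancellation; the test suite
pins the factor against an explicitly summed discount series at $10^{-9}$
and checks continuity at $r = 10^{-12}$.

The built-in reference ledger (`reference_cost_ledger()`) encodes the
trial's published annualized category values as non-capital items, since
the raw capital outlays behind them were not published; the annualization
path is exercised separately by synthetic capital items. The published
implementation-phase line items sum to one dollar less than the published
subtotal; the ledger carries that dollar as an explicit `other` line
("rounding residual of published subtotals") so the printed totals --
172,052 intervention, 17,789 control, difference 154,263 -- are reproduced
exactly rather than approximately.

## Outcome surveillance and analysis sets

Birth records store each pregnancy outcome once, with death timing as
*disjoint* windows (early neonatal < 7 d, neonatal 7-27 d, post-neonatal
28-364 d) and report them *nested* (neonatal includes early neonatal,
infant includes all three), which matches the cumulative definitions used
in mortality reporting while making double-counting impossible by
construction. Stillbirths are excluded from live-birth denominators and
from the valued outcome.

Two analysis sets are built from the same records:

* **ITT** -- every live birth in the study villages;
* **PP** -- only births to mothers native to the study village, excluding
  the roughly 30% of women who deliver at their maternal home and are
  therefore only partially exposed to their assigned arm. Partial-exposure
  weighting of the excluded births is not attempted; exposure duration per
  record is unknown.

The infant mortality rate is deaths per 1000 live births; deaths averted
are the control-minus-intervention rate difference (negative values signal
harm and are propagated, not clamped).

## The ICER panel

With annual incremental cost $\Delta C$, intervention-arm live births $B$,
and deaths averted per 1000 live births $\Delta E$:

* cost per 1000 live births $= 1000\,\Delta C / B$ (the intervention arm
  is the costing denominator -- the cost is incurred where the program
  runs);
* cost per infant death averted $= (1000\,\Delta C / B) / \Delta E$;
* life-years saved per 1000 live births $= \Delta E \times L$ with life
  expectancy $L = 68.35$ years (2016 value);
* cost per life-year saved $=$ cost per death averted $/\,L$.

Life-years saved are **undiscounted** by default: an averted infant death
is credited the full remaining life expectancy. A discounting option
exists (`lys_discount_rate`), which replaces $L$ by the annuity factor
over $\lfloor L \rfloor$ years; it defaults off because the reference
convention values the full expectancy.

The verdict compares cost per life-year saved with GDP per capita
(default US$1709, 2016): **strictly** below the threshold is
cost-effective, a tie is not. Cheaper-and-more-effective is `dominant`
(no ratio needed), costlier-and-less-effective is `dominated`. Zero
effect leaves the ratios `NA` and flagged undefined rather than infinite,
with the verdict taken from the cost-effectiveness-plane quadrant alone.
The same quadrant logic backs `ce_plane_point()`, and coordinates are
emitted both per 1000 live births and for the whole cohort, since either
normalization is defensible for plotting.

The decision model is deliberately the *minimal* two-arm chance tree:
each live birth dies with arm-specific probability or survives, with an
arm-specific cost per live birth. Rolled forward over a cohort it
reproduces the direct incremental arithmetic exactly, and the test suite
holds the two routes together to $10^{-6}$ relative on randomized draws.
Nothing richer (state transitions, time cycles) is warranted by a
one-year horizon with a single terminal outcome.

## Scenario analysis

Scenarios are named deterministic perturbations re-run through the same
panel: an effect multiplier (1 = observed), an analysis-set switch, and
one of three cost bases -- an explicit annual incremental cost, a cost
per ASHA times a head-count, or an externally supplied cost per death
averted for scale-up settings whose full cost model lives outside the
evaluation (district scale-up is costed by the implementing government,
not derivable from the trial ledger, so the package accepts the quoted
figure as an input; the quoted figure is taken at 100% observed
effectiveness and rescaled by the multiplier). Halving effectiveness
therefore exactly doubles cost per death averted and per life-year saved,
an identity the tests pin pre-rounding.

One reporting note: the trial-scale cost per ASHA depends on which ASHA
head-count divides the incremental cost (the arms fielded 280 and 281
workers; published reporting is consistent with 283). `cost_per_asha()`
takes the count as an explicit argument and the reference parameters use
the intervention arm's 280; no result downstream depends on this line.

A second note: the evaluation's headline annual incremental cost
(US$163,841, from which every published ratio chains) differs from the
cost table's arm difference (US$154,263). The engine takes the
incremental cost as an explicit parameter so either can be run, and
`run_full_evaluation()` always reports both; the package does not
adjudicate between them.

## Synthetic-data generator

`simulate_surveillance()` emulates the *outcome-level statistical
structure* of the trial, not its causal mechanism: per cluster, live
births are Poisson around a configurable mean (default 379, matching
~4,170 per arm over 11 clusters); each live birth dies in infancy with
probability equal to the arm rate (defaults 67.2 and 56.4 per 1000) times
a log-normal cluster effect with mean exactly 1 (log-scale SD 0.15 -- a
modeling choice, since no intracluster correlation was published);
death windows follow the nested fractions (79% of neonatal deaths early,
61% of infant deaths neonatal); stillbirths arrive at ~21 per 1000 total
births; and 30% of mothers are non-native (approximating the observed
28-33% per-protocol exclusion). Fixed seeds give byte-identical output.

What passing tests on these data do **not** show: robustness to
informative migration (native status independent of mortality here),
cluster-size/rate correlation, seasonality, or under-ascertainment of
deaths -- features real surveillance can have and the generator does not.

`parameter_recovery_report()` closes the loop: it simulates many trials,
estimates deaths averted from each, and summarizes bias and interval
coverage. The interval uses the design-based cluster-level
ratio-estimator variance (the Hayes-Moulton form,
$\hat V = \frac{k}{k-1}\sum_j (d_j - \hat R n_j)^2 / (\sum_j n_j)^2$ per
arm) with a normal quantile: an individual-level binomial interval would
ignore the between-cluster heterogeneity the generator puts in and
under-cover badly, while the cluster-robust form achieves ~94-95%
empirical coverage at the default 11-clusters-per-arm scale, which is the
property the suite asserts (92-98% over 500 replicates). With 22
clusters, a normal rather than $t_{20}$ quantile costs about one point of
coverage; the normal form is kept for its transparency.

## Problem sizes and runtime choices

The test suite runs the reference chain on the full ~8,400-record fixture,
recovery at 500 replicates (plus 200 under a null effect) at trial scale,
and the large-sample convergence check at 100x cluster size with zero
dispersion (tolerance 1%); the whole suite completes in about a minute on
one CPU. These sizes are the package's validation choices: large enough
that Monte-Carlo error is well inside the asserted bands, small enough to
run everywhere.

## Known limitations

* Effectiveness inference (confidence intervals on the trial's own effect,
  ICC estimation) is out of scope; the pipeline values point estimates.
* No probabilistic sensitivity analysis, DALYs, age-weighting, or
  budget-impact analysis; scenarios are deterministic.
* Single price year; no currency conversion or inflation indexing.
* The per-protocol analysis inherits the usual caveat that migration-based
  exclusion is assumed non-informative for mortality.
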