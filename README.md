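# ceapipe

Incremental cost-effectiveness analysis for community health-worker
programs evaluated in two-arm cluster trials with birth and
infant-mortality surveillance.

Health programs delivered through frontline workers (such as India's
ASHAs) are typically evaluated by asking what one year of the program
costs *beyond routine care* and what that buys in infant deaths averted.
`ceapipe` implements that evaluation end to end, for analysts who need it
reproducible and tested rather than spreadsheet-bound:

* **Costing** — a validated cost ledger (category, start-up vs
  implementation phase, arm, capital flag); capital outlays annualized by
  the discounted annuity factor `AF(r, n) = (1 − (1+r)^−n)/r` (default
  r = 3%, per-category default useful lives); per-arm summaries and the
  incremental cost ΔC.
* **Surveillance** — birth-level records with disjoint death windows,
  counted nested (early neonatal ⊆ neonatal ⊆ infant); intention-to-treat
  (all live births) and per-protocol (native mothers only) cohorts.
* **ICER panel** — with intervention-arm live births B, deaths averted per
  1000 live births ΔE and life expectancy L: cost per 1000 live births
  `1000·ΔC/B`, cost per death averted `(1000·ΔC/B)/ΔE`, life-years saved
  `ΔE·L`, cost per life-year saved, and a strict GDP-per-capita threshold
  verdict — plus an equivalent minimal two-arm decision tree and
  cost-effectiveness-plane coordinates.
* **Scenarios** — deterministic sensitivity analysis over effect
  multipliers, analysis sets and alternative cost bases (annual cost,
  cost per ASHA × head-count, or an externally quoted cost per death
  averted for district scale-up).
* **Synthetic data** — a seeded generator for cluster-trial surveillance
  (Poisson cluster sizes, log-normal cluster rate heterogeneity, nested
  death windows, migration fraction) with a parameter-recovery harness
  using cluster-robust (ratio-estimator) intervals.

## Worked example

```r
library(ceapipe)

records <- reference_surveillance()            # built-in trial fixture
effect  <- effect_from_cohort(build_cohort(records, "PP"))
params  <- reference_cea_parameters("PP")      # ΔC = 163,841; L = 68.35; GDP = 1709
icer_panel(params, effect)
```

```
Cost-effectiveness panel (PP analysis)
  Annual incremental cost (US$)           163,841
  Live births, intervention arm (n)         3,014
  Cost per live birth (US$)                    54
  Cost per 1000 live births (US$)          54,360
  Infant deaths averted per 1000 (n)           11
  Life years saved per 1000 (LE 68.35)        735
  Cost per infant death averted (US$)       5,057
  Cost per life year saved (US$)               74
  Verdict vs GDP per capita 1,709: cost_effective
```

Reading: per-protocol infant mortality was 56.4 vs 67.2 per 1000 live
births (intervention vs control), i.e. ~11 deaths averted per 1000 live
births (a 16% relative reduction). At US$163,841 of annual incremental
cost that is US$54,360 per 1000 live births, US$5,057 per death averted
and US$74 per life-year saved — far below the US$1,709 GDP-per-capita
threshold, so the program is cost-effective. `run_full_evaluation()`
chains the same stages from files (or simulation directives) and writes
the tables, cost-effectiveness-plane coordinates and a JSON summary with
provenance; `inst/scripts/ceapipe-cli.R` wraps it for the shell.

The methods vignette (`vignettes/economic-evaluation.Rmd`) documents the
model, parameter defaults, numerical choices and the generator's scope.

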