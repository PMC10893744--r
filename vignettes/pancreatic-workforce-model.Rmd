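---
title: "A deterministic stage-shift and workforce model for pancreatic cancer planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic stage-shift and workforce model for pancreatic cancer planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancwf)
```

## The model and its assumptions

`pancwf` implements a deterministic, aggregate-count scenario model. Nothing
in it is stochastic at run time: given the same configuration and inputs it
produces the same report, cell for cell. Randomness exists only in the
synthetic-data generator, which exists so the fitting operations can be
exercised and validated without registry access.

The model chain is:

1. **Incidence.** Annual new-case totals `N_y` over a planning horizon,
   either supplied directly (when a published projection is trusted, as in
   the bundled Victorian 2023–2027 inputs) or projected from a registry
   history by a log-linear trend. The trend model assumes a constant
   multiplicative growth factor per year — an intentionally minimal model
   that captures joint population growth, ageing, mortality and migration as
   one net drift. No age–period–cohort or joinpoint structure is attempted.
2. **Stage mix.** A fixed stage distribution `s = (s_{I-II}, s_III, s_IV)`
   splits each year's total. The assumption is that current diagnostic
   practice is stable over the horizon.
3. **Stage-shift scenarios.** An early-diagnosis scenario `(r, q)` reassigns
   a fraction `r` of stage-IV and `1 − q` of stage-III diagnoses to stages
   I–II *within the same year*, leaving `N_y` unchanged (conservation of
   incidence). This is conservative: screening is not allowed to find extra
   cases, only to find the same cases earlier. Stage I–II is always computed
   by subtraction from the year total rather than by adding shifted cases to
   the (possibly display-rounded) early-stage cell, so conservation holds
   exactly even when input cells carry rounding noise.
4. **Survival.** A fixed 5-year relative survival probability per stage
   group, applied as an expectation: `S_y = Σ_k C_{y,k} v_k`. Stage groups
   map to the surveillance summary categories localized / regional / distant.
   There is no survival curve, no interim mortality timing, no competing
   risks, and no lead-time-bias correction — survivor gains arise purely from
   the more favourable stage mix.
5. **Geography.** Four remoteness bands from the Modified Monash scale (MM1,
   MM2, MM3, MM4–7 combined) receive fixed proportional shares of every cell.
   Allocation happens after the statewide model, which makes it exactly
   commutative with the stage shift (a tested invariant).
6. **Workforce.** Registered headcounts per profession and band are compared
   with band-level demand as *cases per registered specialist*. Headcounts
   are persons at their primary registration location, not FTE, and no
   conversion from cases to appointments or procedures is attempted; the
   metric is a descriptive pressure indicator, not a capacity model.

## Parameters that matter

| parameter | units | default | why this default |
|---|---|---|---|
| stage shares `s` | proportions | 0.20 / 0.30 / 0.50 | reproduces the bundled 2023 status-quo row (198.2 / 297.3 / 495.5 of 991) |
| survival `v` | probability | 0.416 / 0.144 / 0.030 | SEER-derived localized / regional / distant 5-year relative survival |
| stage-IV shift `r` | fraction | 0.2, 0.5, 0.7 | the pessimistic / middle / optimistic screening scenarios in the bundled inputs |
| stage-III retained `q` | fraction | 0.8216 | calibrated as 244 / 297 from the bundled 2023 scenario rows, whose proposed stage-III column (244, 253, 259, 265, 271) is identical across all three scenarios; exposed as a config parameter |
| remoteness shares `w` | proportions | 0.81 / 0.0575 / 0.06 / 0.0725 | calibrated as (324, 23, 24, 29)/400 from the bundled 2023 band allocation |
| log-fit offset | cases | 0, or 0.5 with zero counts | an offset distorts the slope on all-positive data (an exactly geometric series must be recovered exactly), but is required for zeros; applied only when needed, configurable |
| display rounding | — | half away from zero | reproduces the bundled tables' cells almost everywhere; residual ±1 disagreements are tolerated, never propagated (all arithmetic stays unrounded) |
| lead time `L` | years | 0 | values > 1 enable the experimental pull-forward variant (below) |

## Numerical and design choices

**Real-valued internals.** Published planning tables round from non-integer
internals: the bundled 2023 row prints cells 198 + 297 + 495 = 990 against a
printed total of 991. The package therefore keeps all arithmetic real-valued,
lets an explicit year total take precedence over the stage-cell sum (within a
slack of half a case per cell), and rounds once, at display.

**Identity scenario.** `r = 0, q = 1` returns the input untouched. Running it
through the subtraction formula instead would silently absorb the rounding
gap between printed cells and printed totals into the early-stage cell, which
would make a declared no-op change the data.

**Infeasibility.** If `q·C_III + (1−r)·C_IV > N_y` the implied early-stage
cell would be negative; the scenario raises an error rather than clamping,
because clamping would silently break conservation.

**Lead time.** The "diagnosed five years earlier" variant has no unambiguous
published construction. The implemented reading pulls the scenario's
early-stage *gains* of the following `L − 1` horizon years into the first
horizon year (whose total then grows accordingly, deliberately breaking
within-year conservation). The output is flagged `experimental`, and no
headline figure of the package depends on it.

**Supply projection.** The bundled workforce table is already a projection,
so it is passed through as input. The log-linear supply fitter exists for
registry-style or synthetic series and mirrors the incidence fitter exactly.

**Uncertain fixture cells.** The non-metropolitan rows of the bundled
current-workforce-by-band snapshot could not be transcribed unambiguously
from their source; they ship flagged `uncertain = TRUE` and none of the
package's checks assert on them.

## What the synthetic generator emulates — and what it does not

`synth_params()` + `generate_full_bundle()` produce a registry-style bundle:
a 12-year incidence history with constant-growth means and Poisson count
noise (variance equal to the mean, the natural first model for registry
counts), near-geometric workforce series per profession, and the share
tables. Defaults mirror the bundled Victorian conditions: history ending 2022
at a level projecting to ≈991 cases in 2023 with 2.6%/year growth (the growth
the published 2023–2027 totals imply), the default stage/survival/remoteness
shares, and the seven professions' 2023 headcounts with their fitted growth
rates. One seed governs all streams, with fixed per-stream offsets, so a
stream can be regenerated alone and bundles are byte-identical under a fixed
seed.

The generator does *not* emulate: overdispersion or registration lag in
registry counts, structural breaks in incidence trends, correlation between
workforce and population growth, or within-band heterogeneity. Passing tests
on synthetic data therefore demonstrate that the estimators recover the
model's own assumptions (unbiased growth recovery at 12 years × ~1000
cases/year was checked over 500 seeded replicates), not that real incidence
is log-linear.

## Problem sizes used in the checks

The test-suite simulations are deliberately small because the estimators
converge quickly at registry-scale counts: 500 replicates for the
growth-recovery and interval-coverage checks (12-year histories, ≈900–1200
cases/year) and a 2000-draw flat series for the Poisson variance/mean check.
The full pipeline runs on the five-year bundled horizon in well under a
second.

## Known limitations

* Incidence conservation means screening yield, overdiagnosis and diagnostic
  operating characteristics are out of scope by construction.
* Survival is a point probability; nothing is said about when within the five
  years deaths occur, or about lead-time bias in the survival comparison.
* The workforce side has no FTE, age-structure, retirement, multi-site
  practice or telehealth adjustments; "cases per registered specialist"
  overstates pressure where specialists service multiple bands.
* Remoteness shares are held constant over the horizon; differential regional
  growth would need per-band incidence inputs, which the model accepts but
  the bundled fixture does not provide.
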