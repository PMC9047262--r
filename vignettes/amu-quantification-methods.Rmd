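---
title: "Quantifying farm-level antimicrobial use in swine: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying farm-level antimicrobial use in swine: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swineamu)
```

## The measurement problem

Antimicrobials reach pigs by four routes — medicated feed rations, creep
feed offered to suckling piglets, medicated drinking water, and
injection — and the questionnaire records each route in its natural
unit: grams of active ingredient per tonne of feed, grams per litre of
water, or an injectable concentration (mg/mL) with a daily volume. Only
the injectable route states a per-animal mass directly. For the oral
routes the consumed antimicrobial mass is the product of a
*concentration* and an estimated *intake*, so the quality of the AMU
estimate rests on the intake models, and every downstream metric is a
deterministic transformation of the per-record mass:

* `mg/kg biomass = total mg / (pigs at risk × standard weight)`,
* `doses per pig = total mg / (DDD × standard weight × pigs at risk)`,
* `dose rate = doses per pig / time at risk × 1000` (per 1000 pig-days).

Pigs at risk subtract half the cycle's deaths from the entering count —
the usual assumption that deaths occur uniformly, so a dead pig was at
risk for half the cycle on average. The count is deliberately kept
fractional (half-integral) internally; rounding it would bias every
biomass denominator slightly and in the same direction.

A farrowing questionnaire covers two populations at once: lactating sows
and their suckling litters share one herd, one room and one time at
risk. The data model therefore gives a farrowing herd two cohort rows
(`farrowing_sows`, `suckling`) under a single `cohort_id`, and every
treatment record names its `pig_type`, which is how sow feed and piglet
creep feed from the same questionnaire end up in different report rows.

## Intake models and their parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| sow gross feed | 6280 | g/day | lactating-sow ration offered |
| sow feed wastage | 0.05 | — | offered − consumed; net 5966 g/day |
| sow water | 18 | L/day | fixed lactating-sow water intake |
| water intercept | 0.149 | L/day | water intake at zero feed |
| water slope | 3.053 | L per kg feed | affine water–feed coupling |
| standard litter | 11 | pigs | creep model normalization |
| standard weights | 240 / 4 / 11.5 / 65 | kg | sows / suckling / nursery / grower-finisher weight at treatment |

Growing pigs (nursery, grower-finisher) do not eat a constant ration:
daily intake rises with age. The package represents each stage's intake
as sampled (day, kg/day) points, fits a least-squares polynomial
(default degree 2) and integrates the fit *analytically* over the ration
window, so cumulative feed is exact for the fitted curve and free of
quadrature error. Herds are first stratified by average daily gain
(ADG): below the stage's 25th percentile "low", above the 75th "high",
otherwise "average", each stratum carrying its own curve. A ration that
starts mid-cycle is offset into the curve by
`(ration start weight − cohort start weight) / ADG` days, converting the
recorded weight window into the curve's time axis.

Two numerical conventions matter here. Percentiles interpolate linearly
at `(n + 1)p` positions (quantile type 6, the common epidemiological
convention), and a herd lying exactly on a quartile (within a 1e-9
relative tolerance) is assigned to the *average* stratum — extremes are
reserved for herds strictly beyond the thresholds. With a single herd in
a stage both quartiles collapse onto its own ADG and the herd is
"average", which is the sensible degenerate behaviour.

The packaged curve sets (`inst/extdata/intake_curves.yaml`) and the
quadratic creep model (litter-total grams as a function of creep-feeding
duration, divided by an 11-pig standard litter) are calibrated to
plausible commercial magnitudes only — roughly 32 kg of nursery feed
over 52 days and 255 kg of grower-finisher feed over 112 days for
average performers — and are intended to be replaced by
calculator-specific curves via the YAML config. Creep wastage, estimated
by the producer, is applied against the *consumed medicated mass*
(`× (1 − pct_wasted)`) after the per-piglet intake is computed: wasted
medicated feed is antimicrobial that entered the barn but not the pig.

In-water mass for growing pigs uses the affine water model driven by the
*mean* daily feed intake over the full production period (cumulative
feed ÷ days at risk). The averaging window is a design choice — the
model needs one representative feed intake and water medication windows
are short relative to the cycle; using the full period keeps the choice
independent of where in the cycle the medication fell. Water medication
of suckling piglets is not modelled (they drink primarily milk) and is
rejected with an error rather than silently mis-estimated.

## From exposure to report tables

The default reporting mode is **pooled**: masses are summed over all
cohorts of a stage and divided once by the pooled denominator (total
pigs at risk × standard weight; the stage *median* cycle length for dose
rates). Pooled metrics are mass-weighted study-level values and make the
route rows exactly additive: the all-routes mg/kg of a stage equals the
sum of its route rows because they share one denominator. A `per_herd`
mode computes each cohort's metrics against its own denominators and
time at risk, for benchmarking individual herds; its median summaries
will generally differ from pooled values, which is expected, not a bug.

Conventions fixed at this layer:

* Creep feed is reported under the **feed** route for suckling pigs.
* Mass columns are reported in **grams**. The published route-level
  summary shipped for reconciliation (`reference_route_summary()`)
  labels the same column "kg", but its own mg/kg and additivity
  arithmetic only reconciles in grams, so the package standardizes on
  grams. The same reference prints a nursery all-routes mg/kg (274.2)
  slightly below the sum of its route rows (276.6); the package follows
  additivity and does not reproduce the printed figure.
* Combination products (e.g. trimethoprim + sulfadoxine) are one record
  per constituent with its own concentration, so each constituent
  carries its own standard dose and report row.
* Long-acting injectable formulations are distinct registry keys
  (`aai`, `long_acting`), because their standard daily dose differs.
* Ionophores (e.g. salinomycin) count as antimicrobials, consistent
  with their regulatory classification in Canada (category IV).
* The exposed fraction (`pct_fed`, `pct_exposed`) multiplies the
  *mass*, not just the exposed head count: 50% of pigs fed a ration
  consume 50% of the ration's antimicrobial.
* A missing DDD registry entry is an error naming the ingredient; a
  silent default dose would corrupt dose-based metrics invisibly. The
  packaged registry ships *illustrative* standard doses and is meant to
  be replaced by a jurisdiction-specific table
  (`--ddd-registry`, `read_ddd_registry()`).
* Report files round to 1 decimal (confidence bounds to 2) with
  round-half-even; in-memory values are never rounded.
* Time at risk uses whole-day arithmetic, inclusive of the start day
  and exclusive of the end day.

Health-status reports collapse the five questionnaire levels to
positive / negative / unknown, counting "likely" answers with
"confirmed" ones: herds are managed (and medicated) according to
believed status, with or without laboratory confirmation. Biosecurity
frequencies carry exact Clopper–Pearson intervals from beta quantiles
(`qbeta(α/2, k, n−k+1)`; `qbeta(1−α/2, k+1, n−k)`), chosen because herd
denominators are small (~25) where asymptotic intervals undercover, and
verified in the test suite against `binom.test` inversion for every
`k ≤ n ≤ 30`.

## The synthetic generator and what passing tests mean

`generate_study()` emulates the marginal structure of a cross-sectional
Ontario-style study: 25 farrowing, 25 nursery, 23 grower-finisher herds;
four continuous-flow herds per stage; 4 / 2 / 1 herds per stage on a
raised-without-antimicrobials program (modelled as using only injectable
individual treatment); cycle lengths spanning 18–41 / 28–99 / 87–157
days constructed so each stage's sample median is exactly 23 / 52 / 112;
batch sizes tuned so stage totals of pigs at risk land near 780 sows,
10,000 suckling, 13,250 nursery and 21,600 grower-finisher pigs;
binomial mortality feeding the minus-half-the-deaths rule; and a
treatment menu echoing a realistic ingredient mix (chlortetracycline
dominant in sow/creep/nursery feed, lincomycin in grower-finisher feed,
procaine penicillin G the commonest injectable, amoxicillin the
commonest nursery water medication). Doses and exposed fractions are
drawn on discrete grids, which keeps values realistic and lets the
CSV round trip reproduce them exactly.

Every drawn quantity is recorded in a **ledger**, and
`expected_metrics()` computes the pooled report values from the ledger
alone with explicitly written-out arithmetic — no calls into the
exposure or metrics code paths. The headline property test generates a
study, writes it to CSV, re-reads it, runs the full pipeline and
requires agreement with the ledger to 1e-9; in practice agreement is at
machine precision. This validates the *plumbing* end-to-end (readers,
percent conversion, joins, stratum assignment, aggregation), while the
*formulas* are validated separately against hand arithmetic and an
independent quadrature oracle.

What the generator does **not** emulate: between-farm correlation
(common ownership, shared veterinarians), seasonality, within-herd dose
variation, or the published mass totals themselves — synthetic exposure
intensity is plausible in scale but not calibrated to any published
total. Passing recovery tests therefore demonstrates computational
correctness on realistic structure, not epidemiological agreement with
any particular study population.

## Problem sizes and runtime

The test suite runs the full 73-herd configuration for the acceptance
recovery check and 5-herd-per-stage configurations for multi-seed
property tests (15 seeds for range checks), completing in well under a
minute on one CPU. `scripts/acceptance.R` runs one full-size synthetic
study plus the closed-form reconciliations in a few seconds.

## Known limitations

* Intake curves and the creep regression are placeholders of realistic
  magnitude; absolute synthetic masses inherit their scale.
* The DDD registry defaults are illustrative, not an official standard;
  dose-based metrics are only comparable across studies when the same
  registry is used.
* Sow body weight is treated as constant (no lactation weight loss),
  and sow feed as a constant daily ration.
* Oral individual (non-water, non-feed) dosing is not modelled; the
  study design this package mirrors found no reported use of it.
* Time at risk for all-in-all-out barns uses the questionnaire date as
  the anticipated cycle end; if a questionnaire is completed well before
  the cycle ends, time at risk is underestimated.
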