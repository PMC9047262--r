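# swineamu

Farm-level antimicrobial-use (AMU) quantification for swine herds.

Surveillance of on-farm antimicrobial use underpins antimicrobial
stewardship in pig production, where most antimicrobial mass is given to
groups of animals in feed or water rather than to individuals by
injection. `swineamu` turns questionnaire-style records from farrowing
(lactating sows + suckling pigs), nursery and grower-finisher herds —
feed rations in g of active ingredient per tonne, water medications in
g/L, injections by concentration and volume, plus herd demographics,
health status and biosecurity — into the three families of AMU metrics
used in veterinary surveillance:

* **frequency** — the percentage of herds using antimicrobials, by route
  of administration and active ingredient;
* **weight-based** — mg of active ingredient per kg of biomass, where
  biomass = pigs at risk × standard weight at treatment
  (240 / 4 / 11.5 / 65 kg for sows, suckling, nursery and
  grower-finisher pigs);
* **dose-based** — the number of defined daily doses (nDDD) per pig,
  `total mg / (DDD_mg/kg/day × standard weight × pigs at risk)`, and the
  dose rate per 1000 pig-days, `doses per pig / time at risk × 1000`.

The exposure denominators follow the surveillance convention: **pigs at
risk** = pigs entering the production cycle − half the deaths, and
**time at risk** = the production-cycle length (questionnaire date −
first entry for all-in-all-out barns; reported average cycle length for
continuous flow), with stage *median* cycle lengths as the animal-time
denominator of pooled dose rates.

Because in-feed and in-water doses are concentrations, consumption must
be modelled: sows eat a fixed 6280 g/day less 5% wastage (5966 g
consumed), piglet creep intake follows a litter-level regression in
creep-feeding duration (normalized to an 11-pig litter, with
producer-estimated wastage applied against the medicated mass), growing
pigs follow performance-stratified daily-intake curves (herds split into
low / average / high performers at the 25th/75th ADG percentiles, and
the stratum curve is fit by least squares and integrated in closed form
over the ration window), and water intake is the affine model
`L/day = 0.149 + 3.053 × mean daily feed intake (kg/day)` (18 L/day for
lactating sows).

The package also builds the descriptive surveillance tables (herd health
status collapsed to positive / negative / unknown, vaccination, AMU by
disease, biosecurity practices with exact Clopper–Pearson binomial
confidence intervals), and ships a seeded synthetic questionnaire
generator whose ground-truth ledger gives closed-form expected metrics —
so the entire pipeline is testable end-to-end without any restricted
farm data.

## Worked example

```r
library(swineamu)

g  <- generate_study(generator_config(seed = 1))  # 25 + 25 + 23 herds
ex <- compute_exposure(g$study)                   # mg per record
m  <- build_metrics_tables(g$study, ex)           # pooled stage metrics
m$by_route
```

```
   pig_type   route      pct_herds pigs_at_risk total_g mg_per_kg_biomass ddd_per_pig
 1 sows       feed            20           800.  7.30e3              38.1         2.5
 2 sows       injection      100           800.  8.39e1               0.4         0
 3 sows       all_routes     100           800.  7.39e3              38.5         2.6
 4 suckling   feed            32          9978   2.24e2               5.6         0.3
 5 suckling   injection       92          9978   2.55e2               6.4         1.1
 6 suckling   all_routes      96          9978   4.79e2              12           1.4
 7 nursery    feed            92         14500.  1.42e5             851.         43.6
 ...
```

Each row is one production stage × route (plus an `all_routes` sum):
the share of herds using the route, the pooled pigs at risk, total grams
of active ingredient, mg per kg of stage biomass, defined daily doses
per pig, and doses per 1000 pig-days at the stage median time at risk.
Creep feed is reported under the feed route for suckling pigs.

```r
proportion_ci(3, 25)   # e.g. 3 of 25 herds using a boot dip
#>   numerator denominator point  lower upper level
#> 1         3          25  0.12 0.0255 0.312  0.95

sow_daily_feed()          # 5966 g consumed per sow per day
water_intake_per_day(1)   # 3.202 L/day at 1 kg/day feed intake
```

The same flow is scriptable from a shell via
`inst/scripts/amu_pipeline.R` with subcommands `validate`, `simulate`,
`quantify` and `describe`.

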