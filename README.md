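# vaportox

First-tier toxicological risk assessment for additives in vaporized
cannabis concentrates.

State-legal cannabis markets sell concentrate vaporization products that
routinely contain additives — botanical terpenes, diluents, flavourings —
for which regulators and manufacturers have had no structured way to judge
inhalation safety. `vaportox` implements a complete first-tier (screening
and prioritization) risk assessment for a single additive: categorical
hazard screening, safety-limit derivation from a point of departure with
uncertainty factors, threshold-of-toxicological-concern (TTC) routing for
data-poor substances, exposure assessment from consumption data, and risk
characterization with a back-calculated maximum allowable concentration.
It is aimed at regulators, cannabis manufacturers and risk assessors who
need a defensible, auditable screen without deep toxicological tooling.

## The method

For a substance that passes categorical screening (no non-native
respiratory sensitization, no "Big 8" allergen source, no phenolic acetate
moiety, no supplement/vitamin/HPHC listing), a safety limit is derived from
the most sensitive point of departure (POD — a NOAEL, NOAEC or regulatory
limit; never an LD50/LC50):

```
safety limit = POD_adj / (UF1 × UF2 × UF3 × UF4 × UF5 × UF6)
```

where `POD_adj` is the POD adjusted to continuous exposure (×h/24 for
inhalation, ×d/7, × test-article purity) and the six uncertainty factors
cover interspecies (10), intraspecies (10, reducible to 3 or 1),
oral-to-inhalation route extrapolation (2 × 3), LOAEL-to-NOAEL (10),
study duration (10 subacute, 3 subchronic) and database completeness
(1/3/10). A total UF above 10,000 refuses a numeric limit. Limits are
normalized to mg/day with a 60 kg body weight and inhalation volumes of
0.3 / 6.7 / 20 m³ for 15-min / 8-h / 24-h windows. Substances without
usable PODs route through a five-question TTC decision tree to a fixed
µg/day limit by chemical category.

Exposure uses

```
daily exposure (mg/day) = concentration (mg/g) × consumption (mg/day) / 1000
```

with a default consumption of 100 mg/day — the mean of the weekly and
monthly 95th-percentile daily averages observed in smart-vaporizer
telemetry — and risk is characterized by the margin `limit / exposure`,
with the maximum allowable concentration back-calculated as
`limit / consumption × 100` (% w/w). A seeded synthetic usage-log
simulator (intermittent use days, heavy-tailed per-use-day consumption)
makes the whole exposure pipeline testable without any proprietary data.

## Worked example

```r
library(vaportox)

d <- substance_dossier("geraniol",
  native_to_cannabis = TRUE, gras_or_food_use = TRUE, cramer_class = "1"
)
run_assessment(d, product_context(), concentration_mg_per_g = 0.5)
#> == First-tier assessment: geraniol ==
#> concentration assessed: 0.5 mg/g at 100 mg/day consumption
#> <risk_verdict> low_risk
#>   exposure: 0.05 mg/day
#>   limit: 0.865 mg/day ( ttc )
#>   margin: 17.3
#>   Exposure is at or below the safety limit; toxicological risk is expected to be low.
#> max allowable concentration: 0.865 % w/w
```

Geraniol has no PODs in this dossier, so the assessment routes through the
TTC tree: it is cannabis-native/GRAS and Cramer class 1, giving an
865 µg/day (0.865 mg/day) limit. At 0.5 mg/g in the concentrate and
100 mg/day consumption, daily exposure is 0.05 mg/day, a 17.3-fold margin
below the limit; concentrations up to 0.865 % w/w (8.65 mg/g) would still
screen as low risk.

A POD-derived example:

```r
pod <- pod_record(100, "mg_per_m3", "NOAEC",
  route = "inhalation", species = "animal", duration_class = "subchronic",
  hours_per_day = 6, days_per_week = 5
)
adjust_pod(pod)$value      # 17.857 mg/m3 (100 × 6/24 × 5/7)
normalize_limit_to_mg_per_day(135, "mg_per_m3", "twa_8h")  # 904.5 mg/day
```

A command-line front end (`inst/cli/vaportox`) exposes `assess`,
`summarize-usage`, `simulate` and `max-conc` subcommands with exit codes
0 (low risk), 2 (exceeds limit), 3 (excluded), 4 (insufficient data) for
scripted batch screening.

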