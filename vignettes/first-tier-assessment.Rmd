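---
title: "First-tier risk assessment of vaporized concentrate additives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-tier risk assessment of vaporized concentrate additives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaportox)
```

## The assessment model

`vaportox` implements a first-tier — deliberately conservative, screening
level — toxicological risk assessment for a single additive in a vaporized
cannabis concentrate. The pipeline follows the classical four steps:
hazard assessment (categorical screening), dose–response (safety-limit
derivation or TTC), exposure assessment, and risk characterization. It is
a prioritization tool: a `low_risk` verdict means the additive does not
warrant priority concern at the assessed concentration under conservative
assumptions, not that it is proven safe; `exceeds_limit` means the
concentration should be reduced or a higher-tier assessment performed.

### Categorical screening

Some hazard classes are handled by rule rather than by dose because their
effects are severe at doses far below anything measurable in a first-tier
setting. Respiratory sensitizers can elicit asthma or anaphylaxis, and no
validated quantitative sensitization risk method exists for inhalation;
non-cannabis-native sensitizers and "Big 8" food-allergen sources are
excluded outright. Phenolic acetates are excluded because thermal
breakdown of the phenolic acetate moiety releases ketene, the mechanism
implicated in the EVALI outbreak. Supplements, vitamins, minerals and
listed harmful/potentially harmful constituents are excluded for their
pharmacological activity by an untested route. Sensitizers that the
cannabis plant itself produces are not excluded — consumers are already
exposed — but are capped at the plant's own level relative to THC:
`cap (mg/g) = plant ratio to THC × product THC concentration (mg/g)`.

Genotoxicants and listed carcinogens are a deliberate design point: the
framework offers either avoidance or a genotoxic TTC limit, so the default
here routes them to the TTC tier and a `strict_genotox` switch turns the
flag into an exclusion. All rules are evaluated without short-circuiting
so a report lists every triggered rule.

### Safety-limit derivation

The safety limit divides an adjusted point of departure by six
multiplicative uncertainty factors. The POD is adjusted to continuous
exposure — `× hours/24` (inhalation concentrations only; an oral NOAEL is
a daily dose however it is gavaged), `× days/7`, `× purity` — and the
factors default to: interspecies 10; intraspecies 10 (3 or 1 only on an
explicit assertion that the study population was sensitive — the
reduction is permissive, never automatic); oral-to-inhalation 6 (a
toxicokinetic 2 times a toxicodynamic 3, the 2 replaced when measured
absorption data exist); LOAEL-to-NOAEL 10; duration 10 (subacute) or 3
(subchronic); database completeness 10, or 3 when structural features are
not suggestive of developmental toxicity, waived entirely for age-gated
products or when developmental data exist. A total above 10,000 is
treated as "insufficient information": the pipeline refuses a numeric
limit and falls back to TTC. Dermal PODs are rejected — no dermal
extrapolation factors are defined and we do not invent any — and
LD50/LC50 are unrepresentable by construction in the POD type enum.

A NOAEL is only trusted if it is below every LOAEL for the same endpoint
track; otherwise the LOAEL-derived candidate (with its factor of 10)
governs, since a NOAEL above an observed-effect level contradicts it.
Local respiratory and systemic endpoints are tracked separately — oral
data cannot speak to local respiratory effects — and the lower of the two
tracks governs. Every discard and selection is written to the audit trail.

Unit normalization to mg/day uses a 60 kg body weight (a conservative
adult assumption) and window-matched inhalation volumes: 0.3 m³ per
15 min (STEL), 6.7 m³ per 8-h workday (TWA), 20 m³ per 24 h. These
conversions are centralized in one function; the µg→mg conversion for TTC
limits likewise passes through a single choke point, because a silent
1000-fold unit slip is the worst failure mode a framework like this can
have.

### TTC routing

When no usable POD exists, a five-question decision tree assigns a
generic exposure limit by chemical category: an applicability gate
(metals, nanoparticles, proteins, steroids and other classes for which
TTC is invalid); organophosphates/carbamates at 18 µg/day; genotoxicants
at a duration-tiered 1.5/10/20/120 µg/day; cannabis-native or GRAS/food
substances by Cramer class (865 µg/day class 1, 145 µg/day classes 2–3);
and a fallback by OASIS mode of action (22.39 µg/day base/surface
narcotics, 4.286 µg/day reactive). The printed question order is
authoritative: an organophosphate with a genotoxicity alert keeps
18 µg/day, with a warning rather than a silent minimum. A
`conservative = TRUE` mode instead takes the minimum over every branch
whose predicate holds, reflecting the advice that multiple models be run
and the more conservative value kept; it is off by default to match the
printed tree. Cramer class and OASIS MOA are inputs classified with
external tools (ToxTree, OECD QSAR Toolbox) — reimplementing those
decision trees is out of scope, and reaching a question that needs a
missing classification is an error naming the tool, never a guess. The
limits ship as a versioned JSON table that a regulator can audit or
override.

One open point is a carcinogen listing without a genotoxicity alert: the
tree does not address it, so the router warns and proceeds to Q4/Q5
rather than silently applying the genotoxic tier.

### Exposure and risk

Daily additive exposure is `concentration (mg/g) × consumption (mg/day) /
1000`. The default consumption of 100 mg/day is the mean of the weekly
and monthly 95th-percentile daily averages from large-scale smart-device
telemetry (140 and 57 mg/day → 98.5, headline-rounded to one significant
figure). Using a 95th-percentile figure for one parameter while others
stay at central values avoids compounding conservatism. Bioavailability
is 100% by default (conservative) and deliberately does not enter the
additive-exposure equation.

Risk is low when exposure ≤ limit. Equality is a measure-zero case the
source convention leaves undefined ("less than" is low risk, "exceeds"
is action); we treat it as low risk with an explicit boundary warning so
the conservatism question stays visible. The maximum allowable
concentration inverts the exposure equation:
`limit / consumption × 100` (% w/w), capped at 100%. Exposure and
back-calculation are exact inverses, which the tests assert as a
round-trip identity.

## Consumption summaries

`summarize_usage()` reduces a per-device-day log to the standard
habits-and-practices structure: per-use-day consumption (conditioning on
use days, since most consumers use intermittently), weekly and monthly
totals including non-use days, their daily averages (÷7 and ÷30.5), and
use days per month. Design choices the data format forces us to make
explicitly:

* **Percentile convention** — empirical quantiles with linear
  interpolation between order statistics (type 7), the most common
  default, documented so results are reproducible elsewhere.
* **Windows** — calendar-aligned ISO weeks and calendar months,
  zero-filled inside each device's first-to-last observed day. Rolling
  windows were the alternative; calendar alignment matches how monthly
  "days of consumption" counts are naturally reported.
* **Devices ≈ users** — one device is treated as one consumer; shared
  devices are a known source of upward bias we cannot correct.
* Display rounding (integer daily averages, one-significant-figure
  headline) is separate from stored full-precision values.

## The synthetic usage simulator

`simulate_usage()` generates logs with the two structural features that
matter for exposure: intermittent use and a heavy right tail. Use-day
counts per device-month are zero-truncated negative binomial with
size 0.914 and mean 6.67, chosen so the truncated distribution has mean
7.8 and median 5 use days/month with a 95th percentile near 24 — the
over-dispersion the telemetry reports. Per-use-day consumption is
i.i.d. log-normal calibrated in closed form to a median of 44 mg and
mean of 151 mg (`meanlog = ln 44`, `sdlog = √(2 ln(151/44)) ≈ 1.571`).
Draws are i.i.d. across days and months because the telemetry summaries
provide no within-device dependence information; every device-month is
drawn from the truncated distribution, so the simulator represents a
panel of devices active in every month of the horizon rather than
modelling churn. The default horizon is three calendar months from a
month boundary, enough to exercise daily, weekly and monthly summaries in
one run.

What the simulator does *not* emulate: device sharing, seasonal or
weekday patterns, within-user autocorrelation, and the enrolment churn
that makes real monthly totals much lower than a full-panel calculation
would give. Consequently simulated weekly/monthly *percentiles* are not
expected to match the published ones (which also carry ~20% estimation
error from the upstream puff-mass model); passing recovery tests shows
the exposure pipeline is correct on data with realistic daily structure,
not that the simulator reproduces the real fleet.

Test and acceptance runs use 10,000 devices × 3 months (~230k use days)
for parameter-recovery checks at 10% tolerance and 50–2,000 devices for
structural properties; recovery of the daily median/mean is comfortably
inside the Monte-Carlo noise at that size.

## Numerical and interface choices

* Validation collects *all* invariant violations before aborting, so a
  dossier author fixes a file in one pass.
* Hazard flags absent from an input file default to `FALSE` but are
  recorded as "not asserted", distinguishing screened-clean from
  never-asserted.
* JSON is the canonical nested dossier form; the CSV dialect (one row
  per POD, dossier fields repeated) exists for spreadsheet entry by
  non-programmers. Round-trip identity over randomly generated dossiers
  is property-tested for both.
* Limits carry full floating precision internally; reports display 3
  significant figures.
* All randomness is seeded through a single parameter object;
  identical parameters and seed give byte-identical logs.

## Known limitations

First-tier scope only: no mixture interactions, no device-specific
thermal degradation, no aerosol chemistry, no benchmark-dose modelling,
no probabilistic exposure. Cannabinoids themselves and contaminants
(solvents, pesticides, metals) are out of scope. The 60 kg body weight is
the only stated conversion weight — child/adolescent scenarios are not
modelled because the products are assumed age-gated. Verdicts are only as
good as the dossier: hazard flags and classifications are user-asserted
inputs, not predictions.
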