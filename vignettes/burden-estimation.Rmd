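---
title: "Estimating dementia prevalence and cost of illness across countries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dementia prevalence and cost of illness across countries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiburden)
```

## The model

`coiburden` implements a country-level cost-of-illness (COI) model for
dementia. It has three stages.

**Prevalence.** For each country, sex $s$ and age band $a$, the number of
people living with dementia is

$$N_{a,s} = p_{a,s} \cdot \mathrm{Pop}_{a,s},$$

where $p_{a,s}$ is an age-band-by-sex prevalence schedule and
$\mathrm{Pop}_{a,s}$ a population pyramid. Case counts are summed over bands
and sexes above age thresholds (50+ and 60+ by default) and divided by the
matching population to give country prevalence proportions. Population
pyramids usually arrive on 5-year bands while schedules use decades, so
pyramids are first collapsed onto the schedule's bands. Collapsing only ever
*sums whole source bands*: a source band that straddles a target boundary is
rejected rather than split, because splitting would require a within-band age
model the data do not support.

**Direct costs.** Per-person direct cost is modelled as an income-class
fraction of GDP per capita at purchasing power parity,

$$D = f_k \cdot \mathrm{GDPpc}^{PPP} \cdot N_{50+},$$

with $f_k$ a dimensionless factor per World Bank income class $k$ (low,
lower-middle, upper-middle, high). The 50+ case count is priced; the
threshold is a configuration knob (`case_threshold`).

**Indirect costs.** Informal caregiver time is priced at the national average
wage under two bracketing scenarios:

$$I_\text{scen} = w \cdot h_\text{scen} \cdot 365 \cdot c_\text{scen} \cdot N_{50+},$$

where $w$ is the hourly wage, $h$ the caregiver hours per day and $c$ the
share of people with dementia living in the community (and hence receiving
informal rather than institutional care). Defaults: best case $h = 1.6$,
$c = 0.90$; worst case $h = 3.7$, $c = 0.99$; 365 days/year. Retired
caregivers are priced at the working-age wage — there is no separate wage
track. For any common wage and case count the two scenarios are locked in the
exact ratio $(3.7 \times 0.99)/(1.6 \times 0.90) = 2.54375$, which the tests
assert per country. The *mean scenario* is defined per country as the
midpoint $(I_\text{best} + I_\text{worst})/2$ and then summed for the region;
a region midpoint computed from already-summed totals is identical by
linearity, but the per-country definition is the one reported.

Totals are $T_s = D + I_s$ and the burden relative to the economy is
$100 \cdot T_s / \mathrm{GDP}$.

## Tunable parameters

| parameter | unit | default | notes |
|---|---|---|---|
| scenario hours | h/day | 1.6 (best), 3.7 (worst) | `care_scenario()`; extra scenarios allowed |
| community share | proportion | 0.90 / 0.99 | fraction of cases cared for at home |
| days of care | days/yr | 365 | informal care has no weekends |
| wage convention | h/wk, wk/yr | 40 × 52 | monthly→hourly divisor ≈ 173.33 |
| case threshold | years | 50 | case count priced in both cost arms |
| direct-cost factors | — | per income class | supplied as a CSV table |

The monthly-to-hourly wage conversion deserves a note: published monthly
earnings do not determine an hourly wage without a full-time convention. We
adopt 40 h/week × 52 weeks (hourly = monthly × 12 / 2080) and expose both
knobs. Under this convention a monthly class wage of \$3943.33 prices out at
\$22.75/h and \$104/month at \$0.60/h, matching the hourly figures typically
quoted for high- and low-income country groups, which is why it is the
default rather than a 44-h or paid-leave-adjusted variant.

## Missing economic data

GDP per capita and especially ILO wage coverage are incomplete in practice
(wage rows exist for only a handful of countries in some regions). Missing
values are filled by income-class donors:

* `impute_gdp()` takes a named mapping class → value (group-value mode, e.g.
  published income-group aggregates);
* `impute_wage()` takes class averages, either supplied directly or computed
  from an observed wage table with `group_average_wage()` (group-mean mode).

Imputation never overwrites an observed value, is idempotent, and sets
`imputed_gdp`/`imputed_wage` flags so provenance survives into the report
tables. A country whose class has no donor raises a typed error rather than
silently propagating `NA`.

Countries with missing *total* GDP get `NA` percent-of-GDP entries and are
excluded from the pooled region ratio (both cost and GDP removed, so the
ratio stays internally consistent). Because "region percent of GDP" is
ambiguous — cost-weighted pooling versus a simple average of country
percentages differ whenever small economies carry high burdens — both
variants are always emitted (`pct_gdp_*_pooled` and
`pct_gdp_*_country_mean`).

## The synthetic-data generator

`generate_inputs()` produces a complete, internally consistent input set with
known ground truth:

* **pyramids** on 5-year bands with an open 90+ band; stratum size decays
  exponentially with the band midpoint (`age_decay = 0.045` per year gives
  old-age tails of the kind high-fertility, fast-ageing regions show), with a
  mild female survival advantage (`sex_ratio_at_60 = 0.52`, drifting up with
  age);
* a **prevalence schedule** on decade bands from age 50 that rises
  multiplicatively with age (base 0.006 in the 50–59 male band, ×2.8 per
  decade, female/male rate ratio 1.25) — dementia prevalence roughly doubles
  to triples per decade of age and is higher in women, and these defaults
  keep band rates inside the ranges global schedules report;
* **economics** with lognormal GDP per capita (log-mean 9.3, log-sd 1.1,
  i.e. a median near \$11,000 and a long right tail), income classes cut at
  \$4,000/\$13,000/\$30,000, wages tied to GDP by a power law (elasticity
  0.9) with 20% lognormal noise, and deliberate missingness — 14% of GDP
  values and 85% of wages blanked, mirroring how sparse ILO wage coverage is
  relative to World Bank GDP coverage;
* the **ground truth** needed downstream: pre-blanking GDP/wages and the
  class donor mappings derived from them.

The generator uses one private RNG stream per call and restores the caller's
global RNG state.

`ground_truth()` recomputes every pipeline output with naive per-stratum,
per-country scalar loops that share no code with the vectorized path. The
test suite asserts agreement to 1e-9 relative on 20 seeds; this is the
generator's reason to exist.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: migration-distorted pyramids (e.g. working-age expat
bulges that depress 60+ shares), institutionalisation rates that vary with
income, within-income-class heterogeneity of care costs, wage distributions
decoupled from GDP (oil economies), and correlated missingness (data gaps
cluster in conflict-affected countries rather than occurring independently).
Results on real inputs depend entirely on the quality of the supplied
schedule, factor and wage tables.

## Numerical choices

* All case counts and costs are double precision throughout; rounding (whole
  USD, 2-decimal percentages, 4-decimal proportions) happens only in
  `build_report()` formatting. This avoids compounding rounding across
  stages, at the cost of report `TOTAL` rows differing from the sum of the
  rounded body cells by up to half a dollar per country.
* A zero population above a threshold yields `NA` prevalence, never 0.
* Thresholds must coincide with band boundaries; a threshold cutting through
  a band is an error, not an interpolation.
* Rankings sort stably with ties broken by country id ascending.
* CSV output is deterministic (fixed column order, countries ascending,
  plain decimal notation, LF endings): write→read→write is byte-stable, which
  the tests check on generated fixtures.
* Errors are typed conditions (`coi_validation_error`, `coi_alignment_error`,
  `coi_imputation_error`, ...) so callers can react to the failure class;
  validation is total — malformed inputs raise, nothing is silently dropped.

## Shipped fixtures

`inst/extdata/` carries small illustrative tables whose filenames mark them
as synthetic: a prevalence schedule, a direct-cost factor table and class
monthly wages. They are stand-ins constructed to be consistent with the few
anchor values this model family quotes (a low-income per-person direct cost
of ≈\$223 on a GDP per capita of \$2,327 fixes the low-income factor at
0.0958; \$22.75/h and \$0.60/h fix the high- and low-class monthly wages
under the default convention). `gdp_income_group_values_2021.csv` carries the
two published 2021 income-group GDP donor values (high: 48,894; low: 2,327).
They are not transcriptions of any authoritative schedule: users analysing
real data must supply their own extracts.

## Workflow and problem sizes

The `analysis/` directory holds the four-stage driver workflow
(`01_simulate.R` → `04_report.R`) over a 22-country synthetic region at seed
2021, writing all tables under `results/`. The test suite runs the full
pipeline on 8–22 country problems across dozens of seeds; these sizes keep
the whole suite in a few seconds while exercising every code path, and
results are size-independent because every operation is exact arithmetic, not
an approximation that improves with n.

## Limitations

This is a prevalence-based COI model: no incidence or projection, no
dementia-subtype split, no discounting, no mortality adjustment, no QALY/DALY
computation, and no currency or inflation adjustment beyond what PPP inputs
already embody. Direct costs inherit the strong assumption that per-person
cost is a fixed fraction of GDP per capita within an income class; indirect
costs price caregiver time at average wages, which overstates opportunity
cost where caregivers are outside the labour force and understates it where
care displaces higher-paid work. The bracketing scenarios are assumptions,
not estimates: the best/worst spread should be read as sensitivity, not a
confidence interval.
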