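# phewasmr

Phenome-wide survival scans and genotype-area Mendelian randomization for
alcohol-disease epidemiology.

Large East Asian biobank studies relate questionnaire-measured alcohol
consumption to hundreds of hospitalized disease outcomes, and corroborate
the observational associations with a genetic instrument built from
*ALDH2*-rs671 and *ADH1B*-rs1229984 — two variants that strongly suppress
drinking in men but are essentially unrelated to drinking in women, making
women a built-in pleiotropy control. The individual-level data behind such
studies are access-controlled, so this package implements the full
analysis pipeline as tested, reusable code and pairs it with a seeded
synthetic-cohort generator that emulates the statistical structure the
analyses assume. It is aimed at epidemiologists and biostatisticians who
want to run, audit or extend this class of analysis.

## What it computes

**Exposure.** Drinker status (non / ex / occasional / current) from
past-year frequency and past weekly drinking; weekly ethanol grams

```
g/week = f × Σ_b (volume_b × vv_b × ρ),   f ∈ {1.5, 4, 6.5} days/week
```

with beverage ethanol fractions (v/v) beer 4%, grape wine 12%, rice wine
15%, weak spirits 38%, strong spirits 53% and ethanol density ρ = 0.79
g/ml; sex-specific intake categories; heavy-episodic (>60 g men / >40 g
women per occasion), daily, outside-meals and spirit-drinking flags; and
the McMahon–Peto regression dilution ratio (RDR) — the slope of
quantile-group mean resurvey intakes on group mean baseline intakes —
used to express dose–response estimates per usual (long-term) intake.

**Endpoints.** ICD-10 three-character codes are curated into endpoints:
those with ≥80 first events among current drinkers are analyzed
individually, the remainder pool into one "less-common" endpoint per
chapter; perinatal and congenital chapters are excluded (pregnancy too, in
men). First-event survival data use age 35–84 as the time scale, with
death treated as censoring (cause-specific hazards).

**Survival.** Cox proportional-hazards models on the age scale with
delayed entry, Lexis-expanded and stratified by 5-year age band × study
area, Efron tie handling, adjusted for education and smoking. Floating
absolute risks give every exposure level (including the occasional-drinker
reference) its own variance λ_k such that
var(logHR_i − logHR_j) ≈ λ_i + λ_j. Dose–response log HRs and standard
errors are divided by the RDR (0.53 under the default generator) and
reported per 280 g/week (men) or 100 g/week (women) higher usual intake.

**Phenome scan.** Both analyses — ever-regular vs occasional drinking, and
dose–response within current drinkers — run across the whole catalog;
Benjamini–Hochberg FDR is controlled within ICD-10 chapters; chapter-wise
significance counts distinguish WHO alcohol-related endpoints (raw
p < 0.05) from others (FDR-adjusted p < 0.05).

**Mendelian randomization.** Mean male intake is computed for the 9
genotype combinations × areas cells (occasional drinkers assigned 5
g/week, ex-drinkers excluded), cells collapse into six ordinal categories
C1–C6 at 10/25/50/100/150 g/week, and every genotyped participant —
women and ex-drinkers included — is assigned by genotype and area alone.
Within each area, a weighted line through the floated category log HRs
against genotype-predicted mean male intake gives a purely genotypic
slope; slopes are combined by inverse-variance-weighted meta-analysis and
reported as an HR per 280 g/week. Sex heterogeneity of the slopes tests
for pleiotropy; a two-stage least-squares fit with bootstrap errors and a
first-stage F statistic is available as a sensitivity analysis.

**Burden.** The mean cumulative count of hospitalization episodes,
MCC(t) = Σ_{u≤t} Ŝ(u⁻) d(u)/n(u), with Kaplan–Meier death-free survival
Ŝ, compares cumulative hospitalizations of ever-regular vs occasional
drinkers without assuming independence of hospitalization and death.

## Worked example

```r
library(phewasmr)

cfg <- sim_config(n_participants = 30000, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic cohort: 30000 participants, 4260 hospitalization events

exposure <- derive_exposure(cohort$participants)
round(100 * prop.table(table(exposure$status[exposure$sex == "M"])), 1)
#>    current         ex        non occasional
#>       32.9        8.9       19.7       38.6
mean(exposure$gpw[exposure$sex == "M" & exposure$status == "current"])
#> 287 g/week

# conventional dose-response, corrected to usual intake via the RDR
fit <- endpoint_dose_response(cohort$participants, cohort$events, exposure,
                              codes = c("K70", "K74"), sex = "M",
                              rdr = 0.53)
#> liver cirrhosis, HR per 280 g/week usual intake:
#> 2.05 (95% CI 1.25-3.36, 25 events)

# genotype-area instrument and area-stratified IVW slope
inst <- derive_genetic_instrument(cohort$participants, exposure)
men <- cohort$participants[cohort$participants$sex == "M", ]
sv <- extract_first_events(cohort$events, unique(cohort$events$code), men)
area_stratified_ivw_slope(sv, inst, men)
#> Genotypic slope: HR 1.104 (95% CI 0.876-1.392) per 280 g/week, p = 0.401
#>   IVW of 10 area slopes
```

The cirrhosis estimate recovers the generator's planted effect (true HR
2.3 per 280 g/week) within its confidence interval; at n = 30,000 the
genetic slope on all-cause morbidity is directionally right but
underpowered — the acceptance script below runs the properly sized
versions.

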