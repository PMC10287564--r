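---
title: "Methods: phenome-wide alcohol scans and genotype-area Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide alcohol scans and genotype-area Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phewasmr)
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, the synthetic cohorts they are
validated on, and the design choices made where the methodology left the
design genuinely open.

## The analysis problem

Cohorts recruited across heterogeneous regions, with questionnaire-based
alcohol assessment, hospital-registry follow-up coded in ICD-10, and
genotypes at two alcohol-metabolism loci (an *ALDH2*-like locus whose A
allele strongly suppresses drinking, and an *ADH1B*-like locus with a
weaker effect), support three complementary views of alcohol-disease
relations:

1. **Conventional observational analyses** — ever-regular vs occasional
   drinking, and dose-response within current drinkers — across every
   disease endpoint with enough cases ("phenome-wide").
2. **Genetic (Mendelian randomization) analyses**, replacing self-reported
   intake with genotype-predicted mean male intake, which is immune to
   reverse causation and to confounding by behaviour.
3. **Burden analyses** of recurrent hospitalizations under competing
   mortality.

Occasional drinkers are the reference group throughout: non-drinkers and
ex-drinkers include people who abstain or quit *because* they are ill
(the sick-quitter problem), so comparing against them biases alcohol
effects upward at the low end.

## Survival machinery

All hazard ratios come from Cox proportional-hazards models on the
**age** time scale with delayed entry at `max(baseline age, 35)` and exit
at the first event, death, loss to follow-up or age 85. `lexis_expand()`
splits follow-up at 5-year age boundaries and the model is stratified by
age band × study area, so each stratum has its own baseline hazard;
education and smoking enter as adjustment covariates in the conventional
arm, genomic principal-component surrogates in the genetic arm. Ties use
the Efron approximation, which is less biased than Breslow under the
heavy tying of hospital data (the record-duplication invariance that
holds exactly under Breslow is checked in the tests under both
conventions). Fitting is delegated to `survival::coxph` (score tolerance
1e-10, up to 100 Newton-Raphson iterations); its `timefix` tie-rounding
is disabled because event ages here are genuinely continuous and a Lexis
slice may legitimately be shorter than its tolerance. The test suite
verifies the fitted coefficients against a hand-written Efron partial
likelihood maximized by brute force, to 1e-6, on tied tiny datasets.

Deaths censor disease endpoints (cause-specific hazards). No Fine-Gray
subdistribution option is provided: the cause-specific contract is what
the downstream meta-analytic steps assume.

## Floating absolute risks

Plotting category-specific hazard ratios requires a confidence interval
for every category *including the reference*. `float_absolute_risks()`
attributes a variance λ_k to each level so that
`var(logHR_i − logHR_j) ≈ λ_i + λ_j` for every pair. The default is the
heterogeneity method: λ_0 (reference) is the mean off-diagonal covariance
of the fitted contrasts and λ_i = V_ii − λ_0. For Cox category fits the
off-diagonals are nearly equal (they share the reference's information)
and the reconstruction error is small; the acceptance suite requires all
pairwise reconstructions within 10% on six-level fits. When the closed
form produces a non-positive variance, an iterative minimax fit (Nelder-
Mead on log-variances, minimizing the maximum relative reconstruction
error) takes over; with a diagonal covariance the closed form is already
exact (λ_0 = 0). With a single non-reference level the method is
degenerate and the variance is split proportionally to level event
counts, which reduces to the symmetric half-split for balanced groups.

## Usual intake and regression dilution

A single baseline intake report is a noisy snapshot of long-term (usual)
intake, so a Cox coefficient on baseline intake is attenuated. The
McMahon-Peto correction divides the log HR and its standard error by the
regression dilution ratio (RDR): participants with a resurvey measurement
are grouped into baseline-intake quintiles, and the RDR is the slope of
group-mean resurvey intake on group-mean baseline intake (size-weighted;
quintiles are the method's convention, configurable via `n_groups`). The
estimator is scale-invariant and exact under noise-free linear shrinkage.
Bootstrap over participants supplies its CI.

The correction is valid when `E[usual | baseline]` is linear with slope
equal to the RDR. The synthetic generator therefore *defines* usual
intake by that structural assumption: `U = r·X_b + (1−r)·m_g`, where
`X_b` is the reported baseline intake, `r` the configured RDR target
(default 0.53) and `m_g` the mean baseline intake of the participant's
sex-genotype group; resurvey reports are `U` times mean-one log-normal
noise (CV 0.35 per report). An earlier design with multiplicative noise
around a latent log-normal usual intake was abandoned: it makes
`E[usual | baseline]` a power function, so the grouped estimator, the
cov/var attenuation factor and the correction cannot agree — no noise
variance reconciles them. Under the structural definition the grouped
estimator, the Cox attenuation and the correction coincide by
construction, which is exactly the situation the correction method
presumes of real data.

## The phenome scan

Each endpoint is tested twice (ever-regular vs occasional; dose-response
per 280 g/week usual intake in men, 100 g/week in women, within current
drinkers). The Wald p-value of the dose-response test is computed on the
uncorrected scale and is invariant to the RDR division. Within each
ICD-10 chapter and analysis, Benjamini-Hochberg adjustment controls the
FDR; the family is per analysis because the two analyses answer different
questions (whether pooling both into one chapter family is intended is
not documented for this design; the per-analysis choice is the
conservative reading and is configurable by adjusting the returned raw
p-values). Significance classes follow the reporting convention:
WHO-alcohol-related endpoints use raw p < 0.05 (hypothesis tests of prior
claims), all others need FDR-adjusted p < 0.05 (discovery claims).
Endpoints whose fit fails are reported as `NA`, never dropped silently.
Chapter summaries count an endpoint once when significant in either
analysis, flagging direction conflicts instead of resolving them.

`estimate_detection_power()` is the Monte-Carlo power utility behind the
≥80-case curation rule: it calibrates a constant baseline hazard to a
target expected case count (on a fixed 100,000-draw reference sample of
the intake distribution, so the calibration is deterministic given the
seed) and reports the rejection rate of the dose-response Wald test.
Scenario comparisons share random numbers through the seed so power is
monotone in case count replicate by replicate.

## The genotype-area instrument

Mean male intake per genotype-combination × area cell uses current
drinkers at reported g/week, occasional drinkers at an assigned 5 g/week
and non-drinkers at 0; ex-drinkers are excluded from the means because
their baseline report (zero) does not reflect the long-term intake their
genotype produced — but they are assigned to a category like everyone
else, since assignment depends only on genotype and area. Non-drinkers
contribute 0 rather than being excluded: their long-term intake genuinely
is about zero. Cells collapse into C1-C6 at cutoffs 10/25/50/100/150
g/week, read as left-closed intervals (a cell mean of exactly 10 g/week
is C2; 150 is C6). Cells empty in a given cohort borrow the all-area mean
of the same genotype combination, then of the same locus-1 genotype —
a pooling rule chosen here (none is documented for the original design)
and logged on the instrument object.

Because drinking prevalence varies strongly by region and allele
frequencies follow a geographic gradient, category membership is
confounded with area. The causal contrast is therefore estimated within
areas: floated category log HRs are regressed on genotype-predicted mean
male intake (categories present in that area only; weights = inverse
floated variances; free intercept, so the choice of within-area reference
category cancels), and the per-area slopes are combined by
inverse-variance-weighted meta-analysis. The per-category x-coordinates
are fixed at instrument derivation (male-weighted mean of cell means), so
female and single-area analyses regress on the same male intake scale.
Correlation between category estimates is ignored at the meta-regression
stage — the floating procedure is designed to make that approximation
accurate. A deliberately unstratified variant (one pooled fit ignoring
area) is provided to demonstrate the confounding, and an age×area-
stratified pooled fit as the "area-adjusted" sensitivity analysis.

Women are assigned by the *male* cell means and their category log HRs
are regressed on the same male intake scale: since women barely drink in
any genotype group, a nonzero female slope indicates pleiotropy rather
than alcohol effects. `sex_heterogeneity_test()` compares the male and
female slopes by a 1-df chi-squared.

`two_stage_least_squares()` is the IV sensitivity analysis: a linear
first stage of numeric intake (same 5/0 conventions, ex-drinkers excluded
from fitting) on category indicators plus area and PCs, then a Cox fit on
the predicted intake, with participant-bootstrap standard errors and the
first-stage partial F reported (a warning below F = 10). Deriving the
instrument and testing it on the same individuals is slightly circular —
cell-mean noise correlates in-sample with intake — which is why the
derivation accepts an explicit male random subset; the irrelevant-
instrument test in the suite derives cells on one half and analyzes the
other.

## Hospitalization burden

`mean_cumulative_count()` implements
`MCC(t) = Σ_{u≤t} Ŝ(u⁻)·d(u)/n(u)` with Ŝ the Kaplan-Meier estimator of
death-free survival, d(u) the episodes at age u and n(u) the number
entered, alive and uncensored just before u. Delayed entry is honoured.
An episode tied with a death at the same age is counted before the death
is processed (the hospitalization that ends in death should count).
Curves are reported on a 1-year grid over ages 35-84, unstandardized;
standardization hooks are a matter of subsetting the inputs. Without
mortality the curve reduces to the cumulative episode count over n, and
the tests pin the estimator to a hand-computed three-person oracle.

## The synthetic cohort generator

The generator is first-class, tested code: every downstream property
claim in the test suite is a statement about what the pipeline recovers
from cohorts with known structure. Its defaults are the study conditions:

* ten areas, equal size in expectation; A-allele frequencies on a linear
  north-south gradient (±0.08) around overall means 0.21 (locus 1) and
  0.69 (locus 2); genotypes in Hardy-Weinberg proportions within areas
  (pooled frequencies deviate by design — that *is* population
  structure); 11 genomic-PC surrogates built from area loadings plus
  unit noise.
* baseline age truncated-normal (mean 52, sd 10.5, range 35-74); 41%
  men; 12 years of follow-up; independent competing mortality at 0.010
  per person-year (about 11% deaths over follow-up).
* regular drinking by a per-sex logistic model in A-allele doses
  (log-odds −1.60/−0.35 per allele in men, −0.30/−0.10 in women), with
  the intercept calibrated numerically so current-drinker prevalence hits
  33% in men and 2% in women; 21.4% of would-be ever-regular men (33.3%
  of women) are reclassified ex-drinkers, so ex-drinkers inherit the
  genotype dependence; a configurable sick-quitter log-rate shift for
  ex-drinkers defaults to 0 so that null-effect calibration tests are
  meaningful.
* baseline intake among current drinkers log-normal (sd 0.9 on the log
  scale, genotype shifts −0.40/−0.15 per allele in men), capped at 1,500
  g/week — a questionnaire-realism bound without which the log-normal
  tail at n = 50,000 produces intakes whose log-linear hazard multipliers
  are astronomically large — with the mean calibrated on the truncated
  scale to 286 g/week in men and 116 in women. These choices reproduce
  the observed male category distribution (roughly 36/28/17/19% across
  <140/140-279/280-419/420+) and, with daily-drinking frequency at 62%,
  heavy-episodic drinking near 36%.
* questionnaire fields are back-constructed from the drawn baseline
  intake (frequency category, one dominant beverage with spirit-heavy
  mix, typical-day volume, per-occasion grams), so the exposure module's
  grams formula recovers the generator's intake exactly — making the
  exposure derivation testable bit-for-bit.
* usual intake follows the structural shrinkage model of the regression-
  dilution section; a 5% random subset attends resurveys (half of them
  twice). Occasional drinkers carry 5 g/week of usual intake, matching
  the instrument convention.
* each configured endpoint generates hospitalization episodes from a
  Poisson process with rate `rate × exp(β·U/280 + c·z_area)`, truncated
  at death/censoring; `c` (default 0) plants area-level confounding
  aligned with the allele-frequency gradient for the MR robustness
  scenario. The default endpoint table spans nine chapters with effect
  sizes echoing reported magnitudes (cirrhosis HR 2.3, gout 1.57,
  stroke 1.38, cataract 1.21 per 280 g/week) plus null endpoints.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: reporting biases
(under-reporting of heavy drinking), time-varying drinking trajectories,
dependence between mortality and endpoint hazards, within-chapter
correlation of endpoint events beyond shared exposure, calendar effects,
loss to follow-up (<1% in the motivating setting, omitted), genuine
genotype-area interaction in drinking norms, and any gene-environment
interaction in disease risk.

### Scenario definitions used by the acceptance suite

The parameter-recovery studies fix their scenarios once. The
conventional arm uses n = 50,000 cohorts, one planted endpoint (HR 1.5
per 280 g/week, baseline rate 8e-3 per person-year, about a thousand
drinker events per cohort) and corrects by the configured RDR 0.53 — the
constant-divisor usage the correction method prescribes; the estimator
itself is validated separately at 5,000 resurveyed participants. The MR
arm uses n = 40,000 cohorts with area confounding 0.3, no ex-drinkers
and no female genotype-intake path: the first makes the instrument's
cell means equal the mean usual intake of every man in a cell (with
ex-drinkers, whose usual intake is 0 but who are excluded from cell
means, the genetic slope estimand is attenuated by roughly the
ex-drinker share — a real feature of the design, not an estimator
defect), and the second is the definition of the pleiotropy-free null
that the female calibration test is about.

## Numerical choices

* Logistic intercepts and truncated-lognormal means: `uniroot` to 1e-10.
* Cox: Newton-Raphson via `survival::coxph`, score tolerance 1e-10.
* Floating variances: closed form, else Nelder-Mead minimax to reltol
  1e-12; positivity enforced on the log scale.
* BH adjustment: `stats::p.adjust(method = "BH")` per chapter; an
  independent brute-force implementation lives in the tests.
* Intake category and instrument cutoffs: left-closed upward intervals
  everywhere, so boundary values promote.
* Cohort serialization: doubles at 17 significant digits for exact
  round trips; YAML configs at precision 17 with named vectors as maps.
* Problem sizes in the test suite (50,000/40,000-participant recovery
  studies at 100 replicates; 15,000-participant null scans; 37,000 for
  the RDR study) were chosen as the smallest sizes at which the
  quantities under test are decisively powered.

## Known limitations

* The shipped endpoint catalog covers the named endpoints and common
  controls, not an exhaustive ICD-10 partition; unlisted codes fall into
  less-common pools, and the CSV is user-editable.
* Floating absolute risks assume near-homogeneous off-diagonal
  covariances; pathological covariance structures fall back to a minimax
  fit whose error is reported, not hidden.
* The 2SLS stage-2 is a Cox fit on predicted intake ("two-stage
  predictor substitution"); with non-rare events its estimand differs
  slightly from the ratio estimator, which is why it is a sensitivity
  check rather than the primary MR estimate.
* No spline dose-response shapes: category-level HRs against usual
  intake are the unit of reporting, matching the floated-risk framework.
* Calendar time is not modelled; baseline date-to-age conversion is
  implicit in the age-based follow-up bounds.
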