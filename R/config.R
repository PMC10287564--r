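#' Drinking-behaviour model parameters
#'
#' Parameters of the genotype- and sex-dependent drinking model used by
#' [simulate_cohort()]. Regular (at-least-weekly) drinking follows a logistic
#' model in the number of A alleles at the two loci; the intercept is
#' calibrated at simulation time so that the population fraction of current
#' drinkers hits `current_target` for each sex. Intake among current drinkers
#' is log-normal with a genotype-shifted mean, calibrated so the marginal
#' mean among current drinkers equals `mean_intake`.
#'
#' @param current_target named fractions of current (at-least-weekly)
#'   drinkers, by sex.
#' @param ex_fraction fraction of would-be ever-regular drinkers reclassified
#'   as ex-drinkers, by sex.
#' @param occasional_share among never-regular participants, share classified
#'   occasional (the rest are non-drinkers), by sex.
#' @param geno_logodds per-A-allele log-odds shifts for ever-regular drinking,
#'   `locus1`/`locus2` within `male`/`female`. Locus 1 (ALDH2-like) carries
#'   the dominant suppression.
#' @param mean_intake target mean baseline intake among current drinkers
#'   (g/week), by sex.
#' @param sdlog log-scale standard deviation of intake among current drinkers.
#' @param geno_meanlog_shift per-A-allele shifts of the intake mean on the
#'   log scale, by locus and sex.
#' @param max_gpw cap on reported weekly intake (g/week); questionnaire
#'   reports above it are truncated to it.
#' @param freq_probs probabilities of the three weekly frequency categories
#'   (1-2, 3-5, 6-7 days/week) among current drinkers.
#' @param beverage_probs probabilities that a current drinker's dominant
#'   beverage is beer, grape wine, rice wine, weak spirits, strong spirits.
#' @param sick_quitter_lograte additive log-rate morbidity shift applied to
#'   ex-drinkers in the event generator (0 disables sick-quitter structure).
#' @return a list of class `drinking_model`.
#' @export
drinking_model <- function(current_target = c(male = 0.33, female = 0.02),
                           ex_fraction = c(male = 0.214, female = 0.333),
                           occasional_share = c(male = 0.655, female = 0.340),
                           geno_logodds = list(
                             male = c(locus1 = -1.60, locus2 = -0.35),
                             female = c(locus1 = -0.30, locus2 = -0.10)
                           ),
                           mean_intake = c(male = 286, female = 116),
                           sdlog = 0.9,
                           max_gpw = 1500,
                           geno_meanlog_shift = list(
                             male = c(locus1 = -0.40, locus2 = -0.15),
                             female = c(locus1 = -0.05, locus2 = -0.02)
                           ),
                           freq_probs = c(weekly_1_2 = 0.18,
                                          weekly_3_5 = 0.20,
                                          weekly_6_7 = 0.62),
                           beverage_probs = c(beer = 0.15, grape_wine = 0.05,
                                              rice_wine = 0.05,
                                              weak_spirits = 0.15,
                                              strong_spirits = 0.60),
                           sick_quitter_lograte = 0) {
  stopifnot(all(current_target >= 0 & current_target <= 1),
            all(ex_fraction >= 0 & ex_fraction < 1),
            all(occasional_share >= 0 & occasional_share <= 1),
            all(mean_intake > 0), sdlog >= 0, max_gpw > 0)
  structure(list(current_target = current_target,
                 ex_fraction = ex_fraction,
                 occasional_share = occasional_share,
                 geno_logodds = geno_logodds,
                 mean_intake = mean_intake,
                 sdlog = sdlog,
                 max_gpw = max_gpw,
                 geno_meanlog_shift = geno_meanlog_shift,
                 freq_probs = freq_probs / sum(freq_probs),
                 beverage_probs = beverage_probs / sum(beverage_probs),
                 sick_quitter_lograte = sick_quitter_lograte),
            class = "drinking_model")
}

#' Within-person measurement model
#'
#' The generator treats the reported baseline intake as a snapshot around
#' the usual (long-term) intake: usual intake is the component of the
#' baseline report that persists at remeasurement,
#' `U = rdr * baseline + (1 - rdr) * m_g` with `m_g` the mean baseline
#' intake of the participant's sex-genotype group — i.e. the conditional
#' mean of usual intake given a baseline report is linear with slope
#' `rdr_target`, which is exactly the structural assumption of the grouped
#' repeat-measurement (McMahon-Peto) correction. Resurvey reports are
#' `U` times independent mean-one log-normal noise with coefficient of
#' variation `resurvey_cv`. With `rdr_target = 1` and `resurvey_cv = 0`
#' there is no within-person variation and the estimated regression
#' dilution ratio is 1.
#'
#' @param rdr_target regression dilution ratio in (0, 1].
#' @param resurvey_cv coefficient of variation of a single resurvey report
#'   around usual intake.
#' @return a list of class `measurement_model`.
#' @export
measurement_model <- function(rdr_target = 0.53, resurvey_cv = 0.35) {
  stopifnot(rdr_target > 0, rdr_target <= 1, resurvey_cv >= 0)
  structure(list(rdr_target = rdr_target, resurvey_cv = resurvey_cv),
            class = "measurement_model")
}

#' Default endpoint effects for the synthetic cohort
#'
#' A handful of ICD-10 endpoints spanning several chapters, with true log
#' hazard ratios per 280 g/week usual intake echoing the magnitudes reported
#' for alcohol-associated diseases in large Chinese cohort data, plus null
#' endpoints for calibration. `rate` is the baseline event (hospitalization
#' episode) rate per person-year at zero usual intake.
#'
#' @return data.frame with columns `id`, `label`, `codes` (semicolon
#'   separated three-character ICD-10 codes), `chapter`, `who_flag`,
#'   `loghr_per_280`, `rate`.
#' @export
default_endpoint_effects <- function() {
  df <- data.frame(
    id = c("tuberculosis", "oesophageal_cancer", "diabetes", "cataract",
           "hypertension", "ischaemic_stroke", "pneumonia", "liver_cirrhosis",
           "gerd", "gout", "renal_colic", "abdominal_pain", "femur_fracture"),
    label = c("Tuberculosis", "Oesophageal cancer", "Diabetes mellitus",
              "Cataract", "Essential hypertension", "Ischaemic stroke",
              "Pneumonia", "Liver cirrhosis", "Gastro-oesophageal reflux",
              "Gout", "Renal colic", "Abdominal and pelvic pain",
              "Fracture of femur"),
    codes = c("A15;A16", "C15", "E11", "H25;H26", "I10", "I63", "J18",
              "K70;K74", "K21", "M10", "N20", "R10", "S72"),
    who_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE),
    loghr_per_280 = c(log(1.3), log(1.97), log(1.2), log(1.21), log(1.2),
                      log(1.38), log(1.12), log(2.3), log(1.2), log(1.57),
                      0, 0, log(1.4)),
    rate = c(4e-4, 3e-4, 1.5e-3, 1.2e-3, 2.5e-3, 1.5e-3, 1.2e-3, 3e-4,
             6e-4, 2.5e-4, 8e-4, 1.5e-3, 4e-4),
    stringsAsFactors = FALSE
  )
  df$chapter <- icd10_chapter(vapply(strsplit(df$codes, ";"), `[`, "", 1L))
  df[, c("id", "label", "codes", "chapter", "who_flag",
         "loghr_per_280", "rate")]
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' emulate the statistical structure of a large two-variant-genotyped Chinese
#' biobank: ten areas with a linear north-south allele-frequency gradient
#' around overall A-allele frequencies of 0.21 (ALDH2-like locus 1) and 0.69
#' (ADH1B-like locus 2); roughly 33% male and 2% female current drinkers with
#' male mean intake 286 g/week; within-person intake variation targeting a
#' regression dilution ratio of 0.53; a ~5% resurvey subset; 12 years of
#' follow-up with competing mortality.
#'
#' @param n_participants cohort size.
#' @param prop_male fraction male.
#' @param n_areas number of study areas.
#' @param allele_freq_locus1,allele_freq_locus2 per-area A-allele
#'   frequencies; defaults are linear gradients with overall means 0.21 and
#'   0.69.
#' @param drinking a [drinking_model()].
#' @param measurement a [measurement_model()].
#' @param endpoints endpoint effect table as from
#'   [default_endpoint_effects()].
#' @param mortality_hazard constant all-cause death hazard per person-year.
#' @param followup_years administrative censoring horizon after baseline.
#' @param baseline_age_mean,baseline_age_sd,baseline_age_range parameters of
#'   the truncated-normal baseline age distribution.
#' @param resurvey_fraction fraction of participants invited to resurveys.
#' @param area_confounding per-area log-hazard shift applied as
#'   `area_confounding * z_area` where `z_area` is the standardized area
#'   index; nonzero values plant population-structure confounding aligned
#'   with the allele-frequency gradient.
#' @param n_pcs number of genomic principal-component surrogates.
#' @param seed integer seed; identical configs and seeds give identical
#'   cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10000,
                       prop_male = 0.41,
                       n_areas = 10,
                       allele_freq_locus1 = NULL,
                       allele_freq_locus2 = NULL,
                       drinking = drinking_model(),
                       measurement = measurement_model(),
                       endpoints = default_endpoint_effects(),
                       mortality_hazard = 0.010,
                       followup_years = 12,
                       baseline_age_mean = 52,
                       baseline_age_sd = 10.5,
                       baseline_age_range = c(35, 74),
                       resurvey_fraction = 0.05,
                       area_confounding = 0,
                       n_pcs = 11,
                       seed = 1L) {
  if (is.null(allele_freq_locus1))
    allele_freq_locus1 <- gradient_freqs(0.21, n_areas)
  if (is.null(allele_freq_locus2))
    allele_freq_locus2 <- gradient_freqs(0.69, n_areas)
  if (any(allele_freq_locus1 < 0 | allele_freq_locus1 > 1) ||
      any(allele_freq_locus2 < 0 | allele_freq_locus2 > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (length(allele_freq_locus1) != n_areas ||
      length(allele_freq_locus2) != n_areas)
    stop("one allele frequency per area is required")
  stopifnot(n_participants >= 1, prop_male >= 0, prop_male <= 1,
            mortality_hazard > 0, followup_years > 0,
            all(endpoints$rate > 0),
            resurvey_fraction >= 0, resurvey_fraction <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 prop_male = prop_male,
                 n_areas = as.integer(n_areas),
                 allele_freq_locus1 = allele_freq_locus1,
                 allele_freq_locus2 = allele_freq_locus2,
                 drinking = drinking,
                 measurement = measurement,
                 endpoints = endpoints,
                 mortality_hazard = mortality_hazard,
                 followup_years = followup_years,
                 baseline_age_mean = baseline_age_mean,
                 baseline_age_sd = baseline_age_sd,
                 baseline_age_range = baseline_age_range,
                 resurvey_fraction = resurvey_fraction,
                 area_confounding = area_confounding,
                 n_pcs = as.integer(n_pcs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# linear "north-south" gradient of area allele frequencies around a mean
gradient_freqs <- function(mean_freq, n_areas, half_spread = 0.08) {
  if (n_areas == 1) return(mean_freq)
  f <- mean_freq + seq(-half_spread, half_spread, length.out = n_areas)
  pmin(pmax(f, 0), 1)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d (%.0f%% male), areas: %d, seed: %d\n",
              x$n_participants, 100 * x$prop_male, x$n_areas, x$seed))
  cat(sprintf("  A-allele freq locus1: %.3f-%.3f (mean %.3f)\n",
              min(x$allele_freq_locus1), max(x$allele_freq_locus1),
              mean(x$allele_freq_locus1)))
  cat(sprintf("  A-allele freq locus2: %.3f-%.3f (mean %.3f)\n",
              min(x$allele_freq_locus2), max(x$allele_freq_locus2),
              mean(x$allele_freq_locus2)))
  cat(sprintf("  current drinkers target: %.0f%% men / %.0f%% women; male mean intake %g g/week\n",
              100 * x$drinking$current_target[["male"]],
              100 * x$drinking$current_target[["female"]],
              x$drinking$mean_intake[["male"]]))
  cat(sprintf("  measurement RDR target: %.2f; resurvey fraction: %.2f\n",
              x$measurement$rdr_target, x$resurvey_fraction))
  cat(sprintf("  mortality hazard: %g /yr; follow-up: %g yr; area confounding: %g\n",
              x$mortality_hazard, x$followup_years, x$area_confounding))
  cat(sprintf("  endpoints: %d (%d with nonzero effect)\n",
              nrow(x$endpoints), sum(x$endpoints$loghr_per_280 != 0)))
  invisible(x)
}

#' Write or read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  # yaml serializes named atomic vectors as plain sequences; converting
  # them to lists keeps the names as map keys
  keep_names <- function(v) {
    if (is.list(v)) lapply(v, keep_names)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else v
  }
  x <- unclass(config)
  x$drinking <- keep_names(unclass(x$drinking))
  x$measurement <- unclass(x$measurement)
  x$endpoints <- as.list(x$endpoints)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  ep <- as.data.frame(x$endpoints, stringsAsFactors = FALSE)
  dm <- x$drinking
  drink <- drinking_model(
    current_target = unlist(dm$current_target),
    ex_fraction = unlist(dm$ex_fraction),
    occasional_share = unlist(dm$occasional_share),
    geno_logodds = lapply(dm$geno_logodds, unlist),
    mean_intake = unlist(dm$mean_intake),
    sdlog = dm$sdlog,
    max_gpw = dm$max_gpw,
    geno_meanlog_shift = lapply(dm$geno_meanlog_shift, unlist),
    freq_probs = unlist(dm$freq_probs),
    beverage_probs = unlist(dm$beverage_probs),
    sick_quitter_lograte = dm$sick_quitter_lograte
  )
  sim_config(n_participants = x$n_participants,
             prop_male = x$prop_male,
             n_areas = x$n_areas,
             allele_freq_locus1 = unlist(x$allele_freq_locus1),
             allele_freq_locus2 = unlist(x$allele_freq_locus2),
             drinking = drink,
             measurement = measurement_model(x$measurement$rdr_target,
                                    x$measurement$resurvey_cv),
             endpoints = ep,
             mortality_hazard = x$mortality_hazard,
             followup_years = x$followup_years,
             baseline_age_mean = x$baseline_age_mean,
             baseline_age_sd = x$baseline_age_sd,
             baseline_age_range = unlist(x$baseline_age_range),
             resurvey_fraction = x$resurvey_fraction,
             area_confounding = x$area_confounding,
             n_pcs = x$n_pcs,
             seed = x$seed)
}
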