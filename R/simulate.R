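# Synthetic cohort generator.
#
# The generator draws, in order: area/sex/age/covariates + two-locus
# genotypes in per-area Hardy-Weinberg proportions + genomic-PC surrogates;
# genotype- and sex-dependent drinking behaviour expressed as questionnaire
# fields; and multi-endpoint hospitalization histories with log-linear
# usual-intake effects and independent competing mortality. All randomness
# flows from the single seed in the configuration.

ETHANOL_DENSITY <- 0.79 # g/ml, ethanol mass density used to convert ml to g

FREQ_LEVELS <- c("never", "occasional", "certain_seasons", "monthly",
                 "weekly_1_2", "weekly_3_5", "weekly_6_7")
BEVERAGES <- c("beer", "grape_wine", "rice_wine", "weak_spirits",
               "strong_spirits")
BEVERAGE_VV <- c(beer = 0.04, grape_wine = 0.12, rice_wine = 0.15,
                 weak_spirits = 0.38, strong_spirits = 0.53)
FREQ_DAYS <- c(weekly_1_2 = 1.5, weekly_3_5 = 4, weekly_6_7 = 6.5)

geno_label <- function(dose) c("GG", "AG", "AA")[dose + 1L]
geno_dose <- function(label) match(label, c("GG", "AG", "AA")) - 1L

# joint distribution of (dose1, dose2) across areas under HWE, as a
# data.frame of weights; areas are equally sized in expectation
genotype_weights <- function(config) {
  grid <- expand.grid(area = seq_len(config$n_areas), d1 = 0:2, d2 = 0:2)
  f1 <- config$allele_freq_locus1[grid$area]
  f2 <- config$allele_freq_locus2[grid$area]
  grid$w <- stats::dbinom(grid$d1, 2, f1) * stats::dbinom(grid$d2, 2, f2) /
    config$n_areas
  grid
}

# intercept alpha such that sum_g w_g plogis(alpha + off_g) = target
calibrate_logit_intercept <- function(target, offsets, weights) {
  if (target <= 0) return(-Inf)
  f <- function(a) sum(weights * stats::plogis(a + offsets)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# mean of min(X, cap) for X ~ lognormal(meanlog, sdlog)
trunc_lnorm_mean <- function(meanlog, sdlog, cap) {
  if (sdlog == 0) return(pmin(exp(meanlog), cap))
  lc <- log(cap)
  exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((lc - meanlog - sdlog^2) / sdlog) +
    cap * stats::pnorm((lc - meanlog) / sdlog, lower.tail = FALSE)
}

# sex-specific calibration of the drinking model against the configured
# marginal targets: logistic intercept for ever-regular drinking and the
# log-normal meanlog intercept such that the capped baseline intake has the
# configured mean among current drinkers
calibrate_drinking <- function(config, sex = c("male", "female")) {
  sex <- match.arg(sex)
  dm <- config$drinking
  gw <- genotype_weights(config)
  b <- dm$geno_logodds[[sex]]
  off <- b[["locus1"]] * gw$d1 + b[["locus2"]] * gw$d2
  ever_target <- dm$current_target[[sex]] / (1 - dm$ex_fraction[[sex]])
  if (ever_target > 1)
    stop("current-drinker target incompatible with ex-drinker fraction")
  alpha <- calibrate_logit_intercept(ever_target, off, gw$w)
  # genotype mixture among current drinkers (proportional to ever-regular)
  wc <- gw$w * stats::plogis(alpha + off)
  wc <- wc / sum(wc)
  s <- dm$geno_meanlog_shift[[sex]]
  shift <- s[["locus1"]] * gw$d1 + s[["locus2"]] * gw$d2
  f <- function(mu0)
    sum(wc * trunc_lnorm_mean(mu0 + shift, dm$sdlog, dm$max_gpw)) -
    dm$mean_intake[[sex]]
  mu0 <- stats::uniroot(f, c(-5, 20), tol = 1e-10)$root
  list(alpha = alpha, mu0 = mu0)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate genotypes, demographics and PC surrogates
#'
#' Draws the cohort "base" frame: sex, study area, baseline age, adjustment
#' covariates, two-locus genotypes in per-area Hardy-Weinberg proportions,
#' and genomic principal-component surrogates encoding area structure plus
#' noise. Uses the current RNG state; [simulate_cohort()] seeds it from the
#' configuration.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per participant.
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_participants
  area <- sample.int(config$n_areas, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
  age <- rtruncnorm(n, config$baseline_age_mean, config$baseline_age_sd,
                    config$baseline_age_range[1], config$baseline_age_range[2])
  d1 <- stats::rbinom(n, 2, config$allele_freq_locus1[area])
  d2 <- stats::rbinom(n, 2, config$allele_freq_locus2[area])
  education <- sample.int(4L, n, replace = TRUE,
                          prob = c(0.10, 0.32, 0.45, 0.13))
  smoking <- integer(n)
  m <- sex == "M"
  smoking[m] <- sample.int(6L, sum(m), replace = TRUE,
                           prob = c(0.32, 0.07, 0.10, 0.17, 0.24, 0.10))
  smoking[!m] <- sample.int(4L, sum(!m), replace = TRUE,
                            prob = c(0.92, 0.03, 0.02, 0.03))
  income <- sample.int(4L, n, replace = TRUE, prob = c(0.25, 0.30, 0.25, 0.20))
  fruit <- sample.int(2L, n, replace = TRUE, prob = c(0.25, 0.75))
  met <- pmax(stats::rnorm(n, 22, 15), 0.5)
  bmi <- stats::rnorm(n, 23.4, 3.2)
  base <- data.frame(id = seq_len(n), sex = sex, area = area,
                     age_baseline = age, education = education,
                     smoking = smoking, income = income, fruit = fruit,
                     met = met, bmi = bmi,
                     g1 = geno_label(d1), g2 = geno_label(d2),
                     stringsAsFactors = FALSE)
  loadings <- matrix(stats::rnorm(config$n_areas * config$n_pcs),
                     config$n_areas, config$n_pcs)
  pcs <- loadings[area, , drop = FALSE] +
    matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
  cbind(base, as.data.frame(pcs))
}

#' Simulate questionnaire drinking behaviour
#'
#' Adds genotype- and sex-dependent drinking fields to a base frame from
#' [simulate_genotypes()]: frequency category, past-weekly flag, typical-day
#' beverage volumes, per-occasion grams, mealtime habit, ages started and
#' stopped, resurvey intake measurements and the latent usual intake
#' (`usual_gpw`, the generator's ground truth) used by the event model.
#' Records with missing genotypes are flagged (`geno_missing`) and sampled
#' from the genotype-free marginal model.
#'
#' @param base data.frame from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return `base` with drinking columns appended.
#' @export
simulate_drinking_behaviour <- function(base, config) {
  n <- nrow(base)
  dm <- config$drinking
  d1 <- geno_dose(base$g1)
  d2 <- geno_dose(base$g2)
  miss <- is.na(d1) | is.na(d2)
  d1[miss] <- 0L
  d2[miss] <- 0L
  male <- base$sex == "M"

  cal <- list(male = calibrate_drinking(config, "male"),
              female = calibrate_drinking(config, "female"))
  rdr <- config$measurement$rdr_target
  rs_sdlog <- sqrt(log1p(config$measurement$resurvey_cv^2))

  p_ever <- numeric(n)
  meanlog <- numeric(n)
  for (sx in c("male", "female")) {
    idx <- if (sx == "male") male else !male
    b <- dm$geno_logodds[[sx]]
    s <- dm$geno_meanlog_shift[[sx]]
    off <- b[["locus1"]] * d1[idx] + b[["locus2"]] * d2[idx]
    shift <- s[["locus1"]] * d1[idx] + s[["locus2"]] * d2[idx]
    if (any(miss[idx])) { # marginal model for unflagged genotype effects
      off[miss[idx]] <- 0
      shift[miss[idx]] <- 0
    }
    p_ever[idx] <- stats::plogis(cal[[sx]]$alpha + off)
    meanlog[idx] <- cal[[sx]]$mu0 + shift
  }
  ex_frac <- ifelse(male, dm$ex_fraction[["male"]], dm$ex_fraction[["female"]])
  occ_share <- ifelse(male, dm$occasional_share[["male"]],
                      dm$occasional_share[["female"]])
  ever <- stats::runif(n) < p_ever
  ex <- ever & stats::runif(n) < ex_frac
  current <- ever & !ex
  occasional <- !ever & stats::runif(n) < occ_share
  status <- ifelse(current, "current",
                   ifelse(ex, "ex", ifelse(occasional, "occasional", "non")))

  # reported baseline intake (g/week, questionnaire-capped) and the latent
  # usual intake driving hazards: U = rdr * baseline + (1 - rdr) * m_g,
  # the linear shrinkage toward the sex-genotype group mean that the
  # grouped repeat-measurement correction assumes
  baseline_gpw <- numeric(n)
  baseline_gpw[current] <- pmin(
    stats::rlnorm(sum(current), meanlog[current], dm$sdlog), dm$max_gpw)
  group_mean <- trunc_lnorm_mean(meanlog, dm$sdlog, dm$max_gpw)
  usual <- numeric(n)
  usual[current] <- rdr * baseline_gpw[current] +
    (1 - rdr) * group_mean[current]
  usual[status == "occasional"] <- 5

  noisy <- function(u) { # mean-one resurvey reporting noise
    if (rs_sdlog == 0) return(u)
    u * stats::rlnorm(length(u), -rs_sdlog^2 / 2, rs_sdlog)
  }

  # questionnaire back-construction so the exposure module recovers
  # baseline_gpw exactly from frequency + volumes
  freq_cat <- rep("never", n)
  freq_cat[status == "occasional"] <-
    sample(c("occasional", "certain_seasons", "monthly"),
           sum(status == "occasional"), replace = TRUE,
           prob = c(0.70, 0.15, 0.15))
  freq_cat[ex] <- sample(c("never", "occasional", "monthly"), sum(ex),
                         replace = TRUE, prob = c(0.5, 0.3, 0.2))
  freq_cat[current] <- sample(names(dm$freq_probs), sum(current),
                              replace = TRUE, prob = dm$freq_probs)
  past_weekly <- ex
  f_days <- unname(FREQ_DAYS[freq_cat])
  vols <- matrix(0, n, length(BEVERAGES),
                 dimnames = list(NULL, paste0("vol_", BEVERAGES)))
  bev <- sample(BEVERAGES, n, replace = TRUE, prob = dm$beverage_probs)
  ci <- which(current)
  vols[cbind(ci, match(bev[ci], BEVERAGES))] <-
    baseline_gpw[ci] / (f_days[ci] * BEVERAGE_VV[bev[ci]] * ETHANOL_DENSITY)
  grams_occasion <- ifelse(current, baseline_gpw / f_days, NA_real_)
  mealtime <- rep(NA_character_, n)
  mealtime[current] <- sample(c("with_meals", "between_after", "no_pattern"),
                              sum(current), replace = TRUE,
                              prob = c(0.55, 0.30, 0.15))
  age_started <- rep(NA_real_, n)
  age_started[ever] <- pmax(18, base$age_baseline[ever] -
                              stats::runif(sum(ever), 5, 35))
  years_stopped <- rep(NA_real_, n)
  years_stopped[ex] <- pmin(stats::runif(sum(ex), 1, 15),
                            0.8 * (base$age_baseline[ex] - age_started[ex]))

  resurveyed <- stats::runif(n) < config$resurvey_fraction
  r1 <- r2 <- rep(NA_real_, n)
  ri <- which(resurveyed)
  r1[ri] <- ifelse(current[ri], noisy(usual[ri]), usual[ri])
  second <- ri[stats::runif(length(ri)) < 0.5]
  r2[second] <- ifelse(current[second], noisy(usual[second]), usual[second])

  out <- base
  out$geno_missing <- miss
  out$freq_cat <- freq_cat
  out$past_weekly <- past_weekly
  out <- cbind(out, as.data.frame(vols))
  out$grams_per_occasion <- grams_occasion
  out$mealtime <- mealtime
  out$age_started <- age_started
  out$years_stopped <- years_stopped
  out$resurvey1 <- r1
  out$resurvey2 <- r2
  out$usual_gpw <- usual
  out
}

#' Simulate disease histories and competing mortality
#'
#' For each configured endpoint, hospitalization episodes arise from a
#' Poisson process with rate `rate * exp(loghr_per_280 * usual_gpw / 280 +
#' area_confounding * z_area [+ sick-quitter shift for ex-drinkers])`,
#' observed from baseline until death or administrative censoring. Death is
#' an independent constant-hazard competing process; no events are generated
#' after death.
#'
#' @param participants data.frame from [simulate_drinking_behaviour()].
#' @param config a [sim_config()].
#' @return list with `participants` (death/censoring columns appended) and
#'   `events` (`id`, `code`, `age`).
#' @export
simulate_disease_history <- function(participants, config) {
  if (any(config$endpoints$rate <= 0) || config$mortality_hazard <= 0)
    stop("hazard parameters must be positive")
  n <- nrow(participants)
  t_death <- stats::rexp(n, config$mortality_hazard)
  censor_age <- participants$age_baseline + config$followup_years
  death_age <- ifelse(t_death < config$followup_years,
                      participants$age_baseline + t_death, NA_real_)
  end_age <- pmin(censor_age, death_age, na.rm = TRUE)
  t_obs <- end_age - participants$age_baseline

  z_area <- if (config$n_areas > 1) {
    a <- seq_len(config$n_areas)
    (a - mean(a)) / stats::sd(a)
  } else 0
  area_shift <- config$area_confounding *
    (if (config$n_areas > 1) z_area[participants$area] else 0)
  ex_drinker <- participants$past_weekly &
    !participants$freq_cat %in% names(FREQ_DAYS)
  sick_shift <- config$drinking$sick_quitter_lograte * as.numeric(ex_drinker)
  x <- participants$usual_gpw / 280

  ev_id <- integer(0); ev_code <- character(0); ev_age <- numeric(0)
  for (k in seq_len(nrow(config$endpoints))) {
    ep <- config$endpoints[k, ]
    rate <- ep$rate * exp(ep$loghr_per_280 * x + area_shift + sick_shift)
    counts <- stats::rpois(n, rate * t_obs)
    tot <- sum(counts)
    if (tot == 0) next
    idx <- rep.int(seq_len(n), counts)
    codes <- strsplit(ep$codes, ";", fixed = TRUE)[[1]]
    ev_id <- c(ev_id, idx)
    ev_code <- c(ev_code, sample(codes, tot, replace = TRUE))
    ev_age <- c(ev_age, participants$age_baseline[idx] +
                  stats::runif(tot) * t_obs[idx])
  }
  events <- data.frame(id = ev_id, code = ev_code, age = ev_age,
                       stringsAsFactors = FALSE)
  events <- events[order(events$id, events$age), , drop = FALSE]
  rownames(events) <- NULL
  participants$death_age <- death_age
  participants$censor_age <- censor_age
  participants$end_age <- end_age
  list(participants = participants, events = events)
}

#' Simulate a complete synthetic cohort
#'
#' Seeds the RNG from `config$seed` and composes [simulate_genotypes()],
#' [simulate_drinking_behaviour()] and [simulate_disease_history()].
#' Identical configurations (including seed) reproduce identical cohorts.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: list with `participants`,
#'   `events` and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base <- simulate_genotypes(config)
  part <- simulate_drinking_behaviour(base, config)
  sim <- simulate_disease_history(part, config)
  structure(list(participants = sim$participants, events = sim$events,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d hospitalization events\n",
              nrow(x$participants), nrow(x$events)))
  invisible(x)
}

fmt_col <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else x
}

#' Write / read a cohort as delimited text
#'
#' Writes `participants.tsv` and `events.tsv` (UTF-8, tab-separated) into
#' `dir`. Doubles are serialized with 17 significant digits so a round trip
#' reproduces every field exactly.
#'
#' @param cohort a `synthetic_cohort` or list with `participants`/`events`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   list with `participants` and `events`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (what in c("participants", "events")) {
    df <- cohort[[what]]
    out <- as.data.frame(lapply(df, fmt_col), stringsAsFactors = FALSE,
                         check.names = FALSE)
    utils::write.table(out, file.path(dir, paste0(what, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE,
                                      fileEncoding = "UTF-8")
  part <- rd("participants.tsv")
  ev <- rd("events.tsv")
  ev$id <- as.integer(ev$id)
  ev$code <- as.character(ev$code)
  ev$age <- as.numeric(ev$age)
  list(participants = part, events = ev)
}
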