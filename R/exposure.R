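# Questionnaire-derived alcohol exposure: drinker status, weekly grams,
# consumption categories, drinking-pattern flags, regression dilution and
# group-level usual intake.

WEEKLY_CATS <- c("weekly_1_2", "weekly_3_5", "weekly_6_7")

#' Classify drinker status from questionnaire frequency and history
#'
#' Status follows past-year frequency and past weekly drinking: weekly
#' drinking in the past year gives a current drinker; less-than-weekly (or
#' no) past-year drinking with weekly drinking in the past gives an
#' ex-drinker; less-than-weekly past-year drinking without past weekly
#' drinking gives an occasional drinker; never in the past year and never
#' weekly gives a non-drinker. "Certain seasons" and "monthly but not
#' weekly" past-year drinkers count as less-than-weekly.
#'
#' @param freq_cat character vector with values among `never`, `occasional`,
#'   `certain_seasons`, `monthly`, `weekly_1_2`, `weekly_3_5`, `weekly_6_7`.
#' @param past_weekly logical: drank at least weekly for a year or more in
#'   the past. Required (non-`NA`) for participants not currently drinking
#'   weekly; such records are otherwise unclassifiable and return `NA`.
#' @return character vector: `"non"`, `"ex"`, `"occasional"` or `"current"`
#'   (`NA` when unclassifiable).
#' @export
classify_drinker_status <- function(freq_cat, past_weekly) {
  bad <- !is.na(freq_cat) & !freq_cat %in% FREQ_LEVELS
  if (any(bad))
    stop("unknown frequency category: ", paste(unique(freq_cat[bad]),
                                               collapse = ", "))
  current <- freq_cat %in% WEEKLY_CATS
  status <- rep(NA_character_, length(freq_cat))
  status[current] <- "current"
  need <- !current
  known <- need & !is.na(past_weekly)
  status[known & past_weekly] <- "ex"
  status[known & !past_weekly & freq_cat == "never"] <- "non"
  status[known & !past_weekly & freq_cat != "never"] <- "occasional"
  status
}

#' Weekly grams of ethanol from typical-day volumes
#'
#' `grams = f * sum_b(volume_b * vv_b * density)` where `f` is the number of
#' drinking days per week taken as the midpoint of the reported interval
#' (1.5, 4 or 6.5 for 1-2, 3-5 and 6-7 days/week), `vv_b` the ethanol
#' content by volume typical of each beverage (beer 4%, grape wine 12%, rice
#' wine 15%, weak spirits 38%, strong spirits 53%), and `density` the mass
#' of ethanol per ml.
#'
#' @param freq_cat weekly frequency category (see
#'   [classify_drinker_status()]); non-weekly categories give 0 g/week.
#' @param vol_beer,vol_grape_wine,vol_rice_wine,vol_weak_spirits,vol_strong_spirits
#'   typical-drinking-day volumes in ml (non-negative).
#' @param density ethanol mass density in g/ml (default 0.79).
#' @return numeric vector of g ethanol per week.
#' @export
weekly_alcohol_grams <- function(freq_cat, vol_beer = 0, vol_grape_wine = 0,
                                 vol_rice_wine = 0, vol_weak_spirits = 0,
                                 vol_strong_spirits = 0,
                                 density = ETHANOL_DENSITY) {
  vols <- cbind(vol_beer, vol_grape_wine, vol_rice_wine, vol_weak_spirits,
                vol_strong_spirits)
  if (any(vols < 0, na.rm = TRUE)) stop("beverage volumes must be >= 0")
  f <- FREQ_DAYS[freq_cat]
  f[is.na(f)] <- 0
  daily <- as.vector(vols %*% BEVERAGE_VV) * density
  unname(f * daily)
}

#' Assign sex-specific weekly intake category
#'
#' Men: `<140`, `140-279`, `280-419`, `420+` g/week; women: `<70`, `70-139`,
#' `140+` g/week. Boundaries are left-closed upward (140 g/week is
#' `140-279` for a man, `140+` for a woman).
#'
#' @param g_per_week numeric weekly grams (non-negative).
#' @param sex `"M"` or `"F"`.
#' @return character category labels.
#' @export
assign_intake_category <- function(g_per_week, sex) {
  if (any(g_per_week < 0, na.rm = TRUE)) stop("intake must be >= 0")
  men_labels <- c("<140", "140-279", "280-419", "420+")
  women_labels <- c("<70", "70-139", "140+")
  out <- rep(NA_character_, length(g_per_week))
  m <- sex == "M"
  out[m] <- men_labels[findInterval(g_per_week[m], c(140, 280, 420)) + 1L]
  out[!m] <- women_labels[findInterval(g_per_week[!m], c(70, 140)) + 1L]
  out
}

#' Drinking-pattern flags for current drinkers
#'
#' Heavy episodic drinking is strictly more than 60 g (men) / 40 g (women)
#' of ethanol on a typical drinking occasion. Drinking outside of meals is a
#' usual habit of drinking between/after meals or with no regular pattern.
#' Daily drinking is the 6-7 days/week frequency category. A spirit drinker
#' reports any positive weak- or strong-spirit volume. Duration is baseline
#' age minus age started drinking.
#'
#' @param sex `"M"`/`"F"`.
#' @param grams_per_occasion grams of ethanol on a typical occasion.
#' @param freq_cat weekly frequency category.
#' @param mealtime `"with_meals"`, `"between_after"` or `"no_pattern"`.
#' @param vol_weak_spirits,vol_strong_spirits typical-day volumes (ml).
#' @param age_baseline,age_started ages in years; `age_started` may not
#'   exceed `age_baseline`.
#' @return data.frame with `heavy_episodic`, `daily`, `outside_meals`,
#'   `spirit_drinker`, `duration`.
#' @export
flag_drinking_patterns <- function(sex, grams_per_occasion, freq_cat,
                                   mealtime, vol_weak_spirits,
                                   vol_strong_spirits, age_baseline,
                                   age_started) {
  if (any(age_started > age_baseline, na.rm = TRUE))
    stop("age started drinking exceeds baseline age")
  thr <- ifelse(sex == "M", 60, 40)
  data.frame(
    heavy_episodic = !is.na(grams_per_occasion) & grams_per_occasion > thr,
    daily = freq_cat == "weekly_6_7",
    outside_meals = !is.na(mealtime) &
      mealtime %in% c("between_after", "no_pattern"),
    spirit_drinker = (!is.na(vol_weak_spirits) & vol_weak_spirits > 0) |
      (!is.na(vol_strong_spirits) & vol_strong_spirits > 0),
    duration = age_baseline - age_started
  )
}

#' Derive the per-participant exposure table
#'
#' Applies status classification, the weekly-grams formula, sex-specific
#' categories and pattern flags to a participants table (as produced by
#' [simulate_cohort()] or read from `participants.tsv`).
#'
#' @param participants participants data.frame.
#' @param density ethanol density g/ml.
#' @return data.frame keyed by `id` with `status`, `ever_regular`, `gpw`
#'   (0 except for current drinkers), `category`, the pattern flags,
#'   `duration` and `resurvey_mean` (mean of available resurvey intakes).
#' @export
derive_exposure <- function(participants, density = ETHANOL_DENSITY) {
  p <- participants
  status <- classify_drinker_status(p$freq_cat, p$past_weekly)
  gpw <- weekly_alcohol_grams(p$freq_cat, p$vol_beer, p$vol_grape_wine,
                              p$vol_rice_wine, p$vol_weak_spirits,
                              p$vol_strong_spirits, density)
  gpw[is.na(status) | status != "current"] <- 0
  flags <- flag_drinking_patterns(p$sex, p$grams_per_occasion, p$freq_cat,
                                  p$mealtime, p$vol_weak_spirits,
                                  p$vol_strong_spirits, p$age_baseline,
                                  p$age_started)
  category <- rep(NA_character_, nrow(p))
  cur <- !is.na(status) & status == "current"
  category[cur] <- assign_intake_category(gpw[cur], p$sex[cur])
  rs <- rowMeans(cbind(p$resurvey1, p$resurvey2), na.rm = TRUE)
  rs[is.nan(rs)] <- NA_real_
  data.frame(id = p$id, sex = p$sex, status = status,
             ever_regular = !is.na(status) & status %in% c("ex", "current"),
             gpw = gpw, category = category, flags,
             resurvey_mean = rs, stringsAsFactors = FALSE)
}

#' Regression dilution ratio by grouped repeat measurements
#'
#' McMahon-Peto estimate: participants with a repeat measurement are split
#' into quantile groups of baseline intake; the ratio is the slope of the
#' group mean repeat values regressed on the group mean baseline values
#' (weighted by group size). The estimator is scale invariant. A bootstrap
#' over participants provides the confidence interval.
#'
#' @param baseline,resurvey numeric vectors of baseline and repeat intake
#'   (same length; pairs with a missing value are dropped). Callers should
#'   restrict to current drinkers at baseline.
#' @param n_groups number of baseline quantile groups (default quintiles).
#' @param n_boot bootstrap replicates for the CI (0 disables).
#' @param conf confidence level.
#' @return list with `ratio`, `ci`, `group_means` (data.frame), `n`.
#' @export
estimate_regression_dilution_ratio <- function(baseline, resurvey,
                                               n_groups = 5, n_boot = 200,
                                               conf = 0.95) {
  keep <- !is.na(baseline) & !is.na(resurvey)
  b <- baseline[keep]; r <- resurvey[keep]
  point <- function(b, r) {
    qs <- stats::quantile(b, probs = seq(0, 1, length.out = n_groups + 1))
    grp <- findInterval(b, unique(qs), rightmost.closed = TRUE)
    mb <- tapply(b, grp, mean)
    mr <- tapply(r, grp, mean)
    nw <- tapply(b, grp, length)
    if (length(mb) < 2) stop("fewer than 2 baseline groups with data")
    wm <- function(x) sum(nw * x) / sum(nw)
    sum(nw * (mb - wm(mb)) * (mr - wm(mr))) / sum(nw * (mb - wm(mb))^2)
  }
  ratio <- point(b, r)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(b), replace = TRUE)
      tryCatch(point(b[idx], r[idx]), error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, (1 + conf) / 2),
                                 na.rm = TRUE))
  }
  qs <- stats::quantile(b, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- findInterval(b, unique(qs), rightmost.closed = TRUE)
  gm <- data.frame(group = sort(unique(grp)),
                   baseline_mean = as.numeric(tapply(b, grp, mean)),
                   resurvey_mean = as.numeric(tapply(r, grp, mean)),
                   n = as.integer(tapply(b, grp, length)))
  list(ratio = ratio, ci = ci, group_means = gm, n = length(b))
}

#' Mean usual intake per baseline consumption category
#'
#' The usual (long-term) intake of a baseline category is estimated by the
#' mean repeat-measurement intake of its members; these means serve as
#' x-coordinates when plotting category hazard ratios.
#'
#' @param category baseline category labels.
#' @param resurvey repeat intake values (`NA` for participants without one).
#' @return data.frame with `category`, `usual_mean`, `n_resurveyed`; empty
#'   categories get `NA` and are flagged in the `flagged_empty` attribute.
#' @export
usual_intake_by_group <- function(category, resurvey) {
  cats <- unique(category[!is.na(category)])
  out <- data.frame(category = cats,
                    usual_mean = NA_real_, n_resurveyed = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cats)) {
    v <- resurvey[!is.na(category) & category == cats[i] & !is.na(resurvey)]
    out$n_resurveyed[i] <- length(v)
    if (length(v) > 0) out$usual_mean[i] <- mean(v)
  }
  attr(out, "flagged_empty") <- out$category[out$n_resurveyed == 0]
  out
}
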