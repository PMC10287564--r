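# Cumulative hospitalization burden by age via the mean cumulative count
# (MCC), which treats death as a competing risk rather than censoring.

#' Mean cumulative count of recurrent hospitalizations
#'
#' `MCC(t) = sum_{u <= t} S(u-) * d(u) / n(u)` where `S` is the
#' Kaplan-Meier estimator of death-free survival, `d(u)` the number of
#' hospitalization episodes at age `u` and `n(u)` the number at risk
#' (entered, alive and uncensored) just before `u`. Delayed entry is
#' honoured; an episode tied with a death at the same age is counted before
#' the death is processed. Without deaths or censoring the curve reduces to
#' the cumulative episode count divided by n.
#'
#' @param episodes data.frame `id`, `age` of hospitalization episodes
#'   (possibly several per participant; ids without episodes need no rows).
#' @param persons data.frame `id`, `entry`, `exit`, `death` (logical or
#'   0/1: exit by death rather than censoring), one row per participant.
#' @param grid ages at which to evaluate the curve (default integer ages
#'   35-84).
#' @return data.frame `age`, `mcc`, `n_risk` (at risk just before each grid
#'   age); step-function values, non-decreasing in age.
#' @export
mean_cumulative_count <- function(episodes, persons, grid = 35:84) {
  if (nrow(persons) == 0) stop("empty group")
  stopifnot(all(persons$entry < persons$exit))
  if (nrow(episodes) > 0) {
    ok <- episodes$id %in% persons$id
    episodes <- episodes[ok, , drop = FALSE]
    ex <- persons$exit[match(episodes$id, persons$id)]
    if (any(episodes$age > ex + 1e-9))
      stop("episode after death/censoring")
  }
  death <- as.logical(persons$death)
  times <- sort(unique(c(episodes$age, persons$exit[death])))
  entry_s <- sort(persons$entry)
  exit_s <- sort(persons$exit)
  n_at <- function(u) # entered strictly before u, exit not yet passed
    findInterval(u, entry_s, left.open = TRUE) -
    findInterval(u, exit_s, left.open = TRUE)
  nt <- length(times)
  n_u <- n_at(times)
  d_u <- tabulate(match(episodes$age, times), nbins = nt)
  dd_u <- tabulate(match(persons$exit[death], times), nbins = nt)
  surv <- 1
  mcc <- 0
  step_v <- numeric(nt)
  for (i in seq_len(nt)) {
    if (d_u[i] > 0 && n_u[i] > 0) mcc <- mcc + surv * d_u[i] / n_u[i]
    step_v[i] <- mcc
    if (dd_u[i] > 0 && n_u[i] > 0) surv <- surv * (1 - dd_u[i] / n_u[i])
  }
  idx <- findInterval(grid, times)
  data.frame(age = grid,
             mcc = c(0, step_v)[idx + 1],
             n_risk = n_at(grid))
}

#' MCC burden curves by drinking group
#'
#' Convenience wrapper computing the mean cumulative count of all (or
#' code-filtered) hospitalization episodes for ever-regular and occasional
#' drinkers over the age-at-risk window.
#'
#' @param participants,events cohort tables.
#' @param exposure exposure table.
#' @param codes optional ICD-10 code filter for the episodes.
#' @param window age window; episodes and follow-up are restricted to it.
#' @param grid evaluation ages.
#' @return data.frame `group`, `age`, `mcc`, `n_risk`.
#' @export
burden_by_group <- function(participants, events, exposure, codes = NULL,
                            window = c(35, 85),
                            grid = seq(window[1], window[2] - 1)) {
  ev <- events
  if (!is.null(codes)) ev <- ev[ev$code %in% codes, , drop = FALSE]
  ev <- ev[ev$age >= window[1] & ev$age < window[2], , drop = FALSE]
  out <- list()
  for (grp in c("ever_regular", "occasional")) {
    ids <- if (grp == "ever_regular") exposure$id[exposure$ever_regular]
    else exposure$id[!is.na(exposure$status) &
                       exposure$status == "occasional"]
    p <- participants[participants$id %in% ids, , drop = FALSE]
    persons <- data.frame(
      id = p$id,
      entry = pmax(p$age_baseline, window[1]),
      exit = pmin(p$end_age, window[2]),
      death = !is.na(p$death_age) & p$death_age <= window[2])
    persons <- persons[persons$entry < persons$exit, , drop = FALSE]
    m <- mean_cumulative_count(ev[, c("id", "age")], persons, grid)
    m$group <- grp
    out[[grp]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("group", "age", "mcc", "n_risk")]
}
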