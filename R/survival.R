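# Stratified proportional-hazards machinery: age-at-risk Lexis expansion,
# Cox fits on the age time scale with delayed entry, floating absolute
# risks, regression-dilution-corrected dose-response, and subgroup
# heterogeneity/trend tests.

#' Lexis expansion into 5-year age-at-risk bands
#'
#' Splits each follow-up interval at the age-band boundaries so that Cox
#' models can be stratified by age at risk. Person-time and events are
#' conserved; the event lands on the slice containing the event age.
#'
#' @param data survival data.frame with `entry`, `exit`, `event` and any
#'   further columns (carried through).
#' @param band_width band width in years (default 5).
#' @param window age window `c(lo, hi)`; must lie within `[35, 85]` by
#'   default convention of the analysis.
#' @return data.frame of slices with `entry`, `exit`, `event`, `age_band`
#'   (factor) and the original columns.
#' @importFrom survival Surv strata coxph survSplit
#' @export
lexis_expand <- function(data, band_width = 5, window = c(35, 85)) {
  if (window[1] < 35 || window[2] > 85 || window[2] <= window[1])
    stop("age window must lie within [35, 85]")
  stopifnot(all(data$entry < data$exit),
            all(data$entry >= window[1] - 1e-9),
            all(data$exit <= window[2] + 1e-9))
  cuts <- seq(window[1], window[2], by = band_width)
  inner <- cuts[cuts > min(data$entry) & cuts < max(data$exit)]
  sp <- survival::survSplit(Surv(entry, exit, event) ~ .,
                            data = data, cut = inner,
                            start = "entry", end = "exit", event = "event")
  band_lo <- cuts[findInterval(sp$entry, cuts)]
  sp$age_band <- factor(band_lo, levels = cuts[-length(cuts)])
  sp
}

#' Fit an age-at-risk- and area-stratified Cox model
#'
#' Maximizes the stratified Cox partial likelihood on the age time scale
#' with delayed entry, Efron tie handling, baseline hazards stratified by
#' the `strata_vars` (5-year age band and study area by default).
#'
#' @param slices Lexis-expanded data.frame (see [lexis_expand()]) with the
#'   exposure and covariate columns.
#' @param exposure character vector of exposure term(s), e.g. `"xb280"` or
#'   `"factor(category)"`.
#' @param covariates character vector of adjustment terms (e.g.
#'   `c("factor(education)", "factor(smoking)")`).
#' @param strata_vars columns defining baseline-hazard strata.
#' @param ties tie-handling approximation (`"efron"` default, less biased
#'   with the heavy tying of Lexis-expanded hospital data).
#' @param control convergence control passed to [survival::coxph()]
#'   (default: score tolerance 1e-10, up to 100 iterations).
#' @return list with `coef`, `vcov` (exposure+covariate terms; aliased
#'   terms dropped with a warning), `n`, `n_event` and the `coxph` fit.
#' @export
fit_stratified_cox <- function(slices, exposure,
                               covariates = character(),
                               strata_vars = c("age_band", "area"),
                               ties = "efron",
                               control = survival::coxph.control(
                                 eps = 1e-10, iter.max = 100,
                                 timefix = FALSE)) {
  if (sum(slices$event) < 1) stop("no events in the fitted dataset")
  strat <- sprintf("strata(%s)", paste(strata_vars, collapse = ", "))
  rhs <- paste(c(exposure, covariates, strat), collapse = " + ")
  f <- stats::as.formula(paste("Surv(entry, exit, event) ~", rhs))
  environment(f) <- environment()
  # control disables timefix: ages are continuous, and Lexis slices whose
  # length falls below its tolerance (an event at a band cut) are valid
  fit <- survival::coxph(f, data = slices, ties = ties, control = control)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    warning("dropping aliased/empty terms: ",
            paste(names(co)[is.na(co)], collapse = ", "))
    keep <- !is.na(co)
    co <- co[keep]
    V <- stats::vcov(fit)[keep, keep, drop = FALSE]
  } else V <- stats::vcov(fit)
  list(coef = co, vcov = V, n = fit$n, n_event = fit$nevent, fit = fit)
}

#' Floating absolute risks for the levels of one exposure factor
#'
#' Attributes a variance to every level of a factor, including the
#' reference, such that the variance of any log hazard-ratio difference is
#' recovered as the sum of the two floated variances. The default
#' heterogeneity method sets the reference variance to the mean off-diagonal
#' covariance and each level's variance to its conventional variance minus
#' that; when this produces a non-positive variance, an iterative fit
#' minimizing the maximum relative error of the pairwise reconstructions
#' takes over. With a single non-reference level the variance is split
#' proportionally to level sizes.
#'
#' @param coef named numeric vector: log HRs of the non-reference levels.
#' @param vcov their covariance matrix.
#' @param ref_label label for the reference level.
#' @param n_by_level optional counts (reference first) used for the
#'   two-level proportional split; equal sizes assumed when missing.
#' @param method `"heterogeneity"` (default, with automatic fallback) or
#'   `"iterative"`.
#' @return data.frame `level`, `loghr`, `var_conventional`, `var_floated`,
#'   `se_floated`; attributes `method` and `max_rel_error` (largest relative
#'   error of the pairwise variance reconstruction).
#' @export
float_absolute_risks <- function(coef, vcov, ref_label = "ref",
                                 n_by_level = NULL,
                                 method = c("heterogeneity", "iterative")) {
  method <- match.arg(method)
  vcov <- as.matrix(vcov)
  k <- length(coef)
  stopifnot(nrow(vcov) == k, ncol(vcov) == k)
  if (any(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("covariance matrix must be positive definite")
  used <- method
  if (k == 1) {
    if (is.null(n_by_level)) n_by_level <- c(1, 1)
    w <- n_by_level / sum(n_by_level)
    lam0 <- vcov[1, 1] * w[2]
    lam <- vcov[1, 1] - lam0
    used <- "proportional-split"
  } else {
    off <- vcov[upper.tri(vcov)]
    lam0 <- mean(off)
    lam <- diag(vcov) - lam0
    if (method == "iterative" || lam0 < 0 || any(lam <= 0)) {
      start <- log(pmax(c(lam0, lam), 1e-8))
      obj <- function(lg) max_rel_err(exp(lg), vcov)
      opt <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      lam0 <- exp(opt$par[1])
      lam <- exp(opt$par[-1])
      used <- "iterative"
    }
  }
  out <- data.frame(level = c(ref_label, names(coef)),
                    loghr = c(0, unname(coef)),
                    var_conventional = c(NA_real_, diag(vcov)),
                    var_floated = c(lam0, unname(lam)),
                    stringsAsFactors = FALSE)
  out$se_floated <- sqrt(out$var_floated)
  attr(out, "method") <- used
  attr(out, "max_rel_error") <- max_rel_err(c(lam0, lam), vcov)
  out
}

# largest relative error of var(b_i - b_j) reconstruction over all pairs
# (the reference has b_0 = 0, var from the conventional fit = V_ii)
max_rel_err <- function(lams, vcov) {
  lam0 <- lams[1]; lam <- lams[-1]
  k <- length(lam)
  err <- abs((lam0 + lam) / diag(vcov) - 1)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- vcov[i, i] + vcov[j, j] - 2 * vcov[i, j]
      err <- c(err, abs((lam[i] + lam[j]) / d - 1))
    }
  }
  max(err)
}

#' Regression-dilution-corrected dose-response estimate
#'
#' Divides a baseline-intake log HR and its standard error by the
#' regression dilution ratio to express the association per unit of usual
#' (long-term) intake.
#'
#' @param loghr log HR per exposure unit of baseline intake (e.g. per
#'   280 g/week).
#' @param se its standard error.
#' @param rdr regression dilution ratio in (0, 1].
#' @param conf confidence level.
#' @return list with `hr`, `ci`, `loghr`, `se` (corrected scale), `rdr`,
#'   `p` (unchanged by the correction).
#' @export
dose_response_corrected <- function(loghr, se, rdr, conf = 0.95) {
  if (is.na(rdr) || rdr <= 0 || rdr > 1) stop("rdr must lie in (0, 1]")
  b <- loghr / rdr
  s <- se / rdr
  z <- stats::qnorm((1 + conf) / 2)
  list(hr = exp(b), ci = exp(c(b - z * s, b + z * s)),
       loghr = b, se = s, rdr = rdr,
       p = 2 * stats::pnorm(-abs(loghr / se)))
}

#' Chi-squared heterogeneity and trend tests across subgroups
#'
#' Heterogeneity: `sum w_g (b_g - b_bar)^2` with inverse-variance weights
#' and the IVW mean, on G-1 degrees of freedom. Trend (when ordered scores
#' are supplied): the 1-df chi-squared of the inverse-variance-weighted
#' regression slope of the estimates on the scores.
#'
#' @param est numeric subgroup estimates (log HRs).
#' @param se their standard errors.
#' @param scores optional ordered scores for the trend test.
#' @return list with `het` (`statistic`, `df`, `p`) and, if scores given,
#'   `trend` (`slope`, `se`, `statistic`, `df`, `p`).
#' @export
subgroup_heterogeneity_trend <- function(est, se, scores = NULL) {
  stopifnot(length(est) == length(se))
  if (length(est) < 2) stop("at least two subgroups are required")
  w <- 1 / se^2
  bbar <- sum(w * est) / sum(w)
  q <- sum(w * (est - bbar)^2)
  out <- list(het = list(statistic = q, df = length(est) - 1,
                         p = stats::pchisq(q, length(est) - 1,
                                           lower.tail = FALSE)))
  if (!is.null(scores)) {
    xbar <- sum(w * scores) / sum(w)
    sxx <- sum(w * (scores - xbar)^2)
    slope <- sum(w * (scores - xbar) * est) / sxx
    slope_se <- sqrt(1 / sxx)
    stat <- (slope / slope_se)^2
    out$trend <- list(slope = slope, se = slope_se, statistic = stat,
                      df = 1, p = stats::pchisq(stat, 1, lower.tail = FALSE))
  }
  out
}

#' Floated hazard-ratio profile across detailed exposure categories
#'
#' Fits one stratified Cox model over detailed drinker categories
#' (non-drinkers, ex-drinkers, occasional drinkers as reference, and intake
#' bands among current drinkers — or any other category column) and floats
#' the level variances. Additional adjustment terms (e.g. total intake for
#' drinking-pattern contrasts) can be appended.
#'
#' @param slices Lexis-expanded survival data with a `category` column.
#' @param ref reference category label.
#' @param covariates adjustment terms.
#' @param strata_vars baseline-hazard strata columns.
#' @param extra_terms further model terms (e.g. `"gpw"`).
#' @return [float_absolute_risks()] table with `n_event` per level attached;
#'   attribute `fit` holds the Cox fit summary pieces.
#' @export
categorical_hr_profile <- function(slices, ref,
                                   covariates = character(),
                                   strata_vars = c("age_band", "area"),
                                   extra_terms = character()) {
  lev <- unique(as.character(slices$category))
  lev <- c(ref, sort(setdiff(lev, ref)))
  empty <- setdiff(lev, unique(as.character(slices$category)))
  if (length(empty) > 0) {
    warning("dropping empty categories: ", paste(empty, collapse = ", "))
    lev <- setdiff(lev, empty)
  }
  slices$.cat <- factor(as.character(slices$category), levels = lev)
  fit <- fit_stratified_cox(slices, c(".cat", extra_terms), covariates,
                            strata_vars)
  sel <- grep("^\\.cat", names(fit$coef))
  co <- fit$coef[sel]
  names(co) <- sub("^\\.cat", "", names(co))
  ev_by <- tapply(slices$event, slices$.cat, sum)
  res <- float_absolute_risks(co, fit$vcov[sel, sel, drop = FALSE],
                              ref_label = ref,
                              n_by_level = as.numeric(ev_by[lev]))
  res$n_event <- as.integer(ev_by[res$level])
  attr(res, "fit") <- fit
  res
}
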