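test_that("lexis expansion splits at band boundaries and conserves time", {
  d <- data.frame(id = 1, entry = 52, exit = 61, event = 1, area = 3)
  sl <- lexis_expand(d)
  expect_equal(nrow(sl), 3)
  expect_equal(sl$entry, c(52, 55, 60))
  expect_equal(sl$exit, c(55, 60, 61))
  expect_equal(sl$event, c(0, 0, 1))
  expect_equal(as.character(sl$age_band), c("50", "55", "60"))
  # entry and exit within one band give a single slice
  one <- lexis_expand(data.frame(entry = 41, exit = 44, event = 0))
  expect_equal(nrow(one), 1)
  # person-time and event conservation on random data
  set.seed(8)
  rd <- data.frame(id = 1:50, entry = runif(50, 35, 70))
  rd$exit <- pmin(rd$entry + runif(50, 0.5, 20), 84.9)
  rd$event <- rbinom(50, 1, 0.5)
  sl2 <- lexis_expand(rd)
  expect_equal(sum(sl2$exit - sl2$entry), sum(rd$exit - rd$entry))
  expect_equal(sum(sl2$event), sum(rd$event))
  expect_equal(as.numeric(tapply(sl2$exit - sl2$entry, sl2$id, sum)),
               rd$exit - rd$entry)
  expect_error(lexis_expand(rd, window = c(20, 85)), "\\[35, 85\\]")
})

test_that("stratified Cox matches the brute-force Efron oracle on ties", {
  set.seed(301)
  checked <- 0
  while (checked < 8) {
    d <- tiny_cox_data()
    if (is.null(d)) next
    oracle <- efron_mle(d$entry, d$exit, d$event, d$x)
    if (abs(oracle) > 5) next
    fit <- fit_stratified_cox(d, "x", strata_vars = "age_band")
    expect_equal(unname(fit$coef["x"]), oracle, tolerance = 1e-6)
    checked <- checked + 1
  }
})

test_that("duplicating every record keeps the estimate, halves the variance", {
  set.seed(77)
  d <- data.frame(entry = runif(60, 35, 40))
  d$exit <- d$entry + runif(60, 1, 15)
  d$event <- rbinom(60, 1, 0.6)
  d$x <- rnorm(60)
  d$age_band <- "all"
  # exact under Breslow (duplication scales the partial likelihood); Efron
  # re-weights the induced ties so it is only approximate there
  f1 <- fit_stratified_cox(d, "x", strata_vars = "age_band",
                           ties = "breslow")
  f2 <- fit_stratified_cox(rbind(d, d), "x", strata_vars = "age_band",
                           ties = "breslow")
  expect_equal(unname(f2$coef), unname(f1$coef), tolerance = 1e-7)
  expect_equal(f2$vcov[1, 1], f1$vcov[1, 1] / 2, tolerance = 0.02)
  e1 <- fit_stratified_cox(d, "x", strata_vars = "age_band")
  e2 <- fit_stratified_cox(rbind(d, d), "x", strata_vars = "age_band")
  expect_equal(unname(e2$coef), unname(e1$coef), tolerance = 0.05)
})

test_that("cox estimates are invariant to within-stratum time-origin shifts", {
  set.seed(90)
  d <- data.frame(entry = runif(80, 36, 40))
  d$exit <- d$entry + runif(80, 1, 4)
  d$event <- rbinom(80, 1, 0.6)
  d$x <- rnorm(80)
  d$age_band <- "all"
  f1 <- fit_stratified_cox(d, "x", strata_vars = "age_band")
  d2 <- d
  d2$entry <- d2$entry + 7
  d2$exit <- d2$exit + 7
  f2 <- fit_stratified_cox(d2, "x", strata_vars = "age_band")
  expect_equal(unname(f1$coef), unname(f2$coef), tolerance = 1e-8)
})

test_that("floated variances follow the heterogeneity closed form", {
  # equal off-diagonal covariance c gives lambda0 = c exactly
  V <- matrix(0.03, 3, 3)
  diag(V) <- c(0.08, 0.10, 0.12)
  co <- c(a = 0.1, b = 0.5, c = 0.9)
  fl <- float_absolute_risks(co, V)
  expect_equal(fl$var_floated, c(0.03, 0.05, 0.07, 0.09))
  expect_equal(fl$loghr, c(0, 0.1, 0.5, 0.9))
  expect_lt(attr(fl, "max_rel_error"), 1e-10)
  # diagonal covariance: lambda0 = 0 and lambda_i = V_ii exactly
  V0 <- diag(c(0.05, 0.07))
  fl0 <- float_absolute_risks(c(a = 1, b = 2), V0)
  expect_equal(fl0$var_floated, c(0, 0.05, 0.07))
  # two-level case: proportional split by level sizes
  fl2 <- float_absolute_risks(c(a = 0.3), matrix(0.06), n_by_level = c(30, 10))
  expect_equal(fl2$var_floated, c(0.06 * 0.25, 0.06 * 0.75))
  expect_error(float_absolute_risks(c(a = 1), matrix(-0.1)),
               "positive definite")
})

test_that("iterative fallback yields positive minimax-fitted variances", {
  # a small diagonal next to a large off-diagonal makes the closed form
  # produce a negative level variance; the minimax fit must take over
  V <- rbind(c(0.05, 0.06), c(0.06, 0.30))
  fl <- float_absolute_risks(c(a = 1, b = 2), V)
  expect_equal(attr(fl, "method"), "iterative")
  expect_true(all(fl$var_floated > 0))
  expect_lt(attr(fl, "max_rel_error"), 0.15)
  # on a floatable matrix the iterative fit does at least as well as the
  # closed form
  V2 <- matrix(0.03, 3, 3)
  diag(V2) <- c(0.08, 0.10, 0.12)
  co <- c(a = 1, b = 2, c = 3)
  it <- float_absolute_risks(co, V2, method = "iterative")
  het <- float_absolute_risks(co, V2, method = "heterogeneity")
  expect_lte(attr(it, "max_rel_error"),
             attr(het, "max_rel_error") + 1e-6)
})

test_that("dose-response correction rescales estimate and CI by 1/rdr", {
  r <- dose_response_corrected(log(1.10), 0.05, 0.53)
  expect_equal(r$hr, exp(log(1.10) / 0.53), tolerance = 1e-12)
  expect_equal(round(r$hr, 3), 1.197)
  r1 <- dose_response_corrected(log(1.10), 0.05, 1)
  expect_equal(r1$hr, 1.10)
  expect_equal(diff(log(r$ci)), diff(log(r1$ci)) / 0.53)
  expect_equal(r$p, r1$p) # Wald p invariant to the rescaling
  expect_error(dose_response_corrected(0.1, 0.05, 0), "\\(0, 1\\]")
})

test_that("heterogeneity and trend statistics match algebraic identities", {
  same <- subgroup_heterogeneity_trend(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(same$het$statistic, 0)
  expect_equal(same$het$p, 1)
  two <- subgroup_heterogeneity_trend(c(0.2, 0.6), c(0.1, 0.15))
  expect_equal(two$het$statistic, (0.2 - 0.6)^2 / (0.1^2 + 0.15^2))
  tr <- subgroup_heterogeneity_trend(c(0.1, 0.2, 0.4), c(0.1, 0.1, 0.1),
                                     scores = 1:3)
  w <- rep(100, 3)
  xb <- 2
  sl <- sum(w * (1:3 - xb) * c(0.1, 0.2, 0.4)) / sum(w * (1:3 - xb)^2)
  expect_equal(tr$trend$slope, sl)
  expect_error(subgroup_heterogeneity_trend(0.1, 0.1), "two subgroups")
})

test_that("heterogeneity p-values are uniform under a common effect", {
  set.seed(55)
  reps <- 400
  ps <- vapply(seq_len(reps), function(i) {
    se <- runif(4, 0.05, 0.2)
    est <- rnorm(4, 0.3, se)
    subgroup_heterogeneity_trend(est, se)$het$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("category profiles float the reference and recover a J-shape", {
  set.seed(123)
  n <- 8000
  cat_lev <- c("occasional", "non", "ex", "mod", "heavy")
  category <- sample(cat_lev, n, replace = TRUE,
                     prob = c(0.35, 0.2, 0.1, 0.2, 0.15))
  lhr <- c(occasional = 0, non = 0.3, ex = 0.4, mod = 0.05, heavy = 0.6)
  entry <- runif(n, 40, 60)
  tt <- rexp(n, 0.02 * exp(lhr[category]))
  d <- data.frame(entry = entry, exit = pmin(entry + tt, entry + 12, 84.9),
                  event = as.integer(tt < 12 &
                                       entry + tt < 84.9),
                  category = category, area = sample(1:2, n, TRUE))
  sl <- lexis_expand(d)
  prof <- categorical_hr_profile(sl, ref = "occasional")
  expect_equal(prof$level[1], "occasional")
  expect_true(all(prof$se_floated > 0)) # reference CI has positive width
  est <- prof$loghr[match(c("non", "ex", "mod", "heavy"), prof$level)]
  expect_true(all(abs(est - lhr[c("non", "ex", "mod", "heavy")]) < 0.25))
  expect_gt(est[4], est[3]) # heavy above moderate
  expect_gt(est[1], est[3]) # non-drinkers above moderate: J-shape
  expect_lt(attr(prof, "max_rel_error"), 0.10)
})
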