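# small hand-built cohort with fully controlled cell means
instrument_fixture <- function() {
  # area 1: GG/GG men: two current drinkers (300, 200) + one occasional
  #         (counts 5) + one non-drinker (0) + one ex-drinker (excluded)
  #         -> cell mean (300+200+5+0)/4 = 126.25 -> C5
  # area 1: AA/GG men: occasional only -> mean 5 -> C1
  # area 2: GG/GG men: one drinker at 10 -> mean 10 -> C2 (left-closed)
  # area 2: AG/GG men: one drinker at 150 -> mean 150 -> C6
  # area 2: AA/AA cell is empty -> pooled from same combo across areas
  part <- data.frame(
    id = 1:12,
    sex = c(rep("M", 10), "F", "F"),
    area = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 1, 2),
    g1 = c("GG", "GG", "GG", "GG", "GG", "AA", "GG", "AG", "AA", "AA",
           "GG", "AA"),
    g2 = c("GG", "GG", "GG", "GG", "GG", "GG", "GG", "GG", "AA", "AA",
           "GG", "AA"),
    stringsAsFactors = FALSE)
  exposure <- data.frame(
    id = 1:12,
    sex = part$sex,
    status = c("current", "current", "occasional", "non", "ex",
               "occasional", "current", "current", "current", "current",
               "non", "non"),
    gpw = c(300, 200, 0, 0, 400, 0, 10, 150, 30, 50, 0, 0),
    stringsAsFactors = FALSE)
  list(part = part, exposure = exposure)
}

test_that("instrument cells follow the exclusion and cutoff rules", {
  fx <- instrument_fixture()
  inst <- derive_genetic_instrument(fx$part, fx$exposure)
  cells <- attr(inst, "cells")
  cell <- function(g1, g2, a)
    cells[cells$g1 == g1 & cells$g2 == g2 & cells$area == a, ]
  expect_equal(cell("GG", "GG", 1)$cell_mean, 126.25) # ex-drinker excluded
  expect_equal(cell("GG", "GG", 1)$category, "C5")
  expect_equal(cell("AA", "GG", 1)$cell_mean, 5) # occasional assigned 5
  expect_equal(cell("AA", "GG", 1)$category, "C1")
  expect_equal(cell("GG", "GG", 2)$category, "C2") # mean 10, left-closed
  expect_equal(cell("AG", "GG", 2)$category, "C6") # mean 150, left-closed
  # empty AA/AA cell in area 1 pooled from the same combo across areas
  expect_equal(cell("AA", "AA", 1)$cell_mean, mean(c(30, 50)))
  expect_true("AA/AA/1" %in% attr(inst, "pooled_cells"))
  # every participant assigned, including women and the ex-drinker
  expect_false(anyNA(inst$category))
  expect_equal(inst$category[inst$id == 5], "C5") # ex-drinker: same cell
  expect_equal(inst$category[inst$id == 11], "C5") # woman, GG/GG area 1
  # assignment is a deterministic function of genotype and area alone
  key <- paste(inst$g1, inst$g2, inst$area)
  expect_true(all(tapply(inst$category, key,
                         function(z) length(unique(z))) == 1))
})

test_that("category boundaries match the published instrument range", {
  # cell means 4 and 255 are the extremes C1 and C6
  expect_equal(paste0("C", findInterval(c(4, 255, 10, 150, 9.99, 149.9),
                                        c(10, 25, 50, 100, 150)) + 1L),
               c("C1", "C6", "C2", "C6", "C1", "C5"))
})

test_that("IVW combination and regression match hand arithmetic", {
  comb <- ivw_combine(c(0.001, 0.003), c(0.001, 0.002))
  expect_equal(comb$slope, 0.0014)
  expect_equal(comb$se, sqrt(1 / 1.25e6))
  # equal slopes and equal variances: combination returns the common slope
  expect_equal(ivw_combine(c(0.002, 0.002), c(0.01, 0.01))$slope, 0.002)
  # weighted regression on an exact line recovers the slope
  x <- c(5, 50, 120, 200)
  y <- 0.1 + 0.002 * x
  r <- phewasmr:::ivw_regression(x, y, rep(0.04, 4))
  expect_equal(r$slope, 0.002)
})

test_that("sex-heterogeneity test follows the normal-quantile identity", {
  same <- sex_heterogeneity_test(0.002, 0.001, 0.002, 0.003)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  gap <- qnorm(0.975) * sqrt(0.001^2 + 0.0015^2)
  bord <- sex_heterogeneity_test(0.002 + gap, 0.001, 0.002, 0.0015)
  expect_equal(bord$p, 0.05, tolerance = 1e-10)
  expect_error(sex_heterogeneity_test(0.1, NA, 0, 0.1), "standard errors")
})

test_that("with a single area the IVW slope equals that area's slope", {
  cfg <- mr_cfg(n = 12000, confounding = 0, seed = 202)
  cfg$n_areas <- 1L
  cfg$allele_freq_locus1 <- 0.21
  cfg$allele_freq_locus2 <- 0.69
  s <- sim_with_exposure(cfg)
  inst <- derive_genetic_instrument(s$part, s$exposure)
  sv <- extract_first_events(s$events, "R69",
                             s$part[s$part$sex == "M", , drop = FALSE])
  res <- area_stratified_ivw_slope(sv, inst, s$part[s$part$sex == "M", ])
  expect_equal(res$n_areas, 1)
  expect_equal(res$slope, res$per_area$slope[1])
  expect_equal(res$se, res$per_area$se[1])
  expect_equal(res$hr, exp(280 * res$slope))
})

test_that("genotypic category HRs are null when genotype has no intake path", {
  dm <- drinking_model(
    geno_logodds = list(male = c(locus1 = 0, locus2 = 0),
                        female = c(locus1 = 0, locus2 = 0)),
    geno_meanlog_shift = list(male = c(locus1 = 0, locus2 = 0),
                              female = c(locus1 = 0, locus2 = 0)))
  cfg <- sim_config(n_participants = 20000, seed = 404, drinking = dm,
                    endpoints = one_endpoint_table(log(1.5), 0.02),
                    resurvey_fraction = 0)
  s <- sim_with_exposure(cfg)
  inst <- derive_genetic_instrument(s$part, s$exposure)
  men <- s$part[s$part$sex == "M", , drop = FALSE]
  sv <- extract_first_events(s$events, "R69", men)
  prof <- genotypic_category_hrs(sv, inst, men)
  expect_true(all(prof$se_floated > 0))
  covered <- abs(prof$loghr[-1]) <= 1.96 * sqrt(
    prof$var_floated[-1] + prof$var_floated[1])
  expect_gte(mean(covered), 0.5) # most category CIs cover the null
  res <- area_stratified_ivw_slope(sv, inst, men)
  expect_gt(res$p, 0.01)
})

test_that("2SLS flags an irrelevant instrument and recovers a planted effect", {
  # no genotype -> intake path: categories arise from cell-mean noise only
  dm <- drinking_model(
    geno_logodds = list(male = c(locus1 = 0, locus2 = 0),
                        female = c(locus1 = 0, locus2 = 0)),
    geno_meanlog_shift = list(male = c(locus1 = 0, locus2 = 0),
                              female = c(locus1 = 0, locus2 = 0)))
  cfg0 <- sim_config(n_participants = 8000, prop_male = 1, seed = 71,
                     drinking = dm,
                     endpoints = one_endpoint_table(0, 0.02),
                     resurvey_fraction = 0)
  s0 <- sim_with_exposure(cfg0)
  # derive cells on one random half, analyze the other: with no genotype
  # effect the out-of-sample categories carry no information on intake
  set.seed(1)
  half_a <- sample(s0$part$id, 4000)
  inst0 <- derive_genetic_instrument(s0$part, s0$exposure,
                                     male_ids = half_a)
  keep <- !s0$part$id %in% half_a
  p0 <- s0$part[keep, , drop = FALSE]
  sv0 <- extract_first_events(s0$events, "R69", p0)
  expect_warning(
    r0 <- two_stage_least_squares(sv0, inst0, p0,
                                  s0$exposure[keep, , drop = FALSE],
                                  n_boot = 10),
    "weak instrument")
  expect_true(r0$weak_instrument)
  expect_true(is.na(r0$first_stage_F) || r0$first_stage_F < 10)

  # strong instrument, planted HR 1.4 per 280 g/week
  cfg1 <- mr_cfg(n = 25000, confounding = 0, seed = 72)
  cfg1$prop_male <- 1
  s1 <- sim_with_exposure(cfg1)
  inst1 <- derive_genetic_instrument(s1$part, s1$exposure)
  sv1 <- extract_first_events(s1$events, "R69", s1$part)
  r1 <- two_stage_least_squares(sv1, inst1, s1$part, s1$exposure,
                                n_boot = 30)
  expect_false(r1$weak_instrument)
  expect_gt(r1$first_stage_F, 10)
  expect_lt(abs(r1$loghr - log(1.4)), 3 * r1$se)
  # consistency with the IVW-slope route on the same cohort
  ivw <- area_stratified_ivw_slope(sv1, inst1, s1$part)
  expect_lt(abs(r1$loghr - 280 * ivw$slope),
            3 * sqrt(r1$se^2 + (280 * ivw$se)^2))
})
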