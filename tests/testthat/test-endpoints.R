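test_that("ICD-10 chapters map by letter and number blocks", {
  expect_equal(icd10_chapter(c("A15", "C15", "D48", "D69", "E11", "G45",
                               "H25", "H60", "I63", "J18", "K74", "M10",
                               "N20", "O10", "P05", "Q20", "R10", "S72",
                               "T14", "W00", "X60")),
               c("I", "II", "II", "III", "IV", "VI", "VII", "VIII", "IX",
                 "X", "XI", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
                 "XIX", "XIX", "XX", "XX"))
  expect_true(is.na(icd10_chapter("U07")))
})

# fixture: a cohort where endpoint counts around the retention threshold
# are fully controlled
curation_fixture <- function(n80 = 80, n79 = 79) {
  n <- 400
  part <- data.frame(id = seq_len(n), sex = rep(c("M", "F"), each = n / 2),
                     age_baseline = 50, end_age = 62,
                     death_age = NA_real_, censor_age = 62)
  exposure <- data.frame(id = part$id, sex = part$sex,
                         status = rep(c("current", "occasional"),
                                      length.out = n),
                         stringsAsFactors = FALSE)
  cur_m <- exposure$id[exposure$sex == "M" & exposure$status == "current"]
  ev <- rbind(
    data.frame(id = cur_m[seq_len(n80)], code = "K74", age = 55),
    data.frame(id = cur_m[seq_len(n79)], code = "M10", age = 56),
    data.frame(id = cur_m[1:5], code = "O10", age = 57),   # pregnancy ch XV
    data.frame(id = cur_m[1:5], code = "P05", age = 57),   # perinatal XVI
    data.frame(id = cur_m[1:5], code = "Q20", age = 57),   # congenital XVII
    data.frame(id = cur_m[1:3], code = "U07", age = 57))   # invalid
  list(part = part, exposure = exposure, events = ev)
}

test_that("the 80-case rule retains at the boundary and pools below it", {
  fx <- curation_fixture()
  catalog <- load_endpoint_catalog()
  cur <- curate_endpoint_catalog(fx$events, fx$exposure, "M", catalog)
  expect_true("liver_cirrhosis" %in% cur$id)       # exactly 80 cases
  expect_false("gout" %in% cur$id)                 # 79 cases -> pooled
  lc <- cur[cur$id == "less_common_XIII", ]
  expect_equal(nrow(lc), 1)
  expect_equal(lc$codes, "M10")
  expect_equal(lc$n_cases_current, 79)
  expect_false(lc$who_flag)
  # chapter exclusions: XV for men, XVI/XVII always; invalid codes reported
  expect_false(any(cur$chapter %in% c("XV", "XVI", "XVII")))
  expect_equal(attr(cur, "rejected_codes"), "U07")
  # women keep chapter XV codes available for pooling
  cur_f <- curate_endpoint_catalog(fx$events, fx$exposure, "F", catalog,
                                   min_cases = 1)
  expect_false(any(cur_f$chapter %in% c("XVI", "XVII")))
})

test_that("curation is idempotent and covers every retained event code", {
  s <- sim_with_exposure(sim_config(n_participants = 20000, seed = 43))
  cat1 <- curate_endpoint_catalog(s$events, s$exposure, "M",
                                  catalog_from_config(s$coh$config),
                                  min_cases = 40)
  cat2 <- curate_endpoint_catalog(s$events, s$exposure, "M",
                                  catalog_from_config(s$coh$config),
                                  min_cases = 40)
  expect_identical(cat1, cat2)
  # every male event code outside excluded chapters maps to exactly one
  # retained endpoint or less-common pool
  male_ids <- s$exposure$id[s$exposure$sex == "M"]
  codes <- unique(s$events$code[s$events$id %in% male_ids])
  codes <- codes[!icd10_chapter(codes) %in% c("XV", "XVI", "XVII")]
  membership <- vapply(codes, function(cd)
    sum(vapply(strsplit(cat1$codes, ";"), function(cs) cd %in% cs,
               logical(1))), numeric(1))
  expect_true(all(membership == 1))
})

test_that("first events follow the window, death censoring and first-only rule", {
  part <- data.frame(id = 1:4, age_baseline = c(28, 50, 45, 40),
                     end_age = c(70, 60, 70, 70),
                     death_age = c(NA, 60, NA, NA), censor_age = 70)
  ev <- data.frame(id = c(1, 1, 3, 3), code = "K74",
                   age = c(30, 40, 50, 55))
  sv <- extract_first_events(ev, "K74", part)
  sv <- sv[order(sv$id), ]
  # id 1: event at 30 is before the window start and is discarded
  expect_equal(sv$entry[sv$id == 1], 35)
  expect_equal(sv$exit[sv$id == 1], 40)
  expect_equal(sv$event[sv$id == 1], 1L)
  # id 2: death without event -> censored at death
  expect_equal(sv$exit[sv$id == 2], 60)
  expect_equal(sv$event[sv$id == 2], 0L)
  expect_equal(sv$censor_reason[sv$id == 2], "death")
  # id 3: two events -> first one counts
  expect_equal(sv$exit[sv$id == 3], 50)
  expect_equal(sv$event[sv$id == 3], 1L)
  # id 4: no event -> administrative censoring
  expect_equal(sv$event[sv$id == 4], 0L)
  # events outside follow-up are a data-integrity error
  bad <- data.frame(id = 2, code = "K74", age = 65)
  expect_error(extract_first_events(bad, "K74", part), "follow-up")
})

test_that("age-85 truncation censors long follow-up", {
  part <- data.frame(id = 1, age_baseline = 80, end_age = 92,
                     death_age = NA_real_, censor_age = 92)
  sv <- extract_first_events(data.frame(id = integer(), code = character(),
                                        age = numeric()), "K74", part)
  expect_equal(sv$exit, 85)
  expect_equal(sv$censor_reason, "age-85")
})

test_that("aggregates take the earliest member event", {
  catalog <- data.frame(id = c("a", "b"), label = c("A", "B"),
                        codes = c("K70", "K74"), chapter = "XI",
                        who_flag = TRUE, stringsAsFactors = FALSE)
  part <- data.frame(id = 1:2, age_baseline = 40, end_age = 70,
                     death_age = NA_real_, censor_age = 70)
  ev <- data.frame(id = c(1, 1), code = c("K70", "K74"), age = c(50, 45))
  agg <- build_aggregate_endpoint(catalog, c("a", "b"), ev, part)
  expect_equal(agg$exit[agg$id == 1], 45)
  # aggregate of a single endpoint equals that endpoint's dataset
  single <- build_aggregate_endpoint(catalog, "b", ev, part)
  expect_equal(single, extract_first_events(ev, "K74", part))
  expect_error(build_aggregate_endpoint(catalog, character(), ev, part),
               "at least one member")
  # summed member first-event counts bound the aggregate count
  s <- sim_with_exposure(sim_config(n_participants = 8000, seed = 3))
  cfg_cat <- catalog_from_config(s$coh$config)
  members <- c("liver_cirrhosis", "gout", "cataract")
  agg2 <- build_aggregate_endpoint(cfg_cat, members, s$events, s$part)
  indiv <- vapply(members, function(mid)
    sum(extract_first_events(
      s$events, strsplit(cfg_cat$codes[cfg_cat$id == mid], ";")[[1]],
      s$part)$event), numeric(1))
  expect_lte(sum(agg2$event), sum(indiv))
})
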