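# Shared simulation scenarios. Generator parameters are the study
# conditions; scenario-specific deviations (e.g. a single planted endpoint,
# no ex-drinkers in the instrument-recovery scenario) are part of the
# scenario definition, fixed here once.

one_endpoint_table <- function(beta, rate = 0.02, code = "R69",
                               id = "morbidity", who = FALSE) {
  data.frame(id = id, label = "All morbidity", codes = code,
             chapter = icd10_chapter(code), who_flag = who,
             loghr_per_280 = beta, rate = rate, stringsAsFactors = FALSE)
}

# conventional-arm parameter recovery scenario: one endpoint with a planted
# log-linear effect per 280 g/week usual intake
recovery_cfg <- function(n = 50000, beta = log(1.5), rate = 8e-4,
                         seed = 1) {
  sim_config(n_participants = n, seed = seed,
             endpoints = one_endpoint_table(beta, rate),
             resurvey_fraction = 0)
}

# MR scenario: genotype-mediated intake, area-level confounding aligned
# with the allele-frequency gradient, no ex-drinkers (the instrument's
# cell means then equal the mean usual intake of every man in the cell)
# and no genotype -> intake path in women (pleiotropy-free by design)
mr_cfg <- function(n = 40000, beta = log(1.4), rate = 0.02,
                   confounding = 0.3, seed = 1) {
  dm <- drinking_model(
    ex_fraction = c(male = 0, female = 0),
    geno_logodds = list(male = c(locus1 = -1.60, locus2 = -0.35),
                        female = c(locus1 = 0, locus2 = 0)),
    geno_meanlog_shift = list(male = c(locus1 = -0.40, locus2 = -0.15),
                              female = c(locus1 = 0, locus2 = 0)))
  sim_config(n_participants = n, seed = seed, drinking = dm,
             endpoints = one_endpoint_table(beta, rate),
             area_confounding = confounding,
             resurvey_fraction = 0)
}

# all-null phenome scenario across several chapters
null_scan_cfg <- function(n = 15000, seed = 1) {
  ep <- default_endpoint_effects()
  ep$loghr_per_280 <- 0
  sim_config(n_participants = n, seed = seed, endpoints = ep,
             resurvey_fraction = 0)
}

sim_with_exposure <- function(cfg) {
  coh <- simulate_cohort(cfg)
  list(coh = coh, part = coh$participants, events = coh$events,
       exposure = derive_exposure(coh$participants))
}
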