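# Off-label rule engine: the four label criteria plus the adult rules.

ofl_one <- function(rx, config = "sweden", patient = NULL, diagnoses = NULL) {
  if (is.null(patient)) patient <- mk_patient("A")
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(patient_id = character(), code_class = character(),
                            diagnosis_date = as.Date(character()))
  }
  evaluate_offlabel(patient, rx, diagnoses, config)
}

test_that("prior-diagnosis criterion uses strictly-before and source capability", {
  dx <- data.frame(patient_id = "A", code_class = "ADHD", diagnosis_date = D0 - 1)
  f <- ofl_one(mk_rx("A", "LDX", 0), diagnoses = dx)
  expect_false(f$no_prior_diagnosis)

  f2 <- ofl_one(mk_rx("A", "LDX", 0))  # no diagnosis records, source records them
  expect_true(f2$no_prior_diagnosis)

  # a diagnosis on the same day as the first prescription is not "before"
  dx3 <- data.frame(patient_id = "A", code_class = "ADHD", diagnosis_date = D0)
  expect_true(ofl_one(mk_rx("A", "LDX", 0), diagnoses = dx3)$no_prior_diagnosis)

  # Swiss pharmacy panels cannot evaluate the criterion
  ch <- mk_patient("A", source_id = "ch_ppp")
  f4 <- ofl_one(mk_rx("A", "LDX", 0), config = "switzerland", patient = ch)
  expect_true(is.na(f4$no_prior_diagnosis))
})

test_that("prior-MPH criterion requires 365 days of enrolment history", {
  pat_long <- mk_patient("A", start = D0 - 1100)
  rx <- rbind(mk_rx("A", "MPH", -730), mk_rx("A", "LDX", 0))
  f <- ofl_one(rx, patient = pat_long)
  expect_false(f$no_prior_mph)
  expect_true(f$mph_evaluable)

  f2 <- ofl_one(mk_rx("A", "LDX", 0), patient = pat_long)  # no MPH at all
  expect_true(f2$no_prior_mph)

  pat_short <- mk_patient("A", start = D0 - 100)
  f3 <- ofl_one(mk_rx("A", "LDX", 0), patient = pat_short)
  expect_true(is.na(f3$no_prior_mph))
  expect_false(f3$mph_evaluable)
})

test_that("age and dose criteria use year-granular age and a strict cap", {
  # age 5 at prescription (birth 2010, rx 2015)
  f <- ofl_one(mk_rx("A", "LDX", 0), patient = mk_patient("A", birth_year = 2010))
  expect_true(f$under_min_age)
  expect_equal(f$age_first_ldx, 5)

  f2 <- ofl_one(mk_rx("A", "LDX", 0), patient = mk_patient("A", birth_year = 2009))
  expect_false(f2$under_min_age)

  # steady 70 mg/day sits on the boundary: "exceeding" means strictly above
  expect_false(ofl_one(mk_rx("A", "LDX", 0, dose = 70))$dose_exceeds_cap)
  expect_true(ofl_one(mk_rx("A", "LDX", 0, dose = 75))$dose_exceeds_cap)

  # missing birth year (self-dispensing-panel-like) propagates not-evaluable
  ch <- mk_patient("A", birth_year = NA, source_id = "ch_sdpp")
  f3 <- ofl_one(mk_rx("A", "LDX", 0), config = "switzerland", patient = ch)
  expect_true(is.na(f3$under_min_age))
  expect_true(is.na(f3$adult_off_label))
})

test_that("adult use follows approval dates, age caps and continuation", {
  rx16 <- mk_rx("A", "LDX", 365)  # issued 2016-01-01
  srcs <- c(sweden = "se_registry", norway = "no_registry")
  adult30 <- function(cfg_key, rx) {
    ofl_one(rx, config = cfg_key,
            patient = mk_patient("A", birth_year = 1986,
                                 source_id = srcs[[cfg_key]]))$adult_off_label
  }
  # Sweden approved adults in 2015: a 30-year-old in 2016 is on-label
  expect_false(adult30("sweden", rx16))
  # Norway had no adult approval in the window: off-label
  expect_true(adult30("norway", rx16))
  # before the approval date the same Swedish prescription is off-label
  rx14 <- mk_rx("A", "LDX", -200)  # 2014-06-15
  expect_true(adult30("sweden", rx14))

  # Switzerland: approved for adults up to 55
  ch_rx <- mk_rx("A", "LDX", 365)
  f45 <- ofl_one(ch_rx, config = "switzerland",
                 patient = mk_patient("A", birth_year = 1971, source_id = "ch_ppp"))
  expect_false(f45$adult_off_label)
  f60 <- ofl_one(ch_rx, config = "switzerland",
                 patient = mk_patient("A", birth_year = 1956, source_id = "ch_ppp"))
  expect_true(f60$adult_off_label)
})

test_that("continuation from adolescence exempts adults within an unbroken episode", {
  # patient turns 19 during therapy started at 18 (birth 1997; rx years 2015/2016)
  pat <- mk_patient("A", birth_year = 1997, source_id = "no_registry")
  rx <- mk_rx("A", "LDX", seq(330, 450, by = 30))  # unbroken episode crossing 2016
  f <- ofl_one(rx, config = "norway", patient = pat)
  expect_false(f$adult_off_label)

  # a break above the grace period before the adult prescription removes it
  rx2 <- rbind(mk_rx("A", "LDX", 330), mk_rx("A", "LDX", 500))
  f2 <- ofl_one(rx2, config = "norway", patient = pat)
  expect_true(f2$adult_off_label)
})

test_that("the rule engine is declarative and monotone in the approval date", {
  co <- simulate_cohort(simulation_config(n_patients = 250, seed = 37,
                                          country = "norway"))
  base_cfg <- co$country_config
  dates <- list(NULL, "2016-06-01", "2015-06-01", "2014-09-01")
  flags <- lapply(dates, function(d) {
    cfg <- base_cfg
    cfg$adult_approval_date <- if (is.null(d)) as.Date(NA) else as.Date(d)
    evaluate_offlabel(co$patients, co$prescriptions, co$diagnoses, cfg)
  })
  # only the adult flag may change between configs
  for (f in c("no_prior_diagnosis", "no_prior_mph", "under_min_age", "dose_exceeds_cap")) {
    for (k in 2:4) expect_identical(flags[[k]][[f]], flags[[1]][[f]])
  }
  counts <- vapply(flags, function(f) sum(f$adult_off_label, na.rm = TRUE), 0)
  expect_true(all(diff(counts) <= 0))  # earlier approval, never more off-label
})

test_that("not-evaluable flags never contribute to any_off_label", {
  pat <- mk_patient("A", birth_year = NA, start = D0 - 100, source_id = "ch_sdpp")
  f <- ofl_one(mk_rx("A", "LDX", 0, dose = 50), config = "switzerland", patient = pat)
  expect_true(is.na(f$no_prior_diagnosis))
  expect_true(is.na(f$no_prior_mph))
  expect_true(is.na(f$under_min_age))
  expect_true(is.na(f$adult_off_label))
  expect_false(f$any_off_label)
})
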