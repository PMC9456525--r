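spec0 <- cohort_spec()

test_that("new-user identification applies window, washout and dual-initiation rules", {
  disp <- data.frame(
    patient_id = c("p1", "p2", "p2", "p3", "p3", "p4"),
    date = as.Date(c("2017-05-01",                      # clean metformin start
                     "2017-05-01", "2017-03-15",        # washout violation
                     "2017-05-10", "2017-05-10",        # dual initiation
                     "2017-08-01")),                    # outside window
    drug_class = c("metformin", "dpp4", "metformin", "dpp4", "metformin", "dpp4"))
  ds <- make_claims(simple_patient(c("p1", "p2", "p3", "p4")),
                    full_enrollment(c("p1", "p2", "p3", "p4")), disp)
  cand <- identify_new_users(ds, spec0)
  expect_equal(cand$patient_id, "p1")
  expect_equal(cand$group, "comparator")
  expect_equal(cand$index_date, as.Date("2017-05-01"))
  expect_equal(attr(cand, "attrition")[["washout"]], 1L)
  expect_equal(attr(cand, "attrition")[["dual"]], 1L)
})

test_that("a study-drug fill just outside the washout window does not exclude", {
  # washout window is (index - 3 months, index): 91.3 days
  disp <- data.frame(patient_id = c("p1", "p1"),
                     date = as.Date(c("2017-06-01", "2017-02-20")),
                     drug_class = "dpp4")
  ds <- make_claims(simple_patient("p1"), full_enrollment("p1"), disp)
  expect_equal(nrow(identify_new_users(ds, spec0)), 1L)
})

test_that("exclusion rules fire and are attributed in flowchart order", {
  ids <- c("p1", "p2", "p3", "p4")
  disp <- data.frame(patient_id = c(ids, "p2"),
                     date = as.Date(c(rep("2017-05-01", 4), "2016-09-01")),
                     drug_class = c(rep("dpp4", 4), "opioid"))
  dx <- data.frame(patient_id = "p1", date = as.Date("2017-04-01"),
                   icd10 = "I639", primary_at_admission = TRUE)  # stroke 1 month pre-index
  pats <- simple_patient(ids)
  pats$birth_date[3] <- as.Date("1940-01-01")  # aged >= 75 at index
  enr <- full_enrollment(ids)
  enr$end[4] <- as.Date("2017-04-20")          # not enrolled through index
  ds <- make_claims(pats, enr, disp, dx)
  spec <- cohort_spec(controlled_drug_classes = "opioid")
  cand <- identify_new_users(ds, spec)
  coh <- apply_exclusions(cand, ds, spec)
  att <- attr(coh, "attrition")
  expect_equal(nrow(coh), 0L)
  expect_equal(att[["prior_event"]], 1L)
  expect_equal(att[["controlled_drug"]], 1L)
  expect_equal(att[["age"]], 1L)
  expect_equal(att[["enrollment"]], 1L)
  expect_equal(att[["candidates"]] - sum(att[c("prior_event", "controlled_drug",
                                               "age", "enrollment")]),
               att[["cohort"]])
})

test_that("clean candidates pass through exclusions unchanged", {
  disp <- data.frame(patient_id = c("p1", "p2"),
                     date = as.Date("2017-05-01"),
                     drug_class = c("dpp4", "metformin"))
  ds <- make_claims(simple_patient(c("p1", "p2")),
                    full_enrollment(c("p1", "p2")), disp)
  cand <- identify_new_users(ds, spec0)
  coh <- apply_exclusions(cand, ds, spec0)
  expect_equal(coh$patient_id, cand$patient_id)
  expect_equal(attr(coh, "attrition")[["cohort"]], 2L)
})

test_that("planted generator violations reproduce the attrition counts exactly", {
  cfg <- claims_sim_config(n_patients = 1500, seed = 66,
                           frac_prior_event = 0.04, frac_controlled_drug = 0.03,
                           frac_elderly = 0.02, frac_washout_violation = 0.02)
  ds <- generate_claims_population(cfg)
  spec <- cohort_spec(controlled_drug_classes = "controlled_drug")
  cand <- identify_new_users(ds, spec)
  coh <- apply_exclusions(cand, ds, spec)
  expect_equal(attr(cand, "attrition")[["washout"]], 30L)
  att <- attr(coh, "attrition")
  expect_equal(att[["prior_event"]], 60L)
  expect_equal(att[["controlled_drug"]], 45L)
  expect_equal(att[["age"]], 30L)
  expect_equal(att[["cohort"]], 1500L - 30L - 60L - 45L - 30L - att[["enrollment"]])
})

test_that("follow-up records implement outcome, censoring and the month scale", {
  ids <- c("p1", "p2", "p3")
  disp <- data.frame(patient_id = ids, date = as.Date("2017-05-01"),
                     drug_class = c("dpp4", "metformin", "dpp4"))
  dx <- data.frame(
    patient_id = c("p1", "p1", "p3"),
    date = as.Date(c("2018-03-01", "2019-01-01", "2017-05-01")),
    icd10 = c("I219", "I219", "I500"),
    primary_at_admission = c(TRUE, TRUE, TRUE))
  enr <- full_enrollment(ids)
  enr$end[2] <- as.Date("2018-11-01")  # ~18 months, disenrollment
  enr$end_reason[2] <- "disenrollment"
  ds <- make_claims(simple_patient(ids), enr, disp, dx)
  cand <- identify_new_users(ds, spec0)

  fu <- build_followup(cand, ds, "myocardial_infarction", spec0)
  p1 <- fu[fu$patient_id == "p1", ]
  expect_true(p1$event)
  expect_equal(p1$censor_reason, "outcome")
  expect_equal(p1$time_months, 304 / 30.4375)  # first qualifying diagnosis
  p2 <- fu[fu$patient_id == "p2", ]
  expect_false(p2$event)
  expect_equal(p2$censor_reason, "disenrollment")
  expect_equal(p2$time_months, 549 / 30.4375, tolerance = 1e-10)

  # index-date heart-failure diagnosis: event at half a day
  fu_hf <- build_followup(cand, ds, "heart_failure", spec0)
  p3 <- fu_hf[fu_hf$patient_id == "p3", ]
  expect_true(p3$event)
  expect_equal(p3$time_months, 0.5 / 30.4375)
  expect_true(all(fu$time_months > 0) && all(fu_hf$time_months > 0))

  expect_error(build_followup(cand, ds, "no_such_outcome", spec0),
               "unknown outcome")
})

test_that("censoring at the 75th birthday precedes the study end", {
  disp <- data.frame(patient_id = "p1", date = as.Date("2017-05-01"),
                     drug_class = "dpp4")
  pats <- simple_patient("p1", birth = as.Date("1943-06-15"))  # turns 75 in 2018
  ds <- make_claims(pats, full_enrollment("p1"), disp)
  fu <- build_followup(identify_new_users(ds, spec0), ds,
                       "major_cardiovascular_events", spec0)
  expect_equal(fu$censor_reason, "age75")
  expect_lt(fu$time_months, 16)
})

test_that("cohort and follow-up match the brute-force per-patient scan", {
  cfg <- claims_sim_config(n_patients = 400, seed = 99,
                           frac_prior_event = 0.05, frac_controlled_drug = 0.04,
                           frac_elderly = 0.03, frac_washout_violation = 0.03)
  ds <- generate_claims_population(cfg)
  spec <- cohort_spec(controlled_drug_classes = "controlled_drug")
  cand <- identify_new_users(ds, spec)
  coh <- apply_exclusions(cand, ds, spec)
  oracle <- oracle_cohort(ds, spec)
  expect_equal(coh$patient_id, oracle$cohort$patient_id)
  expect_equal(coh$group, oracle$cohort$group)
  expect_equal(coh$index_date, oracle$cohort$index_date)
  expect_equal(attr(coh, "attrition")[["prior_event"]],
               sum(oracle$exclusion_reasons == "prior_event"))
  expect_equal(attr(coh, "attrition")[["controlled_drug"]],
               sum(oracle$exclusion_reasons == "controlled_drug"))

  fu <- build_followup(coh, ds, "major_cardiovascular_events", spec)
  ofu <- oracle_followup(coh, ds, "major_cardiovascular_events", spec)
  expect_equal(fu$event, ofu$event)
  expect_equal(fu$time_months, ofu$time_months)

  # structural invariants
  expect_false(any(duplicated(fu$patient_id)))
  expect_true(all(fu$index_date >= spec$enrollment_window[1] &
                    fu$index_date <= spec$enrollment_window[2]))
})
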