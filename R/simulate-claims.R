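#' Configuration for the claims-population simulator
#'
#' Describes a synthetic health-insurance claims population of working-age
#' adults (the source population is capped below 75 years, as in Japanese
#' employer-based claims data) initiating one of two antidiabetic drug
#' classes, with a configurable confounding channel: baseline covariates
#' act on both the treatment-assignment logit and the outcome hazards.
#' Outcome diagnosis streams are generated per event type (myocardial
#' infarction, stroke, heart failure); composite outcomes such as major
#' cardiovascular events arise downstream as code-prefix unions, the way
#' they do in real claims analyses.
#'
#' Default calendar geometry — initiation window 2017-04-01..2017-06-30,
#' study end 2020-06-30 — and the default disenrollment hazard of 0.004
#' per person-month give a mean observable follow-up of about 33 months.
#' Default baseline hazards (events per person-month) are calibrated to
#' cumulative risks of roughly 4% (myocardial infarction), 6% (stroke) and
#' 11% (heart failure) over that horizon, hence about 10% for their
#' major-cardiovascular-events union.
#'
#' @param n_patients Number of patients (>= 2). The default 8400 is the
#'   scale of the source study's pre-match cohort (5531 + 2857 initiators),
#'   which with the default assignment model yields roughly 2500 matched
#'   pairs.
#' @param age_mean,age_sd Mean/SD of age at index (years), truncated to
#'   `(age_min, age_max)`; defaults 52.2 and 9.74.
#' @param age_min,age_max Truncation bounds; `age_max` must stay below 75.
#' @param male_share Probability of male sex (default 0.703).
#' @param covariate_effects_treatment Numeric vector of log-odds effects of
#'   the standard-normal covariates on treatment assignment; its length
#'   defines the number of covariates.
#' @param covariate_effects_outcome Log-hazard effects of the same
#'   covariates on every outcome process (same length).
#' @param treatment_intercept Intercept of the assignment logit; the default
#'   0.7 yields roughly two treated initiators per comparator initiator.
#' @param baseline_hazard Named positive vector, events per person-month,
#'   one entry per outcome process.
#' @param true_hr Named positive vector, multiplicative treatment effect on
#'   each outcome hazard; names must match `baseline_hazard`.
#' @param censoring_hazard Disenrollment hazard per person-month (death and
#'   migration folded into a single censoring process).
#' @param max_followup_months Administrative cap on follow-up (default Inf;
#'   the study end usually binds first).
#' @param weibull_shape Shape of the event-time distribution; 1 (default)
#'   gives constant hazards, other values stress the proportional-hazards
#'   assumption while keeping the same cumulative-hazard scale.
#' @param enrollment_window Character or Date length-2: initiation window.
#' @param study_end Study termination date.
#' @param frac_prior_event,frac_controlled_drug,frac_elderly,frac_washout_violation
#'   Fractions of patients planted (on disjoint subsets) with, respectively,
#'   a primary cardiovascular diagnosis shortly before index, a
#'   controlled-drug dispensing within the prior year, an index age of 75+,
#'   and a study-drug fill inside the washout window. All default to 0;
#'   they exist so exclusion-rule accounting can be checked against known
#'   ground truth.
#' @param seed RNG seed.
#' @return An object of class `claims_sim_config`.
#' @export
claims_sim_config <- function(n_patients = 8400,
                              age_mean = 52.2, age_sd = 9.74,
                              age_min = 20, age_max = 74.9,
                              male_share = 0.703,
                              covariate_effects_treatment = c(0.5, 0.5, 0.3),
                              covariate_effects_outcome = c(0.5, 0.3, 0.2),
                              treatment_intercept = 0.7,
                              baseline_hazard = c(myocardial_infarction = 0.00135,
                                                  stroke = 0.0019,
                                                  heart_failure = 0.0036),
                              true_hr = c(myocardial_infarction = 1,
                                          stroke = 1,
                                          heart_failure = 1),
                              censoring_hazard = 0.004,
                              max_followup_months = Inf,
                              weibull_shape = 1,
                              enrollment_window = c("2017-04-01", "2017-06-30"),
                              study_end = "2020-06-30",
                              frac_prior_event = 0,
                              frac_controlled_drug = 0,
                              frac_elderly = 0,
                              frac_washout_violation = 0,
                              seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2 || n_patients != round(n_patients))
    stop_config("n_patients", "must be an integer >= 2")
  if (any(baseline_hazard <= 0))
    stop_config("baseline_hazard", "hazards must be strictly positive")
  if (censoring_hazard < 0)
    stop_config("censoring_hazard", "must be non-negative")
  if (any(true_hr <= 0))
    stop_config("true_hr", "hazard ratios must be strictly positive")
  if (is.null(names(baseline_hazard)) || is.null(names(true_hr)) ||
      !setequal(names(baseline_hazard), names(true_hr)))
    stop_config("true_hr", "must carry the same outcome names as baseline_hazard")
  if (length(covariate_effects_outcome) != length(covariate_effects_treatment))
    stop_config("covariate_effects_outcome",
                "must have the same length as covariate_effects_treatment")
  if (age_max >= 75)
    stop_config("age_max", "source population is capped below 75 years")
  if (weibull_shape <= 0) stop_config("weibull_shape", "must be positive")
  window <- as_date(enrollment_window)
  study_end <- as_date(study_end)
  if (window[1] > window[2] || window[2] > study_end)
    stop_config("enrollment_window", "requires start <= end <= study_end")
  structure(list(n_patients = as.integer(n_patients),
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 male_share = male_share,
                 covariate_effects_treatment = covariate_effects_treatment,
                 covariate_effects_outcome = covariate_effects_outcome,
                 treatment_intercept = treatment_intercept,
                 baseline_hazard = baseline_hazard,
                 true_hr = true_hr[names(baseline_hazard)],
                 censoring_hazard = censoring_hazard,
                 max_followup_months = max_followup_months,
                 weibull_shape = weibull_shape,
                 enrollment_window = window,
                 study_end = study_end,
                 frac_prior_event = frac_prior_event,
                 frac_controlled_drug = frac_controlled_drug,
                 frac_elderly = frac_elderly,
                 frac_washout_violation = frac_washout_violation,
                 seed = as.integer(seed)),
            class = "claims_sim_config")
}

# ICD-10-style codes emitted per outcome process (prefix-matchable).
.sim_icd_codes <- list(
  myocardial_infarction = c("I210", "I219", "I220"),
  stroke = c("I600", "I610", "I630", "I639"),
  heart_failure = c("I500", "I509"))

#' Simulate a claims population
#'
#' Generates patients (age truncated below 75 at index, sex, standard-normal
#' covariates), one initiation dispensing per patient on a uniformly drawn
#' index date inside the enrollment window (class assigned by the logistic
#' assignment model), enrollment intervals that open well before the washout
#' window and close at the earliest of a disenrollment time (exponential
#' with the censoring hazard, folding death and migration together), the
#' administrative follow-up cap and the study end, and dated diagnosis
#' records: per outcome process a Weibull event time with cumulative hazard
#' baseline * exp(covariate effects) * true_hr^treated * t^shape, recorded
#' as a primary-at-admission diagnosis only while the patient is enrolled,
#' plus non-primary background diagnoses. Deterministic given the config.
#'
#' @param config A [claims_sim_config()].
#' @return A `claims_dataset`: list of data frames `patients`, `enrollment`,
#'   `dispensings`, `diagnoses`, plus `truth` (treatment flag, true event
#'   times in months, planted-violation flags) and the config.
#' @export
generate_claims_population <- function(config) {
  stopifnot(inherits(config, "claims_sim_config"))
  n <- config$n_patients
  k <- length(config$covariate_effects_treatment)
  outcomes <- names(config$baseline_hazard)
  with_seed(config$seed, {
    patient_id <- sprintf("P%06d", seq_len(n))
    index_date <- config$enrollment_window[1] +
      sample.int(as.integer(config$enrollment_window[2] -
                              config$enrollment_window[1]) + 1L, n,
                 replace = TRUE) - 1L
    lo <- stats::pnorm(config$age_min, config$age_mean, config$age_sd)
    hi <- stats::pnorm(config$age_max, config$age_mean, config$age_sd)
    age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
    sex <- ifelse(stats::runif(n) < config$male_share, "male", "female")
    X <- matrix(stats::rnorm(n * k), nrow = n,
                dimnames = list(NULL, sprintf("x%d", seq_len(k))))

    # disjoint planted-violation subsets, in a single shuffled order
    planted <- sample.int(n)
    take <- function(frac, used) {
      m <- round(frac * n)
      if (m == 0L) return(integer())
      avail <- setdiff(planted, used)
      avail[seq_len(m)]
    }
    idx_prior <- take(config$frac_prior_event, integer())
    idx_ctrl <- take(config$frac_controlled_drug, idx_prior)
    idx_old <- take(config$frac_elderly, c(idx_prior, idx_ctrl))
    idx_wash <- take(config$frac_washout_violation, c(idx_prior, idx_ctrl, idx_old))
    age[idx_old] <- stats::runif(length(idx_old), 75, 80)
    birth_date <- index_date - round(age * 365.25)

    eta <- config$treatment_intercept +
      drop(X %*% config$covariate_effects_treatment)
    treated <- stats::runif(n) < stats::plogis(eta)

    # enrollment: opens 400-900 days pre-index, closes at disenrollment /
    # follow-up cap / study end, whichever first
    enroll_start <- index_date - sample(400:900, n, replace = TRUE)
    t_dis <- if (config$censoring_hazard > 0)
      stats::rexp(n, config$censoring_hazard) else rep(Inf, n)
    t_dis <- pmin(t_dis, config$max_followup_months)
    end_cal <- index_date + round(months_to_days(t_dis))
    disenrolled <- end_cal < config$study_end
    enroll_end <- pmin(end_cal, config$study_end)
    enrollment <- data.frame(
      patient_id = patient_id,
      start = enroll_start,
      end = enroll_end,
      end_reason = ifelse(disenrolled, "disenrollment", "study_end"))

    disp <- list(data.frame(
      patient_id = patient_id,
      date = index_date,
      drug_class = ifelse(treated, "dpp4", "metformin")))
    if (length(idx_wash))
      # one day before the window opens: outside the initiation window for
      # every index date, inside the 3-month washout for every index date
      disp[[2L]] <- data.frame(
        patient_id = patient_id[idx_wash],
        date = config$enrollment_window[1] - 1L,
        drug_class = ifelse(treated[idx_wash], "dpp4", "metformin"))
    if (length(idx_ctrl))
      disp[[length(disp) + 1L]] <- data.frame(
        patient_id = patient_id[idx_ctrl],
        date = index_date[idx_ctrl] -
          round(stats::runif(length(idx_ctrl), 30, 330)),
        drug_class = "controlled_drug")
    dispensings <- do.call(rbind, disp)

    risk_mult <- exp(drop(X %*% config$covariate_effects_outcome))
    dx <- list()
    truth_times <- matrix(NA_real_, n, length(outcomes),
                          dimnames = list(NULL, outcomes))
    for (o in outcomes) {
      lambda <- config$baseline_hazard[[o]] * risk_mult *
        ifelse(treated, config$true_hr[[o]], 1)
      # inverse-CDF Weibull with cumulative hazard lambda * t^shape
      t_ev <- (stats::rexp(n) / lambda)^(1 / config$weibull_shape)
      truth_times[, o] <- t_ev
      dx_date <- index_date + round(months_to_days(t_ev))
      observed <- dx_date <= enroll_end  # claims stop at disenrollment
      if (any(observed))
        dx[[length(dx) + 1L]] <- data.frame(
          patient_id = patient_id[observed],
          date = dx_date[observed],
          icd10 = sample(.sim_icd_codes[[o]], sum(observed), replace = TRUE),
          primary_at_admission = TRUE)
    }
    if (length(idx_prior))
      dx[[length(dx) + 1L]] <- data.frame(
        patient_id = patient_id[idx_prior],
        date = index_date[idx_prior] -
          round(stats::runif(length(idx_prior), 5, 85)),
        icd10 = sample(c("I219", "I639"), length(idx_prior), replace = TRUE),
        primary_at_admission = TRUE)
    # non-primary background diagnoses (diabetes, hypertension)
    n_noise <- stats::rpois(n, 1)
    noise_pat <- rep(patient_id, n_noise)
    if (length(noise_pat)) {
      noise_start <- rep(enroll_start, n_noise)
      noise_span <- as.integer(rep(enroll_end, n_noise) - noise_start)
      dx[[length(dx) + 1L]] <- data.frame(
        patient_id = noise_pat,
        date = noise_start + floor(stats::runif(length(noise_pat)) * (noise_span + 1)),
        icd10 = sample(c("E11", "I10"), length(noise_pat), replace = TRUE),
        primary_at_admission = FALSE)
    }
    diagnoses <- do.call(rbind, dx)
    diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date), ]
    rownames(diagnoses) <- NULL

    patients <- data.frame(patient_id = patient_id, birth_date = birth_date,
                           sex = sex)
    patients <- cbind(patients, as.data.frame(X))
    truth <- data.frame(patient_id = patient_id, treated = treated,
                        index_date = index_date, age_at_index = age)
    truth <- cbind(truth, as.data.frame(truth_times))
    truth$planted_prior_event <- seq_len(n) %in% idx_prior
    truth$planted_controlled_drug <- seq_len(n) %in% idx_ctrl
    truth$planted_elderly <- seq_len(n) %in% idx_old
    truth$planted_washout <- seq_len(n) %in% idx_wash

    structure(list(patients = patients, enrollment = enrollment,
                   dispensings = dispensings, diagnoses = diagnoses,
                   truth = truth, config = config),
              class = "claims_dataset")
  })
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat(sprintf(paste0("claims dataset: %d patients, %d dispensing rows, ",
                     "%d diagnosis rows\n"),
              nrow(x$patients), nrow(x$dispensings), nrow(x$diagnoses)))
  invisible(x)
}

#' Write / read a claims dataset as delimited text
#'
#' Four tab-separated files (`patients.tsv`, `enrollment.tsv`,
#' `dispensings.tsv`, `diagnoses.tsv`) with ISO-8601 dates. The ground-truth
#' table is not serialised: files are the interface a real extract would
#' present.
#'
#' @param dataset A `claims_dataset`.
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(dataset, dir) {
  stopifnot(inherits(dataset, "claims_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tbl in c("patients", "enrollment", "dispensings", "diagnoses"))
    utils::write.table(dataset[[tbl]], file.path(dir, paste0(tbl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  read1 <- function(name, date_cols) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) stop(sprintf("claims table not found: %s", path))
    df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
    for (dc in intersect(date_cols, names(df))) df[[dc]] <- as_date(df[[dc]])
    df
  }
  patients <- read1("patients", "birth_date")
  for (cv in setdiff(names(patients), c("patient_id", "birth_date", "sex")))
    patients[[cv]] <- as.numeric(patients[[cv]])
  diagnoses <- read1("diagnoses", "date")
  diagnoses$primary_at_admission <- diagnoses$primary_at_admission == "TRUE"
  structure(list(patients = patients,
                 enrollment = read1("enrollment", c("start", "end")),
                 dispensings = read1("dispensings", "date"),
                 diagnoses = diagnoses,
                 truth = NULL, config = NULL),
            class = "claims_dataset")
}

#' Simulate follow-up records directly
#'
#' Micro-generator for the survival stage alone: two arms of exponential
#' event times (hazard `event_hazard`, multiplied by `true_hr` in the
#' treatment arm) under independent exponential censoring and an
#' administrative cap. Useful for operating-characteristic studies (CI
#' coverage, non-inferiority power) where the cohort-building machinery is
#' not under study.
#'
#' @param n_per_group Subjects per arm.
#' @param event_hazard Events per person-month in the comparator arm.
#' @param true_hr Treatment hazard ratio.
#' @param censoring_hazard Censoring events per person-month.
#' @param max_months Administrative censoring time.
#' @param seed RNG seed.
#' @return A `followup` data frame (see [build_followup()]).
#' @export
simulate_followup <- function(n_per_group, event_hazard, true_hr = 1,
                              censoring_hazard = 0, max_months = 37.5,
                              seed = 1L) {
  stopifnot(event_hazard > 0, true_hr > 0, n_per_group >= 1)
  with_seed(seed, {
    n <- 2L * n_per_group
    group <- rep(c("comparator", "treatment"), each = n_per_group)
    haz <- event_hazard * ifelse(group == "treatment", true_hr, 1)
    t_ev <- stats::rexp(n, haz)
    t_cn <- if (censoring_hazard > 0) stats::rexp(n, censoring_hazard) else rep(Inf, n)
    t_cn <- pmin(t_cn, max_months)
    event <- t_ev <= t_cn
    followup_frame(data.frame(
      patient_id = sprintf("S%06d", seq_len(n)),
      group = group,
      index_date = as.Date("2017-05-15"),
      time_months = pmin(t_ev, t_cn),
      event = event,
      censor_reason = ifelse(event, "outcome",
                             ifelse(t_cn < max_months, "disenrollment",
                                    "study_end"))))
  })
}
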