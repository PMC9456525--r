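# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (per-case loops, dense grids) so the package
# implementations are checked against a second, unrelated route.

# --- contingency: double loop over cases ------------------------------------
oracle_contingency <- function(reports, drug, event, suspect_only = TRUE) {
  members <- setdiff(drug$members, drug$exclude_names)
  drugs_by_case <- split(reports$drugs, reports$drugs$case_id)
  events_by_case <- split(reports$events$event_pt, reports$events$case_id)
  n11 <- n1 <- n2 <- 0L
  for (cid in reports$case_ids) {
    d <- drugs_by_case[[cid]]
    if (!is.null(d) && suspect_only) d <- d[d$role == "suspect", , drop = FALSE]
    has_d <- !is.null(d) && any(d$drug %in% members)
    has_e <- !is.null(events_by_case[[cid]]) &&
      any(events_by_case[[cid]] %in% event$pt_terms)
    n1 <- n1 + has_d
    n2 <- n2 + has_e
    n11 <- n11 + (has_d && has_e)
  }
  c(n11 = n11, n1dot = n1, ndot1 = n2, ndotdot = length(reports$case_ids))
}

# --- Kaplan-Meier: hand product-limit ---------------------------------------
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    d <- sum(event & time == ts[i])
    n <- sum(time >= ts[i])
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# --- Cox: hand Efron log partial likelihood for a binary covariate ----------
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event])) {
    D <- which(event & time == t)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# --- cohort: per-patient scan implementing the rules independently ----------
oracle_cohort <- function(dataset, spec) {
  mdays <- function(m) m * 30.4375
  study <- c(spec$treatment_class, spec$comparator_class)
  excl_prefixes <- unique(unlist(lapply(
    spec$outcome_definitions[spec$exclusion_outcomes],
    function(d) d$icd10_prefixes)))
  out <- list()
  reasons <- character()
  for (pid in dataset$patients$patient_id) {
    disp <- dataset$dispensings[dataset$dispensings$patient_id == pid, ]
    sd <- disp[disp$drug_class %in% study &
                 disp$date >= spec$enrollment_window[1] &
                 disp$date <= spec$enrollment_window[2], ]
    if (nrow(sd) == 0) next
    index <- min(sd$date)
    wash_src <- if (spec$washout_all_drugs) disp else
      disp[disp$drug_class %in% study, ]
    if (any(wash_src$date < index &
              wash_src$date > index - mdays(spec$washout_months))) next
    day1 <- unique(sd$drug_class[sd$date == index])
    if (length(day1) > 1) next
    # exclusion rules, first violated wins
    dx <- dataset$diagnoses[dataset$diagnoses$patient_id == pid, ]
    qual <- dx[vapply(dx$icd10, function(code)
      any(startsWith(code, excl_prefixes)), logical(1)), ]
    reason <- NA_character_
    if (nrow(qual) && any(qual$date < index &
                            qual$date > index - mdays(spec$prior_event_exclusion_months)))
      reason <- "prior_event"
    else if (any(disp$drug_class %in% spec$controlled_drug_classes &
                   disp$date < index &
                   disp$date > index - mdays(spec$prior_drug_exclusion_months)))
      reason <- "controlled_drug"
    else {
      birth <- dataset$patients$birth_date[dataset$patients$patient_id == pid]
      if (as.numeric(index - birth) / 365.25 >= spec$max_age_years)
        reason <- "age"
      else {
        enr <- dataset$enrollment[dataset$enrollment$patient_id == pid, ]
        if (nrow(enr) == 0 || enr$start[1] > index || enr$end[1] < index)
          reason <- "enrollment"
      }
    }
    if (is.na(reason)) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid,
        group = if (day1 == spec$treatment_class) "treatment" else "comparator",
        index_date = index)
    } else reasons <- c(reasons, reason)
  }
  list(cohort = if (length(out)) do.call(rbind, out) else
         data.frame(patient_id = character(), group = character(),
                    index_date = as.Date(character())),
       exclusion_reasons = reasons)
}

oracle_followup <- function(cohort, dataset, outcome_name, spec) {
  def <- spec$outcome_definitions[[outcome_name]]
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    index <- cohort$index_date[i]
    dx <- dataset$diagnoses[dataset$diagnoses$patient_id == pid, ]
    if (def$primary_required) dx <- dx[dx$primary_at_admission, ]
    dx <- dx[vapply(dx$icd10, function(code)
      any(startsWith(code, def$icd10_prefixes)), logical(1)), ]
    dx <- dx[dx$date >= index, ]
    enr <- dataset$enrollment[dataset$enrollment$patient_id == pid, ]
    birth <- dataset$patients$birth_date[dataset$patients$patient_id == pid]
    censor <- min(enr$end[1], birth + round(75 * 365.25), spec$study_end)
    if (nrow(dx) && min(dx$date) <= censor) {
      days <- as.numeric(min(dx$date) - index)
      if (days == 0) days <- 0.5
      rows[[i]] <- data.frame(patient_id = pid, event = TRUE,
                              time_months = days / 30.4375)
    } else {
      rows[[i]] <- data.frame(patient_id = pid, event = FALSE,
                              time_months = as.numeric(censor - index) / 30.4375)
    }
  }
  do.call(rbind, rows)
}

# --- tiny hand-built claims dataset -----------------------------------------
make_claims <- function(patients, enrollment, dispensings, diagnoses = NULL) {
  if (is.null(diagnoses))
    diagnoses <- data.frame(patient_id = character(), date = as.Date(character()),
                            icd10 = character(), primary_at_admission = logical())
  structure(list(patients = patients, enrollment = enrollment,
                 dispensings = dispensings, diagnoses = diagnoses,
                 truth = NULL, config = NULL),
            class = "claims_dataset")
}

simple_patient <- function(id, birth = as.Date("1965-01-01")) {
  data.frame(patient_id = id, birth_date = birth, sex = "male")
}

full_enrollment <- function(id, start = as.Date("2016-01-01"),
                            end = as.Date("2020-06-30")) {
  data.frame(patient_id = id, start = start, end = end,
             end_reason = "study_end")
}

# random small report set built row by row (independent of the simulator)
random_report_set <- function(n_cases, drugs, events, seed) {
  compsafety:::with_seed(seed, {
    drows <- list(); erows <- list()
    ids <- sprintf("R%04d", seq_len(n_cases))
    for (i in seq_len(n_cases)) {
      nd <- sample(1:3, 1); ne <- sample(1:3, 1)
      drows[[i]] <- data.frame(
        case_id = ids[i],
        drug = sample(drugs, nd, replace = TRUE),
        role = sample(c("suspect", "concomitant"), nd, replace = TRUE))
      erows[[i]] <- data.frame(case_id = ids[i],
                               event_pt = sample(events, ne, replace = TRUE))
    }
    compsafety:::report_set(do.call(rbind, drows), do.call(rbind, erows), ids)
  })
}

# hazard_estimate built directly from reported numbers (for decision tests)
hand_estimate <- function(hr, lo, hi) {
  structure(list(outcome_name = NULL, hr = hr, ci_lower = lo, ci_upper = hi,
                 log_hr = log(hr), log_hr_se = (log(hi) - log(lo)) / (2 * 1.959964),
                 conf_level = 0.95, ties = "efron",
                 n_events = c(treatment = 1L, comparator = 1L),
                 n_subjects = c(treatment = 1L, comparator = 1L)),
            class = "hazard_estimate")
}
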