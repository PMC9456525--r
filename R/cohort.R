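#' Specification of the new-user active-comparator cohort
#'
#' Encodes the cohort-building rules: initiation of the treatment or
#' comparator class inside the enrollment window after a washout with no
#' study-drug use, exclusion of patients with a recent qualifying
#' cardiovascular diagnosis or a controlled-drug dispensing in the prior
#' year, an age cap, and follow-up until the outcome, disenrollment, the
#' 75th birthday or the study end.
#'
#' Outcome definitions map an outcome name to a set of ICD-10 code
#' *prefixes* (so `"I21"` matches `"I219"`) plus a flag saying whether only
#' diagnoses recorded as primary at admission qualify. Code lists ship as
#' editable configuration; see [default_outcome_definitions()].
#'
#' @param treatment_class,comparator_class Dispensing `drug_class` labels of
#'   the two arms.
#' @param enrollment_window Length-2 dates: initiation window.
#' @param study_end Study termination date.
#' @param washout_months Study-drug-free months required before index
#'   (default 3). By default only the two study classes are checked;
#'   `washout_all_drugs = TRUE` switches to a strict any-drug washout.
#' @param prior_event_exclusion_months Look-back for excluding patients with
#'   a qualifying cardiovascular diagnosis (default 3).
#' @param prior_drug_exclusion_months Look-back for the controlled-drug
#'   exclusion (default 12).
#' @param max_age_years Age cap at index (default 75, exclusive).
#' @param outcome_definitions Named list; each element a list with
#'   `icd10_prefixes` (character) and `primary_required` (logical).
#' @param exclusion_outcomes Names of outcome definitions whose codes drive
#'   the prior-event exclusion (default: all configured outcomes).
#' @param controlled_drug_classes Dispensing classes counting as controlled
#'   drugs (default empty: the exclusion list is configuration).
#' @param washout_all_drugs See `washout_months`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(treatment_class = "dpp4",
                        comparator_class = "metformin",
                        enrollment_window = c("2017-04-01", "2017-06-30"),
                        study_end = "2020-06-30",
                        washout_months = 3L,
                        prior_event_exclusion_months = 3L,
                        prior_drug_exclusion_months = 12L,
                        max_age_years = 75L,
                        outcome_definitions = default_outcome_definitions(),
                        exclusion_outcomes = names(outcome_definitions),
                        controlled_drug_classes = character(),
                        washout_all_drugs = FALSE) {
  window <- as_date(enrollment_window)
  study_end <- as_date(study_end)
  if (window[1] > window[2] || window[2] > study_end)
    stop_config("enrollment_window", "requires start <= end <= study_end")
  for (fld in c("washout_months", "prior_event_exclusion_months",
                "prior_drug_exclusion_months", "max_age_years")) {
    v <- get(fld)
    if (!is.numeric(v) || v <= 0) stop_config(fld, "must be positive")
  }
  if (!all(exclusion_outcomes %in% names(outcome_definitions)))
    stop_config("exclusion_outcomes", "must name configured outcome definitions")
  structure(list(treatment_class = treatment_class,
                 comparator_class = comparator_class,
                 enrollment_window = window,
                 study_end = study_end,
                 washout_months = washout_months,
                 prior_event_exclusion_months = prior_event_exclusion_months,
                 prior_drug_exclusion_months = prior_drug_exclusion_months,
                 max_age_years = max_age_years,
                 outcome_definitions = outcome_definitions,
                 exclusion_outcomes = exclusion_outcomes,
                 controlled_drug_classes = controlled_drug_classes,
                 washout_all_drugs = washout_all_drugs),
            class = "cohort_spec")
}

#' Default ICD-10 outcome definitions
#'
#' Documented default code prefixes: myocardial infarction I21-I22, stroke
#' I60-I63, heart failure I50; major cardiovascular events (MACE) is the
#' union of myocardial infarction and stroke, and the all-cardiovascular
#' composite unions MACE with heart failure. All require the diagnosis to
#' be primary at admission. Real analyses replace these with licensed code
#' lists.
#'
#' @return Named list of outcome definitions (see [cohort_spec()]).
#' @export
default_outcome_definitions <- function() {
  mi <- c("I21", "I22")
  stroke <- c("I60", "I61", "I62", "I63")
  hf <- "I50"
  mk <- function(prefixes) list(icd10_prefixes = prefixes, primary_required = TRUE)
  list(major_cardiovascular_events = mk(c(mi, stroke)),
       myocardial_infarction = mk(mi),
       heart_failure = mk(hf),
       stroke = mk(stroke),
       all_cardiovascular_events = mk(c(mi, stroke, hf)))
}

#' Identify new users of the study drug classes
#'
#' For each patient: the index date is the first dispensing of the treatment
#' or comparator class inside the enrollment window, provided no dispensing
#' of a study class (or of any class, with `washout_all_drugs`) falls in the
#' washout window `(index - washout_months, index)`. Patients dispensing
#' both classes on the index date are excluded. Group labels follow the
#' index drug.
#'
#' @param dataset A `claims_dataset`.
#' @param spec A [cohort_spec()].
#' @return Data frame `patient_id`, `group` (`treatment`/`comparator`),
#'   `index_date`, with attribute `attrition` counting patients dropped by
#'   the washout and dual-initiation rules.
#' @export
identify_new_users <- function(dataset, spec) {
  stopifnot(inherits(dataset, "claims_dataset"), inherits(spec, "cohort_spec"))
  disp <- dataset$dispensings
  study <- c(spec$treatment_class, spec$comparator_class)
  sd <- disp[disp$drug_class %in% study, , drop = FALSE]
  sd <- sd[sd$date >= spec$enrollment_window[1] &
             sd$date <= spec$enrollment_window[2], , drop = FALSE]
  if (nrow(sd) == 0L)
    return(structure(data.frame(patient_id = character(), group = character(),
                                index_date = as.Date(character())),
                     attrition = c(initiators = 0L, washout = 0L, dual = 0L)))
  sd <- sd[order(sd$patient_id, sd$date), , drop = FALSE]
  first <- sd[!duplicated(sd$patient_id), , drop = FALSE]
  washout_days <- months_to_days(spec$washout_months)

  prior <- if (spec$washout_all_drugs) disp else
    disp[disp$drug_class %in% study, , drop = FALSE]
  idx_of <- match(prior$patient_id, first$patient_id)
  in_washout <- !is.na(idx_of) &
    prior$date < first$date[idx_of] &
    prior$date > first$date[idx_of] - washout_days
  washout_viol <- unique(prior$patient_id[in_washout])

  same_day <- merge(first[, c("patient_id", "date")], sd,
                    by = c("patient_id", "date"))
  dual_tab <- tapply(same_day$drug_class, same_day$patient_id,
                     function(z) length(unique(z)))
  dual <- names(dual_tab)[dual_tab > 1L]

  keep <- !(first$patient_id %in% washout_viol) & !(first$patient_id %in% dual)
  out <- data.frame(
    patient_id = first$patient_id[keep],
    group = ifelse(first$drug_class[keep] == spec$treatment_class,
                   "treatment", "comparator"),
    index_date = first$date[keep])
  rownames(out) <- NULL
  attr(out, "attrition") <- c(initiators = nrow(first),
                              washout = sum(first$patient_id %in% washout_viol),
                              dual = sum(!(first$patient_id %in% washout_viol) &
                                           first$patient_id %in% dual))
  out
}

#' Apply cohort exclusion rules with attrition accounting
#'
#' Rules are applied sequentially, each patient attributed to the first rule
#' it violates (the layout of a study flowchart): (1) a qualifying
#' cardiovascular diagnosis in the `prior_event_exclusion_months` before
#' index, (2) a controlled-drug dispensing in the
#' `prior_drug_exclusion_months` before index, (3) age at index of
#' `max_age_years` or more, (4) enrollment not covering the index date.
#' Look-back windows are open at both ends: `(index - k months, index)`.
#'
#' @param candidates Output of [identify_new_users()].
#' @param dataset The `claims_dataset`.
#' @param spec A [cohort_spec()].
#' @return The retained cohort (same columns as `candidates`) with attribute
#'   `attrition`: named counts `candidates`, `prior_event`,
#'   `controlled_drug`, `age`, `enrollment`, `cohort`.
#' @export
apply_exclusions <- function(candidates, dataset, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n0 <- nrow(candidates)
  if (n0 == 0L) {
    attr(candidates, "attrition") <-
      c(candidates = 0L, prior_event = 0L, controlled_drug = 0L,
        age = 0L, enrollment = 0L, cohort = 0L)
    return(candidates)
  }
  idx <- candidates$index_date

  excl_prefixes <- unique(unlist(lapply(
    spec$outcome_definitions[spec$exclusion_outcomes],
    function(d) d$icd10_prefixes)))
  dx <- dataset$diagnoses
  qual <- rep(FALSE, nrow(dx))
  for (p in excl_prefixes) qual <- qual | startsWith(dx$icd10, p)
  dx <- dx[qual, , drop = FALSE]
  m <- match(dx$patient_id, candidates$patient_id)
  lb <- months_to_days(spec$prior_event_exclusion_months)
  hit <- !is.na(m) & dx$date < idx[m] & dx$date > idx[m] - lb
  prior_event <- candidates$patient_id %in% dx$patient_id[hit]

  disp <- dataset$dispensings
  disp <- disp[disp$drug_class %in% spec$controlled_drug_classes, , drop = FALSE]
  m <- match(disp$patient_id, candidates$patient_id)
  lb <- months_to_days(spec$prior_drug_exclusion_months)
  hit <- !is.na(m) & disp$date < idx[m] & disp$date > idx[m] - lb
  controlled <- candidates$patient_id %in% disp$patient_id[hit]

  birth <- dataset$patients$birth_date[
    match(candidates$patient_id, dataset$patients$patient_id)]
  age_at_index <- as.numeric(idx - birth) / 365.25
  too_old <- age_at_index >= spec$max_age_years

  enr <- dataset$enrollment[match(candidates$patient_id,
                                  dataset$enrollment$patient_id), , drop = FALSE]
  not_enrolled <- is.na(enr$start) | enr$start > idx | enr$end < idx

  reason <- rep(NA_character_, n0)
  reason[not_enrolled] <- "enrollment"
  reason[too_old] <- "age"
  reason[controlled] <- "controlled_drug"
  reason[prior_event] <- "prior_event"  # highest precedence, assigned last
  keep <- is.na(reason)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- c(
    candidates = n0,
    prior_event = sum(reason == "prior_event", na.rm = TRUE),
    controlled_drug = sum(reason == "controlled_drug", na.rm = TRUE),
    age = sum(reason == "age", na.rm = TRUE),
    enrollment = sum(reason == "enrollment", na.rm = TRUE),
    cohort = sum(keep))
  out
}

# Validates and classes a follow-up data frame.
followup_frame <- function(df) {
  stopifnot(all(c("patient_id", "group", "index_date", "time_months",
                  "event", "censor_reason") %in% names(df)))
  stopifnot(all(df$time_months >= 0),
            all(!df$event | df$censor_reason == "outcome"))
  class(df) <- c("followup", "data.frame")
  df
}

#' Build time-to-event follow-up records for one outcome
#'
#' Per cohort subject: the event time is the first post-index diagnosis
#' matching the outcome's ICD-10 prefixes (restricted to primary-at-admission
#' records when the definition requires it); censoring occurs at the
#' earliest of the enrollment end (disenrollment, which folds migration and
#' death), the 75th birthday, and the study end. Times are reported in
#' months of 30.4375 days. A qualifying diagnosis on the index date itself
#' counts as an event at half a day, keeping event times strictly positive.
#'
#' @param cohort Output of [apply_exclusions()] (or any data frame with
#'   `patient_id`, `group`, `index_date`).
#' @param dataset The `claims_dataset`.
#' @param outcome_name Name of a configured outcome definition.
#' @param spec A [cohort_spec()].
#' @return A `followup` data frame: `patient_id`, `group`, `index_date`,
#'   `time_months`, `event`, `censor_reason` (one of `outcome`,
#'   `disenrollment`, `age75`, `study_end`).
#' @export
build_followup <- function(cohort, dataset, outcome_name, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  def <- spec$outcome_definitions[[outcome_name]]
  if (is.null(def))
    stop(sprintf("unknown outcome name: %s (configured: %s)", outcome_name,
                 paste(names(spec$outcome_definitions), collapse = ", ")))
  n <- nrow(cohort)
  idx <- cohort$index_date

  dx <- dataset$diagnoses
  if (def$primary_required) dx <- dx[dx$primary_at_admission, , drop = FALSE]
  qual <- rep(FALSE, nrow(dx))
  for (p in def$icd10_prefixes) qual <- qual | startsWith(dx$icd10, p)
  dx <- dx[qual, , drop = FALSE]
  m <- match(dx$patient_id, cohort$patient_id)
  ok <- !is.na(m) & dx$date >= idx[m]
  first_dx <- rep(as.Date(NA), n)
  if (any(ok)) {
    dd <- data.frame(i = m[ok], date = dx$date[ok])
    dd <- dd[order(dd$i, dd$date), , drop = FALSE]
    dd <- dd[!duplicated(dd$i), , drop = FALSE]
    first_dx[dd$i] <- dd$date
  }

  enr <- dataset$enrollment[match(cohort$patient_id,
                                  dataset$enrollment$patient_id), , drop = FALSE]
  birth <- dataset$patients$birth_date[
    match(cohort$patient_id, dataset$patients$patient_id)]
  date75 <- birth + round(75 * 365.25)
  censor_date <- pmin(enr$end, date75, spec$study_end)
  censor_reason <- rep("study_end", n)
  censor_reason[date75 <= censor_date] <- "age75"
  censor_reason[enr$end <= censor_date & enr$end < spec$study_end] <- "disenrollment"

  is_event <- !is.na(first_dx) & first_dx <= censor_date
  end_date <- ifelse(is_event, first_dx, censor_date)
  time_days <- as.numeric(end_date) - as.numeric(idx)
  time_days[is_event & time_days == 0] <- 0.5  # index-date events
  followup_frame(data.frame(
    patient_id = cohort$patient_id,
    group = cohort$group,
    index_date = idx,
    time_months = days_to_months(time_days),
    event = is_event,
    censor_reason = ifelse(is_event, "outcome", censor_reason)))
}
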