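#' Configuration for the spontaneous-report simulator
#'
#' Describes a synthetic spontaneous-reporting stream with a single target
#' drug-class x event-group pair whose joint reporting frequency is
#' controlled relative to independence, over a background of nuisance drugs
#' and events. With drug share p1, event share p2 and reporting ratio r, a
#' case falls in the joint cell with probability r*p1*p2; the remaining 2x2
#' cell probabilities are chosen so the margins stay at p1 and p2, which
#' requires r*p1*p2 <= min(p1, p2) and 1 - p1 - p2 + r*p1*p2 >= 0.
#'
#' @param n_cases Number of cases (>= 1).
#' @param target_drug_share Probability a case mentions the target class as
#'   suspect drug.
#' @param target_event_share Probability a case mentions the target event
#'   group.
#' @param reporting_ratio Multiplier on the joint cell relative to
#'   independence; 1 means no association.
#' @param target_drugs Character vector of member drug names; a target case
#'   mentions one of them, uniformly. Defaults to the nine DPP-4 inhibitors.
#' @param target_events Character vector of PT labels; a target case
#'   mentions one of them, uniformly.
#' @param n_background_drugs,n_background_events Number of nuisance drug /
#'   event labels.
#' @param background_drug_prob,background_event_prob Independent per-label
#'   attachment probabilities for the nuisance labels.
#' @param seed RNG seed.
#' @return An object of class `report_sim_config`.
#' @export
report_sim_config <- function(n_cases,
                              target_drug_share = 0.01,
                              target_event_share = 0.01,
                              reporting_ratio = 1,
                              target_drugs = default_drug_classes()$dpp4_inhibitors$members,
                              target_events = default_event_definitions()$major_cardiovascular_events$pt_terms,
                              n_background_drugs = 20L,
                              n_background_events = 30L,
                              background_drug_prob = 0.08,
                              background_event_prob = 0.06,
                              seed = 1L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 1 ||
      n_cases != round(n_cases))
    stop_config("n_cases", "must be a positive integer")
  assert_scalar_prob(target_drug_share, "target_drug_share")
  assert_scalar_prob(target_event_share, "target_event_share")
  if (!is.numeric(reporting_ratio) || reporting_ratio <= 0)
    stop_config("reporting_ratio", "must be strictly positive")
  p11 <- reporting_ratio * target_drug_share * target_event_share
  if (p11 > min(target_drug_share, target_event_share))
    stop_config("reporting_ratio",
                "implied joint cell probability exceeds a marginal share")
  if (1 - target_drug_share - target_event_share + p11 < 0)
    stop_config("reporting_ratio",
                "implied 2x2 cell probabilities do not sum to at most 1")
  assert_scalar_prob(background_drug_prob, "background_drug_prob")
  assert_scalar_prob(background_event_prob, "background_event_prob")
  structure(list(n_cases = as.integer(n_cases),
                 target_drug_share = target_drug_share,
                 target_event_share = target_event_share,
                 reporting_ratio = reporting_ratio,
                 target_drugs = target_drugs,
                 target_events = target_events,
                 n_background_drugs = as.integer(n_background_drugs),
                 n_background_events = as.integer(n_background_events),
                 background_drug_prob = background_drug_prob,
                 background_event_prob = background_event_prob,
                 seed = as.integer(seed)),
            class = "report_sim_config")
}

#' Simulate a spontaneous-report stream
#'
#' Each case is assigned to one cell of the 2x2 multinomial implied by the
#' configuration (target drug and/or target event present), then nuisance
#' drugs and events attach independently with small probabilities, never
#' correlated with the target pair — the 2x2 table is the only signal
#' carrier. Every case carries at least one suspect drug and one event
#' label: where the cell assignment and the background leave a case empty,
#' one uniformly chosen background label is forced (this preserves the
#' target margins exactly). One report per case; case ids are unique.
#' Deterministic given the config (including its seed).
#'
#' @param config A [report_sim_config()].
#' @return A `report_set` (see [read_reports()]), with the generating
#'   config attached as attribute `config`.
#' @export
generate_spontaneous_reports <- function(config) {
  stopifnot(inherits(config, "report_sim_config"))
  n <- config$n_cases
  p1 <- config$target_drug_share
  p2 <- config$target_event_share
  p11 <- config$reporting_ratio * p1 * p2
  probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  bg_drugs <- sprintf("background_drug_%03d", seq_len(config$n_background_drugs))
  bg_events <- sprintf("background_event_%03d", seq_len(config$n_background_events))
  with_seed(config$seed, {
    case_ids <- sprintf("C%07d", seq_len(n))
    cell <- sample.int(4L, n, replace = TRUE, prob = probs)
    has_drug <- cell <= 2L
    has_event <- cell == 1L | cell == 3L

    drugs <- list(data.frame(
      case_id = case_ids[has_drug],
      drug = sample(config$target_drugs, sum(has_drug), replace = TRUE),
      role = rep("suspect", sum(has_drug))))
    events <- list(data.frame(
      case_id = case_ids[has_event],
      event_pt = sample(config$target_events, sum(has_event), replace = TRUE)))

    any_bg_suspect <- rep(FALSE, n)
    for (bd in bg_drugs) {
      hit <- stats::runif(n) < config$background_drug_prob
      as_suspect <- hit & stats::runif(n) < 0.5
      any_bg_suspect <- any_bg_suspect | as_suspect
      drugs[[length(drugs) + 1L]] <- data.frame(
        case_id = case_ids[hit], drug = rep(bd, sum(hit)),
        role = ifelse(as_suspect[hit], "suspect", "concomitant"))
    }
    any_bg_event <- rep(FALSE, n)
    for (be in bg_events) {
      hit <- stats::runif(n) < config$background_event_prob
      any_bg_event <- any_bg_event | hit
      events[[length(events) + 1L]] <- data.frame(
        case_id = case_ids[hit], event_pt = rep(be, sum(hit)))
    }

    # every case needs >= 1 suspect drug and >= 1 event; forcing a background
    # label keeps the target-pair margins untouched
    need_drug <- !has_drug & !any_bg_suspect
    if (any(need_drug))
      drugs[[length(drugs) + 1L]] <- data.frame(
        case_id = case_ids[need_drug],
        drug = sample(bg_drugs, sum(need_drug), replace = TRUE),
        role = "suspect")
    need_event <- !has_event & !any_bg_event
    if (any(need_event))
      events[[length(events) + 1L]] <- data.frame(
        case_id = case_ids[need_event],
        event_pt = sample(bg_events, sum(need_event), replace = TRUE))

    out <- report_set(drugs = do.call(rbind, drugs),
                      events = do.call(rbind, events),
                      case_ids = case_ids)
    attr(out, "config") <- config
    out
  })
}

#' Sample 2x2 contingency tables directly from the reporting model
#'
#' Count-level shortcut of [generate_spontaneous_reports()]: draws the four
#' cell counts of the case-level 2x2 multinomial without materialising
#' individual reports. Used for calibration studies (e.g. the false-positive
#' rate of the SDR criterion under independence) where only the table is
#' needed.
#'
#' @param n_cases Case total per table.
#' @param target_drug_share,target_event_share,reporting_ratio As in
#'   [report_sim_config()].
#' @param n_tables Number of independent tables.
#' @param seed RNG seed.
#' @return List of [contingency_table()] objects.
#' @export
simulate_contingency <- function(n_cases, target_drug_share, target_event_share,
                                 reporting_ratio = 1, n_tables = 1L, seed = 1L) {
  cfg <- report_sim_config(n_cases, target_drug_share, target_event_share,
                           reporting_ratio, seed = seed)
  p11 <- reporting_ratio * target_drug_share * target_event_share
  probs <- c(p11, target_drug_share - p11, target_event_share - p11,
             1 - target_drug_share - target_event_share + p11)
  with_seed(seed, {
    cells <- stats::rmultinom(n_tables, cfg$n_cases, probs)
    lapply(seq_len(n_tables), function(i) {
      contingency_table(n11 = cells[1L, i],
                        n1dot = cells[1L, i] + cells[2L, i],
                        ndot1 = cells[1L, i] + cells[3L, i],
                        ndotdot = cfg$n_cases)
    })
  })
}
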