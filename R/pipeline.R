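#' Incidence percentage as rendered in output tables
#'
#' Event percentages in rendered incidence tables are 100 * events / n
#' rounded to one decimal place (machine-readable outputs keep full
#' precision).
#'
#' @param events Event count(s).
#' @param n Group size(s).
#' @return Numeric percentage(s) rounded to one decimal.
#' @examples
#' incidence_percent(239, 2474)  # 9.7
#' @export
incidence_percent <- function(events, n) {
  round(100 * events / n, 1)
}

#' Run the disproportionality track
#'
#' Builds one 2x2 case-count table per drug-class x event-group pair and
#' scores each with the BCPNN information component, producing the layout
#' of a signal table: counts, posterior IC with credible interval, and the
#' IC025 > 0 flag. Inputs may be an in-memory `report_set`, a path to a
#' delimited reports file, or a [report_sim_config()] (the stream is then
#' simulated, deterministically in the config seed).
#'
#' @param reports A `report_set`, file path, or [report_sim_config()].
#' @param drug_classes List of [drug_class()] objects.
#' @param event_definitions List of [event_definition()] objects.
#' @param prior A [bcpnn_prior()].
#' @param level Credibility level.
#' @param suspect_only Count suspect-role drug mentions only (default TRUE).
#' @param outdir Optional output directory; when given, the table is written
#'   to `signal_table.tsv` (full precision) and a rounded rendering to
#'   `signal_table_rendered.tsv`.
#' @return An object of class `signal_table`: data frame with one row per
#'   pair (`drug`, `event`, `n11`, `n1dot`, `ndot1`, `ndotdot`, `ic`,
#'   `ic_lower`, `ic_upper`, `sdr`).
#' @export
run_disproportionality <- function(reports,
                                   drug_classes = default_drug_classes(),
                                   event_definitions = default_event_definitions(),
                                   prior = bcpnn_prior(),
                                   level = 0.95,
                                   suspect_only = TRUE,
                                   outdir = NULL) {
  if (inherits(reports, "report_sim_config"))
    reports <- generate_spontaneous_reports(reports)
  else if (is.character(reports))
    reports <- read_reports(reports)
  stopifnot(inherits(reports, "report_set"))
  pairs <- enumerate_pairs(reports, drug_classes, event_definitions, suspect_only)
  rows <- lapply(pairs, function(p) {
    sig <- detect_signal(p$table, prior, level)
    data.frame(drug = p$drug, event = p$event,
               n11 = p$table$n11, n1dot = p$table$n1dot,
               ndot1 = p$table$ndot1, ndotdot = p$table$ndotdot,
               ic = sig$expected_ic, ic_lower = sig$ic_lower,
               ic_upper = sig$ic_upper, sdr = sig$is_sdr)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("signal_table", "data.frame")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(outdir, "signal_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rendered <- out
    for (cl in c("ic", "ic_lower", "ic_upper")) rendered[[cl]] <- round(out[[cl]], 2)
    utils::write.table(rendered, file.path(outdir, "signal_table_rendered.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf("BCPNN signal table: %d drug x event pairs, %d flagged as SDR\n",
              nrow(x), sum(x$sdr)))
  df <- as.data.frame(x)
  for (cl in c("ic", "ic_lower", "ic_upper")) df[[cl]] <- round(df[[cl]], 2)
  print(df[, c("drug", "event", "n11", "ic", "ic_lower", "ic_upper", "sdr")],
        row.names = FALSE)
  invisible(x)
}

#' Run the real-world-evidence track
#'
#' End-to-end cohort study on a claims dataset: new-user identification,
#' exclusion rules with attrition accounting, propensity estimation, 1:1
#' caliper matching with balance diagnostics, and — per configured outcome —
#' event counts and percentages by group, the Cox hazard ratio with its
#' confidence interval, and the fixed-margin non-inferiority decision; plus
#' cumulative-incidence step curves for the primary (first-listed) outcome.
#' The composite `all_cardiovascular_events` outcome is ascertained as the
#' first occurrence of any qualifying diagnosis across its unioned code
#' prefixes.
#'
#' @param claims A `claims_dataset`, a directory path of claims tables, or a
#'   [claims_sim_config()] (the population is then simulated).
#' @param spec A [cohort_spec()].
#' @param covariate_names Covariates for the propensity model; default NULL
#'   uses every `patients` column except `patient_id` and `birth_date`.
#' @param outcomes Outcome names to analyse (default: all configured).
#' @param margin Non-inferiority margin (default 1.3).
#' @param caliper_multiplier Caliper width in pooled-logit SDs (default 0.2).
#' @param seed Seed for the matching order.
#' @param outdir Optional directory for TSV/JSON artifacts.
#' @return An object of class `rwe_analysis`: `attrition` (named counts),
#'   `balance`, `matched`, `incidence` (data frame), `hazards` (data frame
#'   with the non-inferiority flags), `estimates` (list of
#'   `noninferiority_result`), `cuminc`, `followups`.
#' @export
run_rwe <- function(claims,
                    spec = cohort_spec(),
                    covariate_names = NULL,
                    outcomes = names(spec$outcome_definitions),
                    margin = 1.3,
                    caliper_multiplier = 0.2,
                    seed = 1L,
                    outdir = NULL) {
  if (inherits(claims, "claims_sim_config"))
    claims <- generate_claims_population(claims)
  else if (is.character(claims))
    claims <- read_claims(claims)
  stopifnot(inherits(claims, "claims_dataset"))
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(claims$patients),
                               c("patient_id", "birth_date"))

  candidates <- identify_new_users(claims, spec)
  cohort <- apply_exclusions(candidates, claims, spec)
  attrition <- c(attr(candidates, "attrition"), attr(cohort, "attrition"))

  model <- estimate_propensity(cohort, claims, covariate_names)
  matched <- match_nearest_neighbor(model, caliper_multiplier, seed)
  if (nrow(matched$pairs) == 0L)
    stop("empty matched cohort: no comparator within the caliper of any treated subject")
  balance <- balance_diagnostics(matched, model)
  mcohort <- cohort[cohort$patient_id %in% matched$matched_ids, , drop = FALSE]

  followups <- list(); estimates <- list(); inc_rows <- list(); hz_rows <- list()
  for (o in outcomes) {
    fu <- build_followup(mcohort, claims, o, spec)
    followups[[o]] <- fu
    est <- fit_cox(fu, outcome_name = o)
    ni <- assess_noninferiority(est, margin)
    estimates[[o]] <- ni
    for (g in c("treatment", "comparator")) {
      ev <- sum(fu$event[fu$group == g]); ng <- sum(fu$group == g)
      inc_rows[[length(inc_rows) + 1L]] <- data.frame(
        outcome = o, group = g, n = ng, events = ev,
        percent = incidence_percent(ev, ng),
        percent_full = 100 * ev / ng)
    }
    hz_rows[[length(hz_rows) + 1L]] <- data.frame(
      outcome = o, hr = est$hr, ci_lower = est$ci_lower,
      ci_upper = est$ci_upper, log_hr_se = est$log_hr_se,
      margin = margin, non_inferior = ni$non_inferior)
  }
  out <- structure(list(
    attrition = attrition,
    n_matched_pairs = nrow(matched$pairs),
    balance = balance,
    matched = matched,
    model = model,
    incidence = do.call(rbind, inc_rows),
    hazards = do.call(rbind, hz_rows),
    estimates = estimates,
    cuminc = cumulative_incidence(followups[[1L]]),
    followups = followups,
    margin = margin), class = "rwe_analysis")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.table(
      df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    w(data.frame(stage = names(attrition), count = as.integer(attrition)),
      "attrition.tsv")
    w(out$balance, "balance.tsv")
    w(out$incidence, "incidence.tsv")
    hz <- out$hazards
    for (cl in c("hr", "ci_lower", "ci_upper")) hz[[cl]] <- round(hz[[cl]], 2)
    w(hz, "hazards_rendered.tsv")
    w(out$hazards, "hazards.tsv")
    w(out$cuminc$curves, "cumulative_incidence.tsv")
    jsonlite::write_json(
      list(attrition = as.list(attrition),
           n_matched_pairs = out$n_matched_pairs,
           max_abs_smd_after = max(abs(out$balance$smd_after)),
           hazards = out$hazards),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.rwe_analysis <- function(x, ...) {
  cat("new-user active-comparator cohort analysis\n")
  cat(sprintf("  cohort: %d candidates -> %d after exclusions -> %d matched pairs\n",
              x$attrition[["candidates"]], x$attrition[["cohort"]],
              x$n_matched_pairs))
  cat(sprintf("  max |SMD| after matching: %.3f\n", max(abs(x$balance$smd_after))))
  hz <- x$hazards
  cat(sprintf("  outcomes (non-inferiority margin %.2f):\n", x$margin))
  for (i in seq_len(nrow(hz)))
    cat(sprintf("    %-28s HR %.2f (%.2f-%.2f)  %s\n",
                hz$outcome[i], hz$hr[i], hz$ci_lower[i], hz$ci_upper[i],
                if (hz$non_inferior[i]) "non-inferior" else "not demonstrated"))
  invisible(x)
}
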