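#' Drug class definition
#'
#' A named set of drug-substance names treated as one exposure class in
#' disproportionality analysis (e.g. the nine DPP-4 inhibitors marketed in
#' Japan). Name matching is exact and case-sensitive. Combination products
#' are handled by an explicit exclusion list rather than a code system:
#' any report drug name found in `exclude_names` never counts towards the
#' class, even if it also appears in `members`.
#'
#' @param name Class label used in output tables.
#' @param members Character vector of member drug names (unique, non-empty).
#' @param exclude_names Character vector of names to exclude (combination
#'   products); default none.
#' @return An object of class `drug_class`.
#' @examples
#' drug_class("dpp4_inhibitors", c("sitagliptin", "vildagliptin"))
#' @export
drug_class <- function(name, members, exclude_names = character()) {
  if (!is.character(members) || length(members) == 0L)
    stop_config("members", "must be a non-empty character vector")
  if (anyDuplicated(members))
    stop_config("members", "member names must be unique")
  structure(list(name = name, members = members,
                 exclude_names = exclude_names),
            class = "drug_class")
}

#' Adverse-event group definition
#'
#' A named set of preferred-term (PT) labels, optionally composed from
#' child definitions with set-union semantics — e.g. major cardiovascular
#' events as the union of the myocardial-infarction and stroke groups.
#' PT labels are free-form strings matched exactly (case-sensitive).
#'
#' @param name Group label.
#' @param pt_terms Character vector of PT labels.
#' @param composed_of Optional list of child `event_definition` objects whose
#'   terms are unioned with `pt_terms`.
#' @return An object of class `event_definition`; `$pt_terms` holds the
#'   resolved union.
#' @examples
#' mi <- event_definition("myocardial_infarction", "Myocardial infarction")
#' st <- event_definition("stroke", c("Cerebral infarction", "Ischaemic stroke"))
#' event_definition("major_cardiovascular_events", composed_of = list(mi, st))
#' @export
event_definition <- function(name, pt_terms = character(), composed_of = NULL) {
  terms <- as.character(pt_terms)
  if (!is.null(composed_of)) {
    for (child in composed_of) {
      stopifnot(inherits(child, "event_definition"))
      terms <- union(terms, child$pt_terms)
    }
  }
  if (length(terms) == 0L)
    stop_config("pt_terms", "resolved term set must be non-empty")
  structure(list(name = name, pt_terms = terms), class = "event_definition")
}

#' 2x2 contingency table of case counts
#'
#' The marginal form used throughout disproportionality analysis: `n11`
#' cases reporting both the drug class and the event group, `n1dot` with the
#' drug, `ndot1` with the event, `ndotdot` cases in total. The counting unit
#' is the case, never the report row.
#'
#' @param n11,n1dot,ndot1,ndotdot Non-negative integer counts.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(2, 3, 4, 10)
#' @export
contingency_table <- function(n11, n1dot, ndot1, ndotdot) {
  counts <- c(n11 = n11, n1dot = n1dot, ndot1 = ndot1, ndotdot = ndotdot)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (n11 > min(n1dot, ndot1))
    stop("invalid contingency table: n11 exceeds a margin")
  if (max(n1dot, ndot1) > ndotdot)
    stop("invalid contingency table: a margin exceeds the total")
  if (n1dot + ndot1 - n11 > ndotdot)
    stop("invalid contingency table: cell counts exceed the total")
  structure(list(n11 = as.integer(n11), n1dot = as.integer(n1dot),
                 ndot1 = as.integer(ndot1), ndotdot = as.integer(ndotdot)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 case-count table: n11 = %d, n1. = %d, n.1 = %d, n.. = %d\n",
              x$n11, x$n1dot, x$ndot1, x$ndotdot))
  invisible(x)
}

#' Read a spontaneous-report stream from delimited text
#'
#' Expects a tab-separated file with header columns `case_id`, `drug`,
#' `role`, `event_pt`. Each row may carry a drug mention (non-empty `drug`
#' with `role` in `suspect`/`concomitant`), an event mention (non-empty
#' `event_pt`), or both; rows are aggregated per `case_id` with set
#' semantics, so duplicate mentions collapse. Malformed rows (a drug with an
#' unknown role) are rejected with their line numbers.
#'
#' @param path Path to the reports file.
#' @return A `report_set`: list with data frames `drugs` (`case_id`, `drug`,
#'   `role`) and `events` (`case_id`, `event_pt`), plus `case_ids`.
#' @seealso [write_reports()], [generate_spontaneous_reports()]
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop(sprintf("reports file not found: %s", path))
  raw <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  required <- c("case_id", "drug", "role", "event_pt")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(sprintf("reports file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  bad_case <- which(raw$case_id == "")
  bad_role <- which(raw$drug != "" & !(raw$role %in% c("suspect", "concomitant")))
  bad <- sort(union(bad_case, bad_role))
  if (length(bad))
    stop(sprintf("malformed report rows at line(s): %s",
                 paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  report_set(drugs = raw[raw$drug != "", c("case_id", "drug", "role")],
             events = raw[raw$event_pt != "", c("case_id", "event_pt")],
             case_ids = unique(raw$case_id))
}

# Internal constructor shared by the reader and the simulator.
report_set <- function(drugs, events, case_ids) {
  drugs <- unique(drugs[order(drugs$case_id, drugs$drug, drugs$role), ,
                        drop = FALSE])
  events <- unique(events[order(events$case_id, events$event_pt), , drop = FALSE])
  rownames(drugs) <- NULL; rownames(events) <- NULL
  structure(list(drugs = drugs, events = events,
                 case_ids = sort(unique(case_ids))),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("spontaneous-report set: %d cases, %d drug mentions, %d event mentions\n",
              length(x$case_ids), nrow(x$drugs), nrow(x$events)))
  invisible(x)
}

#' Write a report set as delimited text
#'
#' Serialises a `report_set` to the tab-separated layout read by
#' [read_reports()] (drug rows with empty `event_pt`, event rows with empty
#' `drug`/`role`).
#'
#' @param reports A `report_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  stopifnot(inherits(reports, "report_set"))
  drug_rows <- data.frame(case_id = reports$drugs$case_id,
                          drug = reports$drugs$drug,
                          role = reports$drugs$role,
                          event_pt = "")
  event_rows <- data.frame(case_id = reports$events$case_id,
                           drug = "", role = "",
                           event_pt = reports$events$event_pt)
  out <- rbind(drug_rows, event_rows)
  out <- out[order(out$case_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the 2x2 case-count table for one drug class and event group
#'
#' Counts cases, not report rows: a case contributes at most once to each
#' cell regardless of how many member drugs or PT labels it mentions.
#' With `suspect_only = TRUE` (the default, matching the suspect-drug
#' convention of spontaneous-report analysis) only drug mentions with role
#' `suspect` qualify; concomitant mentions are ignored.
#'
#' @param reports A `report_set`.
#' @param drug A [drug_class()].
#' @param event An [event_definition()].
#' @param suspect_only Count only suspect-role drug mentions (default TRUE).
#' @return A [contingency_table()].
#' @export
build_contingency <- function(reports, drug, event, suspect_only = TRUE) {
  stopifnot(inherits(reports, "report_set"), inherits(drug, "drug_class"),
            inherits(event, "event_definition"))
  if (length(reports$case_ids) == 0L) stop("empty report set")
  d <- reports$drugs
  if (suspect_only) d <- d[d$role == "suspect", , drop = FALSE]
  d <- d[d$drug %in% setdiff(drug$members, drug$exclude_names), , drop = FALSE]
  drug_cases <- unique(d$case_id)
  e <- reports$events
  event_cases <- unique(e$case_id[e$event_pt %in% event$pt_terms])
  contingency_table(n11 = length(intersect(drug_cases, event_cases)),
                    n1dot = length(drug_cases),
                    ndot1 = length(event_cases),
                    ndotdot = length(reports$case_ids))
}

#' Contingency tables for every drug class x event group pair
#'
#' Cartesian product in stable input order; one table per pair, all sharing
#' the same case total.
#'
#' @param reports A `report_set`.
#' @param drug_classes List of [drug_class()] objects.
#' @param event_definitions List of [event_definition()] objects.
#' @param suspect_only Passed to [build_contingency()].
#' @return Data-frame-backed list: one element per pair with fields `drug`,
#'   `event`, `table`.
#' @export
enumerate_pairs <- function(reports, drug_classes, event_definitions,
                            suspect_only = TRUE) {
  out <- vector("list", length(drug_classes) * length(event_definitions))
  k <- 0L
  for (dc in drug_classes) {
    for (ev in event_definitions) {
      k <- k + 1L
      out[[k]] <- list(drug = dc$name, event = ev$name,
                       table = build_contingency(reports, dc, ev, suspect_only))
    }
  }
  out
}

#' Default drug classes of the DPP-4 inhibitor vs. metformin comparison
#'
#' The nine single-agent DPP-4 inhibitors marketed in Japan, and metformin,
#' as two [drug_class()] objects. Combination products are excluded by name
#' via `exclude_names` supplied by the caller.
#'
#' @return Named list with elements `dpp4_inhibitors` and `metformin`.
#' @export
default_drug_classes <- function() {
  list(
    dpp4_inhibitors = drug_class(
      "dpp4_inhibitors",
      c("alogliptin", "anagliptin", "linagliptin", "omarigliptin",
        "saxagliptin", "sitagliptin", "teneligliptin", "trelagliptin",
        "vildagliptin")),
    metformin = drug_class("metformin", "metformin"))
}

#' Default cardiovascular event groups
#'
#' Myocardial infarction, stroke, heart failure, and major cardiovascular
#' events (MACE) as the union of myocardial infarction and stroke. The PT
#' labels are generic placeholders; real analyses supply licensed MedDRA
#' term lists through [event_definition()].
#'
#' @return Named list of [event_definition()] objects.
#' @export
default_event_definitions <- function() {
  mi <- event_definition("myocardial_infarction",
                         c("Myocardial infarction", "Acute myocardial infarction"))
  stroke <- event_definition("stroke",
                             c("Cerebral infarction", "Cerebral haemorrhage",
                               "Ischaemic stroke", "Haemorrhagic stroke"))
  hf <- event_definition("heart_failure",
                         c("Cardiac failure", "Cardiac failure congestive"))
  mace <- event_definition("major_cardiovascular_events",
                           composed_of = list(mi, stroke))
  list(major_cardiovascular_events = mace, myocardial_infarction = mi,
       heart_failure = hf, stroke = stroke)
}
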