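#' Cox proportional-hazards estimate for a two-arm follow-up set
#'
#' Univariable Cox regression of the follow-up times on the group indicator
#' (treatment vs. comparator), partial likelihood maximised with Efron
#' handling of tied event times (Breslow available by flag), Wald 95%
#' confidence interval on the log-hazard scale. Requires at least one event
#' in each arm; a monotone partial likelihood (all events in one arm) is an
#' error rather than a divergent estimate.
#'
#' @param followup A `followup` data frame (see [build_followup()] or
#'   [simulate_followup()]).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level (default 0.95).
#' @param outcome_name Optional label carried into the result.
#' @return An object of class `hazard_estimate`: `hr`, `ci_lower`,
#'   `ci_upper`, `log_hr_se`, per-group event and subject counts.
#' @export
fit_cox <- function(followup, ties = c("efron", "breslow"),
                    conf_level = 0.95, outcome_name = NULL) {
  ties <- match.arg(ties)
  stopifnot(all(c("time_months", "event", "group") %in% names(followup)))
  grp <- factor(followup$group, levels = c("comparator", "treatment"))
  if (any(is.na(grp))) stop("group labels must be `treatment` or `comparator`")
  ev <- tapply(followup$event, grp, sum)
  if (any(is.na(ev)) || any(ev == 0))
    stop("Cox fit requires at least one event in each group")
  fit <- survival::coxph(
    survival::Surv(time_months, event) ~ grp,
    data = data.frame(time_months = followup$time_months,
                      event = followup$event, grp = grp),
    ties = ties)
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(b) || !is.finite(se) || se > 1e3)
    stop("monotone partial likelihood: hazard ratio not estimable")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(outcome_name = outcome_name,
                 hr = exp(b),
                 ci_lower = exp(b - z * se),
                 ci_upper = exp(b + z * se),
                 log_hr = b,
                 log_hr_se = se,
                 conf_level = conf_level,
                 ties = ties,
                 n_events = c(treatment = unname(ev["treatment"]),
                              comparator = unname(ev["comparator"])),
                 n_subjects = c(treatment = sum(grp == "treatment"),
                                comparator = sum(grp == "comparator"))),
            class = "hazard_estimate")
}

#' @export
print.hazard_estimate <- function(x, digits = 2, ...) {
  lbl <- if (is.null(x$outcome_name)) "" else sprintf(" [%s]", x$outcome_name)
  cat(sprintf("Cox proportional-hazards estimate%s\n", lbl))
  cat(sprintf("  HR (treatment vs. comparator) = %.*f, %g%% CI (%.*f, %.*f)\n",
              digits, x$hr, 100 * x$conf_level,
              digits, x$ci_lower, digits, x$ci_upper))
  cat(sprintf("  events: %d / %d subjects (treatment), %d / %d (comparator)\n",
              x$n_events[["treatment"]], x$n_subjects[["treatment"]],
              x$n_events[["comparator"]], x$n_subjects[["comparator"]]))
  invisible(x)
}

#' @export
coef.hazard_estimate <- function(object, ...) c(log_hr = object$log_hr)

#' @export
confint.hazard_estimate <- function(object, parm, level = NULL, ...) {
  if (is.null(level)) level <- object$conf_level
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(ci_lower = exp(object$log_hr - z * object$log_hr_se),
    ci_upper = exp(object$log_hr + z * object$log_hr_se))
}

#' Per-group cumulative incidence (one minus Kaplan-Meier)
#'
#' Product-limit survival per group, reported as cumulative incidence
#' 1 - S(t) with one step per distinct event time.
#'
#' @param followup A `followup` data frame.
#' @return An object of class `cuminc_curves`: a data frame `group`, `time`
#'   (months), `incidence`, plus per-group subject counts.
#' @export
cumulative_incidence <- function(followup) {
  stopifnot(nrow(followup) >= 1L)
  grp <- factor(followup$group)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ grp,
    data = data.frame(time_months = followup$time_months,
                      event = followup$event, grp = grp))
  if (length(levels(grp)) == 1L) {
    curves <- data.frame(group = levels(grp), time = fit$time,
                         incidence = 1 - fit$surv)
  } else {
    curves <- data.frame(
      group = rep(sub("^grp=", "", names(fit$strata)), fit$strata),
      time = fit$time, incidence = 1 - fit$surv)
  }
  curves <- curves[order(curves$group, curves$time), , drop = FALSE]
  rownames(curves) <- NULL
  structure(list(curves = curves,
                 n_subjects = table(grp)),
            class = "cuminc_curves")
}

#' @export
print.cuminc_curves <- function(x, ...) {
  ends <- tapply(x$curves$incidence, x$curves$group, function(z) z[length(z)])
  cat("cumulative-incidence curves (1 - Kaplan-Meier):\n")
  for (g in names(ends))
    cat(sprintf("  %s: %d subjects, final incidence %.3f\n",
                g, x$n_subjects[[g]], ends[[g]]))
  invisible(x)
}

#' @export
plot.cuminc_curves <- function(x, xlab = "months since initiation",
                               ylab = "cumulative incidence", ...) {
  groups <- unique(x$curves$group)
  graphics::plot(NULL, xlim = range(0, x$curves$time),
                 ylim = c(0, max(x$curves$incidence) * 1.05),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(groups)) {
    cc <- x$curves[x$curves$group == groups[i], , drop = FALSE]
    graphics::lines(stats::stepfun(cc$time, c(0, cc$incidence)),
                    do.points = FALSE, col = i, lty = i)
  }
  graphics::legend("topleft", legend = groups, col = seq_along(groups),
                   lty = seq_along(groups), bty = "n")
  invisible(x)
}

#' Fixed-margin non-inferiority decision
#'
#' The treatment is declared non-inferior to the comparator when the upper
#' bound of the two-sided 95% confidence interval for the hazard ratio is
#' strictly below the margin (default 1.3, the conventional cardiovascular
#' safety margin).
#'
#' @param estimate A [fit_cox()] result.
#' @param margin Non-inferiority margin (> 0).
#' @return An object of class `noninferiority_result`: `margin`,
#'   `non_inferior`, and the `estimate`.
#' @export
assess_noninferiority <- function(estimate, margin = 1.3) {
  stopifnot(inherits(estimate, "hazard_estimate"))
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0)
    stop("non-inferiority margin must be a positive number")
  structure(list(margin = margin,
                 non_inferior = estimate$ci_upper < margin,
                 estimate = estimate),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, digits = 2, ...) {
  print(x$estimate, digits = digits)
  cat(sprintf("  non-inferiority at margin %.2f (CI upper %.*f %s %.2f): %s\n",
              x$margin, digits, x$estimate$ci_upper,
              if (x$non_inferior) "<" else ">=", x$margin,
              if (x$non_inferior) "non-inferior" else "not demonstrated"))
  invisible(x)
}
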