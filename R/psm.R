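#' Estimate propensity scores by logistic regression
#'
#' Maximum-likelihood logit of treatment-group membership on the supplied
#' covariates (pulled from the claims `patients` table by name). Constant
#' covariates are dropped with a warning; (quasi-)perfect separation is
#' reported as an error naming the covariate with the largest standardized
#' coefficient.
#'
#' @param cohort Data frame with `patient_id` and `group`.
#' @param dataset A `claims_dataset` providing the covariates.
#' @param covariate_names Character vector of covariate column names in
#'   `dataset$patients`; `sex` is recoded as an indicator automatically.
#' @return An object of class `propensity_model`: coefficients, per-subject
#'   `score` (probability scale) and `logit`, the design data, and the
#'   subject ids/groups.
#' @export
estimate_propensity <- function(cohort, dataset, covariate_names) {
  stopifnot(nrow(cohort) >= 2L)
  if (length(unique(cohort$group)) < 2L)
    stop("propensity estimation needs subjects in both groups")
  pats <- dataset$patients[match(cohort$patient_id, dataset$patients$patient_id),
                           , drop = FALSE]
  X <- pats[, covariate_names, drop = FALSE]
  if ("sex" %in% covariate_names)
    X$sex <- as.numeric(X$sex == "male")
  keep <- vapply(X, function(v) stats::var(as.numeric(v)) > 0, logical(1))
  if (!all(keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(covariate_names[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0L) stop("no non-constant covariates left")
  }
  dat <- cbind(data.frame(.treated = as.numeric(cohort$group == "treatment")), X)
  fit <- suppressWarnings(
    stats::glm(.treated ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  eta <- stats::predict(fit, type = "link")
  if (any(abs(eta) > 15)) {
    std <- abs(stats::coef(fit)[-1]) * vapply(X, function(v) stats::sd(as.numeric(v)), 0)
    stop(sprintf("perfect (or quasi-perfect) separation on covariate `%s`",
                 names(which.max(std))))
  }
  if (!fit$converged) warning("propensity logit did not converge")
  structure(list(coefficients = stats::coef(fit),
                 converged = fit$converged,
                 score = as.numeric(stats::fitted(fit)),
                 logit = as.numeric(eta),
                 patient_id = cohort$patient_id,
                 group = cohort$group,
                 covariates = X),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity model: %d subjects (%d treated), %d covariates\n",
              length(x$score), sum(x$group == "treatment"), ncol(x$covariates)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Wrap externally supplied propensity scores
#'
#' Builds a `propensity_model` from per-subject logit scores computed
#' elsewhere, so [match_nearest_neighbor()] and [balance_diagnostics()] can
#' be used with scores from any estimator.
#'
#' @param patient_id Subject identifiers.
#' @param group Group labels (`treatment`/`comparator`).
#' @param logit Logit-scale propensity scores.
#' @param covariates Optional data frame of covariates (needed only for
#'   balance diagnostics).
#' @return An object of class `propensity_model`.
#' @export
as_propensity_model <- function(patient_id, group, logit, covariates = NULL) {
  stopifnot(length(patient_id) == length(group),
            length(logit) == length(group), all(is.finite(logit)))
  structure(list(coefficients = NULL, converged = NA,
                 score = stats::plogis(logit), logit = as.numeric(logit),
                 patient_id = patient_id, group = group,
                 covariates = covariates),
            class = "propensity_model")
}

#' 1:1 nearest-neighbour caliper matching on the logit score
#'
#' Greedy nearest-neighbour matching without replacement: treated subjects
#' are processed in a seed-shuffled random order; each is paired with the
#' unmatched comparator closest on the logit scale, ties broken towards the
#' lower comparator id; pairs farther apart than the caliper are not
#' formed. The caliper is `caliper_multiplier` times the standard deviation
#' of the logit score pooled over both groups (default 0.2, the
#' conventional choice).
#'
#' @param model A [estimate_propensity()] fit.
#' @param caliper_multiplier Caliper width in pooled-logit SDs.
#' @param seed RNG seed for the treated processing order.
#' @return An object of class `matched_cohort`: `pairs` (data frame
#'   `treated_id`, `comparator_id`, `distance`), `caliper_value`, unmatched
#'   counts, and the matched subject ids.
#' @export
match_nearest_neighbor <- function(model, caliper_multiplier = 0.2, seed = 1L) {
  stopifnot(inherits(model, "propensity_model"))
  caliper <- caliper_multiplier * stats::sd(model$logit)
  ti <- which(model$group == "treatment")
  ci <- which(model$group != "treatment")
  # sort comparators by id: which.min then lands on the lowest id among ties
  ci <- ci[order(model$patient_id[ci])]
  c_logit <- model$logit[ci]
  avail <- rep(TRUE, length(ci))
  order_t <- with_seed(seed, sample(ti))
  pairs <- vector("list", length(order_t))
  k <- 0L
  for (t in order_t) {
    if (!any(avail)) break
    d <- abs(c_logit - model$logit[t])
    d[!avail] <- Inf
    j <- which.min(d)
    if (d[j] <= caliper) {
      k <- k + 1L
      pairs[[k]] <- data.frame(treated_id = model$patient_id[t],
                               comparator_id = model$patient_id[ci[j]],
                               distance = d[j])
      avail[j] <- FALSE
    }
  }
  pairs <- if (k) do.call(rbind, pairs[seq_len(k)]) else
    data.frame(treated_id = character(), comparator_id = character(),
               distance = numeric())
  structure(list(pairs = pairs,
                 caliper_value = caliper,
                 n_unmatched_treated = length(ti) - nrow(pairs),
                 n_unmatched_comparator = length(ci) - nrow(pairs),
                 matched_ids = c(pairs$treated_id, pairs$comparator_id)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(paste0("matched cohort: %d pairs (caliper %.4f on the logit ",
                     "scale); unmatched: %d treated, %d comparator\n"),
              nrow(x$pairs), x$caliper_value,
              x$n_unmatched_treated, x$n_unmatched_comparator))
  invisible(x)
}

#' Standardized mean differences before and after matching
#'
#' SMD = (mean treated - mean comparator) / pooled SD, with the pooled SD
#' the root of the average of the two group variances, computed within each
#' stage. |SMD| below 0.1 is the conventional balance threshold. A zero
#' pooled SD yields SMD 0 with the `degenerate` flag set.
#'
#' @param matched A [match_nearest_neighbor()] result.
#' @param model The [estimate_propensity()] fit the matching was made on
#'   (supplies covariates and groups).
#' @return Data frame: `covariate`, `smd_before`, `smd_after`, `degenerate`.
#' @export
balance_diagnostics <- function(matched, model) {
  stopifnot(inherits(matched, "matched_cohort"),
            inherits(model, "propensity_model"))
  if (nrow(matched$pairs) == 0L) stop("empty matching: no pairs to diagnose")
  smd1 <- function(v, treated) {
    mt <- mean(v[treated]); mc <- mean(v[!treated])
    s <- sqrt((stats::var(v[treated]) + stats::var(v[!treated])) / 2)
    if (!is.finite(s) || s == 0) return(c(0, TRUE))
    c((mt - mc) / s, FALSE)
  }
  treated <- model$group == "treatment"
  in_match <- model$patient_id %in% matched$matched_ids
  out <- lapply(names(model$covariates), function(nm) {
    v <- as.numeric(model$covariates[[nm]])
    b <- smd1(v, treated)
    a <- smd1(v[in_match], treated[in_match])
    data.frame(covariate = nm, smd_before = b[1], smd_after = a[1],
               degenerate = as.logical(b[2] | a[2]))
  })
  do.call(rbind, out)
}
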