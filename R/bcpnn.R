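#' BCPNN prior pseudo-counts
#'
#' Conjugate Beta/Dirichlet pseudo-counts of the Bayesian Confidence
#' Propagation Neural Network (BCPNN) disproportionality model in its
#' WHO-UMC closed-form parameterization. `alpha1`/`beta1` act on the drug
#' and event margins, `alpha`/`beta` on their totals, and `gamma11` on the
#' joint cell. The joint-total pseudo-count `gamma` is not free: it is
#' derived from the observed margins inside [ic_moments()] so that the
#' prior is centred at independence (IC = 0).
#'
#' @param alpha1,beta1 Margin pseudo-counts (default 1).
#' @param alpha,beta Margin-total pseudo-counts (default 2).
#' @param gamma11 Joint-cell pseudo-count (default 1).
#' @return An object of class `bcpnn_prior`.
#' @examples
#' bcpnn_prior()
#' @export
bcpnn_prior <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        is.na(vals[[nm]]) || vals[[nm]] <= 0)
      stop_config(nm, "prior pseudo-counts must be strictly positive")
  }
  structure(as.list(vals), class = "bcpnn_prior")
}

#' Posterior moments of the information component
#'
#' Closed-form posterior mean and variance of the information component
#' IC = log2 p11 / (p1. * p.1) for a 2x2 drug-event contingency table under
#' the BCPNN model. With n the table counts and the prior pseudo-counts of
#' [bcpnn_prior()], the derived joint-total pseudo-count is
#' gamma = gamma11 (n.. + alpha)(n.. + beta) / ((n1. + alpha1)(n.1 + beta1)),
#' the posterior mean is
#' E(IC) = log2 (n11 + gamma11)(n.. + alpha)(n.. + beta) /
#'              ((n.. + gamma)(n1. + alpha1)(n.1 + beta1)),
#' and the posterior variance (in bits^2; the 1/ln(2)^2 factor converts the
#' natural-log variance) is
#' V(IC) = ln(2)^-2 * ((n.. - n11 + gamma - gamma11)/((n11 + gamma11)(1 + n.. + gamma))
#'   + (n.. - n1. + alpha - alpha1)/((n1. + alpha1)(1 + n.. + alpha))
#'   + (n.. - n.1 + beta - beta1)/((n.1 + beta1)(1 + n.. + beta))).
#'
#' @param table A [contingency_table()].
#' @param prior A [bcpnn_prior()].
#' @return Named numeric vector with elements `expected_ic` (bits) and
#'   `variance_ic` (bits squared).
#' @examples
#' tab <- contingency_table(25, 100, 200, 10000)
#' ic_moments(tab)
#' @export
ic_moments <- function(table, prior = bcpnn_prior()) {
  stopifnot(inherits(table, "contingency_table"), inherits(prior, "bcpnn_prior"))
  n11 <- table$n11; n1. <- table$n1dot; n.1 <- table$ndot1; n.. <- table$ndotdot
  if (n.. == 0)
    stop("degenerate contingency table: n.. = 0 (no cases, prior-only signal refused)")
  g11 <- prior$gamma11
  gamma <- g11 * (n.. + prior$alpha) * (n.. + prior$beta) /
    ((n1. + prior$alpha1) * (n.1 + prior$beta1))
  e_ic <- log2((n11 + g11) * (n.. + prior$alpha) * (n.. + prior$beta) /
                 ((n.. + gamma) * (n1. + prior$alpha1) * (n.1 + prior$beta1)))
  v_ic <- (1 / log(2)^2) * (
    (n.. - n11 + gamma - g11) / ((n11 + g11) * (1 + n.. + gamma)) +
    (n.. - n1. + prior$alpha - prior$alpha1) / ((n1. + prior$alpha1) * (1 + n.. + prior$alpha)) +
    (n.. - n.1 + prior$beta - prior$beta1) / ((n.1 + prior$beta1) * (1 + n.. + prior$beta)))
  c(expected_ic = e_ic, variance_ic = v_ic)
}

#' Credible interval for the information component
#'
#' Normal approximation E(IC) +/- z * sqrt(V(IC)) on the closed-form
#' posterior moments. For `level = 0.95`, z = 1.959964.
#'
#' @param expected_ic Posterior mean IC in bits.
#' @param variance_ic Posterior variance in bits squared; must be >= 0.
#' @param level Two-sided credibility level in (0, 1).
#' @return Named numeric vector `c(ic_lower, ic_upper)`.
#' @examples
#' ic_credible_interval(1, 0.25)  # 1 +/- 1.96 * 0.5
#' @export
ic_credible_interval <- function(expected_ic, variance_ic, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop("`level` must lie strictly inside (0, 1)")
  if (variance_ic < 0) stop("`variance_ic` must be non-negative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance_ic)
  c(ic_lower = expected_ic - half, ic_upper = expected_ic + half)
}

#' BCPNN signal detection for one drug-event pair
#'
#' Composes [ic_moments()] and [ic_credible_interval()] and applies the
#' signal-of-disproportionate-reporting (SDR) criterion: the pair is flagged
#' when the lower credible bound IC025 is strictly greater than zero.
#'
#' @param table A [contingency_table()].
#' @param prior A [bcpnn_prior()].
#' @param level Credibility level (default 0.95).
#' @return An object of class `bcpnn_signal` with fields `expected_ic`,
#'   `variance_ic`, `ic_lower`, `ic_upper`, `is_sdr`, `n11`, `level`.
#' @examples
#' detect_signal(contingency_table(30, 100, 200, 100000))
#' @export
detect_signal <- function(table, prior = bcpnn_prior(), level = 0.95) {
  mom <- ic_moments(table, prior)
  ci <- ic_credible_interval(mom[["expected_ic"]], mom[["variance_ic"]], level)
  structure(
    list(expected_ic = mom[["expected_ic"]],
         variance_ic = mom[["variance_ic"]],
         ic_lower = ci[["ic_lower"]],
         ic_upper = ci[["ic_upper"]],
         is_sdr = ci[["ic_lower"]] > 0,
         n11 = table$n11,
         level = level,
         table = table),
    class = "bcpnn_signal")
}

#' @export
print.bcpnn_signal <- function(x, digits = 2, ...) {
  cat(sprintf("BCPNN information component (n11 = %d)\n", x$n11))
  cat(sprintf("  IC = %.*f, %g%% credible interval (%.*f, %.*f)\n",
              digits, x$expected_ic, 100 * x$level,
              digits, x$ic_lower, digits, x$ic_upper))
  cat(sprintf("  signal of disproportionate reporting (IC025 > 0): %s\n",
              if (x$is_sdr) "yes" else "no"))
  invisible(x)
}

#' @export
coef.bcpnn_signal <- function(object, ...) {
  c(ic = object$expected_ic)
}

#' @export
confint.bcpnn_signal <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && level != object$level) {
    ci <- ic_credible_interval(object$expected_ic, object$variance_ic, level)
    return(ci)
  }
  c(ic_lower = object$ic_lower, ic_upper = object$ic_upper)
}

#' Monte-Carlo oracle for the IC posterior
#'
#' Independent validation of the closed-form moments: samples the three
#' reporting probabilities from the conjugate Beta posteriors implied by the
#' BCPNN model,
#' p11 ~ Beta(n11 + gamma11, n.. - n11 + gamma - gamma11),
#' p1. ~ Beta(n1. + alpha1, n.. - n1. + alpha - alpha1),
#' p.1 ~ Beta(n.1 + beta1,  n.. - n.1 + beta - beta1),
#' computes IC = log2 p11/(p1. p.1) per draw and returns the empirical
#' moments and 2.5/97.5 percentiles.
#'
#' @param table A [contingency_table()].
#' @param prior A [bcpnn_prior()].
#' @param n_draws Number of posterior draws (>= 1e4).
#' @param seed RNG seed; output is deterministic given the seed.
#' @return Named vector `mean`, `variance`, `p2.5`, `p97.5` (all in bits).
#' @export
mc_ic_oracle <- function(table, prior = bcpnn_prior(), n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(table, "contingency_table"))
  if (n_draws < 1e4) stop("`n_draws` must be at least 10^4")
  n11 <- table$n11; n1. <- table$n1dot; n.1 <- table$ndot1; n.. <- table$ndotdot
  if (n.. == 0) stop("degenerate contingency table: n.. = 0")
  gamma <- prior$gamma11 * (n.. + prior$alpha) * (n.. + prior$beta) /
    ((n1. + prior$alpha1) * (n.1 + prior$beta1))
  with_seed(seed, {
    p11 <- stats::rbeta(n_draws, n11 + prior$gamma11, n.. - n11 + gamma - prior$gamma11)
    p1. <- stats::rbeta(n_draws, n1. + prior$alpha1, n.. - n1. + prior$alpha - prior$alpha1)
    p.1 <- stats::rbeta(n_draws, n.1 + prior$beta1, n.. - n.1 + prior$beta - prior$beta1)
    ic <- log2(p11 / (p1. * p.1))
    q <- stats::quantile(ic, c(0.025, 0.975), names = FALSE)
    c(mean = mean(ic), variance = stats::var(ic), `p2.5` = q[1], `p97.5` = q[2])
  })
}
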