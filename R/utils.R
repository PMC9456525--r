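# Shared internals: calendar arithmetic and scoped RNG.

# Average Gregorian month; all month<->day conversions in the package go
# through these two helpers so follow-up times and exclusion windows agree.
DAYS_PER_MONTH <- 30.4375

months_to_days <- function(m) m * DAYS_PER_MONTH
days_to_months <- function(d) d / DAYS_PER_MONTH

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop_config(field, "must be a probability strictly inside (0, 1)")
  invisible(x)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}
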