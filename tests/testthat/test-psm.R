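# builds a cohort + dataset pair straight from patient-level vectors
psm_fixture <- function(group, covariates) {
  n <- length(group)
  ids <- sprintf("p%04d", seq_len(n))
  pats <- cbind(data.frame(patient_id = ids,
                           birth_date = as.Date("1965-01-01"), sex = "male"),
                as.data.frame(covariates))
  list(cohort = data.frame(patient_id = ids, group = group,
                           index_date = as.Date("2017-05-01")),
       dataset = make_claims(pats, full_enrollment(ids),
                             data.frame(patient_id = character(),
                                        date = as.Date(character()),
                                        drug_class = character())))
}

test_that("a pure-noise covariate gets a slope within 3 SE of zero", {
  fx <- compsafety:::with_seed(11, {
    psm_fixture(sample(c("treatment", "comparator"), 5000, replace = TRUE),
                list(x1 = rnorm(5000)))
  })
  m <- estimate_propensity(fx$cohort, fx$dataset, "x1")
  se <- sqrt(diag(stats::vcov(stats::glm(
    I(fx$cohort$group == "treatment") ~ fx$dataset$patients$x1,
    family = stats::binomial()))))[2]
  expect_lt(abs(m$coefficients[["x1"]]), 3 * se)
  expect_true(m$converged)
  expect_true(all(m$score > 0 & m$score < 1))
})

test_that("the generator's assignment coefficients are recovered within 3 SE", {
  cfg <- claims_sim_config(n_patients = 1e4, seed = 31)
  ds <- generate_claims_population(cfg)
  cand <- identify_new_users(ds, cohort_spec())
  m <- estimate_propensity(cand, ds, c("x1", "x2", "x3"))
  glm_se <- sqrt(diag(stats::vcov(stats::glm(
    treated ~ x1 + x2 + x3,
    data = cbind(ds$truth["treated"], ds$patients[c("x1", "x2", "x3")]),
    family = stats::binomial()))))
  truthv <- c(`(Intercept)` = cfg$treatment_intercept,
              x1 = 0.5, x2 = 0.5, x3 = 0.3)
  for (nm in names(truthv))
    expect_lt(abs(m$coefficients[[nm]] - truthv[[nm]]), 3 * glm_se[[nm]])
})

test_that("degenerate covariates are reported, not silently fitted", {
  fx <- compsafety:::with_seed(5, {
    psm_fixture(rep(c("treatment", "comparator"), each = 50),
                list(x1 = rnorm(100), x2 = rep(1, 100)))
  })
  expect_warning(m <- estimate_propensity(fx$cohort, fx$dataset, c("x1", "x2")),
                 "constant covariate")
  expect_false("x2" %in% names(m$coefficients))

  sep <- psm_fixture(rep(c("treatment", "comparator"), each = 50),
                     list(x1 = rep(c(1, 0), each = 50)))
  expect_error(estimate_propensity(sep$cohort, sep$dataset, "x1"),
               "separation on covariate `x1`")
})

test_that("matching pairs score-duplicates and respects the caliper", {
  logit <- stats::qlogis(c(0.1, 0.25, 0.4, 0.55, 0.7))
  m <- as_propensity_model(sprintf("p%02d", 1:10),
                           rep(c("treatment", "comparator"), each = 5),
                           rep(logit, 2))
  mt <- match_nearest_neighbor(m, seed = 2)
  expect_equal(nrow(mt$pairs), 5L)
  expect_true(all(mt$pairs$distance == 0))
  # each treated subject p0k pairs with its score-duplicate p0(k+5)
  got <- mt$pairs[order(mt$pairs$treated_id), ]
  expect_equal(got$comparator_id, sprintf("p%02d", 6:10))

  # a treated subject farther than the caliper from every comparator
  mfar <- as_propensity_model(sprintf("q%d", 1:5),
                              c("treatment", rep("comparator", 4)),
                              c(10, 0, 0.1, -0.1, 0.2))
  expect_equal(nrow(match_nearest_neighbor(mfar, seed = 1)$pairs), 0L)
})

test_that("matching is without replacement, tie-broken to the lower id, seed-stable", {
  grp <- rep(c("treatment", "comparator"), c(3, 6))
  # comparators p0004..p0009 at +/-0.25 offsets (exact in binary floating
  # point, so the distances tie exactly)
  m <- as_propensity_model(sprintf("p%04d", 1:9), grp,
                           c(0, 1, 2, 0.25, -0.25, 1.25, 0.75, 2.25, 1.75))
  mt <- match_nearest_neighbor(m, caliper_multiplier = 10, seed = 7)
  expect_equal(nrow(mt$pairs), 3L)
  expect_false(any(duplicated(c(mt$pairs$treated_id, mt$pairs$comparator_id))))
  # each treated's match is the lower-id member of its equidistant pair
  expect_setequal(mt$pairs$comparator_id[order(mt$pairs$treated_id)],
                  c("p0004", "p0006", "p0008"))
  expect_identical(mt$pairs, match_nearest_neighbor(m, 10, seed = 7)$pairs)
  expect_true(all(mt$pairs$distance <= mt$caliper_value))
})

test_that("greedy matching is near the optimal assignment on a small instance", {
  fx <- compsafety:::with_seed(19, {
    psm_fixture(rep(c("treatment", "comparator"), c(5, 7)),
                list(x1 = rnorm(12)))
  })
  m <- estimate_propensity(fx$cohort, fx$dataset, "x1")
  mt <- match_nearest_neighbor(m, seed = 3)
  # exhaustive enumeration over all injective treated -> comparator maps
  ti <- which(m$group == "treatment"); ci <- which(m$group == "comparator")
  best <- list(pairs = -1L, dist = Inf)
  recurse <- function(k, used, npairs, dist) {
    if (k > length(ti)) {
      if (npairs > best$pairs ||
          (npairs == best$pairs && dist < best$dist))
        best <<- list(pairs = npairs, dist = dist)
      return(invisible())
    }
    recurse(k + 1L, used, npairs, dist)  # leave treated k unmatched
    for (j in seq_along(ci)) {
      if (used[j]) next
      d <- abs(m$logit[ti[k]] - m$logit[ci[j]])
      if (d <= mt$caliper_value) {
        used[j] <- TRUE
        recurse(k + 1L, used, npairs + 1L, dist + d)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(ci)), 0L, 0)
  expect_equal(nrow(mt$pairs), best$pairs)
  expect_lte(sum(mt$pairs$distance), 1.05 * best$dist)
})

test_that("balance diagnostics: zero for identical groups, repaired by matching", {
  fx <- psm_fixture(rep(c("treatment", "comparator"), each = 4),
                    list(x1 = rep(c(1, 2, 3, 4), 2), x2 = rep(5, 8)))
  expect_warning(m <- estimate_propensity(fx$cohort, fx$dataset, c("x1", "x2")),
                 "constant")
  mt <- match_nearest_neighbor(m, caliper_multiplier = 10, seed = 1)
  bal <- balance_diagnostics(mt, m)
  expect_true(all(bal$smd_before == 0) && all(bal$smd_after == 0))

  cfg <- claims_sim_config(n_patients = 4000, seed = 43)
  ds <- generate_claims_population(cfg)
  coh <- apply_exclusions(identify_new_users(ds, cohort_spec()), ds, cohort_spec())
  m2 <- estimate_propensity(coh, ds, c("sex", "x1", "x2", "x3"))
  mt2 <- match_nearest_neighbor(m2, seed = 4)
  bal2 <- balance_diagnostics(mt2, m2)
  expect_lt(max(abs(bal2$smd_after)), max(abs(bal2$smd_before)))
  expect_lt(max(abs(bal2$smd_after)), 0.1)
  expect_false(any(duplicated(mt2$matched_ids)))
  expect_lte(max(mt2$pairs$distance), mt2$caliper_value)
})
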