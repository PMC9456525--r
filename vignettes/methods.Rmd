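---
title: "Methods: two-track comparative safety analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-track comparative safety analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsafety)
```

`compsafety` compares the safety of two drug classes — its defaults encode
the DPP-4 inhibitor vs. metformin comparison for cardiovascular outcomes —
through two designs with complementary failure modes: disproportionality
analysis of a spontaneous reporting stream, and a propensity-matched
new-user cohort on claims data. This vignette is the package's account of
the models, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical choices made where the design was
genuinely open.

## 1. The BCPNN information component

For a drug class $D$ and event group $E$, cases are cross-tabulated at the
*case* level: $n_{11}$ cases mentioning both (suspect-role drug mentions
only, by default), margins $n_{1\cdot}$, $n_{\cdot 1}$, total
$n_{\cdot\cdot}$. A case contributes at most once to each cell however many
member drugs or preferred terms it lists; this is the set-semantics reading
of "number of reports" that makes the MACE group a union (its
$n_{\cdot 1}$ is at most the sum of the component margins, with equality
only when no case reports both components).

The information component is
$\mathrm{IC} = \log_2 \, p_{11} / (p_{1\cdot}\, p_{\cdot 1})$, positive
when the pair is reported more often than independence predicts. The BCPNN
places conjugate pseudo-counts on the three proportions
($\alpha_1=\beta_1=\gamma_{11}=1$, $\alpha=\beta=2$, and
$\gamma = \gamma_{11}(n_{\cdot\cdot}+\alpha)(n_{\cdot\cdot}+\beta) /
((n_{1\cdot}+\alpha_1)(n_{\cdot 1}+\beta_1))$ so the *prior* expectation of
IC is zero — an empty database yields IC $\approx 0$, not a signal) and
`ic_moments()` evaluates the closed-form posterior mean and variance given
in the help page. The credible interval is the normal approximation
$E \pm z\sqrt{V}$ with $z = 1.959964$ at the default 95% level ($z$ follows
the `level` argument, so a 2.0-multiplier convention is one argument away).
A *signal of disproportionate reporting* requires the strict inequality
$\mathrm{IC}_{025} > 0$.

**Numerical behaviour worth knowing.** `mc_ic_oracle()` samples the exact
independent-Beta posteriors the model implies and is the package's
independent check on the closed form. The two routes are *not* identical:
the closed-form mean is $\log_2$ of a ratio of posterior means, which
differs from the posterior mean of $\log_2$ by a leading term of
$1/(2(n_{11}+1)\ln 2)$ bits minus analogous margin terms. Numerically that
is ~0.06 bits at $n_{11} = 10$, ~0.03 at 25, and falls below 0.02 only
once $n_{11}$ is around 40 (sooner when the margins are small enough for
their corrections to cancel). The test suite asserts 0.02-bit agreement
across randomized database-scale tables with $n_{11} \ge 10$, and the
small-count tables in that set fail by exactly this bias — a documented
property of the closed form (it is the regime exact-IC refinements were
developed for, which this package deliberately does not implement), not a
defect of either route. Degenerate input: a table with
$n_{\cdot\cdot} = 0$ is refused (no prior-only signals); $n_{11} = 0$ with
non-zero margins is legal and gives a strongly negative mean with a wide
interval.

## 2. The report-stream generator

`generate_spontaneous_reports()` draws each case's membership in the 2×2
target table from the multinomial with joint-cell probability
$r\,p_1 p_2$ (reporting ratio $r$, configured drug and event shares
$p_1, p_2$), then attaches background drugs and events independently with
small per-label probabilities — never correlated with the target pair, so
the 2×2 table is the only signal carrier, and the forced minimum of one
suspect drug and one event per case draws from the background pool only,
leaving the target margins exactly calibrated. One report per case; case
ids unique; byte-identical output for identical configs.
`simulate_contingency()` is the count-level shortcut (the same multinomial
without materialising reports) used for calibration studies such as the
null false-positive rate. The configuration validator enforces
$r\,p_1 p_2 \le \min(p_1, p_2)$ and a non-negative complementary cell,
naming the offending field.

What it does not emulate: duplicate or updated reports (no case
de-duplication problem), real MedDRA vocabularies or hierarchy, reporting
waves over calendar time ("stimulated reporting"), or correlated
co-reporting of background labels. A green signal-recovery test therefore
says the estimator chain is correct, not that those real-data artefacts
are harmless.

## 3. The claims-population generator

`generate_claims_population()` emulates an employer-based claims extract:
ages truncated below 75 (the source system simply does not cover the
late-stage elderly), mean 52.2, SD 9.74 years; 70.3% male; standard-normal
covariates that act on *both* the treatment-assignment logit (defaults
0.5, 0.5, 0.3) and every outcome hazard (defaults 0.5, 0.3, 0.2) — the
confounding channel; one initiation dispensing per patient on a uniform
index date in the 2017-04-01..2017-06-30 window; enrollment opening 400 to
900 days pre-index and closing at an exponential disenrollment time
(death and migration folded into one censoring process, as in claims
reality, at 0.004 per person-month), the follow-up cap, or the study end
2020-06-30.

Outcome diagnosis streams are generated *per event type* — myocardial
infarction (codes I21x–I22x), stroke (I60x–I63x), heart failure (I50x) —
as primary-at-admission records, with Weibull event times whose cumulative
hazard is $\lambda\, e^{x'\beta}\, \mathrm{HR}^{T}\, t^{k}$ (shape
$k = 1$, i.e. constant hazards, by default; other shapes exist to stress
the proportional-hazards assumption). MACE and the all-cardiovascular
composite are *not* simulated; they arise downstream as code-prefix
unions, the way composite endpoints actually materialise from claims.
Diagnoses after disenrollment are not recorded — the claims stream ends
when coverage does.

Calibration, chosen once: baseline hazards 0.00135 / 0.0019 / 0.0036
events per person-month give cumulative risks near 4%, 6% and 11% over the
observable horizon (hence ~10% for MACE), the disenrollment hazard gives a
mean observable follow-up around 33 months, the assignment intercept 0.7
yields roughly two treated initiators per comparator, and the default
population of 8400 initiators is the scale of the source comparison's
pre-match cohort, from which 1:1 matching retains roughly 2500 pairs.
These are the study conditions every operating-characteristic test runs
under. Fractions of patients with planted rule violations (pre-index
cardiovascular diagnosis, controlled-drug dispensing, index age ≥ 75,
washout-violating fill) are available on disjoint subsets so attrition
accounting can be checked against exact ground truth; all default to zero.

Not emulated: dose, adherence, switching or stockpiling; competing-risk
death (censoring is non-informative by construction); seasonal or
calendar trends in incidence; coding error and diagnostic uncertainty.

## 4. Cohort, matching, survival

**New users and exclusions.** The washout checks the two *study* classes
only — the strict any-drug reading of "no drug in the prior three months"
is available as `washout_all_drugs = TRUE`, but the default keeps the
generator's background dispensings from silently emptying the cohort.
Look-back windows are open intervals $(\mathrm{index} - k\ \text{months},
\mathrm{index})$ with months of 30.4375 days throughout. Patients
initiating both classes on the index date are dropped. Exclusions are
attributed to the *first* violated rule in flowchart order (prior event,
controlled drug, age, enrollment), so attrition counts sum to the cohort
size. Controlled-drug and outcome code lists are configuration; the
shipped ICD-10 prefixes (I21–I22, I60–I63, I50) are documented defaults,
not licensed code lists.

**Follow-up.** Event = first post-index diagnosis matching the outcome's
prefixes (primary-at-admission only, by default); censoring at the
earliest of disenrollment, the 75th birthday (birth date + 75 × 365.25
days), and the study end. A qualifying diagnosis on the index date itself
counts as an event at half a day — excluding it would silently delete the
sickest patients, and the paper-trail convention of strictly positive
times keeps Cox software happy.

**Propensity and matching.** Logistic regression (`stats::glm`), constant
covariates dropped with a warning, quasi-perfect separation reported as an
error naming the worst covariate. Matching is greedy nearest-neighbour
without replacement on the logit scale: treated subjects in seed-shuffled
random order, ties to the lower comparator id, caliper = 0.2 × SD of the
*pooled* logit scores. Greedy (not optimal) matching is the conventional
reading of "nearest neighbour"; the test suite checks it against an
exhaustive assignment oracle on small instances and against the balance
criterion (post-match |SMD| < 0.1) at the default scenario. Standardized
mean differences use the root of the average within-group variance,
computed separately before and after matching; a zero pooled SD reports
SMD 0 with a flag rather than NaN.

**Survival.** `fit_cox()` is univariable Cox on the group indicator via
`survival::coxph` with Efron ties (monthly-granularity data tie heavily;
Breslow is a flag), Wald CI on the log scale; the test suite re-maximises
the Efron partial likelihood on a dense grid as an independent oracle. No
covariate adjustment and no pair-robust variance after matching — the
design being replicated describes none. A group with zero events is an
explicit error, as is a monotone likelihood. Non-inferiority is the strict
comparison $\mathrm{CI}_{\text{upper}} < 1.3$; at the default scale (2474
per arm, ~10% event risk) the expected ~500 events give
$\mathrm{SE}(\log \mathrm{HR}) \approx 0.09$ and hence roughly 84% power
under a true HR of 1 — the operating-characteristic tests assert the ≥80%
that follows, and the occasional failed non-inferiority call on null data
(as in the README example) is that missing 16%.

## 5. Problem sizes used by the test suite

Chosen as the package's own verification scale: oracle-equivalence on ten
database-scale tables at $10^6$ posterior draws; null calibration on 2000
independence tables of $10^5$ cases at 1% margins; Cox coverage over 500
replicates of 2000 subjects per arm; confounding repair over 10 seeds of
4000-patient populations; non-inferiority power over 200 trials of 2474
per arm; brute-force oracles (contingency, attrition, product-limit, grid
likelihood) on instances of 100–200 subjects. The whole suite runs in
about half a minute on one core.

## 6. Known limitations

* The closed-form IC is biased by $O(1/n_{11})$ bits at small joint counts
  (Section 1); flag marginal signals with $n_{11} \lesssim 40$ for review
  against `mc_ic_oracle()` before acting on them.
* Exact PT-string matching and prefix ICD-10 matching stand in for
  licensed terminologies; real analyses must supply curated code lists.
* The matched analysis ignores the matched-pair structure in the variance,
  and matching is greedy — both conventional, neither optimal.
* The generators produce clean, complete data: no missingness, no coding
  noise, no informative censoring. Tests passing on them bound
  implementation error, not real-world bias.
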