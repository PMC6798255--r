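test_that("identical numerator and denominator models give unit factors", {
  co <- simulate_cohort(sim_config(n_persons = 300, seed = 21,
                                   missingness = "none"))
  tw <- treatment_weight_components(
    co, "regimen", ~ prev_regimen + age_c, ~ prev_regimen + age_c,
    subset = co$visit >= 1)
  w <- co$visit >= 1
  expect_equal(tw$num[w], tw$den[w], tolerance = 1e-10)
})

test_that("stabilized factors and cumulative weights follow the defining
          arithmetic", {
  # hand-built 2-visit toy with stipulated probabilities
  tc <- list(num = c(0.5, 0.4), den = c(0.25, 0.8))
  cc <- list(num = c(1, 1), den = c(1, 1))
  sw <- stabilized_weights(tc, cc, id = c(1, 1))
  expect_equal(sw, c(2.0, 1.0))              # factors (2.0, 0.5) cumulated
  expect_equal(stabilized_weights(tc, cc, id = c(1, 1), cumulative = FALSE),
               c(2.0, 0.5))
  # censoring factors multiply in
  cc2 <- list(num = c(0.9, 0.9), den = c(0.6, 0.95))
  sw2 <- stabilized_weights(tc, cc2, id = c(1, 1))
  expect_equal(sw2[1], 2.0 * 0.9 / 0.6)
  expect_equal(sw2[2], sw2[1] * 0.5 * 0.9 / 0.95)
})

test_that("no censoring in the data yields unit censoring components", {
  cfg <- null_config(200, seed = 22, censored = FALSE)
  co <- simulate_cohort(cfg)
  expect_equal(as.integer(table(co$id)), rep(6L, 200))  # everyone completes
  cw <- censoring_weight_components(co, ~ age_c, ~ age_c + comorb)
  expect_equal(cw$num, rep(1, nrow(co)))
  expect_equal(cw$den, rep(1, nrow(co)))
  expect_null(cw$models)
})

test_that("non-informative censoring gives factors near one", {
  cfg <- sim_config(n_persons = 4000, seed = 23, missingness = "none")
  cfg$censoring[] <- 0
  cfg$censoring["intercept"] <- -2.2   # ~10% dropout, independent of state
  co <- simulate_cohort(cfg)
  cw <- censoring_weight_components(
    co, ~ regimen + age_c, ~ regimen + age_c + cd4_cat + rna_det + comorb,
    max_visits = 6)
  fac <- cw$num / cw$den
  expect_equal(mean(fac), 1, tolerance = 0.01)
  expect_lt(sd(fac), 0.05)
})

test_that("denominator covariates must contain the numerator set", {
  co <- simulate_cohort(sim_config(n_persons = 100, seed = 24,
                                   missingness = "none"))
  expect_error(
    iptc_weights(co, "regimen", numerator = ~ age_c + grp,
                 denominator = ~ age_c + cd4_cat),
    "grp")
})

test_that("truncation clamps to percentile bounds from a sorting oracle and
          is idempotent", {
  # stated operating point: bounds (0.03, 10)
  tr <- truncate_weights(c(0.01, 0.5, 20), bounds = c(0.03, 10))
  expect_equal(tr$weights, c(0.03, 0.5, 10))
  expect_equal(tr$n_truncated, 2)
  # percentile bounds on 1..1000 against a direct order-statistic formula
  w <- as.numeric(1:1000)
  tr2 <- truncate_weights(w, 1, 99)
  h <- function(p) { hh <- 1 + p * 999; lo <- floor(hh); w[lo] + (hh - lo) }
  expect_equal(tr2$bounds, c(h(.01), h(.99)))
  expect_equal(max(tr2$weights), tr2$bounds[2])
  expect_equal(min(tr2$weights), tr2$bounds[1])
  # idempotence
  tr3 <- truncate_weights(tr2$weights, bounds = tr2$bounds)
  expect_equal(tr3$weights, tr2$weights)
  expect_equal(tr3$n_truncated, 0)
  # untouched interior values
  expect_equal(tr2$weights[500], 500)
})

test_that("weight diagnostics summarize deterministically", {
  d <- weight_diagnostics(rep(1, 50), bounds = c(0.03, 10), n_truncated = 0)
  expect_equal(d$mean, 1)
  expect_equal(d$sd, 0)
  expect_equal(d$n_truncated, 0)
  w <- as.numeric(1:100)
  d2 <- weight_diagnostics(w)
  expect_equal(d2$percentiles$`50%`, 50.5)
  expect_equal(d2$max, 100)
})

test_that("cumulative stabilized weights average near one and balance the
          time-varying confounders", {
  co <- simulate_cohort(sim_config(n_persons = 3000, seed = 25,
                                   missingness = "none"))
  co <- cartmsm:::.add_age_spline(as.data.frame(co),
                                  rq_spline_knots(co$age))
  w <- iptc_weights(
    co, "regimen",
    numerator = ~ prev_regimen + age_c + age_s1 + age_s2 + grp,
    denominator = ~ prev_regimen + age_c + age_s1 + age_s2 + grp +
      cd4_cat + rna_det + comorb,
    censor_numerator = ~ regimen + age_c + grp,
    censor_denominator = ~ regimen + age_c + grp + cd4_cat + rna_det +
      comorb,
    max_visits = 6)
  win <- co$visit >= 1
  expect_equal(mean(w$sw[win]), 1, tolerance = 0.1)
  # visit-level stabilization identity: E[num/den] = 1
  expect_equal(mean((w$t_num / w$t_den)[win]), 1, tolerance = 0.05)
})

test_that("inverse-probability weighting removes the confounder-treatment
          association within visits", {
  # marginal stabilization (intercept-only numerator): in the weighted
  # pseudo-population treatment is assigned independently of everything,
  # so the cross-sectional standardized differences must vanish. Channeling
  # is halved relative to the reference conditions so that the Monte-Carlo
  # noise of the inverse weights stays well below the 0.1 threshold.
  cfg <- sim_config(n_persons = 5000, seed = 26, missingness = "none")
  cfg$treatment$coefs <- cfg$treatment$coefs / 2
  co <- as.data.frame(simulate_cohort(cfg))
  win <- co$visit >= 1
  den <- ~ prev_regimen + age_c + grp + cd4_cat + rna_det + comorb
  tw <- suppressWarnings(treatment_weight_components(
    co, "regimen", ~ 1, den, subset = win))
  fac <- (tw$num / tw$den)[win]
  cov_names <- c("cd4_cat", "rna_det", "comorb")
  smd_un <- weighted_smd(co[win, ], cov_names, "regimen")
  smd_wt <- weighted_smd(co[win, ], cov_names, "regimen", weights = fac)
  expect_gt(max(abs(smd_un)), 0.2)   # channeling is real before weighting
  expect_lt(max(abs(smd_wt)), 0.1)

  # under the full-strength reference channeling the weights still remove
  # the bulk of the imbalance
  co2 <- as.data.frame(simulate_cohort(
    sim_config(n_persons = 3000, seed = 27, missingness = "none")))
  win2 <- co2$visit >= 1
  tw2 <- suppressWarnings(treatment_weight_components(
    co2, "regimen", ~ 1, den, subset = win2))
  s_un <- weighted_smd(co2[win2, ], cov_names, "regimen")
  s_wt <- weighted_smd(co2[win2, ], cov_names, "regimen",
                       weights = (tw2$num / tw2$den)[win2])
  expect_lt(max(abs(s_wt)), max(abs(s_un)) / 2)
})
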