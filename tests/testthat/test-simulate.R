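test_that("simulation is bit-reproducible and extends without reshuffling
          earlier persons", {
  strip <- function(co) {
    d <- as.data.frame(co)
    attr(d, "truth") <- NULL
    attr(d, "config") <- NULL
    rownames(d) <- NULL
    d
  }
  cfg <- sim_config(n_persons = 120, seed = 51)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(serialize(strip(c1), NULL), serialize(strip(c2), NULL))
  # growing the cohort leaves the first persons' rows unchanged
  big <- simulate_cohort(sim_config(n_persons = 240, seed = 51))
  expect_identical(strip(c1), strip(big[big$id <= 120, ]))
})

test_that("disabling censoring yields complete follow-up", {
  co <- simulate_cohort(null_config(150, seed = 52, censored = FALSE))
  expect_true(all(table(co$id) == 6))
  # visit indices consecutive from zero within person
  by_id <- split(co$visit, co$id)
  expect_true(all(vapply(by_id, function(v) all(v == seq_along(v) - 1),
                         logical(1))))
})

test_that("dropout is absorbing: no gaps after a censoring event", {
  co <- simulate_cohort(sim_config(n_persons = 400, seed = 53))
  by_id <- split(co$visit, co$id)
  expect_true(all(vapply(by_id, function(v) all(diff(v) == 1), logical(1))))
  expect_lt(mean(table(co$id)), 6)   # some dropout does occur
})

test_that("zero channeling coefficients make regimen independent of the
          confounders", {
  cfg <- null_config(5000, seed = 54, confounded = FALSE, censored = FALSE)
  co <- simulate_cohort(cfg)
  w <- co$visit == 0    # first visit: no stickiness, pure assignment model
  p <- chisq.test(table(co$cd4_cat[w], as.character(co$regimen[w])))$p.value
  expect_gt(p, 0.01)
  p2 <- chisq.test(table(co$rna_det[w], as.character(co$regimen[w])))$p.value
  expect_gt(p2, 0.01)
})

test_that("missingness masking hits the configured columns at the
          configured rates", {
  cfg <- sim_config(n_persons = 3000, seed = 55)
  co <- simulate_cohort(cfg)
  fr <- colMeans(is.na(co[c("y_adhere", "y_suppress", "rna_det", "comorb")]))
  target <- c(0.03, 0.08, 0.06, 0.13)
  for (j in 1:4) {
    tol <- 3 * sqrt(target[j] * (1 - target[j]) / nrow(co))
    expect_lt(abs(fr[j] - target[j]), tol)
  }
  expect_false(anyNA(co$regimen))
})

test_that("probability-overflow configurations are rejected at validation", {
  cfg <- sim_config(n_persons = 10, seed = 1)
  cfg$outcomes$y_switch$intercept <- log(0.9)
  expect_error(validate_sim_config(cfg), "y_switch")
  cfg2 <- sim_config(n_persons = 10, seed = 1)
  cfg2$regimens <- cfg2$regimens[1:5]
  expect_error(validate_sim_config(cfg2), "7 regimen")
})

test_that("null regimen effects give marginal rate ratios of one", {
  cfg <- null_config(100, seed = 56)
  t <- true_marginal_rr(cfg, "y_switch", "ATV/r+TDF/FTC", n_mc = 5000,
                        seed = 2)
  expect_lt(abs(t$log_rr), max(3 * t$se_log, 1e-6))
})

test_that("with regime-independent covariate distributions the marginal
          rate ratio collapses to the configured conditional effect", {
  cfg <- sim_config(n_persons = 100, seed = 57, missingness = "none")
  truth <- cfg$outcomes$y_switch$regimen
  for (rg in c("ATV/r+TDF/FTC", "EVG/c/TAF/FTC")) {
    t <- true_marginal_rr(cfg, "y_switch", rg, n_mc = 5000, seed = 2)
    expect_equal(t$log_rr, unname(truth[rg]), tolerance = 1e-6)
  }
  expect_error(true_marginal_rr(cfg, "nope", "ATV/r+TDF/FTC"), "outcome")
  expect_error(true_marginal_rr(cfg, "y_switch", "XYZ"), "category")
})

test_that("the crude oracle exhibits the designed confounding bias", {
  cfg <- sim_config(n_persons = 100, seed = 58, missingness = "none")
  cr <- true_crude_rr(cfg, "y_switch", "ATV/r+TDF/FTC", n_mc = 2e4,
                      seed = 3)
  tr <- true_marginal_rr(cfg, "y_switch", "ATV/r+TDF/FTC", n_mc = 2e4,
                         seed = 3)
  # channeling of sicker patients to the boosted-PI regimen inflates the
  # crude association upward
  expect_gt(cr$log_rr - tr$log_rr, 0.05)
})

test_that("simulation configs survive a YAML round trip", {
  cfg <- sim_config(n_persons = 50, seed = 59)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$treatment$coefs, cfg$treatment$coefs, tolerance = 1e-12)
  expect_equal(cfg2$outcomes, cfg$outcomes, tolerance = 1e-12)
  expect_equal(cfg2$missingness, cfg$missingness, tolerance = 1e-12)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg2)
  expect_equal(as.data.frame(co1)[names(co1)], as.data.frame(co2)[names(co2)],
               tolerance = 1e-9, ignore_attr = TRUE)
})
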