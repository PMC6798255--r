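# Shared fixtures and scenario builders for the test suite.

REGS <- default_regimens()
REF <- REGS[1]

# true log rate ratios of the default switching outcome configuration
default_switch_log_rr <- function() {
  sim_config(n_persons = 10, missingness = "none")$outcomes$y_switch$regimen
}

# null scenario: no regimen effects; optionally strip confounding/dropout
null_config <- function(n_persons, seed, confounded = TRUE,
                        censored = TRUE) {
  cfg <- sim_config(n_persons = n_persons, seed = seed, missingness = "none")
  for (o in names(cfg$outcomes)) cfg$outcomes[[o]]$regimen[] <- 0
  if (!confounded) {
    cfg$treatment$coefs[] <- 0
    cfg$confounders$comorb$treat_effects[] <- 0
  }
  if (!censored) cfg$censoring["intercept"] <- -Inf
  validate_sim_config(cfg)
  cfg
}

# hand-built six-person visit table with mixed gaps and ART status;
# expected pair counts enumerated in test-pairs.R
toy_visits <- function() {
  d <- as.Date("2014-01-01")
  mk <- function(id, visit, days, regimen) {
    data.frame(id = id, visit = visit, date = d + days, regimen = regimen,
               stringsAsFactors = FALSE)
  }
  rbind(
    # person 1: three visits 6 months apart, always on cART -> 2 pairs
    mk(1, 0:2, c(0, 182, 365), "EFV/TDF/FTC"),
    # person 2: two visits 14 months apart -> 0 pairs (gap filter)
    mk(2, 0:1, c(0, 430), "DTG/ABC/3TC"),
    # person 3: on dual therapy (not cART) -> 0 pairs
    mk(3, 0:1, c(0, 182), "TDF/FTC"),
    # person 4: cART at visit 0, discontinued at visit 1 -> 1 pair (switch)
    rbind(mk(4, 0, 0, "ATV/RTV/TDF/FTC"), mk(4, 1, 182, NA)),
    # person 5: no ART at visit 0, cART at visits 1-2 -> 1 pair (1,2)
    rbind(mk(5, 0, 0, NA), mk(5, 1:2, c(182, 365), "EVG/COBI/TDF/FTC")),
    # person 6: single visit -> 0 pairs
    mk(6, 0, 0, "EFV/TDF/FTC")
  )
}

# two-group binary dataset with exact closed-form risk ratio a1/n1 / (a0/n0)
two_group_data <- function(a1 = 30, n1 = 100, a0 = 15, n0 = 100) {
  data.frame(y = c(rep(1, a1), rep(0, n1 - a1), rep(1, a0), rep(0, n0 - a0)),
             g = rep(c(1, 0), c(n1, n0)))
}

expect_no_na <- function(x) expect_false(anyNA(x))
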