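#' Default regimen labels for the 7-category treatment
#' @return Character vector of 7 regimen labels; the first (the most
#'   commonly reported single-pill NNRTI regimen) is the reference.
#' @export
default_regimens <- function() {
  c("EFV/TDF/FTC", "EVG/c/TDF/FTC", "RPV/TDF/FTC", "DTG/ABC/3TC",
    "DRV/r+TDF/FTC", "ATV/r+TDF/FTC", "EVG/c/TAF/FTC")
}

#' Simulation configuration for the synthetic longitudinal cohort
#'
#' Defines the data-generating process of a semiannual-visit HIV cohort with
#' a 7-category time-varying cART regimen, time-varying confounders that both
#' respond to past treatment and predict future treatment, informative
#' dropout, covariate missingness, and Bernoulli outcomes (switching,
#' adherence, suppression) with configurable true regimen effects on the
#' log-risk scale, so that configured effects are rate ratios.
#'
#' Structure of the process, per person:
#' \itemize{
#'   \item baseline: age (years), a binary group indicator \code{grp}, and a
#'     bounded latent frailty \code{u} (unobserved; affects outcomes,
#'     loads on the comorbidity score);
#'   \item CD4: a stationary AR(1) latent scale cut into the three clinical
#'     categories (>=500 reference, 350-499, <350); exogenous to treatment;
#'   \item detectable HIV RNA: Bernoulli given the CD4 category; exogenous to
#'     treatment;
#'   \item comorbidity score: autoregressive, shifted by the previous
#'     regimen (treatment-confounder feedback) and loading on the frailty;
#'     feeds future treatment and dropout but not the outcome risk directly;
#'   \item regimen: multinomial logit on current CD4 category, RNA,
#'     comorbidity, age, group, with a stickiness bonus for remaining on the
#'     previous regimen;
#'   \item dropout (absorbing, no re-entry): logit on the previous visit's
#'     state;
#'   \item outcomes: log-risk linear in current regimen, CD4 category, RNA,
#'     age, group and frailty.
#' }
#'
#' @param n_persons Number of participants.
#' @param n_visits Maximum number of semiannual visits per person.
#' @param visit_interval Months between visits.
#' @param start_date First visit date.
#' @param regimens Character vector of 7 regimen labels; element 1 is the
#'   reference category.
#' @param treatment,confounders,censoring,outcomes,missingness Component
#'   parameter lists; defaults define the package's reference study
#'   conditions. Set \code{censoring$intercept = -Inf} for no dropout and
#'   \code{missingness = NULL} for complete data.
#' @param seed Integer seed. A fixed per-person draw budget is laid out
#'   row-major from one stream, so the draws of person \eqn{j} do not depend
#'   on \code{n_persons}.
#' @return Object of class \code{"sim_config"} (validated).
#' @export
sim_config <- function(n_persons = 1000,
                       n_visits = 6,
                       visit_interval = 6,
                       start_date = as.Date("2014-01-01"),
                       regimens = default_regimens(),
                       treatment = NULL,
                       confounders = NULL,
                       censoring = NULL,
                       outcomes = NULL,
                       missingness = NULL,
                       seed = 1L) {
  if (is.null(treatment)) treatment <- .default_treatment(regimens)
  if (is.null(confounders)) confounders <- .default_confounders(regimens)
  if (is.null(censoring)) censoring <- .default_censoring()
  if (is.null(outcomes)) outcomes <- .default_outcomes(regimens)
  if (is.null(missingness)) {
    missingness <- c(y_adhere = 0.03, y_suppress = 0.08,
                     rna_det = 0.06, comorb = 0.13)
  } else if (identical(missingness, "none") ||
             (length(missingness) == 1 && is.na(missingness))) {
    missingness <- numeric(0)
  }
  cfg <- structure(list(
    n_persons = as.integer(n_persons), n_visits = as.integer(n_visits),
    visit_interval = visit_interval, start_date = as.Date(start_date),
    regimens = regimens, treatment = treatment, confounders = confounders,
    censoring = censoring, outcomes = outcomes, missingness = missingness,
    frailty_range = 0.5, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

.default_treatment <- function(regimens) {
  k <- length(regimens)
  coefs <- matrix(0, k, 6,
                  dimnames = list(regimens,
                                  c("cd4_350to499", "cd4_lt350", "rna_det",
                                    "comorb", "age_c", "grp")))
  # channeling: boosted-PI regimens attract sicker patients, the newer
  # INSTI single-pill regimens attract healthier ones
  coefs["DRV/r+TDF/FTC", ] <- c(0.60, 1.20, 0.80, 0.80, -0.10, 0.20)
  coefs["ATV/r+TDF/FTC", ] <- c(0.55, 1.15, 0.75, 0.75, 0.10, 0.15)
  coefs["DTG/ABC/3TC", ]   <- c(-0.30, -0.70, -0.50, -0.45, 0.10, 0.00)
  coefs["EVG/c/TAF/FTC", ] <- c(-0.30, -0.65, -0.45, -0.40, 0.00, -0.10)
  coefs["EVG/c/TDF/FTC", ] <- c(0.00, -0.15, 0.10, 0.00, -0.15, 0.00)
  coefs["RPV/TDF/FTC", ]   <- c(0.00, 0.00, -0.10, 0.00, -0.10, 0.05)
  list(
    intercepts = stats::setNames(
      c(0, -0.55, -0.65, -0.75, -0.95, -1.05, -1.15), regimens),
    stickiness = 2.6,
    coefs = coefs
  )
}

.default_confounders <- function(regimens) {
  kappa <- stats::setNames(rep(0, length(regimens)), regimens)
  kappa[c("DRV/r+TDF/FTC", "ATV/r+TDF/FTC")] <- 0.20
  kappa[c("DTG/ABC/3TC", "EVG/c/TAF/FTC")] <- -0.08
  list(
    cd4_rho = 0.6, cd4_cuts = c(-0.8, 0),
    cd4_scale = 200, cd4_center = 560,
    rna = c(intercept = -1.6, cd4_lt350 = 1.0, cd4_350to499 = 0.5),
    comorb = list(ar = 0.5, treat_effects = kappa, frailty_load = 1.0,
                  sd = 0.3, sd0 = 0.5)
  )
}

.default_censoring <- function() {
  c(intercept = -2.6, cd4_lt350 = 0.5, cd4_350to499 = 0.2, rna_det = 0.3,
    comorb = 0.4, age_c = 0.1, grp = 0.2)
}

.default_outcomes <- function(regimens) {
  rr <- function(x) stats::setNames(log(x), regimens)
  list(
    y_switch = list(
      intercept = log(0.13),
      regimen = rr(c(1, 1.00, 0.90, 0.16, 1.20, 1.80, 0.12)),
      cd4_lt350 = 0.35, cd4_350to499 = 0.15, rna_det = 0.30,
      age_c = -0.05, grp = 0.10, frailty_load = 0.8),
    y_adhere = list(
      intercept = log(0.88),
      regimen = rr(c(1, 0.98, 1.00, 1.02, 0.97, 0.98, 1.04)),
      cd4_lt350 = -0.05, cd4_350to499 = -0.02, rna_det = -0.04,
      age_c = 0.00, grp = -0.02, frailty_load = -0.15),
    y_suppress = list(
      intercept = log(0.84),
      regimen = rr(c(1, 0.85, 1.00, 1.00, 1.08, 0.97, 0.98)),
      cd4_lt350 = -0.15, cd4_350to499 = -0.05, rna_det = -0.20,
      age_c = 0.00, grp = -0.05, frailty_load = -0.15)
  )
}

# bounds used for outcome-probability validation: age_c in [-2, 2.8]
.AGE_C_RANGE <- c(-2, 2.8)

#' Validate a simulation configuration
#'
#' Checks the structural invariants: exactly 7 regimen categories, category
#' coefficient tables conformable, missingness rates in [0, 1), and — the
#' substantive check — that every outcome's log-risk configuration yields
#' event probabilities strictly inside (0, 1) at the extremes of the
#' covariate space. Configurations that could produce probability >= 1 are
#' rejected here, never clipped silently.
#'
#' @param cfg A \code{"sim_config"} object.
#' @return \code{cfg}, invisibly; errors name the offending parameter.
#' @export
validate_sim_config <- function(cfg) {
  if (length(cfg$regimens) != 7) {
    stop("exactly 7 regimen categories are required, got ",
         length(cfg$regimens), call. = FALSE)
  }
  if (anyDuplicated(cfg$regimens)) stop("duplicate regimen labels",
                                        call. = FALSE)
  if (length(cfg$missingness) &&
      (any(cfg$missingness < 0) || any(cfg$missingness >= 1))) {
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  }
  for (oc in names(cfg$outcomes)) {
    o <- cfg$outcomes[[oc]]
    if (!setequal(names(o$regimen), cfg$regimens)) {
      stop("outcome ", oc, ": regimen effects must be named by the 7 ",
           "regimen labels", call. = FALSE)
    }
    pos <- function(x) max(x, 0)
    worst <- o$intercept + max(o$regimen) + pos(o$cd4_lt350) +
      pos(o$cd4_350to499) + pos(o$rna_det) +
      max(o$age_c * .AGE_C_RANGE) + pos(o$grp) +
      abs(o$frailty_load) * cfg$frailty_range
    if (worst >= 0) {
      stop("outcome ", oc, ": configured log-risks reach ", signif(worst, 3),
           " (probability ", signif(exp(worst), 3), " >= 1) at the covariate",
           " extremes; reduce the intercept or effect sizes", call. = FALSE)
    }
  }
  invisible(cfg)
}

# ---- random-draw layout -----------------------------------------------------
# Fixed per-person draw budget laid out row-major from a single stream, so
# person j's draws are invariant to n_persons.
.sim_draws <- function(n, K, seed) {
  set.seed(seed)
  wN <- 1 + 2 * K          # age | cd4 latent noise (K) | comorb noise (K)
  wU <- 2 + 10 * K         # grp, frailty | per visit: rna, treat, cens,
  #                          3 outcomes, 4 missingness masks
  # one row-major uniform stream per person; the normal block is obtained by
  # inverse-CDF transform, so person j's draws never depend on n
  M <- matrix(stats::runif(n * (wN + wU)), nrow = n, ncol = wN + wU,
              byrow = TRUE)
  list(
    N = stats::qnorm(M[, seq_len(wN), drop = FALSE]),
    U = M[, wN + seq_len(wU), drop = FALSE],
    K = K
  )
}
.N_age <- function(d) d$N[, 1]
.N_cd4 <- function(d, k) d$N[, 2 + k]                 # k is 0-based
.N_com <- function(d, k) d$N[, 2 + d$K + k]
.U_grp <- function(d) d$U[, 1]
.U_fr  <- function(d) d$U[, 2]
.U_vis <- function(d, k, slot) d$U[, 2 + 10 * k + slot] # slot 1..10

# ---- core engine ------------------------------------------------------------
# Simulates the longitudinal dynamics. forced: NULL (observational) or a
# regimen label applied deterministically at every visit. censoring: logical.
# Returns per-visit state lists plus outcome probabilities.
.sim_engine <- function(cfg, n, draws, forced = NULL, censoring = TRUE) {
  K <- cfg$n_visits
  regs <- cfg$regimens
  tr <- cfg$treatment; cf <- cfg$confounders; oc <- cfg$outcomes
  age <- pmin(pmax(52 + 9 * .N_age(draws), 30), 75)
  grp <- as.numeric(.U_grp(draws) < 0.45)
  u <- (2 * .U_fr(draws) - 1) * cfg$frailty_range
  alive <- rep(TRUE, n)
  z_cd4 <- comorb <- numeric(n)
  R <- integer(n)   # regimen index at current visit
  state <- vector("list", K)
  for (k in seq_len(K) - 1L) {
    # CD4 latent AR(1), stationary; exogenous to treatment
    z_cd4 <- if (k == 0) .N_cd4(draws, 0) else
      cf$cd4_rho * z_cd4 + sqrt(1 - cf$cd4_rho^2) * .N_cd4(draws, k)
    lt350 <- as.numeric(z_cd4 < cf$cd4_cuts[1])
    mid   <- as.numeric(z_cd4 >= cf$cd4_cuts[1] & z_cd4 < cf$cd4_cuts[2])
    cd4 <- pmax(round(cf$cd4_center + cf$cd4_scale * z_cd4), 20)
    p_rna <- stats::plogis(cf$rna["intercept"] + cf$rna["cd4_lt350"] * lt350 +
                             cf$rna["cd4_350to499"] * mid)
    rna <- as.numeric(.U_vis(draws, k, 1) < p_rna)
    # comorbidity: treatment-affected, frailty-loaded
    cb <- cf$comorb
    comorb <- if (k == 0) {
      cb$frailty_load * u + cb$sd0 * .N_com(draws, 0)
    } else {
      cb$ar * comorb + unname(cb$treat_effects[regs[R]]) +
        cb$frailty_load * u + cb$sd * .N_com(draws, k)
    }
    # dropout before visit k, based on visit k-1 state
    if (censoring && k > 0) {
      pv <- state[[k]]  # previous visit (list index k = visit k-1)
      cz <- cfg$censoring
      p_drop <- stats::plogis(
        cz["intercept"] + cz["cd4_lt350"] * pv$lt350 +
          cz["cd4_350to499"] * pv$mid + cz["rna_det"] * pv$rna +
          cz["comorb"] * pv$comorb + cz["age_c"] * pv$age_c +
          cz["grp"] * grp)
      alive <- alive & (.U_vis(draws, k, 3) >= p_drop)
    }
    age_k <- age + k * cfg$visit_interval / 12
    age_c <- (age_k - 50) / 10
    # treatment assignment
    if (is.null(forced)) {
      X <- cbind(cd4_350to499 = mid, cd4_lt350 = lt350, rna_det = rna,
                 comorb = comorb, age_c = age_c, grp = grp)
      eta <- matrix(tr$intercepts, n, 7, byrow = TRUE) + X %*% t(tr$coefs)
      if (k > 0) eta[cbind(seq_len(n), R)] <-
          eta[cbind(seq_len(n), R)] + tr$stickiness
      pm <- exp(eta - apply(eta, 1, max))
      pm <- pm / rowSums(pm)
      cum <- t(apply(pm, 1, cumsum))
      R_new <- max.col(cum >= .U_vis(draws, k, 2), ties.method = "first")
      R <- R_new
    } else {
      R <- rep(match(forced, regs), n)
    }
    # outcome probabilities (log-risk model on current state)
    probs <- lapply(oc, function(o) {
      exp(o$intercept + unname(o$regimen[regs[R]]) + o$cd4_lt350 * lt350 +
            o$cd4_350to499 * mid + o$rna_det * rna + o$age_c * age_c +
            o$grp * grp + o$frailty_load * u)
    })
    ys <- mapply(function(p, slot) as.numeric(.U_vis(draws, k, slot) < p),
                 probs, 4:6, SIMPLIFY = FALSE)
    names(ys) <- names(oc)
    state[[k + 1L]] <- list(alive = alive, lt350 = lt350, mid = mid,
                            cd4 = cd4, rna = rna, comorb = comorb,
                            age_k = age_k, age_c = age_c, R = R,
                            probs = probs, ys = ys)
  }
  list(state = state, age = age, grp = grp, u = u, K = K)
}

#' Simulate a longitudinal person-visit cohort
#'
#' Generates the synthetic cohort defined by a [sim_config()]: semiannual
#' visits, 7-category time-varying regimen with treatment-confounder
#' feedback, informative absorbing dropout, Bernoulli outcomes, and MCAR
#' masking of the declared covariate/outcome columns. Bit-reproducible given
#' the config seed, and the rows of person \eqn{j} do not change when
#' \code{n_persons} is increased.
#'
#' @param cfg A \code{"sim_config"} object.
#' @return Data frame of class \code{"cart_cohort"}: one row per observed
#'   person-visit ordered by (id, visit) with columns \code{id}, \code{visit}
#'   (0-based, consecutive until dropout), \code{date}, \code{year},
#'   \code{regimen}, \code{prev_regimen}, \code{age}, \code{age_c},
#'   \code{grp}, \code{cd4}, \code{cd4_cat}, \code{rna_det}, \code{comorb},
#'   \code{y_switch}, \code{y_adhere}, \code{y_suppress}. The latent truth
#'   (event probabilities, frailty) is attached as attribute \code{"truth"};
#'   the config as attribute \code{"config"}.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_persons; K <- cfg$n_visits
  draws <- .sim_draws(n, K, cfg$seed)
  eng <- .sim_engine(cfg, n, draws, forced = NULL, censoring = TRUE)
  regs <- cfg$regimens
  rows <- vector("list", K)
  truths <- vector("list", K)
  prevR <- rep(NA_integer_, n)
  for (k in seq_len(K) - 1L) {
    st <- eng$state[[k + 1L]]
    idx <- which(st$alive)
    date_k <- cfg$start_date + round(k * cfg$visit_interval * 30.4375)
    rows[[k + 1L]] <- data.frame(
      id = idx, visit = k, date = date_k,
      year = as.integer(format(date_k, "%Y")),
      regimen = regs[st$R[idx]],
      prev_regimen = ifelse(is.na(prevR[idx]), NA_character_,
                            regs[prevR[idx]]),
      age = st$age_k[idx], age_c = st$age_c[idx], grp = eng$grp[idx],
      cd4 = st$cd4[idx],
      cd4_cat = ifelse(st$lt350[idx] == 1, "lt350",
                       ifelse(st$mid[idx] == 1, "350to499", "ge500")),
      rna_det = st$rna[idx], comorb = st$comorb[idx],
      y_switch = st$ys$y_switch[idx],
      y_adhere = st$ys$y_adhere[idx],
      y_suppress = st$ys$y_suppress[idx],
      stringsAsFactors = FALSE
    )
    truths[[k + 1L]] <- data.frame(
      id = idx, visit = k,
      p_switch = st$probs$y_switch[idx],
      p_adhere = st$probs$y_adhere[idx],
      p_suppress = st$probs$y_suppress[idx],
      u = eng$u[idx]
    )
    prevR <- ifelse(st$alive, st$R, prevR)  # only update for observed rows
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$visit), , drop = FALSE]
  truth <- do.call(rbind, truths)
  truth <- truth[order(truth$id, truth$visit), , drop = FALSE]
  out$cd4_cat <- factor(out$cd4_cat, levels = c("ge500", "350to499", "lt350"))
  out$regimen <- factor(out$regimen, levels = regs)
  out$prev_regimen <- factor(out$prev_regimen, levels = regs)
  # MCAR masking of declared columns
  if (length(cfg$missingness)) {
    slot_map <- c(y_adhere = 7, y_suppress = 8, rna_det = 9, comorb = 10)
    for (col in names(cfg$missingness)) {
      rate <- cfg$missingness[[col]]
      if (rate <= 0) next
      if (!col %in% names(slot_map)) {
        stop("missingness configured for unsupported column: ", col,
             call. = FALSE)
      }
      mk <- draws$U[cbind(out$id, 2 + 10 * out$visit + slot_map[[col]])]
      out[[col]][mk < rate] <- NA
    }
  }
  rownames(out) <- NULL
  rownames(truth) <- NULL
  structure(out, class = c("cart_cohort", "data.frame"),
            truth = truth, config = cfg)
}

#' @export
print.cart_cohort <- function(x, ...) {
  cat("Synthetic cART cohort:", length(unique(x$id)), "persons,",
      nrow(x), "person-visits,", nlevels(x$regimen), "regimen categories\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' True marginal rate ratio by g-computation
#'
#' Monte-Carlo standardization oracle: simulates the cohort dynamics with the
#' regimen deterministically set to \code{regimen} at every visit versus set
#' to \code{reference}, all other dynamics unchanged and dropout disabled,
#' and returns the ratio of mean event probabilities over the analysis index
#' visits (1 through \code{n_visits - 2}). Both arms share the same random
#' draws (common random numbers), and the Monte-Carlo standard error of the
#' log ratio is computed from the paired person-level means by the delta
#' method.
#'
#' @param cfg A \code{"sim_config"}.
#' @param outcome One of \code{"y_switch"}, \code{"y_adhere"},
#'   \code{"y_suppress"}.
#' @param regimen,reference Regimen labels from \code{cfg$regimens}.
#' @param n_mc Number of Monte-Carlo persons (>= 1e4 recommended).
#' @param seed Seed for the oracle draws (independent of the cohort seed).
#' @return List: \code{rr}, \code{log_rr}, \code{se_log} (MC standard error
#'   of \code{log_rr}), \code{n_mc}.
#' @export
true_marginal_rr <- function(cfg, outcome, regimen, reference = NULL,
                             n_mc = 1e5, seed = 99) {
  if (is.null(reference)) reference <- cfg$regimens[1]
  if (!outcome %in% names(cfg$outcomes)) {
    stop("unknown outcome: ", outcome, call. = FALSE)
  }
  for (r in c(regimen, reference)) {
    if (!r %in% cfg$regimens) stop("unknown regimen category: ", r,
                                   call. = FALSE)
  }
  draws <- .sim_draws(n_mc, cfg$n_visits, seed)
  pm <- function(forced) {
    eng <- .sim_engine(cfg, n_mc, draws, forced = forced, censoring = FALSE)
    ks <- seq(1L, cfg$n_visits - 2L)   # analysis index visits
    rowMeans(sapply(ks, function(k) eng$state[[k + 1L]]$probs[[outcome]]))
  }
  pr <- pm(regimen); ps <- pm(reference)
  mr <- mean(pr); ms <- mean(ps)
  infl <- pr / mr - ps / ms
  se_log <- stats::sd(infl) / sqrt(n_mc)
  list(rr = mr / ms, log_rr = log(mr / ms), se_log = se_log, n_mc = n_mc)
}

#' Crude (confounded) rate ratio implied by the observational design
#'
#' Companion oracle to [true_marginal_rr()]: simulates the observational
#' regime (treatment assigned by the configured channeling model, dropout
#' active) and computes the unadjusted association between the regimen at the
#' analysis index visits and the outcome — the estimand of the naive
#' estimator, including its simulation-designed confounding bias. Uses event
#' probabilities rather than Bernoulli draws, with a person-clustered delta
#' method for the Monte-Carlo standard error.
#'
#' @inheritParams true_marginal_rr
#' @return List: \code{rr}, \code{log_rr}, \code{se_log}, \code{n_mc}.
#' @export
true_crude_rr <- function(cfg, outcome, regimen, reference = NULL,
                          n_mc = 1e5, seed = 99) {
  if (is.null(reference)) reference <- cfg$regimens[1]
  draws <- .sim_draws(n_mc, cfg$n_visits, seed)
  eng <- .sim_engine(cfg, n_mc, draws, forced = NULL, censoring = TRUE)
  ks <- seq(1L, cfg$n_visits - 2L)
  ri <- match(regimen, cfg$regimens); si <- match(reference, cfg$regimens)
  if (is.na(ri) || is.na(si)) stop("unknown regimen category", call. = FALSE)
  num_a <- num_m <- den_a <- den_m <- numeric(n_mc)
  for (k in ks) {
    st <- eng$state[[k + 1L]]
    p <- st$probs[[outcome]]
    sel_r <- st$alive & st$R == ri
    sel_s <- st$alive & st$R == si
    num_a <- num_a + ifelse(sel_r, p, 0); num_m <- num_m + sel_r
    den_a <- den_a + ifelse(sel_s, p, 0); den_m <- den_m + sel_s
  }
  mu_r <- sum(num_a) / sum(num_m); mu_s <- sum(den_a) / sum(den_m)
  infl_r <- (num_a - mu_r * num_m) / sum(num_m)
  infl_s <- (den_a - mu_s * den_m) / sum(den_m)
  se_log <- sqrt(sum((infl_r / mu_r - infl_s / mu_s)^2))
  list(rr = mu_r / mu_s, log_rr = log(mu_r / mu_s), se_log = se_log,
       n_mc = n_mc)
}
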