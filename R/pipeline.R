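#' Analysis configuration for the weighted effectiveness pipeline
#'
#' @param reference Reference regimen category (the most reported regimen).
#'   Default \code{NULL}: chosen as the modal category of the cohort.
#' @param outcomes Outcome columns to analyse; adherence and suppression are
#'   restricted to same-regimen pairs.
#' @param time_fixed Time-fixed covariate columns (enter weight numerators,
#'   denominators and the weighted outcome models).
#' @param time_varying Time-varying confounder columns (enter weight
#'   denominators only).
#' @param history Treatment-history column (previous regimen).
#' @param use_age_spline Add restricted quadratic spline terms for \code{age}
#'   (4 knots at the 20/40/60/80th percentiles) to every model containing the
#'   time-fixed covariates.
#' @param extra_covariates Named list: per-outcome extra columns for the
#'   weighted outcome model (virologic-failure indicator for switching;
#'   adherence for suppression).
#' @param unadjusted \code{"regimen_only"} (default) or
#'   \code{"covariate_adjusted"}: predictor set of the unweighted comparison
#'   model.
#' @param age_cut Age dichotomy for stratified analyses (years).
#' @param truncate_percentiles Percentiles (0-100) for weight truncation.
#' @param m Number of multiple-imputation datasets when missing values are
#'   present (default 25).
#' @param min_person_visits Regimen-frequency threshold for
#'   [select_common_regimens()].
#' @param cumulative Cumulative IPTC weights (default) or visit-level.
#' @param force_unit_weights Replace all weights by 1 (diagnostic mode: the
#'   weighted analysis must then reproduce the unweighted one exactly).
#' @param seed Seed for the imputation draws.
#' @return List of class \code{"analysis_config"}.
#' @export
analysis_config <- function(reference = NULL,
                            outcomes = c("y_switch", "y_adhere", "y_suppress"),
                            time_fixed = c("age_c", "grp"),
                            time_varying = c("cd4_cat", "rna_det", "comorb"),
                            history = "prev_regimen",
                            use_age_spline = TRUE,
                            extra_covariates = list(y_switch = "rna_det",
                                                    y_suppress = "y_adhere"),
                            unadjusted = c("regimen_only",
                                           "covariate_adjusted"),
                            age_cut = 50,
                            truncate_percentiles = c(1, 99),
                            m = 25,
                            min_person_visits = 300,
                            cumulative = TRUE,
                            force_unit_weights = FALSE,
                            seed = 1L) {
  stopifnot(age_cut > 0, m >= 1,
            length(truncate_percentiles) == 2,
            truncate_percentiles[1] < truncate_percentiles[2])
  structure(list(reference = reference, outcomes = outcomes,
                 time_fixed = time_fixed, time_varying = time_varying,
                 history = history, use_age_spline = use_age_spline,
                 extra_covariates = extra_covariates,
                 unadjusted = match.arg(unadjusted), age_cut = age_cut,
                 truncate_percentiles = truncate_percentiles, m = m,
                 min_person_visits = min_person_visits,
                 cumulative = cumulative,
                 force_unit_weights = force_unit_weights,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Select commonly reported regimens
#'
#' Regimens reported by strictly more than \code{min_person_visits}
#' person-visits within the calendar window.
#'
#' @param cohort Person-visit data frame with \code{regimen} and \code{year}.
#' @param years Calendar-year window (default: all years present).
#' @param min_person_visits Frequency threshold (strict inequality).
#' @return Character vector of qualifying regimen labels.
#' @export
select_common_regimens <- function(cohort, years = NULL,
                                   min_person_visits = 300) {
  d <- cohort
  if (!is.null(years)) d <- d[d$year %in% years, , drop = FALSE]
  if (!nrow(d)) return(character(0))
  tab <- table(as.character(d$regimen))
  names(tab)[tab > min_person_visits]
}

#' Yearly trends of regimen/class use and viral suppression
#'
#' Per calendar year, the proportion of person-visits on each cART class (or
#' regimen), plus the proportion virally suppressed, with a secular-trend
#' test per series: modified Poisson regression of the indicator on calendar
#' year with person-clustered robust variance.
#'
#' @param cohort Person-visit data frame with \code{id}, \code{year},
#'   \code{regimen}; suppression uses \code{hiv_rna} (with
#'   \code{threshold}) when present, else \code{1 - rna_det}.
#' @param by \code{"class"} (PI/NNRTI/INSTI/other hierarchy applied to each
#'   regimen label) or \code{"regimen"}.
#' @param threshold Suppression cutoff in copies/mL for the trend era.
#' @return List of class \code{"trend_report"}: \code{proportions} (year x
#'   series), \code{tests} (slope on the log scale per year, robust SE,
#'   p-value), \code{suppression}.
#' @export
run_trends <- function(cohort, by = c("class", "regimen"), threshold = 50) {
  by <- match.arg(by)
  d <- as.data.frame(cohort)
  d$series <- if (by == "regimen") as.character(d$regimen) else
    vapply(as.character(d$regimen), function(r) {
      tryCatch(classify_cart_class(r), error = function(e) "other")
    }, character(1))
  years <- sort(unique(d$year))
  series <- sort(unique(d$series))
  prop <- sapply(series, function(s) {
    vapply(years, function(y) mean(d$series[d$year == y] == s), numeric(1))
  })
  rownames(prop) <- years
  tests <- do.call(rbind, lapply(series, function(s) {
    d$ind <- as.numeric(d$series == s)
    f <- tryCatch(modpois(ind ~ year, d, cluster = id),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(series = s, slope = NA, se = NA, p = NA))
    }
    sm <- summary(f)$coefficients
    data.frame(series = s, slope = sm["year", "estimate"],
               se = sm["year", "robust_se"], p = sm["year", "p"])
  }))
  d$supp <- if ("hiv_rna" %in% names(d)) {
    as.numeric(derive_suppression(d$hiv_rna, threshold = threshold))
  } else if ("rna_det" %in% names(d)) 1 - d$rna_det else NA_real_
  supp <- vapply(years, function(y) {
    mean(d$supp[d$year == y], na.rm = TRUE)
  }, numeric(1))
  names(supp) <- years
  structure(list(proportions = prop, tests = tests, suppression = supp,
                 by = by, threshold = threshold), class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Yearly", x$by, "proportions:\n")
  print(round(x$proportions, 3))
  cat("\nTrend tests (log-scale slope per year, robust SE):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

# spline columns for age added to a dataset; knots fixed from the full cohort
.add_age_spline <- function(d, knots) {
  b <- rq_spline_basis(d$age, knots)
  d$age_s1 <- b[, "s1"]
  d$age_s2 <- b[, "s2"]
  d
}

#' Run the IPTC-weighted comparative-effectiveness analysis
#'
#' End-to-end pipeline: (1) multiple imputation of missing covariates and
#' outcomes when present (multivariate-normal model, \code{m} datasets);
#' (2) per completed dataset, stabilized
#' inverse-probability-of-treatment-and-censoring weights (multinomial
#' regimen models and nested remaining-uncensored logistic models, cumulative
#' within person, truncated at the configured percentiles of the pooled
#' weight distribution), then unweighted and weighted modified-Poisson models
#' for each outcome — switching on all eligible pairs, adherence and
#' suppression on same-regimen pairs — overall and within the two age
#' strata; (3) Rubin's-rules pooling of the per-imputation log rate ratios.
#'
#' Analysis rows are index visits \eqn{V_i} (visit 1 onwards, so that the
#' previous visit supplies treatment history) whose next visit was observed;
#' the outcome stored on the index row is ascertained at \eqn{V_{i+1}}. The
#' weight attached to a row multiplies the treatment factors through
#' \eqn{V_i} with the censoring factors through \eqn{V_{i+1}}.
#'
#' @param cohort Person-visit data frame (see [simulate_cohort()] for the
#'   column contract).
#' @param config An [analysis_config()].
#' @return Object of class \code{"effectiveness_report"}: \code{estimates}
#'   (one row per outcome x stratum x non-reference regimen with unadjusted
#'   and weighted RRs and 95\% CIs), \code{weight_diagnostics}, \code{log}
#'   (filter-step row counts), \code{m}, \code{reference}.
#' @export
run_effectiveness <- function(cohort, config = analysis_config()) {
  d0 <- as.data.frame(cohort)
  .validate_cohort(d0, config)
  log <- character(0)
  logf <- function(...) sprintf(...)
  if (is.null(config$reference)) {
    config$reference <- names(which.max(table(as.character(d0$regimen))))
  }
  K <- max(d0$visit) + 1L
  knots <- if (config$use_age_spline) rq_spline_knots(d0$age) else NULL

  # ---- multiple imputation -------------------------------------------------
  model_vars <- unique(c(config$outcomes, config$time_varying,
                         config$time_fixed))
  model_vars <- model_vars[model_vars %in% names(d0)]
  model_vars <- model_vars[vapply(model_vars, function(v)
    is.numeric(d0[[v]]), logical(1))]
  has_na <- vapply(model_vars, function(v) anyNA(d0[[v]]), logical(1))
  if (any(has_na) && config$m >= 2) {
    imp <- mi_impute(d0, variables = model_vars, m = config$m,
                     seed = config$seed)
    datasets <- imp$datasets
    log <- c(log, logf("multiple imputation: m=%d, variables: %s",
                       config$m,
                       paste(names(has_na)[has_na], collapse = ", ")))
  } else {
    datasets <- list(d0)
    log <- c(log, "no multiple imputation (complete data or m = 1)")
  }
  m <- length(datasets)

  # ---- per-dataset analysis ------------------------------------------------
  per_ds <- vector("list", m)
  diag1 <- NULL
  for (t in seq_len(m)) {
    dd <- datasets[[t]]
    if (config$use_age_spline) dd <- .add_age_spline(dd, knots)
    res <- .analyze_one(dd, config, K)
    if (t == 1) {
      diag1 <- res$weight_diagnostics
      log <- c(log, res$log)
    }
    per_ds[[t]] <- res$estimates
  }

  est <- .pool_datasets(per_ds, m)
  structure(list(estimates = est, weight_diagnostics = diag1, log = log,
                 m = m, reference = config$reference, config = config),
            class = "effectiveness_report")
}

.validate_cohort <- function(d, config) {
  need <- c("id", "visit", "regimen", "age", config$time_fixed,
            config$time_varying)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(stats::na.omit(d$visit) < 0)) stop("negative visit index",
                                             call. = FALSE)
  for (v in c("cd4", "hiv_rna")) {
    if (v %in% names(d) && any(stats::na.omit(d[[v]]) < 0)) {
      stop("negative values in column ", v, " (row ",
           which(d[[v]] < 0)[1], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# weights + fits on one completed dataset
.analyze_one <- function(dd, config, K) {
  tf <- config$time_fixed
  if (config$use_age_spline) tf <- c(tf, "age_s1", "age_s2")
  hist <- config$history
  f_num <- stats::reformulate(c(hist, tf))
  f_den <- stats::reformulate(c(hist, tf, config$time_varying))
  cf_num <- stats::reformulate(c("regimen", tf))
  cf_den <- stats::reformulate(c("regimen", tf, config$time_varying))
  w <- iptc_weights(dd, treatment = "regimen",
                    numerator = f_num, denominator = f_den,
                    censor_numerator = cf_num, censor_denominator = cf_den,
                    reference = config$reference, max_visits = K,
                    start_visit = 1L, cumulative = config$cumulative)
  key <- paste(dd$id, dd$visit)
  nxt <- match(paste(dd$id, dd$visit + 1L), key)
  rows <- which(dd$visit >= 1L & dd$visit <= K - 2L & !is.na(nxt))
  log <- sprintf("analysis rows: %d of %d person-visits (index visits 1..%d with next visit observed)",
                 length(rows), nrow(dd), K - 2L)
  an <- dd[rows, , drop = FALSE]
  # lead censoring factor for observing the outcome visit V_{i+1}
  lead_c <- (w$c_num / w$c_den)[nxt[rows]]
  an$.sw_raw <- w$sw[rows] * lead_c
  if (config$force_unit_weights) {
    an$.sw <- rep(1, nrow(an))
    tb <- list(bounds = c(1, 1), n_truncated = 0L)
  } else {
    tb <- truncate_weights(an$.sw_raw,
                           config$truncate_percentiles[1],
                           config$truncate_percentiles[2])
    an$.sw <- tb$weights
  }
  an$same_next <- as.character(an$regimen) ==
    as.character(dd$regimen[nxt[rows]])
  an$.age_ge <- an$age >= config$age_cut
  regs <- levels(factor(as.character(an$regimen)))
  an$regimen <- stats::relevel(factor(as.character(an$regimen), levels = regs),
                               ref = config$reference)
  if (!is.null(an[[hist]])) an[[hist]] <- factor(as.character(an[[hist]]))

  out <- list()
  for (oc in config$outcomes) {
    dat_o <- if (oc == "y_switch") an else an[an$same_next, , drop = FALSE]
    extra <- intersect(config$extra_covariates[[oc]], names(dat_o))
    extra <- setdiff(extra, oc)
    f_un <- if (config$unadjusted == "regimen_only") {
      stats::reformulate("regimen", response = oc)
    } else {
      stats::reformulate(c("regimen", hist, tf, extra), response = oc)
    }
    f_wt <- stats::reformulate(c("regimen", hist, tf, extra), response = oc)
    for (stratum in c("overall", "age_lt", "age_ge")) {
      ds <- switch(stratum, overall = dat_o,
                   age_lt = dat_o[!dat_o$.age_ge, , drop = FALSE],
                   age_ge = dat_o[dat_o$.age_ge, , drop = FALSE])
      ds <- ds[!is.na(ds[[oc]]), , drop = FALSE]
      present <- table(as.character(ds$regimen))
      missing_cats <- setdiff(regs, names(present)[present > 0])
      if (length(missing_cats)) {
        warning("outcome ", oc, ", stratum ", stratum,
                ": regimen categor(ies) absent, contrasts dropped: ",
                paste(missing_cats, collapse = ", "), call. = FALSE)
      }
      if (config$reference %in% missing_cats || nrow(ds) < 20) next
      ds$regimen <- droplevels(ds$regimen)
      fit_un <- tryCatch(
        suppressWarnings(modpois(f_un, ds, cluster = id)),
        error = function(e) NULL)
      fit_wt <- tryCatch(
        suppressWarnings(modpois(f_wt, ds, weights = .sw, cluster = id)),
        error = function(e) NULL)
      for (rg in setdiff(levels(ds$regimen), config$reference)) {
        cn <- paste0("regimen", rg)
        g <- function(f) {
          if (is.null(f) || !cn %in% names(f$coefficients)) {
            return(c(NA, NA))
          }
          c(f$coefficients[[cn]], sqrt(f$vcov_robust[cn, cn]))
        }
        eu <- g(fit_un); ew <- g(fit_wt)
        out[[length(out) + 1L]] <- data.frame(
          outcome = oc, stratum = stratum, regimen = rg,
          n = sum(as.character(ds$regimen) == rg),
          log_rr_unadj = eu[1], se_unadj = eu[2],
          log_rr_wt = ew[1], se_wt = ew[2], stringsAsFactors = FALSE)
      }
    }
  }
  wd <- weight_diagnostics(an$.sw, bounds = tb$bounds,
                           n_truncated = tb$n_truncated)
  wd$mean_raw <- mean(an$.sw_raw)
  list(estimates = do.call(rbind, out), weight_diagnostics = wd, log = log)
}

.pool_datasets <- function(per_ds, m) {
  base <- per_ds[[1]]
  key <- paste(base$outcome, base$stratum, base$regimen)
  pool_col <- function(est_col, se_col) {
    if (m == 1) {
      cbind(est = base[[est_col]], se = base[[se_col]])
    } else {
      t(sapply(seq_along(key), function(i) {
        ests <- vapply(per_ds, function(x) {
          j <- match(key[i], paste(x$outcome, x$stratum, x$regimen))
          if (is.na(j)) NA_real_ else x[[est_col]][j]
        }, numeric(1))
        ses <- vapply(per_ds, function(x) {
          j <- match(key[i], paste(x$outcome, x$stratum, x$regimen))
          if (is.na(j)) NA_real_ else x[[se_col]][j]
        }, numeric(1))
        ok <- !is.na(ests) & !is.na(ses)
        if (sum(ok) < 2) {
          return(c(mean(ests[ok]), if (any(ok)) mean(ses[ok]) else NA))
        }
        p <- pool_rubin(ests[ok], ses[ok]^2)
        c(p$estimate, p$se)
      }))
    }
  }
  un <- pool_col("log_rr_unadj", "se_unadj")
  wt <- pool_col("log_rr_wt", "se_wt")
  z <- stats::qnorm(0.975)
  data.frame(
    outcome = base$outcome, stratum = base$stratum, regimen = base$regimen,
    n = base$n,
    rr_unadj = exp(un[, 1]),
    unadj_lower = exp(un[, 1] - z * un[, 2]),
    unadj_upper = exp(un[, 1] + z * un[, 2]),
    rr_weighted = exp(wt[, 1]),
    weighted_lower = exp(wt[, 1] - z * wt[, 2]),
    weighted_upper = exp(wt[, 1] + z * wt[, 2]),
    log_rr_weighted = wt[, 1], se_weighted = wt[, 2],
    log_rr_unadj = un[, 1], se_unadj = un[, 2],
    stringsAsFactors = FALSE)
}

#' @export
print.effectiveness_report <- function(x, digits = 3, ...) {
  cat("IPTC-weighted comparative-effectiveness analysis\n")
  cat("reference regimen:", x$reference, "  imputations:", x$m, "\n\n")
  e <- x$estimates
  e <- e[e$stratum == "overall", , drop = FALSE]
  for (oc in unique(e$outcome)) {
    cat(oc, "(overall):\n")
    ee <- e[e$outcome == oc, , drop = FALSE]
    for (i in seq_len(nrow(ee))) {
      cat(sprintf(
        "  %-14s n=%5d  unadjusted RR %5.2f (%4.2f-%5.2f)  weighted RR %5.2f (%4.2f-%5.2f)\n",
        ee$regimen[i], ee$n[i], ee$rr_unadj[i], ee$unadj_lower[i],
        ee$unadj_upper[i], ee$rr_weighted[i], ee$weighted_lower[i],
        ee$weighted_upper[i]))
    }
  }
  wd <- x$weight_diagnostics
  cat(sprintf("\nweights: mean %.3f (untruncated %.3f), sd %.3f, %d truncated at [%.3g, %.3g]\n",
              wd$mean, wd$mean_raw, wd$sd, wd$n_truncated, wd$bounds[1],
              wd$bounds[2]))
  invisible(x)
}

#' Write a cohort (and its latent truth) to CSV
#'
#' @param cohort A \code{"cart_cohort"} data frame.
#' @param path Output CSV path; the latent-truth companion (if attached) is
#'   written next to it with suffix \code{"_truth.csv"}.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) {
    utils::write.csv(tr, sub("\\.csv$", "_truth.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a person-visit cohort from CSV with schema validation
#'
#' @param path CSV path.
#' @return Data frame with factor columns restored; validation failures name
#'   the offending column (and first offending row).
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "visit", "regimen")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in c("cd4", "hiv_rna")) {
    if (v %in% names(d)) {
      bad <- which(!is.na(d[[v]]) & d[[v]] < 0)
      if (length(bad)) {
        stop("invalid negative ", v, " at row ", bad[1], call. = FALSE)
      }
    }
  }
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  if ("cd4_cat" %in% names(d)) {
    d$cd4_cat <- factor(d$cd4_cat, levels = c("ge500", "350to499", "lt350"))
  }
  lv <- unique(c(d$regimen, d$prev_regimen))
  lv <- lv[!is.na(lv)]
  d$regimen <- factor(d$regimen, levels = lv)
  if ("prev_regimen" %in% names(d)) {
    d$prev_regimen <- factor(d$prev_regimen, levels = lv)
  }
  d
}

#' Serialize an effectiveness (or trend) report to JSON
#'
#' Deterministic JSON serialization: the same cohort, configuration and seed
#' produce byte-identical files.
#'
#' @param report An \code{"effectiveness_report"} or \code{"trend_report"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  obj$config <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
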