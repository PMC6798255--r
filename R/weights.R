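#' Stabilized inverse-probability-of-treatment-and-censoring weights
#'
#' Builds per-visit stabilized weight components and cumulative weights for a
#' categorical time-varying treatment with informative dropout. The treatment
#' factor at each visit is the ratio of the fitted probability of the regimen
#' actually received under a history-only ("numerator") multinomial model to
#' that under a history-plus-time-varying-covariates ("denominator") model.
#' The censoring factor is the analogous ratio from two nested logistic models
#' for remaining uncensored, fitted on the risk set of person-visits whose
#' previous visit was observed, with predictors taken from the previous
#' visit's row. The final stabilized weight multiplies the treatment and
#' censoring factors and, in the default cumulative mode, takes the running
#' product within person over the visits of the analysis window (weights are
#' reset at the window start).
#'
#' @param data Person-visit data frame; one row per observed visit, visit
#'   indices consecutive integers from 0 within person until dropout.
#' @param treatment Name of the treatment (regimen category) column.
#' @param numerator,denominator Right-hand-side formulas for the treatment
#'   models. The denominator covariate set must contain the numerator set.
#' @param censor_numerator,censor_denominator Right-hand-side formulas for
#'   the remaining-uncensored models (predictors evaluated on the previous
#'   visit's row).
#' @param id,visit Column names for person id and 0-based visit index.
#' @param reference Reference treatment category (default: modal category).
#' @param max_visits Maximum number of visits per person under the design
#'   (administrative end of follow-up); persons with fewer visits are treated
#'   as censored. Default \code{max(visit) + 1}.
#' @param start_visit First visit of the analysis window (default 1: visit 0
#'   supplies history and contributes no weight factor).
#' @param cumulative Cumulative product within person (default) or visit-level
#'   factors only (sensitivity mode).
#' @param prob_floor Probabilities are floored at this value before division;
#'   floored rows are counted in the attributes.
#' @return Data frame of class \code{"iptc_weights"} keyed by (id, visit) with
#'   columns \code{t_num}, \code{t_den}, \code{c_num}, \code{c_den},
#'   \code{factor} (visit-level stabilized factor) and \code{sw} (stabilized
#'   weight). Attributes: fitted \code{models}, \code{n_floored}.
#' @export
iptc_weights <- function(data, treatment, numerator, denominator,
                         censor_numerator = NULL, censor_denominator = NULL,
                         id = "id", visit = "visit", reference = NULL,
                         max_visits = NULL, start_visit = 1L,
                         cumulative = TRUE, prob_floor = 1e-12) {
  stopifnot(all(c(id, visit, treatment) %in% names(data)))
  .check_nested(numerator, denominator)
  data <- data[order(data[[id]], data[[visit]]), , drop = FALSE]
  if (is.null(max_visits)) max_visits <- max(data[[visit]]) + 1L
  vis <- data[[visit]]
  in_window <- vis >= start_visit

  tw <- treatment_weight_components(data, treatment, numerator, denominator,
                                    reference = reference, subset = in_window)
  cw <- censoring_weight_components(data, censor_numerator, censor_denominator,
                                    id = id, visit = visit,
                                    max_visits = max_visits,
                                    start_visit = start_visit)

  n_floored <- sum(tw$den[in_window] < prob_floor, na.rm = TRUE) +
    sum(cw$den < prob_floor, na.rm = TRUE)
  fl <- function(p) pmax(p, prob_floor)

  wr <- data.frame(data[[id]], data[[visit]])
  names(wr) <- c(id, visit)
  wr$t_num <- ifelse(in_window, tw$num, 1)
  wr$t_den <- ifelse(in_window, tw$den, 1)
  wr$c_num <- cw$num
  wr$c_den <- cw$den
  wr$factor <- (fl(wr$t_num) / fl(wr$t_den)) * (fl(wr$c_num) / fl(wr$c_den))
  wr$sw <- if (cumulative) {
    stats::ave(wr$factor, wr[[id]], FUN = cumprod)
  } else {
    wr$factor
  }
  structure(wr, class = c("iptc_weights", "data.frame"),
            models = list(treatment = tw$models, censoring = cw$models),
            n_floored = n_floored, start_visit = start_visit,
            cumulative = cumulative)
}

.check_nested <- function(numerator, denominator) {
  nv <- all.vars(numerator)
  dv <- all.vars(denominator)
  if (!all(nv %in% dv)) {
    stop("denominator covariates must contain the numerator set; missing: ",
         paste(setdiff(nv, dv), collapse = ", "), call. = FALSE)
  }
}

#' Treatment weight components
#'
#' Fits the numerator (history-only) and denominator (history plus
#' time-varying covariates) multinomial models for the observed regimen and
#' returns each row's fitted probability of the regimen actually received.
#'
#' @inheritParams iptc_weights
#' @param subset Logical vector: rows inside the analysis window on which the
#'   models are fitted and probabilities computed (other rows get \code{NA}).
#' @return List with vectors \code{num}, \code{den} (aligned with
#'   \code{data} rows) and the fitted \code{models}.
#' @export
treatment_weight_components <- function(data, treatment, numerator,
                                        denominator, reference = NULL,
                                        subset = NULL) {
  .check_nested(numerator, denominator)
  if (is.null(subset)) subset <- rep(TRUE, nrow(data))
  dd <- data[subset, , drop = FALSE]
  dd[[treatment]] <- factor(as.character(dd[[treatment]]))
  lab <- function(f) {
    tl <- attr(stats::terms(f), "term.labels")
    if (length(tl)) tl else "1"
  }
  f_num <- stats::reformulate(lab(numerator), response = treatment)
  f_den <- stats::reformulate(lab(denominator), response = treatment)
  m_num <- fit_multinomial(f_num, dd, reference = reference)
  m_den <- fit_multinomial(f_den, dd, reference = reference)
  p_num <- p_den <- rep(NA_real_, nrow(data))
  p_num[subset] <- prob_observed(m_num, dd)
  p_den[subset] <- prob_observed(m_den, dd)
  list(num = p_num, den = p_den,
       models = list(numerator = m_num, denominator = m_den))
}

#' Censoring weight components
#'
#' Probabilities of remaining uncensored at each observed visit, from two
#' nested logistic models fitted on the censoring risk set: all person-visits
#' whose previous visit was observed and that lie before the administrative
#' end of follow-up. Predictors are the previous visit's values. If no
#' censoring occurs in the data all probabilities are 1.
#'
#' @inheritParams iptc_weights
#' @return List with vectors \code{num}, \code{den} aligned with \code{data}
#'   rows (1 for rows before \code{start_visit}) and the fitted
#'   \code{models} (\code{NULL} when there is no censoring).
#' @export
censoring_weight_components <- function(data, censor_numerator,
                                        censor_denominator,
                                        id = "id", visit = "visit",
                                        max_visits = NULL,
                                        start_visit = 1L) {
  n <- nrow(data)
  ones <- rep(1, n)
  if (is.null(censor_numerator) || is.null(censor_denominator)) {
    return(list(num = ones, den = ones, models = NULL))
  }
  .check_nested(censor_numerator, censor_denominator)
  if (is.null(max_visits)) max_visits <- max(data[[visit]]) + 1L
  data <- data[order(data[[id]], data[[visit]]), , drop = FALSE]
  key <- paste(data[[id]], data[[visit]])
  # risk set: rows at visit k-1 (k in start_visit..max_visits-1); event =
  # next visit observed
  risk <- data[data[[visit]] >= start_visit - 1L &
                 data[[visit]] <= max_visits - 2L, , drop = FALSE]
  if (!nrow(risk)) return(list(num = ones, den = ones, models = NULL))
  risk$.uncens <- as.integer(
    paste(risk[[id]], risk[[visit]] + 1L) %in% key
  )
  if (all(risk$.uncens == 1L)) {
    return(list(num = ones, den = ones, models = NULL))
  }
  f_num <- stats::reformulate(
    attr(stats::terms(censor_numerator), "term.labels"), response = ".uncens")
  f_den <- stats::reformulate(
    attr(stats::terms(censor_denominator), "term.labels"), response = ".uncens")
  m_num <- fit_logistic(f_num, risk)
  m_den <- fit_logistic(f_den, risk)
  p_num_risk <- stats::predict(m_num, newdata = risk, type = "response")
  p_den_risk <- stats::predict(m_den, newdata = risk, type = "response")
  # factor for surviving to visit k attaches to the row at k
  next_key <- paste(risk[[id]], risk[[visit]] + 1L)
  p_num <- p_den <- ones
  j <- match(key, next_key)
  hit <- !is.na(j)
  p_num[hit] <- p_num_risk[j[hit]]
  p_den[hit] <- p_den_risk[j[hit]]
  list(num = p_num, den = p_den,
       models = list(numerator = m_num, denominator = m_den))
}

#' Combine treatment and censoring components into stabilized weights
#'
#' Visit-level stabilized factor
#' \eqn{(p^T_{num}/p^T_{den}) \cdot (p^C_{num}/p^C_{den})} and its cumulative
#' product within person.
#'
#' @param treatment_components,censoring_components Lists with \code{num} and
#'   \code{den} vectors (as returned by [treatment_weight_components()] and
#'   [censoring_weight_components()]), aligned row-for-row.
#' @param id Person id vector (same length), used for the cumulative product;
#'   rows must be ordered by (id, visit).
#' @param cumulative Cumulative product (default) or visit-level factors.
#' @return Numeric vector of stabilized weights.
#' @export
stabilized_weights <- function(treatment_components, censoring_components,
                               id, cumulative = TRUE) {
  tn <- treatment_components$num; td <- treatment_components$den
  cn <- censoring_components$num; cd <- censoring_components$den
  tn[is.na(tn)] <- 1; td[is.na(td)] <- 1
  fac <- (tn / td) * (cn / cd)
  if (!cumulative) return(fac)
  stats::ave(fac, id, FUN = cumprod)
}

#' Truncate weights at percentile bounds
#'
#' Clamps weights to the values of the pooled weight distribution at the
#' given percentiles (default 1st and 99th), the standard guard against
#' undue influence of extreme weights. Truncation is idempotent: re-applying
#' it with the same bounds leaves the weights unchanged.
#'
#' @param weights Numeric vector of stabilized weights.
#' @param lower_percentile,upper_percentile Percentiles in [0, 100].
#' @param bounds Optional explicit \code{c(lower, upper)} bounds overriding
#'   the percentile computation (e.g. 0.03 and 10).
#' @return List with \code{weights} (truncated), \code{bounds} and
#'   \code{n_truncated}.
#' @export
truncate_weights <- function(weights, lower_percentile = 1,
                             upper_percentile = 99, bounds = NULL) {
  if (is.null(bounds)) {
    bounds <- unname(stats::quantile(
      weights, probs = c(lower_percentile, upper_percentile) / 100,
      type = 7, na.rm = TRUE))
  }
  out <- pmin(pmax(weights, bounds[1]), bounds[2])
  list(weights = out, bounds = bounds,
       n_truncated = sum(weights < bounds[1] | weights > bounds[2],
                         na.rm = TRUE))
}

#' Summarize a weight distribution
#'
#' @param weights Numeric vector of (possibly truncated) weights.
#' @param bounds Optional truncation bounds used, for reporting.
#' @param n_truncated Optional count of clamped weights.
#' @return Named list: \code{n}, \code{mean}, \code{sd}, \code{min},
#'   \code{max}, percentiles (1, 5, 25, 50, 75, 95, 99), \code{n_truncated}.
#' @export
weight_diagnostics <- function(weights, bounds = NULL, n_truncated = NA) {
  qs <- stats::quantile(weights, probs = c(.01, .05, .25, .5, .75, .95, .99),
                        type = 7, na.rm = TRUE)
  list(n = length(weights), mean = mean(weights), sd = stats::sd(weights),
       min = min(weights), max = max(weights),
       percentiles = as.list(qs), bounds = bounds, n_truncated = n_truncated)
}

#' Weighted standardized mean differences by treatment category
#'
#' Balance diagnostic for the weighted pseudo-population: for each covariate
#' and each non-reference treatment category, the difference in weighted
#' means from the reference category divided by the unweighted pooled
#' standard deviation. Factors are expanded to indicator columns.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate column names.
#' @param treatment Treatment column name.
#' @param weights Numeric weights (default: unweighted).
#' @param reference Reference category (default: modal).
#' @return Matrix of SMDs, rows = expanded covariates, columns = categories.
#' @export
weighted_smd <- function(data, covariates, treatment, weights = NULL,
                         reference = NULL) {
  tr <- factor(as.character(data[[treatment]]))
  if (is.null(reference)) reference <- names(which.max(table(tr)))
  if (is.null(weights)) weights <- rep(1, nrow(data))
  X <- stats::model.matrix(
    stats::reformulate(covariates, intercept = FALSE), data)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  cats <- setdiff(levels(tr), reference)
  ref_idx <- tr == reference
  wm <- function(x, w) sum(x * w) / sum(w)
  out <- sapply(cats, function(cc) {
    idx <- tr == cc
    vapply(seq_len(ncol(X)), function(j) {
      (wm(X[idx, j], weights[idx]) - wm(X[ref_idx, j], weights[ref_idx])) /
        sds[j]
    }, numeric(1))
  })
  rownames(out) <- colnames(X)
  out
}
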