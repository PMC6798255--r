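#' Modified Poisson regression with cluster-robust variance
#'
#' Fits a log-link Poisson model by maximum (pseudo-)likelihood and pairs it
#' with a cluster-robust sandwich covariance, the standard device for
#' estimating rate/risk ratios for binary outcomes from longitudinal data
#' ("Poisson regression with robust variance"). Repeated visits of the same
#' participant are accommodated by clustering the sandwich estimator on the
#' participant id; with singleton clusters it reduces to the
#' heteroskedasticity-robust estimator.
#'
#' Point estimates are invariant to rescaling all observation weights by a
#' constant. The sandwich "meat" uses cluster-summed scores with the
#' small-sample multiplier \eqn{G/(G-1)} where \eqn{G} is the number of
#' clusters.
#'
#' @param formula Model formula; the response may be binary (0/1) or a count.
#' @param data Data frame.
#' @param weights Optional non-negative observation weights (e.g. stabilized
#'   IPTC weights): a numeric vector or the name of a column of \code{data}.
#' @param cluster Optional cluster identifiers (vector or column name).
#'   Default: each row is its own cluster.
#' @param epsilon,maxit IRLS convergence control: iteration stops when the
#'   relative deviance change falls below \code{epsilon} (default 1e-10) or
#'   after \code{maxit} (default 100) iterations; non-convergence is flagged,
#'   never silent.
#' @return An object of class \code{"modpois"} with components
#'   \code{coefficients}, \code{vcov} (model-based), \code{vcov_robust},
#'   \code{fitted.values}, \code{converged}, \code{iter}, \code{n_obs},
#'   \code{n_clusters}, \code{separation} and the underlying \code{glm} fit.
#' @examples
#' d <- data.frame(y = c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85)),
#'                 g = rep(c(1, 0), each = 100))
#' fit <- modpois(y ~ g, d)
#' exp(coef(fit)["g"])  # risk ratio 2.0
#' @export
modpois <- function(formula, data, weights = NULL, cluster = NULL,
                    epsilon = 1e-10, maxit = 100) {
  w <- .resolve_col(substitute(weights), data, parent.frame())
  cl <- .resolve_col(substitute(cluster), data, parent.frame())
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  keep <- stats::complete.cases(mf)
  if (!is.null(w)) {
    if (any(!is.finite(w[keep]))) stop("non-finite weights", call. = FALSE)
    if (any(w[keep] < 0)) stop("negative weights", call. = FALSE)
  }
  if (all(y[keep] == 0)) stop("all-zero outcome: rate ratios undefined",
                              call. = FALSE)
  dat <- data
  dat$.mp_w <- if (is.null(w)) rep(1, nrow(data)) else w
  g <- stats::glm(formula, family = stats::quasipoisson(link = "log"),
                  data = dat, weights = .mp_w,
                  control = stats::glm.control(epsilon = epsilon,
                                               maxit = maxit))
  beta <- stats::coef(g)
  if (anyNA(beta)) {
    stop("rank-deficient design: aliased column(s) ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  separation <- any(abs(beta) > 15)
  if (separation) {
    warning("possible separation/divergence: |coefficient| > 15", call. = FALSE)
  }
  X <- stats::model.matrix(g)
  mu <- g$fitted.values
  wv <- g$prior.weights
  yy <- g$y
  info <- crossprod(X * sqrt(wv * mu))        # expected information
  vcov_model <- solve(info)
  scores <- X * (wv * (yy - mu))
  cl_use <- if (is.null(cl)) seq_len(nrow(X)) else cl[keep]
  if (length(cl_use) != nrow(X)) cl_use <- cl_use[seq_len(nrow(X))]
  vr <- .cluster_sandwich(vcov_model, scores, cl_use)
  dimnames(vcov_model) <- list(names(beta), names(beta))
  out <- structure(list(
    coefficients = beta,
    vcov = vcov_model,
    vcov_robust = vr$vcov,
    fitted.values = mu,
    linear.predictors = g$linear.predictors,
    converged = g$converged && !separation,
    iter = g$iter,
    n_obs = nrow(X),
    n_clusters = vr$n_clusters,
    separation = separation,
    deviance = g$deviance,
    glm = g,
    formula = formula,
    call = match.call()
  ), class = "modpois")
  out
}

# cluster-level sandwich: bread %*% meat %*% bread with G/(G-1) correction
.cluster_sandwich <- function(bread, scores, cluster) {
  cs <- rowsum(scores, group = cluster, reorder = FALSE)
  G <- nrow(cs)
  meat <- crossprod(cs) * G / max(G - 1, 1)
  v <- bread %*% meat %*% bread
  dimnames(v) <- dimnames(bread)
  list(vcov = v, n_clusters = G)
}

.resolve_col <- function(expr, data, env) {
  if (is.null(expr)) return(NULL)
  v <- tryCatch(eval(expr, data, env), error = function(e) NULL)
  if (is.null(v)) return(NULL)
  if (is.character(v) && length(v) == 1L && v %in% names(data)) {
    v <- data[[v]]
  }
  v
}

#' @export
print.modpois <- function(x, ...) {
  cat("Modified Poisson regression (log link, cluster-robust variance)\n")
  cat("n =", x$n_obs, " clusters =", x$n_clusters,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.modpois <- function(object, ...) object$coefficients

#' @export
nobs.modpois <- function(object, ...) object$n_obs

#' Covariance of a modified Poisson fit
#' @param object A \code{"modpois"} fit.
#' @param type \code{"robust"} (default) or \code{"model"}.
#' @param ... Unused.
#' @export
vcov.modpois <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$vcov_robust else object$vcov
}

#' @export
summary.modpois <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov_robust))
  z <- object$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(
    estimate = object$coefficients,
    rr = exp(object$coefficients),
    robust_se = se,
    z = z,
    p = p,
    rr_lo = exp(object$coefficients - zq * se),
    rr_hi = exp(object$coefficients + zq * se)
  )
  structure(list(coefficients = tab, level = level,
                 n_obs = object$n_obs, n_clusters = object$n_clusters,
                 converged = object$converged), class = "summary.modpois")
}

#' @export
print.summary.modpois <- function(x, ...) {
  cat("Modified Poisson regression, robust (cluster) variance\n")
  cat("n =", x$n_obs, " clusters =", x$n_clusters, "\n\n")
  stats::printCoefmat(x$coefficients, digits = 4, P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.modpois <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov_robust))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)),
                        "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.modpois <- function(object, newdata = NULL,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "link") object$linear.predictors else
      object$fitted.values)
  }
  stats::predict(object$glm, newdata = newdata, type = type)
}

#' @export
residuals.modpois <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  stats::residuals(object$glm, type = type)
}

#' Forest-style plot of rate ratios from a modified Poisson fit
#' @param x A \code{"modpois"} fit.
#' @param level Confidence level.
#' @param ... Passed to \code{plot}.
#' @export
plot.modpois <- function(x, level = 0.95, ...) {
  s <- summary(x, level = level)$coefficients
  s <- s[rownames(s) != "(Intercept)", , drop = FALSE]
  k <- nrow(s)
  graphics::plot(s[, "rr"], seq_len(k), xlim = range(s[, c("rr_lo", "rr_hi")]),
                 log = "x", yaxt = "n", xlab = "rate ratio", ylab = "",
                 pch = 19, ...)
  graphics::segments(s[, "rr_lo"], seq_len(k), s[, "rr_hi"], seq_len(k))
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = rownames(s), las = 1)
  invisible(x)
}

#' Rate ratio and confidence interval for a contrast
#'
#' Exponentiates a linear contrast of the coefficients with a Wald interval
#' on the robust (sandwich) scale:
#' \eqn{RR = \exp(c'\beta)}, \eqn{CI = \exp(c'\beta \pm z \cdot SE)}.
#'
#' @param fit A \code{"modpois"} fit.
#' @param contrast A coefficient name, or a numeric contrast vector of the
#'   same length as \code{coef(fit)}.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector \code{c(rr, lower, upper)}.
#' @export
rate_ratio_ci <- function(fit, contrast, level = 0.95) {
  beta <- fit$coefficients
  if (is.character(contrast)) {
    cvec <- as.numeric(names(beta) == contrast)
    if (sum(cvec) != 1) stop("unknown coefficient: ", contrast, call. = FALSE)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != length(beta)) {
      stop("contrast length must match coefficient vector", call. = FALSE)
    }
  }
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov_robust %*% cvec))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(rr = exp(est), lower = exp(est - zq * se), upper = exp(est + zq * se))
}

#' Logistic regression with separation and rank diagnostics
#'
#' Maximum-likelihood logistic fit (IRLS via \code{stats::glm}) with the
#' diagnostics the weight-estimation step needs: rank deficiency is an error
#' naming the aliased columns, and (quasi-)separation — any coefficient
#' exceeding 15 in absolute value — is flagged and warned about, never
#' silently regularized.
#'
#' @inheritParams modpois
#' @return The \code{glm} object with extra class \code{"cart_logit"} and
#'   a \code{separation} flag.
#' @export
fit_logistic <- function(formula, data, weights = NULL,
                         epsilon = 1e-10, maxit = 100) {
  w <- .resolve_col(substitute(weights), data, parent.frame())
  dat <- data
  dat$.lg_w <- if (is.null(w)) rep(1, nrow(data)) else w
  g <- suppressWarnings(stats::glm(
    formula, family = stats::quasibinomial(), data = dat, weights = .lg_w,
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  beta <- stats::coef(g)
  if (anyNA(beta)) {
    stop("rank-deficient design: aliased column(s) ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  sep <- any(abs(beta) > 15) || !g$converged
  if (sep) warning("possible separation: fit flagged", call. = FALSE)
  g$separation <- sep
  class(g) <- c("cart_logit", class(g))
  g
}

#' Baseline-category multinomial logistic regression
#'
#' Fits the unordered multinomial logit model used for the 7-category
#' time-varying regimen weights, via \code{nnet::multinom}, with an explicit
#' reference category ("the most reported regimen as the reference").
#'
#' @inheritParams modpois
#' @param reference Reference category label; must be a level of the
#'   response. Default: the modal (most frequent) category.
#' @return Object of class \code{"cart_multinom"} wrapping the \code{nnet}
#'   fit, with \code{$reference} and \code{$levels}.
#' @export
fit_multinomial <- function(formula, data, reference = NULL, weights = NULL) {
  w <- .resolve_col(substitute(weights), data, parent.frame())
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  tab <- table(y)
  if (any(tab == 0)) {
    stop("empty treatment categor(ies): ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(reference)) reference <- names(tab)[which.max(tab)]
  if (!reference %in% levels(y)) {
    stop("reference category not present: ", reference, call. = FALSE)
  }
  dat <- data
  resp <- as.character(formula[[2]])
  dat[[resp]] <- stats::relevel(factor(dat[[resp]], levels = levels(y)),
                                ref = reference)
  fit <- if (is.null(w)) {
    nnet::multinom(formula, data = dat, trace = FALSE, maxit = 500,
                   reltol = 1e-12, MaxNWts = 10000, model = TRUE)
  } else {
    dat$.mn_w <- w
    nnet::multinom(formula, data = dat, weights = .mn_w, trace = FALSE,
                   maxit = 500, reltol = 1e-12, MaxNWts = 10000,
                   model = TRUE)
  }
  coefs <- stats::coef(fit)
  sep <- any(abs(coefs) > 15)
  if (sep) warning("possible separation in multinomial fit", call. = FALSE)
  structure(list(fit = fit, reference = reference,
                 levels = levels(dat[[resp]]), response = resp,
                 separation = sep, formula = formula),
            class = "cart_multinom")
}

#' @export
coef.cart_multinom <- function(object, ...) stats::coef(object$fit)

#' Predicted category probabilities from a multinomial fit
#'
#' @param object A \code{"cart_multinom"} fit.
#' @param newdata Data frame (default: refit data).
#' @param ... Unused.
#' @return Matrix of probabilities, rows summing to 1, columns named by
#'   category.
#' @export
predict.cart_multinom <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) stats::predict(object$fit, type = "probs") else
    stats::predict(object$fit, newdata = newdata, type = "probs")
  if (is.null(dim(p))) {  # two-category case returns P(non-reference)
    p <- cbind(1 - p, p)
    colnames(p) <- object$fit$lev
  }
  p
}

#' Probability of the observed category
#'
#' Per-row fitted probability of the treatment category actually received —
#' the building block of inverse-probability-of-treatment weights.
#'
#' @param object A \code{"cart_multinom"} fit.
#' @param newdata Data frame containing predictors and the response column.
#' @return Numeric vector of probabilities.
#' @export
prob_observed <- function(object, newdata) {
  p <- predict(object, newdata = newdata)
  y <- as.character(newdata[[object$response]])
  j <- match(y, colnames(p))
  if (anyNA(j)) stop("observed category not among model levels", call. = FALSE)
  p[cbind(seq_len(nrow(p)), j)]
}
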