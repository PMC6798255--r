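#' EM estimation of a multivariate normal with missing data
#'
#' Maximum-likelihood mean vector and covariance matrix of a joint normal
#' model over the declared variables under arbitrary missingness patterns,
#' by expectation-maximization. Binary variables are coded 0/1 and included
#' on the continuous scale. With complete data the estimate equals the
#' closed-form sample mean and (maximum-likelihood, divisor \eqn{n})
#' covariance after a single iteration.
#'
#' @param data Data frame or numeric matrix.
#' @param variables Columns to model (default: all).
#' @param tol Relative observed-data log-likelihood change for convergence.
#' @param maxit Maximum EM iterations.
#' @return List with \code{mu}, \code{sigma}, \code{iterations},
#'   \code{converged}, \code{loglik}, \code{n}.
#' @export
fit_mvn_model <- function(data, variables = NULL, tol = 1e-8, maxit = 500) {
  Y <- .as_numeric_matrix(data, variables)
  n <- nrow(Y); p <- ncol(Y)
  if (p < 2) stop("need at least 2 variables", call. = FALSE)
  obs_var <- apply(Y, 2, function(v) stats::var(v[!is.na(v)]))
  if (any(is.na(obs_var)) || any(obs_var == 0)) {
    bad <- colnames(Y)[is.na(obs_var) | obs_var == 0]
    stop("degenerate (constant or unobserved) variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mu <- colMeans(Y, na.rm = TRUE)
  sigma <- .available_case_cov(Y)
  miss <- is.na(Y)
  pat_id <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_id)
  ll_old <- -Inf; converged <- FALSE; it <- 0
  while (it < maxit) {
    it <- it + 1
    S1 <- numeric(p); S2 <- matrix(0, p, p); ll <- 0
    for (rows in pats) {
      m <- miss[rows[1], ]
      o <- !m
      Yo <- Y[rows, o, drop = FALSE]
      So <- sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(ch)) stop("covariance became non-positive-definite ",
                            "during EM (condition number ",
                            format(kappa(sigma)), ")", call. = FALSE)
      ctr <- sweep(Yo, 2, mu[o])
      # observed-data loglik contribution
      z <- forwardsolve(t(ch), t(ctr))
      ll <- ll - 0.5 * length(rows) * (sum(o) * log(2 * pi) +
                                         2 * sum(log(diag(ch)))) -
        0.5 * sum(z^2)
      Yhat <- matrix(rep(mu, each = length(rows)), nrow = length(rows))
      colnames(Yhat) <- colnames(Y)
      Yhat[, o] <- Yo
      Cadd <- matrix(0, p, p)
      if (any(m)) {
        B <- sigma[m, o, drop = FALSE] %*% chol2inv(ch)   # regression coefs
        Yhat[, m] <- matrix(rep(mu[m], each = length(rows)),
                            nrow = length(rows)) + ctr %*% t(B)
        Cmm <- sigma[m, m, drop = FALSE] -
          B %*% sigma[o, m, drop = FALSE]
        Cadd[m, m] <- Cmm * length(rows)
      }
      S1 <- S1 + colSums(Yhat)
      S2 <- S2 + crossprod(Yhat) + Cadd
    }
    mu <- S1 / n
    sigma <- S2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("non-positive-definite covariance after EM (eigenvalues ",
         paste(format(range(ev)), collapse = " .. "), ")", call. = FALSE)
  }
  list(mu = mu, sigma = sigma, iterations = it, converged = converged,
       loglik = ll_old, n = n)
}

.as_numeric_matrix <- function(data, variables = NULL) {
  if (is.null(variables)) variables <- colnames(data)
  Y <- sapply(variables, function(v) as.numeric(data[[v]]))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  colnames(Y) <- variables
  Y
}

.available_case_cov <- function(Y) {
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6 * max(e$values))
  e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
}

#' Multiple imputation from a multivariate normal model
#'
#' Proper multiple imputation of missing entries: for each of \code{m}
#' completed datasets the model parameters are drawn from a normal/Wishart
#' approximation to the sampling distribution of the EM estimates
#' (\eqn{\mu^* \sim N(\hat\mu, \hat\Sigma/n)},
#' \eqn{\Sigma^* \sim Wishart(n-1, \hat\Sigma/(n-1))}), then each missing
#' block is drawn from its conditional normal given the observed entries.
#' Declared binary variables are imputed on the continuous scale and
#' thresholded at 0.5. With no missing values all \code{m} datasets equal the
#' input. Reproducible given \code{seed}.
#'
#' @param data Data frame.
#' @param variables Columns entering the joint normal model.
#' @param m Number of completed datasets (default 25).
#' @param seed Integer seed.
#' @param binary Character vector of variables to round to \{0, 1\} after
#'   imputation; default: variables whose observed values are all 0/1.
#' @param model Optional pre-fitted model from [fit_mvn_model()].
#' @return Object of class \code{"imputation_set"}: list with
#'   \code{datasets} (list of m data frames), \code{m}, \code{seed},
#'   \code{variables}, \code{binary}, \code{missing_fraction}.
#' @export
mi_impute <- function(data, variables, m = 25, seed = 1, binary = NULL,
                      model = NULL) {
  Y <- .as_numeric_matrix(data, variables)
  miss <- is.na(Y)
  miss_frac <- colMeans(miss)
  if (is.null(binary)) {
    binary <- variables[vapply(variables, function(v) {
      vv <- Y[, v][!miss[, v]]
      all(vv %in% c(0, 1))
    }, logical(1))]
  }
  out <- list(datasets = vector("list", m), m = m, seed = seed,
              variables = variables, binary = binary,
              missing_fraction = miss_frac)
  class(out) <- "imputation_set"
  if (!any(miss)) {
    out$datasets <- replicate(m, data, simplify = FALSE)
    return(out)
  }
  if (is.null(model)) model <- fit_mvn_model(data, variables)
  n <- model$n; p <- length(model$mu)
  set.seed(seed)
  ch_mu <- chol(model$sigma / n)
  pat_id <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(nrow(Y)), pat_id)
  for (t in seq_len(m)) {
    mu_s <- drop(model$mu + t(ch_mu) %*% stats::rnorm(p))
    W <- stats::rWishart(1, df = n - 1, Sigma = model$sigma / (n - 1))[, , 1]
    sig_s <- (W + t(W)) / 2
    Yt <- Y
    for (rows in pats) {
      mrow <- miss[rows[1], ]
      if (!any(mrow)) next
      o <- !mrow
      nm <- sum(mrow); nr <- length(rows)
      if (!any(o)) {
        Cch <- chol(sig_s)
        draw <- matrix(rep(mu_s, each = nr), nrow = nr) +
          matrix(stats::rnorm(nr * p), nr, p) %*% Cch
        Yt[rows, ] <- draw
        next
      }
      So <- sig_s[o, o, drop = FALSE]
      B <- sig_s[mrow, o, drop = FALSE] %*% solve(So)
      condmean <- matrix(rep(mu_s[mrow], each = nr), nrow = nr) +
        sweep(Y[rows, o, drop = FALSE], 2, mu_s[o]) %*% t(B)
      Cmm <- sig_s[mrow, mrow, drop = FALSE] -
        B %*% sig_s[o, mrow, drop = FALSE]
      Cmm <- (Cmm + t(Cmm)) / 2
      Cch <- chol(Cmm + diag(1e-12, nm))
      Yt[rows, mrow] <- condmean +
        matrix(stats::rnorm(nr * nm), nr, nm) %*% Cch
    }
    dt <- data
    for (v in variables) {
      newv <- Yt[, v]
      if (v %in% binary) newv <- as.numeric(newv > 0.5)
      orig <- as.numeric(data[[v]])
      orig[miss[, v]] <- newv[miss[, v]]
      dt[[v]] <- orig
    }
    out$datasets[[t]] <- dt
  }
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Multiple imputation set: m =", x$m, "datasets\n")
  mf <- x$missing_fraction[x$missing_fraction > 0]
  if (length(mf)) {
    cat("imputed variables:\n")
    for (v in names(mf)) cat(sprintf("  %s: %.1f%% missing\n", v, 100 * mf[v]))
  } else cat("no missing values\n")
  invisible(x)
}

#' Rubin's rules for pooling multiply-imputed estimates
#'
#' Combines \code{m} per-imputation estimates and squared standard errors:
#' pooled estimate = mean of estimates; within-imputation variance
#' \eqn{\bar W} = mean of variances; between-imputation variance \eqn{B} =
#' sample variance of estimates; total variance
#' \eqn{T = \bar W + (1 + 1/m) B}; degrees of freedom
#' \eqn{(m-1)\,(1 + \bar W / ((1+1/m) B))^2} (infinite when \eqn{B = 0}).
#'
#' @param estimates Numeric vector of m estimates, or an m-by-k matrix for k
#'   parameters.
#' @param variances Squared standard errors, same shape as \code{estimates}.
#' @param level Confidence level for the pooled t-interval.
#' @return Data frame of class \code{"pooled_estimate"} with columns
#'   \code{estimate}, \code{W}, \code{B}, \code{T}, \code{se}, \code{df},
#'   \code{lower}, \code{upper}.
#' @examples
#' pool_rubin(c(1.0, 1.2, 1.1), c(0.04, 0.05, 0.045))
#' @export
pool_rubin <- function(estimates, variances, level = 0.95) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1)
  if (is.null(dim(variances))) variances <- matrix(variances, ncol = 1)
  m <- nrow(estimates)
  if (m < 2) stop("need m >= 2 imputations to estimate between-imputation ",
                  "variance", call. = FALSE)
  est <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  se <- sqrt(Tv)
  tq <- stats::qt(1 - (1 - level) / 2, df = df)
  out <- data.frame(estimate = est, W = W, B = B, T = Tv, se = se, df = df,
                    lower = est - tq * se, upper = est + tq * se)
  if (!is.null(colnames(estimates))) rownames(out) <- colnames(estimates)
  class(out) <- c("pooled_estimate", "data.frame")
  out
}
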