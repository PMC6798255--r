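test_that("logistic fit reproduces the closed-form 2x2 solution", {
  # layout: x=1 -> a events / b non-events; x=0 -> c / d
  a <- 40; b <- 60; c <- 20; d <- 80
  dat <- data.frame(y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
                    x = rep(c(1, 0), c(a + b, c + d)))
  f <- fit_logistic(y ~ x, dat)
  expect_equal(unname(coef(f)["(Intercept)"]), log(c / d), tolerance = 1e-8)
  expect_equal(unname(coef(f)["x"]), log((a / b) / (c / d)),
               tolerance = 1e-8)
  expect_true(all(fitted(f) > 0 & fitted(f) < 1))
  expect_false(f$separation)
})

test_that("degenerate logistic outcomes are flagged as separation", {
  dat <- data.frame(y = rep(0, 40), x = rnorm(40))
  expect_warning(f <- fit_logistic(y ~ 1, dat), "separation")
  expect_true(f$separation)
})

test_that("rank deficiency is an error naming the aliased column", {
  dat <- data.frame(y = rbinom(50, 1, .4), x = rnorm(50))
  dat$x2 <- 2 * dat$x
  expect_error(fit_logistic(y ~ x + x2, dat), "x2")
  expect_error(modpois(y ~ x + x2, dat), "x2")
})

test_that("MLE point estimates are invariant to weight rescaling", {
  set.seed(8)
  dat <- data.frame(y = rbinom(120, 1, .3), x = rnorm(120))
  f1 <- fit_logistic(y ~ x, dat, weights = rep(1, 120))
  f2 <- fit_logistic(y ~ x, dat, weights = rep(2, 120))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  p1 <- modpois(y ~ x, dat, weights = rep(1, 120))
  p2 <- modpois(y ~ x, dat, weights = rep(2, 120))
  expect_equal(coef(p1), coef(p2), tolerance = 1e-10)
})

test_that("two-category multinomial reduces to binary logistic", {
  set.seed(9)
  dat <- data.frame(g = factor(sample(c("A", "B"), 200, TRUE)),
                    x = rnorm(200))
  dat$y <- as.numeric(dat$g == "B")
  fm <- fit_multinomial(g ~ x, dat, reference = "A")
  fl <- fit_logistic(y ~ x, dat)
  expect_equal(unname(drop(coef(fm))), unname(coef(fl)), tolerance = 1e-5)
})

test_that("intercept-only multinomial reproduces category frequencies", {
  set.seed(10)
  dat <- data.frame(g = factor(sample(LETTERS[1:4], 300, TRUE,
                                      prob = c(.4, .3, .2, .1))))
  fm <- fit_multinomial(g ~ 1, dat)
  p <- predict(fm, newdata = dat)
  expect_equal(unname(rowSums(p)), rep(1, 300), tolerance = 1e-12)
  freq <- as.numeric(table(dat$g)[colnames(p)]) / 300
  expect_equal(unname(p[1, ]), freq, tolerance = 1e-6)
})

test_that("three-category multinomial matches direct likelihood
          maximization (independent optimizer oracle)", {
  set.seed(11)
  n <- 150
  x <- rbinom(n, 1, .5)
  eta2 <- -0.3 + 0.8 * x
  eta3 <- 0.2 - 0.5 * x
  pr <- cbind(1, exp(eta2), exp(eta3))
  pr <- pr / rowSums(pr)
  g <- factor(apply(pr, 1, function(p) sample(1:3, 1, prob = p)),
              levels = 1:3)
  dat <- data.frame(g = g, x = x)
  fm <- fit_multinomial(g ~ x, dat, reference = "1")
  # oracle: maximize the multinomial log-likelihood directly with optim,
  # independent of the nnet fitting path
  nll <- function(th) {
    e2 <- th[1] + th[2] * x
    e3 <- th[3] + th[4] * x
    den <- 1 + exp(e2) + exp(e3)
    -sum(ifelse(g == 2, e2, ifelse(g == 3, e3, 0)) - log(den))
  }
  o <- optim(rep(0, 4), nll, method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(as.numeric(t(coef(fm))), o$par, tolerance = 1e-4)
  expect_error(fit_multinomial(g ~ x, dat, reference = "9"),
               "reference")
})

test_that("empty treatment categories are an error", {
  dat <- data.frame(g = factor(c("A", "A", "B"), levels = c("A", "B", "C")),
                    x = 1:3)
  expect_error(fit_multinomial(g ~ x, dat), "empty")
})

test_that("modified Poisson on a two-group binary toy equals the exact
          proportion ratio", {
  f <- modpois(y ~ g, two_group_data())
  expect_equal(unname(exp(coef(f)["g"])), 2.0, tolerance = 1e-8)
  expect_equal(unname(exp(coef(f)["(Intercept)"])), 0.15, tolerance = 1e-8)
  expect_error(modpois(y ~ g, data.frame(y = rep(0, 10), g = rep(0:1, 5))),
               "all-zero")
})

test_that("IRLS solutions satisfy the score equations to 1e-8", {
  set.seed(12)
  dat <- data.frame(y = rbinom(200, 1, .25), x = rnorm(200),
                    z = rnorm(200), w = runif(200, .5, 2))
  f <- modpois(y ~ x + z, dat, weights = w)
  X <- model.matrix(f$glm)
  score <- crossprod(X, dat$w * (dat$y - f$fitted.values))
  expect_lt(max(abs(score)), 1e-8)
  g <- fit_logistic(y ~ x + z, dat)
  score_l <- crossprod(model.matrix(g), g$prior.weights * (g$y - fitted(g)))
  expect_lt(max(abs(score_l)), 1e-8)
})

test_that("cluster sandwich matches the independent sandwich-package
          computation and is relabeling-invariant", {
  skip_if_not_installed("sandwich")
  set.seed(13)
  n <- 300
  dat <- data.frame(y = rbinom(n, 1, .3), x = rnorm(n),
                    cl = sample(1:40, n, TRUE))
  f <- modpois(y ~ x, dat, cluster = cl)
  v_pkg <- sandwich::vcovCL(f$glm, cluster = dat$cl, type = "HC0",
                            cadjust = TRUE)
  expect_equal(unclass(f$vcov_robust), unclass(v_pkg), tolerance = 1e-6,
               ignore_attr = TRUE)
  # relabeling clusters leaves the covariance unchanged
  relab <- match(dat$cl, sample(unique(dat$cl)))
  f2 <- modpois(y ~ x, dat, cluster = relab)
  expect_equal(f$vcov_robust, f2$vcov_robust, tolerance = 1e-10)
})

test_that("singleton clusters reduce to the heteroskedasticity-robust
          covariance", {
  set.seed(14)
  dat <- data.frame(y = rbinom(80, 1, .4), x = rnorm(80))
  f_noc <- modpois(y ~ x, dat)
  f_cl <- modpois(y ~ x, dat, cluster = seq_len(80))
  expect_equal(f_noc$vcov_robust, f_cl$vcov_robust, tolerance = 1e-12)
  expect_equal(f_cl$n_clusters, 80)
})

test_that("rate_ratio_ci applies the Wald construction on the robust scale", {
  f <- modpois(y ~ g, two_group_data())
  # hand computation: coef log 2, the robust SE taken from the fit
  se <- sqrt(f$vcov_robust["g", "g"])
  ci <- rate_ratio_ci(f, "g")
  expect_equal(unname(ci["rr"]), 2, tolerance = 1e-8)
  expect_equal(unname(ci["lower"]), exp(log(2) - qnorm(.975) * se),
               tolerance = 1e-10)
  expect_equal(unname(ci["upper"]), exp(log(2) + qnorm(.975) * se),
               tolerance = 1e-10)
  # ordering property and the degenerate zero-contrast case
  expect_true(ci["lower"] <= ci["rr"] && ci["rr"] <= ci["upper"])
  z <- rate_ratio_ci(f, c(0, 0))
  expect_equal(unname(z), c(1, 1, 1))
  expect_error(rate_ratio_ci(f, "nope"), "unknown")
})

test_that("modpois methods are coherent", {
  dat <- two_group_data()
  f <- modpois(y ~ g, dat)
  s <- summary(f)
  expect_s3_class(s, "summary.modpois")
  expect_equal(unname(s$coefficients["g", "rr"]), 2, tolerance = 1e-8)
  expect_equal(predict(f, newdata = data.frame(g = 0), type = "response"),
               c(`1` = 0.15), tolerance = 1e-8)
  expect_equal(length(residuals(f)), nobs(f))
  ci <- confint(f)
  expect_equal(dim(ci), c(2, 2))
  expect_silent(grDevices::pdf(NULL))
  expect_silent(plot(f))
  grDevices::dev.off()
})
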