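elev49 <- seq(100, 4900, 100)

test_that("VIF is 1 for orthogonal predictors and matches the 1/(1-R2) oracle", {
  x1 <- rep(c(-1, 1), 10)
  x2 <- rep(c(-1, -1, 1, 1), 5)
  expect_equal(as.numeric(vif(data.frame(x1, x2))), c(1, 1), tolerance = 1e-12)

  set.seed(51)
  n <- 200
  a <- rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.8^2) * rnorm(n)
  c_ <- rnorm(n)
  d <- data.frame(a, b, c_)
  v <- vif(d)
  # independent oracle: R2 via normal equations, predictor a on (b, c_)
  X <- cbind(1, b, c_)
  beta <- oracle_ols(X, a)
  r2 <- 1 - sum((a - X %*% beta)^2) / sum((a - mean(a))^2)
  expect_equal(unname(v["a"]), 1 / (1 - r2), tolerance = 1e-8)
})

test_that("VIF agrees with the standard regression-package implementation", {
  set.seed(52)
  d <- data.frame(x = rnorm(60), y = rnorm(60), z = rnorm(60))
  d$w <- d$x + 0.5 * d$y + rnorm(60, 0, 0.4)
  ours <- vif(d)
  resp <- rnorm(60)
  ref <- car::vif(lm(resp ~ x + y + z + w, data = d))
  expect_equal(as.numeric(ours), as.numeric(ref[names(ours)]), tolerance = 1e-8)
})

test_that("duplicated predictors give infinite VIF and are named", {
  d <- data.frame(x = rnorm(30))
  d$y <- d$x
  d$z <- rnorm(30)
  v <- vif(d)
  expect_true(is.infinite(v["x"]) && is.infinite(v["y"]))
  expect_setequal(attr(v, "aliased"), c("x", "y"))
})

test_that("VIF guards degenerate inputs", {
  expect_error(vif(data.frame(x = rnorm(10))), "at least 2")
  expect_error(vif(data.frame(x = rnorm(3), y = rnorm(3), z = rnorm(3), w = rnorm(3))),
               "n > number")
  expect_error(vif(data.frame(x = rnorm(10), y = rep(1, 10))), "constant")
})

test_that("GLS with no correlation reproduces OLS exactly", {
  x <- seq(0, 1, length.out = 49)
  y <- 2 + 3 * x
  f <- fit_gls(y ~ x, data.frame(x = x, y = y), elev49, correlation = "none")
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)

  set.seed(61)
  y2 <- 2 + 3 * x + rnorm(49)
  f2 <- fit_gls(y2 ~ x, data.frame(x = x, y2 = y2), elev49, correlation = "none")
  lmfit <- lm(y2 ~ x)
  expect_equal(unname(f2$coefficients), unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(f2$logLik, as.numeric(logLik(lmfit)), tolerance = 1e-6)
})

test_that("AIC equals -2 logLik + 2k for every structure", {
  set.seed(62)
  x <- rnorm(49)
  y <- 1 + x + as.numeric(arima.sim(list(ar = 0.7), 49))
  for (s in c("none", "gaussian", "exponential", "spherical")) {
    f <- fit_gls(y ~ x, data.frame(x = x, y = y), elev49, correlation = s)
    expect_equal(f$AIC, -2 * f$logLik + 2 * f$k, tolerance = 1e-8)
  }
})

test_that("gaussian-correlation GLS matches an independent likelihood oracle at fixed ranges", {
  set.seed(63)
  D <- abs(outer(elev49, elev49, "-"))
  L <- chol(exp(-(D / 400)^2) + diag(0.25, 49))
  x <- rnorm(49)
  y <- 1 + 0.5 * x + drop(crossprod(L, rnorm(49)))
  X <- cbind(1, x)
  n <- 49
  # ranges kept small enough that the Gaussian kernel matrix stays
  # well-conditioned; beyond ~250 m at 100 m spacing the comparison is
  # numerically meaningless for any implementation
  for (rho in c(80, 150, 250)) {
    f <- fit_gls(y ~ x, data.frame(x = x, y = y), elev49,
                 correlation = "gaussian", fixed_range = rho)
    # closed-form GLS at known range, by hand-coded whitening
    C <- exp(-(D / rho)^2)
    ch <- chol(C)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    beta <- qr.solve(Xi, yi)
    s2 <- sum((yi - Xi %*% beta)^2) / n
    ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
    expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-6)
    expect_equal(f$logLik, ll, tolerance = 1e-6)
    expect_equal(f$corr_param, rho)
  }
  # the free-range fit can only improve on any fixed-range likelihood
  free <- fit_gls(y ~ x, data.frame(x = x, y = y), elev49,
                  correlation = "gaussian")
  fixed400 <- fit_gls(y ~ x, data.frame(x = x, y = y), elev49,
                      correlation = "gaussian", fixed_range = 400)
  expect_gte(free$logLik, fixed400$logLik - 1e-6)
})

test_that("structure comparison ranks by AIC and tolerates single candidates", {
  set.seed(64)
  x <- rnorm(49)
  y <- 1 + x + rnorm(49)
  tab <- compare_correlation_structures(y ~ x, data.frame(x = x, y = y), elev49)
  expect_true(!is.unsorted(tab$AIC[!is.na(tab$AIC)]))
  expect_true(tab$best[1])

  one <- compare_correlation_structures(y ~ x, data.frame(x = x, y = y),
                                        elev49, structures = "none")
  expect_equal(nrow(one), 1)
  expect_true(one$best)
})

test_that("uncorrelated data usually select 'none'; correlated data select 'gaussian' over 'none'", {
  set.seed(65)
  x <- rnorm(49)
  wins_none <- 0
  for (i in 1:20) {
    y <- 1 + x + rnorm(49)
    tab <- compare_correlation_structures(y ~ x, data.frame(x = x, y = y),
                                          elev49, structures = c("none", "gaussian"))
    wins_none <- wins_none + (tab$structure[tab$best][1] == "none")
  }
  expect_gt(wins_none, 10)

  D <- abs(outer(elev49, elev49, "-"))
  L <- chol(exp(-(D / 500)^2) + diag(1e-8, 49))
  wins_gaus <- 0
  for (i in 1:20) {
    y <- 1 + x + drop(crossprod(L, rnorm(49)))
    tab <- compare_correlation_structures(y ~ x, data.frame(x = x, y = y),
                                          elev49, structures = c("none", "gaussian"))
    wins_gaus <- wins_gaus + (tab$structure[tab$best][1] == "gaussian")
  }
  expect_gt(wins_gaus, 10)
})

test_that("likelihood-ratio term tests are non-negative, chi-square distributed guards hold", {
  set.seed(66)
  x1 <- rnorm(49); x2 <- rnorm(49)
  y <- 1 + x1 + rnorm(49)
  f <- fit_gls(y ~ x1 + x2, data.frame(x1 = x1, x2 = x2, y = y), elev49,
               correlation = "none")
  tests <- lrt_term_tests(f)
  expect_setequal(tests$term, c("x1", "x2"))
  expect_true(all(tests$statistic >= -1e-8))
  expect_true(all(tests$df == 1))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))

  expect_error(lrt_term_tests(f, "not_there"), "not in the full model")
  f_null <- fit_gls(y ~ 1, data.frame(y = y), elev49, correlation = "none")
  expect_error(lrt_term_tests(f_null), "no terms")
  f_reml <- fit_gls(y ~ x1, data.frame(x1 = x1, y = y), elev49,
                    correlation = "none", method = "REML")
  expect_error(lrt_term_tests(f_reml), "ML")
})

test_that("singular designs raise a typed GLS error", {
  set.seed(67)
  d <- data.frame(x = rnorm(49), z = 0)
  d$y <- d$x + rnorm(49)
  expect_error(fit_gls(y ~ x + z, d, elev49, correlation = "none"),
               "GLS fit failed")
})

test_that("sequential ANODEV deviances telescope and match the closed-form Poisson deviance", {
  # two groups with counts (2,2) and (8,8): saturated group fit
  y <- c(2, 2, 8, 8)
  g <- data.frame(grp = factor(c("lo", "lo", "hi", "hi")))
  av <- glm_poisson_anodev(y, "grp", g)
  ybar <- mean(y)
  dev_null <- 2 * sum(y * log(y / ybar))
  expect_equal(av$table$resid_dev[1], dev_null, tolerance = 1e-10)
  expect_equal(av$table$deviance[2], dev_null, tolerance = 1e-10)
  expect_equal(av$table$resid_dev[2], 0, tolerance = 1e-10)

  set.seed(68)
  d <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  y2 <- rpois(40, exp(1 + 0.3 * d$a - 0.2 * d$b))
  av2 <- glm_poisson_anodev(y2, c("a", "b", "c"), d)
  tab <- av2$table
  expect_equal(sum(tab$deviance[-1]), tab$resid_dev[1] - tab$resid_dev[nrow(tab)],
               tolerance = 1e-10)
  expect_equal(av2$dispersion,
               sum(residuals(av2$fit, type = "pearson")^2) / av2$fit$df.residual)
})

test_that("all-zero counts give zero deviance throughout", {
  d <- data.frame(x = rnorm(10))
  av <- glm_poisson_anodev(rep(0, 10), "x", d)
  expect_equal(av$table$resid_dev, c(0, 0), tolerance = 1e-8)
  expect_error(glm_poisson_anodev(c(-1, 2), "x", data.frame(x = 1:2)),
               "non-negative")
})

test_that("residual-elevation fit recovers an exact cubic and guards degenerate input", {
  set.seed(69)
  n <- 40
  elev <- seq(100, 4000, length.out = n)
  area <- exp(-elev / 2000) * 100
  mde <- 10 - abs(elev - 2000) / 400
  y <- rpois(n, 5)
  out <- residual_elevation_fit(y, data.frame(area = area, null_model = mde), elev)
  # the fitted-on-residuals R2 must equal an independent refit of the same
  # residuals on the cubic basis
  ref <- lm(out$residuals ~ poly(elev, 3))
  expect_equal(out$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  expect_length(out$coefficients, 4)
  expect_true(out$r_squared >= 0 && out$r_squared <= 1)
  expect_error(residual_elevation_fit(y[1:4],
                                      data.frame(area = area[1:4],
                                                 null_model = mde[1:4]),
                                      elev[1:4]), "at least 5")
  expect_error(residual_elevation_fit(y, data.frame(area = area, null_model = mde),
                                      rep(1000, n)), "constant")
})

test_that("fixed-df spline smooths reproduce lines and recover sin(x)", {
  x <- seq(0, 10, length.out = 80)
  y_lin <- 1 + 2 * x
  sm <- spline_smooth(x, y_lin, df = 3)
  expect_equal(sm$fitted, y_lin, tolerance = 1e-8)

  set.seed(70)
  y_sin <- sin(x) + rnorm(80, 0, 0.05)
  sm2 <- spline_smooth(x, y_sin, df = 6)
  expect_gt(sm2$r_squared, 0.95)
  expect_lt(sm2$test$p_value, 1e-6)

  expect_error(spline_smooth(x[1:5], y_lin[1:5], df = 5), "over-parameterized")
  expect_error(spline_smooth(x, y_lin, df = 1), "at least 2")
  expect_error(spline_smooth(rep(1, 20), rnorm(20), df = 3), "rank|knots|duplicated")
})

test_that("poisson spline smooths fit counts on the response scale", {
  set.seed(71)
  x <- seq(0, 4900, length.out = 49)
  y <- rpois(49, exp(2 - abs(x - 2500) / 1500))
  sm <- spline_smooth(x, y, df = 3, family = "poisson")
  expect_length(sm$fitted, 49)
  expect_true(all(sm$fitted > 0))
  expect_true(is.finite(sm$test$statistic))
})
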