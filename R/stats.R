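#' Variance inflation factors
#'
#' VIF of predictor k is `1 / (1 - R^2_k)` where `R^2_k` comes from
#' regressing predictor k on all the others; values above 10 indicate severe
#' multicollinearity and are flagged. Perfectly collinear predictors get
#' `Inf` and the offending set is named in the `aliased` attribute.
#'
#' @param design Data frame or matrix of predictors (>= 2 columns, more rows
#'   than columns, no constant column).
#' @param flag_threshold Severity threshold (default 10).
#' @return Named numeric vector of VIFs with attributes `flagged` (names
#'   above the threshold) and `aliased` (names with infinite VIF).
#' @export
vif <- function(design, flag_threshold = 10) {
  design <- as.data.frame(design)
  p <- ncol(design)
  if (p < 2) stop("VIF needs at least 2 predictors", call. = FALSE)
  if (nrow(design) <= p) stop("VIF needs n > number of predictors", call. = FALSE)
  sds <- vapply(design, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(names(design)[sds == 0], collapse = ", "), call. = FALSE)
  out <- vapply(seq_len(p), function(k) {
    f <- stats::lm(design[[k]] ~ ., data = design[, -k, drop = FALSE])
    r2 <- suppressWarnings(summary(f)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(design)
  attr(out, "flagged") <- names(out)[is.finite(out) & out > flag_threshold]
  attr(out, "aliased") <- names(out)[is.infinite(out)]
  out
}

.cor_struct <- function(correlation, nugget = FALSE, value = numeric(0),
                        fixed = FALSE) {
  f <- switch(correlation,
              none = return(NULL),
              gaussian = nlme::corGaus,
              exponential = nlme::corExp,
              spherical = nlme::corSpher)
  if (length(value)) f(value = value, form = ~.elev, nugget = nugget,
                       fixed = fixed)
  else f(form = ~.elev, nugget = nugget)
}

#' Generalized least squares with spatial residual correlation
#'
#' Fits `formula` by GLS (via [nlme::gls()]) with residual correlation
#' between bands decaying with the elevation distance between them:
#' `gaussian` is `exp(-(d/rho)^2)` (corGaus), `exponential` is
#' `exp(-d/rho)`, `spherical` the standard spherical function vanishing
#' beyond `rho`, and `none` reduces to ordinary least squares. ML (not REML)
#' is the default so fits with different fixed effects are comparable by
#' likelihood-ratio tests and AIC.
#'
#' @param formula Model formula; the response is used as supplied (apply any
#'   log transform upstream, after excluding zero-richness bands).
#' @param data Data frame holding the model variables, one row per band.
#' @param coords Numeric band coordinates (midband or band-label elevation,
#'   meters), same length as `nrow(data)`.
#' @param correlation One of `"none"`, `"gaussian"`, `"exponential"`,
#'   `"spherical"`.
#' @param method `"ML"` or `"REML"`.
#' @param nugget Include a nugget parameter in the correlation structure.
#' @param fixed_range Hold the spatial range at this value instead of
#'   estimating it (profile-likelihood evaluation at a known range).
#' @return An `elev_gls` object: coefficients, `sigma2`, `corr_param` (the
#'   spatial range, `NA` for `none`), `logLik`, `AIC`, `k` (free-parameter
#'   count including `sigma2` and the correlation parameter), `n_obs`,
#'   residuals, and the underlying [nlme::gls] fit.
#' @export
fit_gls <- function(formula, data, coords,
                    correlation = c("none", "gaussian", "exponential", "spherical"),
                    method = "ML", nugget = FALSE, fixed_range = NULL) {
  correlation <- match.arg(correlation)
  stopifnot(length(coords) == nrow(data))
  data <- as.data.frame(data)
  data$.elev <- coords
  if (correlation == "none" && method == "ML") {
    # plain least squares: exact, fast, and well-defined even for noiseless
    # responses where a variance-profiled fit degenerates
    fit <- stats::lm(formula, data = data)
    if (anyNA(stats::coef(fit)))
      stop("GLS fit failed (none): singular design", call. = FALSE)
    ll <- stats::logLik(fit)
    return(structure(list(coefficients = stats::coef(fit),
                          sigma2 = sum(stats::residuals(fit)^2) / nrow(data),
                          corr_param = NA_real_,
                          logLik = as.numeric(ll), AIC = stats::AIC(fit),
                          k = attr(ll, "df"), n_obs = nrow(data),
                          residuals = stats::residuals(fit),
                          fitted = stats::fitted(fit),
                          formula = formula, correlation = correlation,
                          method = method, data = data, fit = fit,
                          boundary = FALSE),
                     class = "elev_gls"))
  }
  # the profile likelihood over the spatial range can be multimodal, so
  # correlated structures are fitted from several starting ranges and the
  # best-likelihood solution kept
  span <- diff(range(coords))
  starts <- if (correlation == "none" || !is.null(fixed_range)) {
    list(if (is.null(fixed_range)) numeric(0) else fixed_range)
  } else {
    c(list(numeric(0)),
      lapply(span * c(0.02, 0.05, 0.1, 0.25, 0.5),
             function(v) if (nugget) c(v, 0.1) else v))
  }
  fixed <- !is.null(fixed_range)
  fits <- lapply(starts, function(v) tryCatch(
    suppressWarnings(
      nlme::gls(formula, data = data,
                correlation = .cor_struct(correlation, nugget, v, fixed),
                method = method,
                control = nlme::glsControl(opt = "optim"))),
    error = function(e) conditionMessage(e)))
  ok <- !vapply(fits, is.character, logical(1))
  if (!any(ok))
    stop("GLS fit failed (", correlation, "): ",
         fits[[1]], call. = FALSE)
  lls <- vapply(fits, function(f) if (is.character(f)) -Inf
                else as.numeric(stats::logLik(f)), numeric(1))
  fit <- fits[[which.max(lls)]]
  cs <- fit$modelStruct$corStruct
  ll <- stats::logLik(fit)
  cp <- if (is.null(cs)) NA_real_ else if (fixed) fixed_range[1] else {
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)[["range"]])
  }
  structure(list(coefficients = stats::coef(fit),
                 sigma2 = fit$sigma^2,
                 corr_param = cp,
                 logLik = as.numeric(ll),
                 AIC = stats::AIC(fit),
                 k = attr(ll, "df"),
                 n_obs = fit$dims$N,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 formula = formula, correlation = correlation,
                 method = method, data = data, fit = fit,
                 # a range far beyond the coordinate span means the profile
                 # likelihood was flat and the optimizer ran to a boundary
                 boundary = isTRUE(!is.na(cp) && cp > 2 * span)),
            class = "elev_gls")
}

#' @export
print.elev_gls <- function(x, ...) {
  cat(sprintf("<elev_gls> %s correlation, %s; n = %d, logLik = %.3f, AIC = %.3f\n",
              x$correlation, x$method, x$n_obs, x$logLik, x$AIC))
  if (!is.na(x$corr_param)) cat(sprintf("  spatial range: %.1f m\n", x$corr_param))
  print(x$coefficients)
  invisible(x)
}

#' Rank spatial correlation structures by AIC
#'
#' Fits the same model under each candidate residual correlation structure
#' and ranks the fits by AIC (ascending); the lowest-AIC structure is the
#' selected one. A structure whose fit fails is recorded with `NA` and the
#' error message; the others are still ranked.
#'
#' @inheritParams fit_gls
#' @param structures Candidate structures to compare.
#' @return Data frame (one row per structure, AIC-ascending, failed fits
#'   last) with columns `structure`, `k`, `logLik`, `AIC`, `delta_AIC`,
#'   `best`, `error`; the fitted objects are in the `fits` attribute.
#' @export
compare_correlation_structures <- function(formula, data, coords,
                                           structures = c("none", "gaussian",
                                                          "exponential", "spherical"),
                                           method = "ML") {
  fits <- lapply(structures, function(s)
    tryCatch(fit_gls(formula, data, coords, correlation = s, method = method),
             error = function(e) conditionMessage(e)))
  names(fits) <- structures
  ok <- !vapply(fits, is.character, logical(1))
  tab <- data.frame(
    structure = structures,
    k = ifelse(ok, vapply(fits, function(f) if (is.character(f)) NA_real_ else f$k, numeric(1)), NA),
    logLik = vapply(fits, function(f) if (is.character(f)) NA_real_ else f$logLik, numeric(1)),
    AIC = vapply(fits, function(f) if (is.character(f)) NA_real_ else f$AIC, numeric(1)),
    error = vapply(fits, function(f) if (is.character(f)) f else NA_character_, character(1)))
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$best <- seq_len(nrow(tab)) == 1 & !is.na(tab$AIC)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Likelihood-ratio tests of model terms
#'
#' For each term, refits the model without it and reports the likelihood
#' ratio `2 (logLik_full - logLik_reduced)` against the chi-square
#' distribution with df equal to the parameter-count difference, alongside
#' the reduced model's AIC. Both fits use ML on the same observations, so
#' the reduced model is nested in the full one by construction.
#'
#' @param full An `elev_gls` fit produced with `method = "ML"`.
#' @param drop_terms Terms to test; default all terms of the full model.
#' @return Data frame with columns `term`, `df`, `statistic`, `p_value`,
#'   `AIC_reduced`, `delta_AIC`.
#' @export
lrt_term_tests <- function(full, drop_terms = NULL) {
  stopifnot(inherits(full, "elev_gls"))
  if (full$method != "ML")
    stop("likelihood-ratio tests require ML fits", call. = FALSE)
  labels <- attr(stats::terms(full$formula), "term.labels")
  if (is.null(drop_terms)) drop_terms <- labels
  bad <- setdiff(drop_terms, labels)
  if (length(bad))
    stop("term(s) not in the full model (not a nested comparison): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(drop_terms) == 0)
    stop("no terms to drop: full model compared with itself", call. = FALSE)
  rows <- lapply(drop_terms, function(tm) {
    red_formula <- stats::update(full$formula, paste(". ~ . -", tm))
    red <- fit_gls(red_formula, full$data, full$data$.elev,
                   correlation = full$correlation, method = "ML")
    df <- full$k - red$k
    if (df < 1) stop("dropping '", tm, "' removed no parameters", call. = FALSE)
    stat <- 2 * (full$logLik - red$logLik)
    data.frame(term = tm, df = df, statistic = stat,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE),
               AIC_reduced = red$AIC, delta_AIC = red$AIC - full$AIC)
  })
  do.call(rbind, rows)
}

#' Sequential analysis of deviance for overdispersed Poisson counts
#'
#' Fits a Poisson-family GLM with the terms added in the stated order and
#' tests each term's deviance drop with an F test whose denominator uses the
#' Pearson-based dispersion estimate `phi = Pearson chi-square / residual
#' df` (quasi-likelihood control of overdispersion). Term order matters: put
#' area, the null-model expectation and elevation first when the aim is to
#' control for geometry before the biological predictors.
#'
#' @param y Non-negative count response.
#' @param ordered_terms Character vector of term labels, in testing order
#'   (interactions as `"a:b"`).
#' @param design Data frame holding the predictor columns.
#' @return List with `table` (term, df, deviance, resid_df, resid_dev, F,
#'   p_value), `dispersion`, and the fitted `glm` object.
#' @export
glm_poisson_anodev <- function(y, ordered_terms, design) {
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  design <- as.data.frame(design)
  design$.y <- y
  f <- stats::reformulate(ordered_terms, response = ".y")
  fit <- stats::glm(f, data = design, family = stats::quasipoisson())
  if (!fit$converged)
    stop("IRLS did not converge after ", fit$iter, " iterations", call. = FALSE)
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  a <- stats::anova(fit, test = "F")
  tab <- data.frame(term = rownames(a),
                    df = a$Df, deviance = a$Deviance,
                    resid_df = a$`Resid. Df`, resid_dev = a$`Resid. Dev`,
                    F = a$F, p_value = a$`Pr(>F)`)
  rownames(tab) <- NULL
  list(table = tab, dispersion = phi, fit = fit)
}

#' Cubic polynomial fit of partial residuals against elevation
#'
#' Removes the effect of area and the mid-domain (null-model) expectation
#' from the counts with an overdispersed Poisson GLM, then fits the deviance
#' residuals on an orthogonalized degree-3 polynomial of elevation by least
#' squares.
#'
#' @param y Count response per band.
#' @param design_area_mde Data frame with the columns to partial out
#'   (typically area and the null-model expectation).
#' @param elevations Band elevations, meters.
#' @return List with `coefficients` (orthogonal-polynomial scale),
#'   `r_squared`, `p_value` (overall F), `residuals`, and the `lm` fit.
#' @export
residual_elevation_fit <- function(y, design_area_mde, elevations) {
  n <- length(y)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(elevations) == 0)
    stop("elevation vector is constant: degenerate polynomial basis", call. = FALSE)
  av <- glm_poisson_anodev(y, names(design_area_mde), design_area_mde)
  res <- stats::residuals(av$fit, type = "deviance")
  f <- stats::lm(res ~ stats::poly(elevations, 3))
  sm <- summary(f)
  pv <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE)
  list(coefficients = stats::coef(f), r_squared = sm$r.squared,
       p_value = unname(pv), residuals = res, fit = f)
}

#' Fixed-df cubic regression spline smooth
#'
#' Natural cubic spline basis with `df` basis functions at quantile knots,
#' fitted by least squares (gaussian) or IRLS (poisson), for graphical
#' visualization of predictor-response shapes without penalized smoothing.
#' The smooth term is tested against the intercept-only model by an F test
#' (gaussian) or a dispersion-scaled chi-square (poisson).
#'
#' @param x,y Predictor and response vectors.
#' @param df Spline degrees of freedom (>= 2; `n` must exceed `df + 1`).
#' @param family `"gaussian"` or `"poisson"` (Poisson fits use
#'   quasi-likelihood dispersion in the test).
#' @return List with `x`, `fitted`, `se`, `r_squared`, `test` (statistic,
#'   df, p_value), and the underlying fit.
#' @export
spline_smooth <- function(x, y, df = 3, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  if (df < 2) stop("df must be at least 2", call. = FALSE)
  if (length(x) <= df + 1) stop("over-parameterized: need n > df + 1", call. = FALSE)
  basis <- splines::ns(x, df = df)
  X <- cbind(1, basis)
  if (qr(X)$rank < ncol(X))
    stop("duplicated x values reduce the spline basis below full rank",
         call. = FALSE)
  if (family == "gaussian") {
    fit <- stats::lm(y ~ basis)
    null_fit <- stats::lm(y ~ 1)
    a <- stats::anova(null_fit, fit)
    test <- list(statistic = a$F[2], df = c(a$Df[2], fit$df.residual),
                 p_value = a$`Pr(>F)`[2])
    pr <- stats::predict(fit, se.fit = TRUE)
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    fit <- stats::glm(y ~ basis, family = stats::quasipoisson())
    null_fit <- stats::glm(y ~ 1, family = stats::quasipoisson())
    a <- stats::anova(null_fit, fit, test = "F")
    test <- list(statistic = a$F[2], df = c(a$Df[2], fit$df.residual),
                 p_value = a$`Pr(>F)`[2])
    pr <- stats::predict(fit, se.fit = TRUE, type = "response")
    r2 <- 1 - fit$deviance / fit$null.deviance
  }
  list(x = x, fitted = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
       r_squared = r2, test = test, fit = fit)
}
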