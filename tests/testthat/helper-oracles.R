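# Independent oracles, written against the stated rules rather than the
# package internals, so the checks do not share code with the path they test.

# Expected per-band richness of the mid-domain null by exhaustive fine-grid
# enumeration of feasible midpoints (literal re-statement of the binning
# rule: lower floors, upper ceils, half-open bands labelled by upper edge).
oracle_mde_expected <- function(sizes, domain_max = 4900, bw = 100, M = 4001) {
  labs <- seq(bw, domain_max, bw)
  ex <- numeric(length(labs))
  for (R in sizes) {
    lo_f <- R / 2
    hi_f <- domain_max - R / 2
    m <- if (hi_f > lo_f) seq(lo_f, hi_f, length.out = M) else (lo_f + hi_f) / 2
    lb <- floor((m - R / 2) / bw) * bw
    ub <- ceiling((m + R / 2) / bw) * bw
    deg <- ub == lb
    ub[deg] <- pmin(lb[deg] + bw, domain_max)
    lb[deg] <- ub[deg] - bw
    for (k in seq_along(labs))
      ex[k] <- ex[k] + mean(labs[k] > lb & labs[k] <= ub)
  }
  ex
}

# Textbook Pearson correlation from the sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Least squares by hand-coded normal equations.
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Profile-ML gaussian-correlation GLS on a one-dimensional coordinate:
# independent of nlme, used to cross-check fit_gls. For a candidate range
# rho, beta and sigma2 have closed forms; rho is profiled by optimize().
oracle_gls_gaussian <- function(y, X, coords, interval = c(10, 20000)) {
  n <- length(y)
  D <- abs(outer(coords, coords, "-"))
  prof <- function(rho) {
    C <- exp(-(D / rho)^2) + diag(1e-10, n)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    b <- qr.solve(Xi, yi)
    r <- yi - Xi %*% b
    s2 <- sum(r^2) / n
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
  }
  # the profile can be multimodal: coarse log-spaced scan, then local refine
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 80))
  vals <- vapply(grid, prof, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-6)
  rho <- opt$maximum
  C <- exp(-(D / rho)^2) + diag(1e-10, n)
  ch <- chol(C)
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  b <- qr.solve(Xi, yi)
  list(rho = rho, beta = drop(b), logLik = opt$objective)
}

# Small deterministic species table used across io/gridding tests.
toy_species <- function() {
  data.frame(species_id = c("sp1", "sp2", "sp3"),
             taxon_class = c("Aves", "Mammalia", "Reptilia"),
             iucn_status = c("EN", "VU", "CR"),
             lower_m = c(660L, 900L, 0L),
             upper_m = c(1000L, 1200L, 4900L),
             stringsAsFactors = FALSE)
}
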