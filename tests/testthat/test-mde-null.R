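test_that("a full-domain range yields richness exactly 1 in every band with zero variance", {
  null <- simulate_mde_null(4900, n_sims = 20, seed = 5, keep_sims = TRUE)
  expect_true(all(null$sims == 1L))
  expect_equal(unname(null$null_mean), rep(1, 49))
  expect_equal(null$null_lo, null$null_hi)
})

test_that("range sizes beyond the domain are rejected", {
  expect_error(simulate_mde_null(5000), "exceeds")
  expect_error(simulate_mde_null(-10), "negative")
})

test_that("identical seeds reproduce the null exactly; different seeds agree within Monte Carlo error", {
  sizes <- c(300, 800, 1500, 2600, 4000)
  a <- simulate_mde_null(sizes, n_sims = 400, seed = 9, keep_sims = TRUE)
  b <- simulate_mde_null(sizes, n_sims = 400, seed = 9, keep_sims = TRUE)
  expect_identical(a$sims, b$sims)
  c2 <- simulate_mde_null(sizes, n_sims = 400, seed = 10, keep_sims = TRUE)
  se_pool <- sqrt(apply(a$sims, 2, stats::var) / 400 +
                  apply(c2$sims, 2, stats::var) / 400)
  diff_ok <- abs(a$null_mean - c2$null_mean) < 4 * pmax(se_pool, 1e-9)
  expect_true(all(diff_ok | se_pool == 0))
})

test_that("simulation totals respect the occupancy accounting of binned ranges", {
  sizes <- c(50, 250, 999, 2400)
  null <- simulate_mde_null(sizes, n_sims = 200, seed = 2, keep_sims = TRUE)
  totals <- rowSums(null$sims)
  # floor/ceil binning spans ceil(R/bw) or ceil(R/bw)+1 bands, at least one
  lo <- sum(pmax(1, ceiling(sizes / 100)))
  hi <- sum(ceiling(sizes / 100) + 1)
  expect_true(all(totals >= lo & totals <= hi))
  expect_true(all(null$null_lo <= null$null_mean + 1e-12) &&
              all(null$null_mean <= null$null_hi + 1e-12))
})

test_that("simulated means agree with the midpoint-enumeration oracle", {
  set.seed(31)
  sizes <- round(runif(20, 100, 4500))
  null <- simulate_mde_null(sizes, n_sims = 2000, seed = 8, keep_sims = TRUE)
  expected <- oracle_mde_expected(sizes)
  se <- apply(null$sims, 2, stats::sd) / sqrt(2000)
  z <- (null$null_mean - expected) / pmax(se, 1e-9)
  expect_lt(max(abs(z)), 3.5)
})

test_that("the closed-form null expectation is symmetric about the domain center", {
  sizes <- c(400, 1200, 2600, 3900)
  expected <- oracle_mde_expected(sizes)
  expect_equal(expected, rev(expected), tolerance = 1e-10)
})

test_that("pools of large ranges produce a centrally peaked expectation", {
  sizes <- runif(30, 2500, 4800)   # all above half the domain
  expected <- oracle_mde_expected(sizes)
  peak <- which.max(expected)
  expect_true(peak %in% 23:27)
  # unimodal: non-decreasing to the peak, non-increasing after
  expect_true(all(diff(expected[1:peak]) >= -1e-9))
  expect_true(all(diff(expected[peak:49]) <= 1e-9))
})

test_that("with-replacement mode matches without-replacement for degenerate pools", {
  one <- simulate_mde_null(1200, n_sims = 300, seed = 4, keep_sims = TRUE)
  one_r <- simulate_mde_null(1200, n_sims = 300, seed = 4, replace = TRUE,
                             keep_sims = TRUE)
  expect_identical(one$sims, one_r$sims)

  pool <- rep(900, 5)
  a <- simulate_mde_null(pool, n_sims = 500, seed = 6, keep_sims = TRUE)
  b <- simulate_mde_null(pool, n_sims = 500, seed = 6, replace = TRUE,
                         keep_sims = TRUE)
  expect_equal(mean(rowSums(a$sims)), mean(rowSums(b$sims)), tolerance = 0.05)
})

test_that("mixed pools have equal expected total occupancy in both modes", {
  pool <- c(200, 700, 1800, 3300, 4500)
  a <- simulate_mde_null(pool, n_sims = 3000, seed = 12, keep_sims = TRUE)
  b <- simulate_mde_null(pool, n_sims = 3000, seed = 13, replace = TRUE,
                         keep_sims = TRUE)
  ta <- mean(rowSums(a$sims)); tb <- mean(rowSums(b$sims))
  expect_lt(abs(ta - tb) / ta, 0.02)
})

test_that("null-empirical comparison recovers exact relationships", {
  null <- simulate_mde_null(c(500, 1500), n_sims = 50, seed = 3)
  elev <- null$band_label
  v <- as.numeric(seq_along(elev))
  cmp <- compare_null_to_empirical(null, v, v, v)
  expect_equal(cmp$spearman_rho, 1)

  parab <- 2 * (elev / 1000)^2
  cmp2 <- compare_null_to_empirical(null, v, parab, parab)
  fit <- cmp2$poly2_fits$empirical
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["quadratic"]), 2e-6, tolerance = 1e-10)

  expect_error(compare_null_to_empirical(null, v, c(1, 2, rep(NA, 47)),
                                         c(1, 2, rep(NA, 47))),
               "fewer than 3")
})

test_that("degree-2 fits match the hand-coded normal equations", {
  null <- simulate_mde_null(c(500, 1500), n_sims = 20, seed = 3)
  elev <- null$band_label
  set.seed(44)
  y <- 3 + 0.002 * elev - 1e-7 * elev^2 + rnorm(49, 0, 0.2)
  cmp <- compare_null_to_empirical(null, y, y, y)
  X <- cbind(1, elev, elev^2)
  beta <- oracle_ols(X, y)
  expect_equal(unname(cmp$poly2_fits$empirical$coefficients),
               as.numeric(beta), tolerance = 1e-8)
})

test_that("mean simulated range size per band is reproducible and plausible", {
  sizes <- c(300, 900, 2200, 4000)
  null <- simulate_mde_null(sizes, n_sims = 300, seed = 15)
  mrs1 <- null_mean_range_size(null, sizes)
  mrs2 <- null_mean_range_size(null, sizes)
  expect_identical(mrs1, mrs2)
  expect_true(all(mrs1 >= min(sizes) - 1e-9 & mrs1 <= max(sizes) + 1e-9,
                  na.rm = TRUE))
  # central bands admit large ranges; edges only small ones
  expect_gt(mean(mrs1[20:30], na.rm = TRUE), mean(mrs1[c(1:3, 47:49)], na.rm = TRUE))
})
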