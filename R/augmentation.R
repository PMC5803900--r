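#' Range-augmentation scenarios
#'
#' The undersampling sensitivity procedure widens each species' elevational
#' range by a percentage of the gradient that decreases with range size,
#' reflecting a decreasing probability of sampling error for wider-ranged
#' species. A scenario is the percentage triplet applied to the three
#' range-size categories (a: smallest, c: largest); the three built-in
#' scenarios are (20, 10, 0)\%, (30, 20, 10)\% and (50, 25, 10)\%.
#'
#' @param pct_a,pct_b,pct_c Fractions of the gradient added to categories a,
#'   b, c; must be non-increasing and non-negative.
#' @param name Scenario label.
#' @return An `augmentation_scenario` object.
#' @export
augmentation_scenario <- function(pct_a, pct_b, pct_c, name = "custom") {
  stopifnot(pct_a >= pct_b, pct_b >= pct_c, pct_c >= 0)
  structure(list(pct_a = pct_a, pct_b = pct_b, pct_c = pct_c, name = name),
            class = "augmentation_scenario")
}

#' @rdname augmentation_scenario
#' @export
default_scenarios <- function() {
  list(S1 = augmentation_scenario(0.20, 0.10, 0.00, "S1"),
       S2 = augmentation_scenario(0.30, 0.20, 0.10, "S2"),
       S3 = augmentation_scenario(0.50, 0.25, 0.10, "S3"))
}

#' Range-size category rule
#'
#' Category a: range size below `threshold_ab` (1300 m, 26\% of the 5000 m
#' gradient); b: between the thresholds inclusive; c: strictly above
#' `threshold_bc` (2550 m, 51\%).
#'
#' @param threshold_ab,threshold_bc Category boundaries in meters.
#' @return A `category_rule` object.
#' @export
category_rule <- function(threshold_ab = 1300, threshold_bc = 2550) {
  stopifnot(0 < threshold_ab, threshold_ab < threshold_bc)
  structure(list(threshold_ab = threshold_ab, threshold_bc = threshold_bc),
            class = "category_rule")
}

#' Categorize ranges by size
#'
#' @param range_size Range size(s) in meters, non-negative.
#' @param rule A [category_rule()].
#' @return Character vector of `"a"`, `"b"`, `"c"`.
#' @export
categorize_range <- function(range_size, rule = category_rule()) {
  if (any(range_size < 0)) stop("range size must be non-negative", call. = FALSE)
  ifelse(range_size < rule$threshold_ab, "a",
         ifelse(range_size <= rule$threshold_bc, "b", "c"))
}

#' Extension in meters for a category under a scenario
#'
#' Percentages are converted against the grid's
#' `gradient_length_for_pct` (5000 m by default), so category a under the
#' first scenario is widened by 20\% of the gradient = 1000 m in total.
#'
#' @param category `"a"`, `"b"` or `"c"` (vectorized).
#' @param scenario An [augmentation_scenario()].
#' @param grid An [elevation_grid()].
#' @return Total extension in meters.
#' @export
augmentation_extent <- function(category, scenario, grid = elevation_grid()) {
  pct <- c(a = scenario$pct_a, b = scenario$pct_b, c = scenario$pct_c)[category]
  unname(pct * grid$gradient_length_for_pct)
}

#' Augment species ranges under a scenario
#'
#' The total extension is split equally between the two limits, then each
#' limit is clamped to the grid's clamp bounds (67 and 4900 m by default);
#' excess removed by clamping is discarded, not shifted to the other side. A
#' species spanning 200--1400 m (range size 1200 m, category a) under the
#' first scenario gains 500 m on each side and is clamped below, yielding
#' limits 67 and 1900 m. The empirical range is always contained in the
#' augmented one; in particular a limit already outside the clamp bounds is
#' never moved inward.
#'
#' @param species Validated species data frame with `lower_m` / `upper_m`.
#' @param scenario An [augmentation_scenario()].
#' @param rule A [category_rule()].
#' @param grid An [elevation_grid()].
#' @return The species table with `lower_m` / `upper_m` replaced by the
#'   augmented limits and columns `category` and `extension_m` appended.
#' @export
augment_range <- function(species, scenario, rule = category_rule(),
                          grid = elevation_grid()) {
  size <- species$upper_m - species$lower_m
  cat_ <- categorize_range(size, rule)
  ext <- augmentation_extent(cat_, scenario, grid)
  lower <- pmin(species$lower_m, pmax(grid$clamp_min, species$lower_m - ext / 2))
  upper <- pmax(species$upper_m, pmin(grid$clamp_max, species$upper_m + ext / 2))
  out <- species
  out$lower_m <- lower
  out$upper_m <- upper
  out$category <- cat_
  out$extension_m <- ext
  out
}

#' Richness pattern under an augmentation scenario
#'
#' Augments every species, re-bins the widened ranges, and recomputes
#' interpolated per-band richness.
#'
#' @inheritParams augment_range
#' @return Named integer vector of per-band richness.
#' @export
scenario_richness <- function(species, scenario, rule = category_rule(),
                              grid = elevation_grid()) {
  if (nrow(species) == 0)
    return(stats::setNames(integer(n_bands(grid)), band_labels(grid)))
  aug <- augment_range(species, scenario, rule, grid)
  band_richness(presence_matrix(bin_range(aug$lower_m, aug$upper_m, grid), grid))
}

#' Pairwise correlations among richness patterns
#'
#' Pearson correlations, with two-sided t-test p-values, between the
#' empirical richness pattern and each augmented pattern (and among the
#' augmented patterns), Bonferroni-adjusted for the number of pairwise
#' comparisons: `p_adj = min(1, m * p)`.
#'
#' @param empirical Named richness vector.
#' @param augmented Named list of richness vectors of the same length.
#' @return Data frame with one row per pair: `pattern_1`, `pattern_2`, `r`,
#'   `p`, `p_bonferroni`, and logical `undefined` flagging zero-variance
#'   inputs.
#' @export
richness_pattern_correlations <- function(empirical, augmented) {
  vecs <- c(list(empirical = empirical), augmented)
  stopifnot(length(unique(lengths(vecs))) == 1, length(empirical) >= 3)
  nm <- names(vecs)
  pairs <- utils::combn(seq_along(vecs), 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(i) {
    x <- vecs[[pairs[1, i]]]; y <- vecs[[pairs[2, i]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(pattern_1 = nm[pairs[1, i]], pattern_2 = nm[pairs[2, i]],
                        r = NA_real_, p = NA_real_, undefined = TRUE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(pattern_1 = nm[pairs[1, i]], pattern_2 = nm[pairs[2, i]],
               r = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * m)
  out[, c("pattern_1", "pattern_2", "r", "p", "p_bonferroni", "undefined")]
}
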