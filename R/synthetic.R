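#' Parameters for the synthetic community generator
#'
#' The generator emulates the statistical structure of a threatened-species
#' dataset on a mountain gradient: a candidate pool spread over five
#' vertebrate classes in the observed 28/32/4/3/4 mix, right-skewed
#' (truncated lognormal) elevational range sizes, midpoints biased toward
#' low elevations, and a threat-assignment mechanism in which small range
#' size and high local human density raise the probability of being
#' threatened. With the defaults the pool of 150 candidates yields on
#' average about 71 threatened species, the size of the analysed dataset the
#' generator stands in for.
#'
#' @param n_species Candidate pool size (the analysis input is the
#'   threatened subset).
#' @param class_mix Named proportions over taxon classes (summing to 1).
#' @param range_size_log_mean,range_size_log_sd Lognormal parameters of the
#'   range-size distribution, meters, truncated to the domain length.
#' @param midpoint_bias Low-elevation bias strength; 0 = uniform feasible
#'   midpoints, larger values concentrate midpoints toward the valley floor.
#' @param threat_intercept Logistic intercept on the threat scale.
#' @param threat_beta_range Coefficient on standardized log range size
#'   (negative: small ranges are more threatened).
#' @param threat_beta_density Coefficient on standardized log mean human
#'   density over the species' occupied bands (positive).
#' @param threat_beta_interaction Coefficient on their product.
#' @param seed Integer seed; every stochastic choice is reconstructable from
#'   the stored seeds.
#' @return A `community_params` list.
#' @export
community_params <- function(n_species = 150,
                             class_mix = c(Mammalia = 28, Aves = 32,
                                           Reptilia = 4, Amphibia = 3,
                                           Actinopterygii = 4) / 71,
                             range_size_log_mean = 6.9,
                             range_size_log_sd = 0.8,
                             midpoint_bias = 1.5,
                             threat_intercept = 0,
                             threat_beta_range = -1.2,
                             threat_beta_density = 1.2,
                             threat_beta_interaction = -0.6,
                             seed = 1L) {
  stopifnot(n_species >= 1, abs(sum(class_mix) - 1) < 1e-8,
            range_size_log_sd > 0)
  structure(as.list(environment()), class = "community_params")
}

#' Parameters for synthetic band covariates
#'
#' Land area and human population density both decline (roughly
#' exponentially, with lognormal noise) with elevation, emulating a
#' mountainous study region whose low-elevation bands are broad and densely
#' settled.
#'
#' @param area_scale Band area at the valley floor, km^2.
#' @param area_decay Exponential decay rate of area with elevation, per m.
#' @param density_scale Human density at the valley floor, individuals/km^2.
#' @param density_decay Decay rate of density with elevation, per m.
#' @param noise_sd Lognormal noise sd applied to both profiles.
#' @param seed Integer seed.
#' @return A `covariate_params` list.
#' @export
covariate_params <- function(area_scale = 6000, area_decay = 4e-4,
                             density_scale = 1000, density_decay = 9e-4,
                             noise_sd = 0.25, seed = 1L) {
  stopifnot(area_scale > 0, density_scale > 0, area_decay >= 0,
            density_decay >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "covariate_params")
}

#' Generate synthetic band covariates
#'
#' @param params A [covariate_params()] list.
#' @param grid An [elevation_grid()].
#' @return Band covariate data frame: `band_label`, `area`,
#'   `population_density` (strictly positive, monotone decreasing in
#'   expectation).
#' @export
generate_band_covariates <- function(params = covariate_params(),
                                     grid = elevation_grid()) {
  labs <- band_labels(grid)
  local_rng(params$seed, {
    area <- params$area_scale * exp(-params$area_decay * labs) *
      stats::rlnorm(length(labs), 0, params$noise_sd)
    dens <- params$density_scale * exp(-params$density_decay * labs) *
      stats::rlnorm(length(labs), 0, params$noise_sd)
  })
  data.frame(band_label = labs, area = area, population_density = dens)
}

#' Generate a synthetic threatened-species community
#'
#' Draws candidate species (range size from a truncated lognormal, midpoint
#' uniform on its feasible interval then tilted toward low elevations by
#' inverse-CDF re-weighting with strength `midpoint_bias`), computes each
#' species' mean human density over its occupied bands, and marks species
#' threatened by a logistic model in standardized log range size, log mean
#' density, and their product. The threatened subset is the analysis input;
#' the full pool, the threat probabilities and every parameter are returned
#' as ground truth for recovery tests.
#'
#' @param params A [community_params()] list.
#' @param grid An [elevation_grid()].
#' @param covariates Band covariate table (from
#'   [generate_band_covariates()]); if `NULL`, generated with default
#'   covariate parameters and a seed derived from `params$seed`.
#' @return List with `species` (the threatened subset, species-table
#'   schema) and `truth` (full pool with threat probabilities, the
#'   parameters, and the covariates used).
#' @export
generate_community <- function(params = community_params(),
                               grid = elevation_grid(), covariates = NULL) {
  dlen <- grid$domain_max - grid$domain_min
  if (stats::plnorm(dlen, params$range_size_log_mean, params$range_size_log_sd) < 0.01)
    stop("infeasible truncation: range-size distribution lies almost entirely ",
         "above the domain length", call. = FALSE)
  if (is.null(covariates))
    covariates <- generate_band_covariates(
      covariate_params(seed = params$seed + 1000L), grid)
  n <- params$n_species
  local_rng(params$seed, {
    taxon <- sample(names(params$class_mix), n, replace = TRUE,
                    prob = params$class_mix)
    # truncated lognormal by inverse CDF on the truncated quantile range
    pmax_ <- stats::plnorm(dlen, params$range_size_log_mean, params$range_size_log_sd)
    R <- stats::qlnorm(stats::runif(n) * pmax_,
                       params$range_size_log_mean, params$range_size_log_sd)
    u <- stats::runif(n)
    lam <- params$midpoint_bias
    v <- if (lam > 0) -log(1 - u * (1 - exp(-lam))) / lam else u
    lo_f <- grid$domain_min + R / 2
    hi_f <- grid$domain_max - R / 2
    m <- lo_f + v * (hi_f - lo_f)
    lower <- pmax(grid$domain_min, round(m - R / 2))
    upper <- pmin(grid$domain_max, round(m + R / 2))
    upper <- pmax(upper, lower)
    binned <- bin_range(lower, upper, grid)
    pm <- presence_matrix(binned, grid)
    dens_by_band <- covariates$population_density
    mean_dens <- as.numeric(crossprod(pm, dens_by_band) / colSums(pm))
    std <- function(x) if (length(x) > 1 && stats::sd(x) > 0) {
      as.numeric(scale(x))
    } else rep(0, length(x))
    sr <- std(log(binned$range_size))
    sd_ <- std(log(mean_dens))
    z <- params$threat_intercept + params$threat_beta_range * sr +
      params$threat_beta_density * sd_ +
      params$threat_beta_interaction * sr * sd_
    p_threat <- stats::plogis(z)
    threatened <- stats::rbinom(n, 1, p_threat) == 1
    status <- rep(NA_character_, n)
    status[threatened] <- sample(c("CR", "EN", "VU"), sum(threatened),
                                 replace = TRUE, prob = c(0.15, 0.35, 0.5))
  })
  pool <- data.frame(species_id = sprintf("sp%03d", seq_len(n)),
                     taxon_class = taxon, iucn_status = status,
                     lower_m = as.integer(lower), upper_m = as.integer(upper),
                     range_size_m = binned$range_size,
                     midpoint_m = binned$midpoint,
                     mean_density = mean_dens,
                     p_threat = p_threat, threatened = threatened)
  species <- pool[pool$threatened,
                  c("species_id", "taxon_class", "iucn_status",
                    "lower_m", "upper_m")]
  rownames(species) <- NULL
  list(species = species,
       truth = list(pool = pool, params = unclass(params),
                    covariates = covariates))
}

#' Write a self-contained synthetic fixture
#'
#' Writes `species.csv`, `covariates.csv` and `ground_truth.json` (all
#' parameters and seeds, so every stochastic choice is reconstructable) to a
#' directory, ready to be consumed by [run_report()].
#'
#' @param dir Output directory (created if needed).
#' @param community [community_params()].
#' @param covariate [covariate_params()].
#' @param grid An [elevation_grid()].
#' @return Named list of the three file paths, invisibly.
#' @export
end_to_end_fixture <- function(dir, community = community_params(),
                               covariate = covariate_params(),
                               grid = elevation_grid()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- generate_band_covariates(covariate, grid)
  com <- generate_community(community, grid, covariates = cov)
  paths <- list(species = file.path(dir, "species.csv"),
                covariates = file.path(dir, "covariates.csv"),
                ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(com$species, paths$species, row.names = FALSE, quote = FALSE)
  utils::write.csv(cov, paths$covariates, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(community_params = unclass(community),
         covariate_params = unclass(covariate),
         grid = unclass(grid),
         n_threatened = nrow(com$species),
         pool = com$truth$pool),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
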