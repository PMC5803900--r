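#' Bin species ranges onto the elevation grid
#'
#' Lower limits are floored to the band edge below, upper limits are ceiled
#' to the band edge above, so a species recorded between 660 and 1000 m spans
#' the 600 and 1000 m bins: range size 400 m, midpoint 800 m (the average of
#' the binned limits). A degenerate range whose limits coincide on a band
#' edge still occupies one band, so every species remains countable.
#'
#' @param lower,upper Empirical elevational limits in meters (vectors of
#'   equal length are accepted).
#' @param grid An [elevation_grid()].
#' @return Data frame with columns `lower_bin`, `upper_bin`, `range_size`,
#'   `midpoint`.
#' @examples
#' bin_range(660, 1000)   # 600, 1000, 400, 800
#' @export
bin_range <- function(lower, upper, grid = elevation_grid()) {
  stopifnot(length(lower) == length(upper), all(lower <= upper),
            all(lower >= grid$domain_min), all(upper <= grid$domain_max))
  bw <- grid$band_width
  lo <- floor((lower - grid$domain_min) / bw) * bw + grid$domain_min
  up <- ceiling((upper - grid$domain_min) / bw) * bw + grid$domain_min
  deg <- up == lo
  # degenerate on-edge range: occupy the single band above, or below at the
  # domain top
  up[deg] <- pmin(lo[deg] + bw, grid$domain_max)
  lo[deg] <- up[deg] - bw
  data.frame(lower_bin = lo, upper_bin = up,
             range_size = up - lo, midpoint = (lo + up) / 2)
}

#' Bin a whole species table
#'
#' @param species Validated species data frame (see [read_species_table()]).
#' @inheritParams bin_range
#' @return The species table with binned-limit columns appended.
#' @export
bin_species <- function(species, grid = elevation_grid()) {
  b <- bin_range(species$lower_m, species$upper_m, grid)
  cbind(species, b)
}

#' Presence matrix of binned ranges over bands
#'
#' A species is assumed present in every 100 m interval between its binned
#' limits: band `b` is occupied iff `lower_bin < b <= upper_bin`. Each
#' species column is therefore one contiguous run of `TRUE`.
#'
#' @param binned Data frame with `lower_bin` and `upper_bin` columns (and
#'   optionally `species_id` for column names).
#' @inheritParams bin_range
#' @return Logical matrix, bands (rows, named by band label) x species.
#' @export
presence_matrix <- function(binned, grid = elevation_grid()) {
  labs <- band_labels(grid)
  if (nrow(binned) == 0) {
    m <- matrix(FALSE, nrow = length(labs), ncol = 0)
    rownames(m) <- labs
    return(m)
  }
  m <- outer(labs, binned$lower_bin, ">") & outer(labs, binned$upper_bin, "<=")
  rownames(m) <- labs
  colnames(m) <- if (!is.null(binned$species_id)) binned$species_id
  m
}

#' Interpolated richness per band
#'
#' @param pm Presence matrix from [presence_matrix()].
#' @return Named integer vector of per-band species counts.
#' @export
band_richness <- function(pm) {
  r <- as.integer(rowSums(pm))
  names(r) <- rownames(pm)
  r
}

#' Mean range size per band
#'
#' Two assignment conventions are provided. `midpoint` (the default) averages
#' the range sizes of the species whose range midpoint falls in the band --
#' the species spanning 600--1000 m contributes its 400 m range to the 800 m
#' band only. `overlap` averages over every species whose range overlaps the
#' band. Bands with no qualifying species are `NA`.
#'
#' @param binned Data frame of binned ranges (see [bin_range()]).
#' @inheritParams bin_range
#' @param mode `"midpoint"` or `"overlap"`.
#' @return Named numeric vector (meters) per band, `NA` where empty.
#' @export
band_mean_range_size <- function(binned, grid = elevation_grid(),
                                 mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  labs <- band_labels(grid)
  out <- rep(NA_real_, length(labs))
  names(out) <- labs
  if (nrow(binned) == 0) return(out)
  if (mode == "midpoint") {
    bnd <- band_of(binned$midpoint, grid)
    agg <- tapply(binned$range_size, factor(bnd, levels = labs), mean)
    out[] <- as.numeric(agg)
  } else {
    pm <- presence_matrix(binned, grid)
    sums <- pm %*% binned$range_size
    n <- rowSums(pm)
    out[] <- ifelse(n > 0, sums / n, NA_real_)
  }
  out
}
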