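#' Elevational band grid
#'
#' Defines the banded elevational domain used throughout the analysis: a
#' contiguous set of equal-width bands between two hard boundaries, plus the
#' clamp bounds applied when ranges are widened by the undersampling
#' sensitivity procedure. Under the defaults the domain 0--4900 m is divided
#' into 49 bands of 100 vertical meters each.
#'
#' A band is the half-open interval \code{(label - band_width, label]} and is
#' identified by its upper edge, so the band labelled 800 covers elevations
#' above 700 m up to and including 800 m.
#'
#' @param domain_min Lower hard boundary of the gradient, meters.
#' @param domain_max Upper hard boundary, meters.
#' @param band_width Band width, meters; `domain_max - domain_min` must be an
#'   exact multiple.
#' @param clamp_min,clamp_max Bounds that augmented range limits are clamped
#'   to. `clamp_min` may sit above `domain_min` (67 m vs 0 m by default,
#'   reflecting the lowest settled elevations of the study region).
#' @param gradient_length_for_pct Gradient length, meters, used to convert the
#'   percentage rules of the augmentation scenarios into meters (5000 m by
#'   default, so 20\% of the gradient is 1000 m).
#' @return An object of class `elevation_grid`.
#' @examples
#' g <- elevation_grid()
#' n_bands(g)       # 49
#' head(band_labels(g))
#' @export
elevation_grid <- function(domain_min = 0, domain_max = 4900, band_width = 100,
                           clamp_min = 67, clamp_max = 4900,
                           gradient_length_for_pct = 5000) {
  stopifnot(is.numeric(domain_min), is.numeric(domain_max),
            is.numeric(band_width), band_width > 0)
  if ((domain_max - domain_min) %% band_width != 0)
    stop("domain length must be an exact multiple of band_width", call. = FALSE)
  if (domain_max <= domain_min)
    stop("domain_max must exceed domain_min", call. = FALSE)
  if (!(domain_min <= clamp_min && clamp_min < clamp_max && clamp_max <= domain_max))
    stop("clamp bounds must satisfy domain_min <= clamp_min < clamp_max <= domain_max",
         call. = FALSE)
  structure(
    list(domain_min = domain_min, domain_max = domain_max,
         band_width = band_width, clamp_min = clamp_min,
         clamp_max = clamp_max,
         gradient_length_for_pct = gradient_length_for_pct),
    class = "elevation_grid")
}

#' @rdname elevation_grid
#' @param grid An `elevation_grid`.
#' @export
n_bands <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  as.integer((grid$domain_max - grid$domain_min) / grid$band_width)
}

#' @rdname elevation_grid
#' @export
band_labels <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  seq(grid$domain_min + grid$band_width, grid$domain_max, by = grid$band_width)
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d-%d m, %d bands of %g m; clamp [%g, %g] m\n",
              x$domain_min, x$domain_max, n_bands(x), x$band_width,
              x$clamp_min, x$clamp_max))
  invisible(x)
}

# Band containing elevation e under the half-open convention; elevations at
# or below domain_min fall in the lowest band so every in-domain point is
# assigned.
band_of <- function(e, grid) {
  lab <- ceiling((e - grid$domain_min) / grid$band_width) * grid$band_width +
    grid$domain_min
  pmin(pmax(lab, grid$domain_min + grid$band_width), grid$domain_max)
}
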