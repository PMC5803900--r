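#' Read and validate a species range table
#'
#' Reads a CSV with one row per species (columns `species_id`, `taxon_class`,
#' `iucn_status`, `lower_m`, `upper_m`) and validates each row against the
#' grid. Rows with missing or undetermined elevational limits are rejected
#' with a reason, mirroring the exclusion of species whose ranges cannot be
#' placed on the gradient; rejected rows are reported via warnings and the
#' `rejected` attribute of the result.
#'
#' Elevations are stored as integer meters; non-integer inputs are rounded to
#' the nearest meter with a warning.
#'
#' @param path Path to the species CSV.
#' @param grid An [elevation_grid()].
#' @return A data frame of validated species ranges with attribute
#'   `rejected` (a data frame of line numbers and reasons, possibly empty).
#' @export
read_species_table <- function(path, grid = elevation_grid()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species_id", "taxon_class", "iucn_status", "lower_m", "upper_m")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("species table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0) {
    warning("species table contains a header but no rows", call. = FALSE)
    out <- raw[, required]
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  validate_species(raw[, required], grid)
}

#' Validate species ranges against a grid
#'
#' @param species Data frame with the species-table columns.
#' @param grid An [elevation_grid()].
#' @return The accepted rows, with a `rejected` attribute; an error is raised
#'   for rows whose lower limit exceeds the upper (a data defect rather than
#'   an undetermined range).
#' @export
validate_species <- function(species, grid = elevation_grid()) {
  lower <- suppressWarnings(as.numeric(species$lower_m))
  upper <- suppressWarnings(as.numeric(species$upper_m))
  reasons <- character(nrow(species))
  reasons[is.na(lower) | is.na(upper)] <- "missing or undetermined elevational limit"
  in_dom <- !is.na(lower) & !is.na(upper) &
    lower >= grid$domain_min & upper <= grid$domain_max
  reasons[reasons == "" & !in_dom] <-
    sprintf("limits outside domain [%g, %g]", grid$domain_min, grid$domain_max)
  inverted <- !is.na(lower) & !is.na(upper) & lower > upper
  if (any(inverted))
    stop("lower_m exceeds upper_m for species: ",
         paste(species$species_id[inverted], collapse = ", "), call. = FALSE)
  bad <- reasons != ""
  if (any(bad))
    warning(sprintf("rejected %d species row(s): %s", sum(bad),
                    paste(sprintf("line %d (%s): %s", which(bad) + 1L,
                                  species$species_id[bad], reasons[bad]),
                          collapse = "; ")), call. = FALSE)
  keep <- species[!bad, , drop = FALSE]
  lw <- lower[!bad]; up <- upper[!bad]
  if (any(lw != round(lw) | up != round(up)))
    warning("non-integer elevations rounded to nearest meter", call. = FALSE)
  keep$lower_m <- as.integer(round(lw))
  keep$upper_m <- as.integer(round(up))
  rownames(keep) <- NULL
  attr(keep, "rejected") <- data.frame(line = which(bad) + 1L,
                                       reason = reasons[bad])
  keep
}

#' Read per-band covariates
#'
#' Reads the band covariate CSV (`band_label`, `area`, `population_density`)
#' and checks it aligns with the grid's bands.
#'
#' @inheritParams read_species_table
#' @return Data frame with one row per band, ordered by `band_label`.
#' @export
read_band_covariates <- function(path, grid = elevation_grid()) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("band_label", "area", "population_density")
  if (!all(required %in% names(cov)))
    stop("band covariate table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  cov <- cov[order(cov$band_label), required]
  labs <- band_labels(grid)
  if (!identical(as.numeric(cov$band_label), as.numeric(labs)))
    stop("band covariate labels do not match the grid's bands", call. = FALSE)
  rownames(cov) <- NULL
  cov
}

#' Write and re-read a band table
#'
#' The band table carries the per-band derived quantities of the analysis:
#' richness, mean range size, covariates and null-model expectations. The CSV
#' round-trips exactly: `read_band_table(write_band_table(t, p))` equals `t`
#' field for field, with missing mean range sizes preserved as empty fields.
#'
#' @param table Band table data frame (`band_label` plus any of the derived
#'   columns); band labels must be unique and strictly increasing.
#' @param path Destination CSV path.
#' @return `write_band_table` returns `path` invisibly; `read_band_table`
#'   returns the table.
#' @export
write_band_table <- function(table, path) {
  stopifnot(is.data.frame(table), "band_label" %in% names(table))
  if (anyDuplicated(table$band_label))
    stop("duplicated band_label in band table", call. = FALSE)
  if (is.unsorted(table$band_label, strictly = TRUE))
    stop("band labels must be strictly increasing", call. = FALSE)
  if ("richness" %in% names(table) &&
      any(table$richness < 0 | table$richness != round(table$richness), na.rm = TRUE))
    stop("richness must be a non-negative integer count", call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
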