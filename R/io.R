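# CSV input/output and the bundled survey tables.

#' Read a lake table
#'
#' @param path CSV with header `lake_id,lat,lon,altitude_m,<env columns...>`
#'   (decimal point, comma-separated, UTF-8).
#' @return validated data frame; environmental descriptors are every column
#'   after the four mandatory ones.
#' @export
read_lakes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("lake_id", "lat", "lon", "altitude_m")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("lake table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$lake_id)) stop("duplicate lake_id in lake table")
  if (any(!is.finite(x$altitude_m))) stop("altitude_m must be finite")
  x
}

#' Read a species counts table
#'
#' @param path CSV with header `lake_id,taxon,abundance,adults,females`.
#' @return validated data frame (counts nonnegative integers with
#'   `females <= adults <= abundance`).
#' @export
read_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("lake_id", "taxon", "abundance", "adults", "females")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("counts table is missing column(s): ", paste(miss, collapse = ", "))
  for (cn in c("abundance", "adults", "females")) {
    if (any(x[[cn]] < 0) || any(x[[cn]] != round(x[[cn]])))
      stop(cn, " must hold nonnegative integers")
  }
  if (any(x$females > x$adults) || any(x$adults > x$abundance))
    stop("counts must satisfy females <= adults <= abundance")
  x
}

#' Read a morphometry table
#'
#' @param path CSV with header `taxon,L_um,a_um` (or a `mass_ug` column).
#' @return validated data frame.
#' @export
read_morphometry <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!("taxon" %in% names(x))) stop("morphometry table needs a taxon column")
  if (!("mass_ug" %in% names(x)) && !all(c("L_um", "a_um") %in% names(x)))
    stop("morphometry table needs L_um and a_um (or mass_ug)")
  x
}

#' Write a spatial basis to CSV with a YAML sidecar
#'
#' The CSV holds `lake_id,PCNM_1..PCNM_K`; the sidecar records eigenvalues,
#' scale labels, the truncation threshold and (when known) the projection
#' origin.
#'
#' @param basis a `spatial_basis` object.
#' @param coords the projected coordinates the basis was built from (for
#'   lake ids and origin metadata); optional when the basis carries ids.
#' @param path output CSV path; the sidecar is `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_spatial_basis <- function(basis, coords = NULL, path) {
  stopifnot(inherits(basis, "spatial_basis"))
  ids <- basis$ids
  origin <- NULL
  if (!is.null(coords)) {
    ids <- as.character(coords$lake_id)
    origin <- attr(coords, "origin")
  }
  if (is.null(ids)) ids <- sprintf("site_%03d", seq_len(basis$n))
  out <- data.frame(lake_id = ids, basis$vectors, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(eigenvalues = as.numeric(basis$values),
               scale = as.character(basis$scale),
               threshold_km = basis$threshold,
               cuts = as.list(basis$cuts))
  if (!is.null(origin)) meta$origin <- list(lat = origin[1], lon = origin[2])
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Published species summary table from the Pyrenean lake survey
#'
#' Per-taxon summary statistics from a survey of nematodes in 75 Pyrenean
#' mountain lakes: occupancy frequency, total abundance, adult count,
#' average and overall female proportion, body mass, and (for the 20 taxa
#' meeting the analysis filters) Moran's I with its significance flag.
#' Mermithidae and indeterminate material are flagged `exclude`; their
#' printed mass values were not estimated and should not be used.
#'
#' @return data frame with columns `taxon`, `habitat`, `freq`, `abundance`,
#'   `adults`, `afp`, `ofp`, `mass_ug`, `moran_i`, `moran_sig`,
#'   `exclude`.
#' @export
survey_species_table <- function() {
  path <- system.file("extdata", "pyrenees_nematode_species.csv",
                      package = "nemadisp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Published deviance-partition table from the Pyrenean lake survey
#'
#' Adjusted-D2 partition (percent) for the 20 analysed species: total,
#' shared, and unshared fractions for large-, medium- and small-scale
#' PCNMs, environmental variables, and altitude.
#'
#' @return data frame with columns `species`, `total`, `shared`, `large`,
#'   `medium`, `small`, `environment`, `altitude`.
#' @export
survey_partition_table <- function() {
  path <- system.file("extdata", "pyrenees_deviance_partition.csv",
                      package = "nemadisp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
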