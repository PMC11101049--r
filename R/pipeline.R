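# End-to-end orchestration: spatial basis -> per-species selections ->
# partition -> Moran -> cross-species trait models -> elevation analysis.

#' Run the full spatial-metacommunity analysis
#'
#' Orchestrates every stage on one set of inputs: builds the PCNM spatial
#' basis and connectivity from the lake coordinates, applies the species
#' filters, runs the five BIC forward selections per eligible species
#' (large/medium/small-scale PCNMs, environment, altitude), partitions the
#' adjusted deviance, computes Moran's I, then relates the unshared
#' fractions and Moran's I to female proportion and body size across
#' species (zoib Delta-criterion selection, Spearman tests, df-4 spline
#' GAMs, abundance screens), and finally regresses per-lake female
#' proportion and relative body size on altitude. Altitude participates in
#' the partition but is dropped from the cross-species trait comparisons.
#'
#' @param lakes lake table (see [read_lakes()]); every column after
#'   `lake_id,lat,lon,altitude_m` is an environmental candidate.
#' @param counts long occurrence table (see [read_counts()]).
#' @param morphometry optional morphometry table (see [read_morphometry()]).
#' @param cut_large,cut_small PCNM eigenvalue cuts.
#' @param alpha forward-selection significance level.
#' @param delta zoib Delta-criterion margin.
#' @param eps boundary-probability tolerance for the GLMs.
#' @param min_lakes,min_adults species filters.
#' @param criterion information criterion for the zoib choice (`"bic"`
#'   default, or `"dic"` for the seeded sampler).
#' @param gam_df spline df for the Moran's I GAMs.
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV plus a JSON summary and a YAML copy of the
#'   configuration.
#' @return object of class `nemadisp_run`: list with `spatial` (coords,
#'   threshold, basis, connectivity), `traits`, `selections`,
#'   `partition`, `moran`, `cross_species`, `elevation`, `excluded`,
#'   `config`.
#' @export
run_pipeline <- function(lakes, counts, morphometry = NULL,
                         cut_large = 25000, cut_small = 1000,
                         alpha = 0.05, delta = 4, eps = 1e-10,
                         min_lakes = 4, min_adults = 6,
                         criterion = "bic", gam_df = 4, out_dir = NULL) {
  need <- c("lake_id", "lat", "lon", "altitude_m")
  if (!all(need %in% names(lakes)))
    stop("lake table is missing column(s): ",
         paste(setdiff(need, names(lakes)), collapse = ", "))
  if (nrow(counts) == 0L) stop("counts table is empty: nothing to analyse")
  unknown <- setdiff(counts$lake_id, lakes$lake_id)
  if (length(unknown))
    stop("counts reference unknown lake_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  config <- list(cut_large = cut_large, cut_small = cut_small, alpha = alpha,
                 delta = delta, eps = eps, min_lakes = min_lakes,
                 min_adults = min_adults, criterion = criterion,
                 gam_df = gam_df)

  ## spatial stage
  coords <- project_to_cartesian(lakes)
  d <- lake_distances(coords)
  thr <- mst_threshold(d)
  basis <- pcnm_basis(d, thr, cut_large = cut_large, cut_small = cut_small)
  w <- connectivity_matrix(d, thr)
  spatial <- list(coords = coords, threshold = thr, basis = basis,
                  connectivity = w,
                  max_planar_km = max(d),
                  max_ellipsoid_km = max(geosphere::distGeo(
                    cbind(lakes$lon, lakes$lat)[rep(seq_len(nrow(lakes)), each = nrow(lakes)), ],
                    cbind(lakes$lon, lakes$lat)[rep(seq_len(nrow(lakes)), nrow(lakes)), ])) / 1000)

  ## trait stage
  traits <- species_filters(species_traits(counts, morphometry),
                            min_lakes = min_lakes, min_adults = min_adults)
  excluded <- traits$taxon[!traits$eligible_distribution]
  eligible <- traits$taxon[traits$eligible_distribution]
  if (length(eligible) == 0L)
    stop("no species passes the analysis filters (>= ", min_lakes,
         " lakes and >= ", min_adults, " adults)")

  presence <- matrix(0L, nrow(lakes), length(unique(counts$taxon)),
                     dimnames = list(lakes$lake_id, sort(unique(counts$taxon))))
  occ <- counts[counts$abundance > 0, ]
  presence[cbind(match(occ$lake_id, lakes$lake_id),
                 match(occ$taxon, colnames(presence)))] <- 1L

  ## candidate pools
  env_cols <- setdiff(names(lakes), need)
  env_cols <- env_cols[vapply(lakes[env_cols], is.numeric, logical(1))]
  env_cols <- env_cols[vapply(lakes[env_cols], function(v) stats::var(v) > 0, logical(1))]
  pools <- list(
    large = as.data.frame(basis$vectors[, basis$scale == "large", drop = FALSE]),
    medium = as.data.frame(basis$vectors[, basis$scale == "medium", drop = FALSE]),
    small = as.data.frame(basis$vectors[, basis$scale == "small", drop = FALSE]),
    environment = lakes[env_cols],
    altitude = data.frame(altitude = lakes$altitude_m)
  )
  pool_all <- do.call(cbind, unname(pools))

  ## per-species selections and partition
  selections <- list()
  partitions <- list()
  for (sp in eligible) {
    y <- presence[, sp]
    sel <- lapply(pools, function(px) {
      if (ncol(px) == 0L) {
        structure(list(variables = character(0),
                       fit = fit_binomial(y, NULL, eps = eps),
                       steps = list(), alpha = alpha),
                  class = "forward_selection")
      } else forward_select(y, px, alpha = alpha, eps = eps)
    })
    selections[[sp]] <- sel
    partitions[[sp]] <- partition_deviance(
      y, pool_all, lapply(sel, `[[`, "variables"), eps = eps)
  }
  part_tab <- partition_table(partitions)

  ## Moran stage
  moran <- moran_table(presence, w, eligible = eligible)

  ## cross-species stage
  ti <- match(part_tab$species, traits$taxon)
  sp_traits <- data.frame(species = part_tab$species,
                          afp = traits$afp[ti], ofp = traits$ofp[ti],
                          mass_ug = traits$mass_ug[ti],
                          stringsAsFactors = FALSE)
  mor_obs <- moran$observed[match(part_tab$species, moran$species)]
  cross <- list(traits = sp_traits)
  for (tr_name in c("afp", "ofp", "mass_ug")) {
    tv <- sp_traits[[tr_name]]
    if (all(is.na(tv))) next
    cross$deviance_models[[tr_name]] <- tryCatch(
      trait_deviance_models(part_tab, tv, criterion = criterion, delta = delta),
      error = function(e) e)
    cross$gam[[tr_name]] <- tryCatch(gam_spline(tv, mor_obs, df = gam_df),
                                     error = function(e) e)
  }
  cross$abundance <- tryCatch(
    abundance_checks(counts, nrow(lakes), part_tab, moran),
    error = function(e) e)

  ## elevation stage
  lake_sum <- lake_trait_summary(counts, traits, min_adults = min_adults)
  lake_sum <- merge(lake_sum, lakes[, c("lake_id", "altitude_m")], by = "lake_id")
  elevation <- list(lake_summary = lake_sum)
  for (resp in c("afp_mean", "fp_weighted", "size_mean_rel", "size_weighted_rel")) {
    ok <- is.finite(lake_sum[[resp]])
    if (sum(ok) < 10L) next
    yv <- lake_sum[[resp]][ok]; xv <- lake_sum$altitude_m[ok]
    elevation$models[[resp]] <- tryCatch(
      select_zoib(yv, xv, criterion = criterion, delta = delta),
      error = function(e) e)
    elevation$spearman[[resp]] <- tryCatch(spearman_rho(xv, yv),
                                           error = function(e) e)
  }

  run <- structure(list(spatial = spatial, traits = traits,
                        selections = selections, partition = part_tab,
                        moran = moran, cross_species = cross,
                        elevation = elevation, excluded = excluded,
                        config = config),
                   class = "nemadisp_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

#' Per-species selection report
#'
#' @param run a `nemadisp_run` object.
#' @return data frame mirroring the published selection table: one row per
#'   (species, subset, selection step) with the variable name, coefficient
#'   sign and step BIC.
#' @export
selection_report <- function(run) {
  rows <- list()
  for (sp in names(run$selections)) {
    for (sub in names(run$selections[[sp]])) {
      sel <- run$selections[[sp]][[sub]]
      if (length(sel$variables) == 0L) next
      co <- sel$fit$coefficients[sel$variables]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, subset = sub, step = seq_along(sel$variables),
        variable = sel$variables,
        sign = ifelse(co >= 0, "+", "-"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(species = character(0), subset = character(0),
                      step = integer(0), variable = character(0),
                      sign = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(run$traits, "species_traits.csv")
  w(selection_report(run), "selection_report.csv")
  w(run$partition, "deviance_partition.csv")
  w(run$moran, "moran.csv")
  if (!is.null(run$cross_species$abundance) &&
      is.data.frame(run$cross_species$abundance))
    w(run$cross_species$abundance, "abundance_checks.csv")
  dm <- run$cross_species$deviance_models
  if (length(dm)) {
    tab <- do.call(rbind, lapply(names(dm), function(t)
      if (is.data.frame(dm[[t]])) cbind(trait = t, dm[[t]])))
    if (!is.null(tab)) w(tab, "trait_deviance_models.csv")
  }
  w(run$elevation$lake_summary, "lake_summary.csv")
  yaml::write_yaml(run$config, file.path(out_dir, "config.yml"))
  jsonlite::write_json(
    list(n_lakes = run$spatial$basis$n,
         n_axes = ncol(run$spatial$basis$vectors),
         threshold_km = run$spatial$threshold,
         max_planar_km = run$spatial$max_planar_km,
         max_ellipsoid_km = run$spatial$max_ellipsoid_km,
         n_species = nrow(run$traits),
         n_eligible = length(run$selections),
         excluded = run$excluded),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.nemadisp_run <- function(x, ...) {
  cat("spatial metacommunity analysis\n")
  cat(sprintf("  lakes: %d, PCNM axes: %d (threshold %.2f km)\n",
              x$spatial$basis$n, ncol(x$spatial$basis$vectors),
              x$spatial$threshold))
  cat(sprintf("  species: %d total, %d analysed, %d excluded by filters\n",
              nrow(x$traits), length(x$selections), length(x$excluded)))
  cat(sprintf("  total adj-D2 range: %.1f%% to %.1f%%\n",
              min(x$partition$total), max(x$partition$total)))
  invisible(x)
}
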