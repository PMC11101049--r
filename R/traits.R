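# Species trait bookkeeping: female proportions, body mass, analysis
# filters and per-lake community summaries.

#' Nematode fresh weight from morphometry (Andrassy formula)
#'
#' `B = L * a^2 / 1.6e6`, with length `L` and greatest body diameter `a` in
#' micrometres, giving fresh weight in micrograms.
#'
#' @param length_um body length in um, positive.
#' @param diameter_um greatest body diameter in um, positive.
#' @return fresh weight in ug; vectorised.
#' @examples
#' andrassy_mass(1000, 40) # 1 ug
#' @export
andrassy_mass <- function(length_um, diameter_um) {
  if (any(!is.finite(length_um)) || any(length_um <= 0))
    stop("length_um must be positive")
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("diameter_um must be positive")
  length_um * diameter_um^2 / 1.6e6
}

#' Average and overall female proportion of a species
#'
#' Two complementary summaries of sex ratio across lakes: AFP is the mean of
#' the per-lake proportions (each occupied lake counts equally) and OFP pools
#' all adults before dividing (abundant lakes dominate). Lakes without adults
#' contribute to neither.
#'
#' @param females,adults integer vectors of per-lake counts for one species
#'   (`0 <= females <= adults`).
#' @return list with elements `afp` and `ofp`, both in `[0, 1]`; both `NA`
#'   (with a warning) when no lake has adults.
#' @export
female_proportions <- function(females, adults) {
  stopifnot(length(females) == length(adults))
  if (any(females < 0) || any(adults < 0) || any(females > adults))
    stop("counts must satisfy 0 <= females <= adults")
  has <- adults >= 1
  if (!any(has)) {
    warning("no lake with adults: female proportions undefined")
    return(list(afp = NA_real_, ofp = NA_real_))
  }
  list(afp = mean(females[has] / adults[has]),
       ofp = sum(females[has]) / sum(adults[has]))
}

#' Species-level trait table from per-lake counts
#'
#' Aggregates a long counts table into one row per taxon: occupancy
#' frequency, total abundance and adults, average and overall female
#' proportion, and body mass (taken from the morphometry table via
#' [andrassy_mass()] when lengths are supplied, or from a `mass_ug` column).
#'
#' @param counts data frame with columns `lake_id`, `taxon`, `abundance`,
#'   `adults`, `females` (one row per lake x taxon occurrence; absent
#'   combinations are zeros). An optional logical `exclude` column marks taxa
#'   (e.g. undetermined material) carried through the data model but dropped
#'   from trait statistics.
#' @param morphometry optional data frame with `taxon` and either `L_um` and
#'   `a_um` or a precomputed `mass_ug`.
#' @return data frame with columns `taxon`, `freq`, `abundance`, `adults`,
#'   `afp`, `ofp`, `mass_ug`, `exclude`.
#' @export
species_traits <- function(counts, morphometry = NULL) {
  need <- c("lake_id", "taxon", "abundance", "adults", "females")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  if (any(counts$females > counts$adults) || any(counts$adults > counts$abundance))
    stop("counts must satisfy females <= adults <= abundance in every lake")
  if (any(counts$females < 0)) stop("counts must be nonnegative")
  sp <- split(counts, counts$taxon)
  rows <- lapply(sp, function(cc) {
    fp <- suppressWarnings(female_proportions(cc$females, cc$adults))
    data.frame(taxon = cc$taxon[1],
               freq = sum(cc$abundance > 0),
               abundance = sum(cc$abundance),
               adults = sum(cc$adults),
               afp = fp$afp, ofp = fp$ofp,
               exclude = if ("exclude" %in% names(cc)) any(cc$exclude) else FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$mass_ug <- NA_real_
  if (!is.null(morphometry)) {
    i <- match(out$taxon, morphometry$taxon)
    if ("mass_ug" %in% names(morphometry)) out$mass_ug <- morphometry$mass_ug[i]
    miss <- is.na(out$mass_ug)
    if (any(miss) && all(c("L_um", "a_um") %in% names(morphometry)))
      out$mass_ug[miss] <- andrassy_mass(morphometry$L_um[i][miss],
                                         morphometry$a_um[i][miss])
  }
  out[order(out$taxon), , drop = FALSE]
}

#' Eligibility filters for the statistical analyses
#'
#' Distribution models require a species in at least `min_lakes` lakes and
#' represented by at least `min_adults` adults; female-proportion analyses
#' require only the adult count. Taxa flagged `exclude` fail both.
#'
#' @param traits output of [species_traits()] (or any data frame with
#'   `freq`, `adults` and optionally `exclude`).
#' @param min_lakes,min_adults filter thresholds (defaults 4 lakes, 6 adults).
#' @return `traits` with logical columns `eligible_distribution` and
#'   `eligible_femprop` added.
#' @export
species_filters <- function(traits, min_lakes = 4, min_adults = 6) {
  stopifnot(all(c("freq", "adults") %in% names(traits)))
  excl <- if ("exclude" %in% names(traits)) traits$exclude else FALSE
  traits$eligible_distribution <-
    !excl & traits$freq >= min_lakes & traits$adults >= min_adults
  traits$eligible_femprop <- !excl & traits$adults >= min_adults
  traits
}

#' Per-lake community trait summaries
#'
#' For each lake: the mean female proportion across species that have at
#' least `min_adults` adults *in that lake* (`afp_mean`, NA when no species
#' qualifies); the pooled female proportion over all adults in the lake
#' (`fp_weighted`, NA unless the lake holds at least `min_adults` adults in
#' total); mean and abundance-weighted mean body mass over species present;
#' and the same two masses relativised to their maximum across lakes so the
#' largest lake scores exactly 1.
#'
#' @param counts long counts table as in [species_traits()].
#' @param traits species trait table supplying `mass_ug` (and `exclude`).
#' @param min_adults per-lake adult threshold (default 6).
#' @return data frame with one row per lake id appearing in `counts`.
#' @export
lake_trait_summary <- function(counts, traits, min_adults = 6) {
  stopifnot(all(c("lake_id", "taxon", "abundance", "adults", "females") %in% names(counts)))
  excl <- traits$taxon[if ("exclude" %in% names(traits)) traits$exclude else FALSE]
  cc <- counts[!(counts$taxon %in% excl), , drop = FALSE]
  mass <- traits$mass_ug[match(cc$taxon, traits$taxon)]
  by_lake <- split(seq_len(nrow(cc)), cc$lake_id)
  rows <- lapply(by_lake, function(i) {
    ad <- cc$adults[i]; fe <- cc$females[i]
    ab <- cc$abundance[i]; ms <- mass[i]
    qual <- ad >= min_adults
    pres <- ab > 0 & !is.na(ms)
    data.frame(
      lake_id = cc$lake_id[i][1],
      afp_mean = if (any(qual)) mean(fe[qual] / ad[qual]) else NA_real_,
      fp_weighted = if (sum(ad) >= min_adults) sum(fe) / sum(ad) else NA_real_,
      size_mean = if (any(pres)) mean(ms[pres]) else NA_real_,
      size_weighted = if (any(pres)) sum(ms[pres] * ab[pres]) / sum(ab[pres]) else NA_real_,
      n_adults = sum(ad),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$size_mean_rel <- out$size_mean / max(out$size_mean, na.rm = TRUE)
  out$size_weighted_rel <- out$size_weighted / max(out$size_weighted, na.rm = TRUE)
  out
}
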