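# Seeded synthetic metacommunity generator: clustered lakes in an elongated
# mountain band, spatially autocorrelated environment, and species whose
# large-scale spatial clustering weakens as their female proportion rises.

#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate the survey conditions the analysis targets: ~75 lakes in
#' an elongated 250 x 40 km band, altitudes 1620-2990 m, ~31 taxa with
#' female proportions skewed toward 1 and log-normal body sizes, a
#' distance-decay-correlated environment, and occupancy whose large-scale
#' clustering strength decreases with female proportion.
#'
#' @param n_lakes number of lakes (default 75).
#' @param extent_km domain extent `c(east-west, north-south)` in km.
#' @param altitude_range altitude limits in m a.s.l.
#' @param n_species number of taxa.
#' @param n_env number of environmental descriptors.
#' @param seed integer seed; the seed fully determines the output.
#' @param beta_env occupancy logit effect per standard deviation of the
#'   focal environmental field (default 1).
#' @param kappa spatial-clustering coefficient: a species with female
#'   proportion `f` receives a large-scale PCNM logit loading of magnitude
#'   `kappa * (1 - f)` per standard deviation of axis scores (default 3,
#'   i.e. strong dispersal limitation for male-dependent species and none
#'   for all-female ones).
#' @param env_range_km distance-decay range of the exponential covariance
#'   of the environmental fields (default 30 km).
#' @param fp_mix_weight,fp_shapes_high,fp_shapes_low female-proportion
#'   mixture: with probability `fp_mix_weight` draw Beta(`fp_shapes_high`)
#'   (mass near 1), else Beta(`fp_shapes_low`).
#' @param size_meanlog,size_sdlog log-normal body-size parameters (ug).
#' @param mean_abundance,nb_dispersion negative-binomial abundance model
#'   conditional on presence.
#' @param adult_fraction binomial probability that an individual is adult.
#' @param prevalence_range range of baseline occupancy probabilities.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_lakes = 75, extent_km = c(250, 40),
                         altitude_range = c(1620, 2990), n_species = 31,
                         n_env = 28, seed = 1L, beta_env = 1, kappa = 3,
                         env_range_km = 30, fp_mix_weight = 0.55,
                         fp_shapes_high = c(40, 2), fp_shapes_low = c(3, 2),
                         size_meanlog = log(4), size_sdlog = 1.1,
                         mean_abundance = 8, nb_dispersion = 0.8,
                         adult_fraction = 0.7,
                         prevalence_range = c(0.10, 0.45)) {
  cfg <- as.list(environment())
  if (cfg$n_lakes < 3) stop("need at least three lakes")
  if (cfg$n_species < 1) stop("need at least one species")
  if (any(extent_km <= 0)) stop("extent must be positive")
  if (diff(altitude_range) < 0) stop("altitude_range must be increasing")
  class(cfg) <- "synth_config"
  cfg
}

# exponential-covariance Gaussian field over the lake geometry
.synth_field <- function(chol_u, n) drop(crossprod(chol_u, stats::rnorm(n)))

#' Generate a synthetic metacommunity with ground truth
#'
#' Lake coordinates come from a clustered (parent-offspring) point process
#' in the elongated domain and are reported as WGS84 latitude/longitude
#' around a Pyrenean reference point. Environmental descriptors are
#' Gaussian fields with exponential distance-decay covariance, half of
#' them with an added altitude-linked trend. Presence of species `s` at
#' lake `i` follows
#' `logit P = alpha_s + beta_env * env1_i + kappa * (1 - f_s) * g_s * v_i`,
#' where `v` is a variance-standardised large-scale PCNM axis of the
#' generated geometry and `g_s` a random per-species sign. Abundance is
#' negative binomial conditional on presence, adults binomial within
#' abundance, females binomial within adults at the species' true female
#' proportion, so `females <= adults <= abundance` always holds.
#'
#' @param config a [synth_config()] list.
#' @return list of class `synth_metacommunity` with `lakes` (lake table:
#'   id, lat, lon, altitude_m, env columns), `counts` (long occurrence
#'   table), `morphometry` (`taxon`, `L_um`, `a_um`), and `truth`
#'   (per-species female proportion, clustering strength, loading sign and
#'   axis, baseline prevalence, plus the generator's effect sizes).
#' @export
synth_metacommunity <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_lakes
  ex <- config$extent_km

  # clustered point process, reflected into the domain
  n_par <- max(4L, round(n / 9))
  px <- stats::runif(n_par, 0, ex[1]); py <- stats::runif(n_par, 0, ex[2])
  pick <- sample.int(n_par, n, replace = TRUE)
  reflect <- function(v, hi) { v <- abs(v); hi - abs(hi - v %% (2 * hi)) }
  x <- reflect(px[pick] + stats::rnorm(n, 0, ex[1] / 16), ex[1])
  y <- reflect(py[pick] + stats::rnorm(n, 0, ex[2] / 5), ex[2])

  # WGS84 placement around a Pyrenean reference point
  lat0 <- 42.2; lon0 <- -1.0
  ref <- (lat0 + (ex[2] / 2) / 111.2) * pi / 180
  s2 <- .wgs84_e2 * sin(ref)^2
  m_rad <- .wgs84_a * (1 - .wgs84_e2) / (1 - s2)^1.5
  n_rad <- .wgs84_a / sqrt(1 - s2)
  lat <- lat0 + (y / m_rad) * 180 / pi
  lon <- lon0 + (x / (n_rad * cos(ref))) * 180 / pi

  dm <- as.matrix(stats::dist(cbind(x, y)))
  cov_alt <- exp(-dm / (2 * config$env_range_km)) + diag(1e-8, n)
  cov_env <- exp(-dm / config$env_range_km) + diag(1e-8, n)
  u_alt <- chol(cov_alt); u_env <- chol(cov_env)

  alt_field <- .synth_field(u_alt, n)
  ar <- config$altitude_range
  altitude <- ar[1] + (alt_field - min(alt_field)) /
    (max(alt_field) - min(alt_field)) * diff(ar)
  alt_std <- as.numeric(scale(altitude))

  env <- sapply(seq_len(config$n_env), function(j) {
    f <- .synth_field(u_env, n)
    if (j %% 2 == 0) f <- f + 0.7 * alt_std   # altitude-linked descriptors
    as.numeric(scale(f))
  })
  colnames(env) <- sprintf("env_%02d", seq_len(config$n_env))

  lakes <- data.frame(lake_id = sprintf("L%03d", seq_len(n)),
                      lat = lat, lon = lon, altitude_m = altitude,
                      stringsAsFactors = FALSE)
  lakes <- cbind(lakes, as.data.frame(env))

  # spatial basis of the generated geometry; large-scale axes carry the
  # dispersal-limitation signal
  d <- lake_distances(project_to_cartesian(lakes))
  basis <- pcnm_basis(d, mst_threshold(d))
  large_idx <- which(basis$scale == "large")
  if (length(large_idx) == 0L) large_idx <- 1L
  vstd <- scale(basis$vectors[, large_idx, drop = FALSE])

  ns <- config$n_species
  hi <- stats::rbinom(ns, 1, config$fp_mix_weight) == 1
  f_s <- ifelse(hi,
                stats::rbeta(ns, config$fp_shapes_high[1], config$fp_shapes_high[2]),
                stats::rbeta(ns, config$fp_shapes_low[1], config$fp_shapes_low[2]))
  mass <- stats::rlnorm(ns, config$size_meanlog, config$size_sdlog)
  ratio <- stats::runif(ns, 15, 30)            # length / diameter
  a_um <- (1.6e6 * mass / ratio)^(1 / 3)
  l_um <- ratio * a_um
  alpha_s <- stats::qlogis(stats::runif(ns, config$prevalence_range[1],
                                        config$prevalence_range[2]))
  g_s <- sample(c(-1, 1), ns, replace = TRUE)
  axis_s <- sample(seq_along(large_idx), ns, replace = TRUE)

  taxa <- sprintf("sp%02d", seq_len(ns))
  counts <- vector("list", ns)
  env1 <- env[, 1]
  for (s in seq_len(ns)) {
    eta <- alpha_s[s] + config$beta_env * env1 +
      config$kappa * (1 - f_s[s]) * g_s[s] * vstd[, axis_s[s]]
    pres <- stats::rbinom(n, 1, stats::plogis(eta))
    ab <- pres * (1 + stats::rnbinom(n, mu = config$mean_abundance - 1,
                                     size = config$nb_dispersion))
    ad <- stats::rbinom(n, ab, config$adult_fraction)
    fe <- stats::rbinom(n, ad, f_s[s])
    keep <- ab > 0
    counts[[s]] <- data.frame(lake_id = lakes$lake_id[keep], taxon = taxa[s],
                              abundance = ab[keep], adults = ad[keep],
                              females = fe[keep], stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL

  structure(list(
    lakes = lakes,
    counts = counts,
    morphometry = data.frame(taxon = taxa, L_um = l_um, a_um = a_um,
                             stringsAsFactors = FALSE),
    truth = list(taxon = taxa, female_proportion = f_s,
                 clustering_strength = config$kappa * (1 - f_s),
                 loading_sign = g_s, large_axis = large_idx[axis_s],
                 baseline_prevalence = stats::plogis(alpha_s),
                 beta_env = config$beta_env, kappa = config$kappa,
                 mass_ug = mass),
    config = config
  ), class = "synth_metacommunity")
}

#' Write a synthetic metacommunity to disk
#'
#' Emits the CSV schemas the pipeline consumes (`lakes.csv`, `counts.csv`,
#' `morphometry.csv`) plus `truth.json` with the generator's ground truth.
#'
#' @param sim a `synth_metacommunity` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_metacommunity"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$lakes, file.path(dir, "lakes.csv"), row.names = FALSE)
  utils::write.csv(sim$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(sim$morphometry, file.path(dir, "morphometry.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
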