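test_that("the generator is deterministic under its seed", {
  a <- synth_metacommunity(synth_config(n_lakes = 30, n_species = 8, seed = 99))
  b <- synth_metacommunity(synth_config(n_lakes = 30, n_species = 8, seed = 99))
  expect_identical(a$lakes, b$lakes)
  expect_identical(a$counts, b$counts)
  expect_identical(a$morphometry, b$morphometry)
  expect_identical(a$truth, b$truth)
  c2 <- synth_metacommunity(synth_config(n_lakes = 30, n_species = 8, seed = 100))
  expect_false(identical(a$counts, c2$counts))
})

test_that("generated data respect the survey's ranges and count ordering", {
  sim <- synth_metacommunity(synth_config(seed = 3))
  expect_equal(nrow(sim$lakes), 75)
  expect_true(all(sim$lakes$altitude_m >= 1620 & sim$lakes$altitude_m <= 2990))
  expect_true(all(sim$counts$females <= sim$counts$adults))
  expect_true(all(sim$counts$adults <= sim$counts$abundance))
  expect_true(all(sim$counts$abundance >= 1))
  f <- sim$truth$female_proportion
  expect_true(all(f >= 0 & f <= 1))
  expect_gt(mean(f > 0.8), 0.3)            # skewed toward female dominance
  mass <- andrassy_mass(sim$morphometry$L_um, sim$morphometry$a_um)
  expect_equal(mass, sim$truth$mass_ug, tolerance = 1e-9)
  expect_true(all(mass > 0.05 & mass < 300))
  # domain is an elongated band
  xy <- project_to_cartesian(sim$lakes)
  expect_lt(diff(range(xy$y)), 60)
  expect_gt(diff(range(xy$x)), 120)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(n_lakes = 0), "three lakes")
  expect_error(synth_config(extent_km = c(-1, 40)), "positive")
  expect_error(synth_config(altitude_range = c(2000, 1000)), "increasing")
})

test_that("with no spatial effect Moran's I is centred on its null expectation", {
  # kappa = 0: each generated species is a null replicate
  sigs <- c(); obs <- c()
  for (seed in 1:3) {
    sim <- synth_metacommunity(synth_config(seed = seed, kappa = 0, beta_env = 0))
    lakes <- sim$lakes
    d <- lake_distances(project_to_cartesian(lakes))
    w <- connectivity_matrix(d, mst_threshold(d))
    pres <- matrix(0L, nrow(lakes), length(sim$truth$taxon),
                   dimnames = list(lakes$lake_id, sim$truth$taxon))
    pres[cbind(match(sim$counts$lake_id, lakes$lake_id),
               match(sim$counts$taxon, colnames(pres)))] <- 1L
    for (s in colnames(pres)) {
      if (var(pres[, s]) == 0) next
      m <- morans_i(pres[, s], w)
      obs <- c(obs, m$observed)
      sigs <- c(sigs, m$p_value < 0.05)
    }
  }
  expect_gt(length(obs), 60)
  expect_lt(abs(mean(obs) - (-1 / 74)), 0.02)
  expect_lte(mean(sigs), 0.12)
})

test_that("strong clustering for male-dependent species is visible in Moran's I", {
  sim <- synth_metacommunity(synth_config(seed = 17, kappa = 6))
  lakes <- sim$lakes
  d <- lake_distances(project_to_cartesian(lakes))
  w <- connectivity_matrix(d, mst_threshold(d))
  pres <- matrix(0L, nrow(lakes), length(sim$truth$taxon),
                 dimnames = list(lakes$lake_id, sim$truth$taxon))
  pres[cbind(match(sim$counts$lake_id, lakes$lake_id),
             match(sim$counts$taxon, colnames(pres)))] <- 1L
  ok <- apply(pres, 2, var) > 0
  iv <- vapply(colnames(pres)[ok], function(s) morans_i(pres[, s], w)$observed,
               numeric(1))
  f <- sim$truth$female_proportion[match(names(iv), sim$truth$taxon)]
  expect_lt(spearman_rho(f, iv)$rho, 0)
})

test_that("write_synthetic emits the pipeline's CSV schemas and truth", {
  sim <- synth_metacommunity(synth_config(n_lakes = 20, n_species = 5, seed = 2))
  dir <- withr::local_tempdir()
  write_synthetic(sim, dir)
  lk <- read_lakes(file.path(dir, "lakes.csv"))
  ct <- read_counts(file.path(dir, "counts.csv"))
  mp <- read_morphometry(file.path(dir, "morphometry.csv"))
  expect_equal(nrow(lk), 20)
  expect_setequal(unique(ct$taxon), mp$taxon[mp$taxon %in% ct$taxon])
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(tr$female_proportion, sim$truth$female_proportion,
               tolerance = 1e-12)
})
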