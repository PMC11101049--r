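test_that("projection maps the origin to zero and matches ellipsoid geodesics", {
  lakes <- data.frame(lake_id = c("o", "n"), lat = c(42.5, 43.5), lon = c(0.3, 0.3))
  xy <- project_to_cartesian(lakes, origin = c(42.5, 0.3))
  expect_equal(unlist(xy[1, c("x", "y")]), c(x = 0, y = 0), tolerance = 1e-12)
  geo <- geosphere::distGeo(c(0.3, 42.5), c(0.3, 43.5)) / 1000
  expect_lt(abs(xy$y[2] - geo) / geo, 0.005)

  # scattered points over a ~200 x 40 km band: all pairwise distances
  # within 0.5% of the geodesic oracle
  lk <- random_lakes(15, seed = 11)
  xy <- project_to_cartesian(lk)
  d <- as.matrix(lake_distances(xy))
  for (i in 1:14) for (j in (i + 1):15) {
    geo <- geosphere::distGeo(c(lk$lon[i], lk$lat[i]), c(lk$lon[j], lk$lat[j])) / 1000
    expect_lt(abs(d[i, j] - geo) / geo, 0.005)
  }
})

test_that("projection rejects invalid input", {
  expect_error(project_to_cartesian(
    data.frame(lake_id = c("a", "a"), lat = c(42, 43), lon = c(0, 1))),
    "duplicate")
  expect_error(project_to_cartesian(
    data.frame(lake_id = c("a", "b"), lat = c(95, 43), lon = c(0, 1))),
    "latitude")
  expect_error(project_to_cartesian(
    data.frame(lake_id = "a", lat = 42, lon = 0)), "two lakes")
})

test_that("distance matrix is Euclidean, symmetric and zero-diagonal", {
  coords <- data.frame(lake_id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(as.numeric(lake_distances(coords)), 5)

  set.seed(3)
  coords <- data.frame(lake_id = sprintf("p%d", 1:10),
                       x = runif(10, 0, 100), y = runif(10, 0, 40))
  d <- as.matrix(lake_distances(coords))
  expect_equal(diag(d), setNames(rep(0, 10), coords$lake_id))
  for (i in 1:10) for (j in 1:10)
    expect_equal(d[i, j], sqrt((coords$x[i] - coords$x[j])^2 +
                               (coords$y[i] - coords$y[j])^2))
})

test_that("MST threshold equals the longest minimum-spanning-tree edge", {
  two <- matrix(c(0, 7, 7, 0), 2)
  expect_equal(mst_threshold(two), 7)

  line <- as.matrix(dist(c(0, 1, 5)))
  expect_equal(mst_threshold(line), 4)

  for (seed in 1:4) {
    set.seed(seed)
    dm <- as.matrix(dist(cbind(runif(12, 0, 100), runif(12, 0, 30))))
    expect_equal(mst_threshold(dm), oracle_mst_max(dm))
  }
  expect_error(mst_threshold(matrix(0, 1, 1)), "at least two")
})

test_that("PCNM basis agrees with the independent vegan implementation", {
  skip_if_not_installed("vegan")
  # equally spaced points on a line, then irregular clouds
  geoms <- list(cbind(0:4 * 10, rep(0, 5)))
  for (seed in 1:3) {
    set.seed(seed)
    geoms[[length(geoms) + 1]] <- cbind(runif(20, 0, 150), runif(20, 0, 30))
  }
  for (g in geoms) {
    d <- dist(g)
    t <- mst_threshold(d)
    b <- pcnm_basis(d, t)
    v <- vegan::pcnm(d, threshold = t)
    expect_equal(length(b$values), ncol(v$vectors))
    expect_equal(b$values, v$values[seq_along(b$values)], tolerance = 1e-8)
    for (k in seq_along(b$values)) {
      # eigenvectors defined up to sign
      expect_equal(min(sum((b$vectors[, k] - v$vectors[, k])^2),
                       sum((b$vectors[, k] + v$vectors[, k])^2)),
                   0, tolerance = 1e-8)
    }
  }
})

test_that("retained PCNM axes are unit-norm and mutually orthogonal", {
  set.seed(9)
  d <- dist(cbind(runif(25, 0, 200), runif(25, 0, 40)))
  b <- pcnm_basis(d, mst_threshold(d))
  g <- crossprod(b$vectors)
  expect_equal(g, diag(ncol(b$vectors)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(b$values) <= 0))
  expect_lte(ncol(b$vectors), attr(d, "Size") - 1)
})

test_that("PCNM rejects degenerate input", {
  expect_error(pcnm_basis(dist(cbind(0:3, 0)), threshold = 0), "positive")
  same <- dist(matrix(1, 4, 2))
  expect_error(pcnm_basis(same, threshold = 1), "degenerate|coincide")
})

test_that("scale classification uses the eigenvalue cuts with a closed medium band", {
  lab <- classify_scale(c(30000, 25000, 1000, 999.9))
  expect_equal(as.character(lab), c("large", "medium", "medium", "small"))
  expect_error(classify_scale(c(5, 1), cut_large = 10, cut_small = 20),
               "cut_small")
})

test_that("scale labels form contiguous exhaustive blocks", {
  set.seed(5)
  d <- dist(cbind(runif(40, 0, 250), runif(40, 0, 40)))
  b <- pcnm_basis(d, mst_threshold(d))
  lab <- as.integer(b$scale)
  expect_true(all(diff(lab) >= 0))       # large block, then medium, then small
  expect_false(anyNA(lab))
})

test_that("connectivity matrix is binary, thresholded, and connected at the MST threshold", {
  d <- as.matrix(dist(c(0, 1, 5)))
  expect_warning(w0 <- connectivity_matrix(d, 0.5), "isolated")
  expect_true(all(w0 == 0))
  wc <- connectivity_matrix(d, 10)
  expect_equal(wc, 1 - diag(3), ignore_attr = TRUE)

  for (seed in 1:4) {
    set.seed(seed)
    dm <- as.matrix(dist(cbind(runif(15, 0, 200), runif(15, 0, 40))))
    w <- connectivity_matrix(dm, mst_threshold(dm))
    expect_true(all(w %in% c(0, 1)))
    expect_equal(w, t(w))
    expect_true(oracle_connected(w))
  }
})
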