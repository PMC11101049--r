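# Spatial predictor system: planar projection, distances, MST threshold,
# PCNM eigenbasis, scale classification, binary connectivity.

# WGS84 ellipsoid constants (km)
.wgs84_a <- 6378.137
.wgs84_e2 <- 0.00669437999014

#' Project lake coordinates to a local Cartesian plane
#'
#' Equirectangular ellipsoidal approximation about the mean latitude of the
#' input: `x = N(lat) * cos(mean lat) * dlon`, `y = M(lat) * dlat`, with `M`
#' and `N` the WGS84 meridional and normal radii evaluated at the mean
#' latitude. Over extents of a few hundred kilometres this reproduces
#' ellipsoid geodesic distances to well under 0.5 percent, which is all the
#' downstream eigenvector construction needs.
#'
#' @param lakes data frame with columns `lake_id`, `lat`, `lon` (decimal
#'   degrees, WGS84). Additional columns are ignored.
#' @param origin optional `c(lat, lon)` used as the plane origin; defaults to
#'   `(min(lat), min(lon))` of the input so all coordinates are nonnegative.
#' @return data frame with columns `lake_id`, `x`, `y` (km), carrying the
#'   origin and reference latitude as attributes `origin` and `ref_lat`.
#' @examples
#' lakes <- data.frame(lake_id = c("a", "b"), lat = c(42.5, 43.5), lon = 0)
#' project_to_cartesian(lakes)
#' @export
project_to_cartesian <- function(lakes, origin = NULL) {
  stopifnot(is.data.frame(lakes), all(c("lake_id", "lat", "lon") %in% names(lakes)))
  if (nrow(lakes) < 2L)
    stop("need at least two lakes to define a plane")
  if (anyDuplicated(lakes$lake_id))
    stop("duplicate lake_id: ", paste(unique(lakes$lake_id[duplicated(lakes$lake_id)]), collapse = ", "))
  if (any(!is.finite(lakes$lat)) || any(abs(lakes$lat) > 90))
    stop("latitude must be finite and within [-90, 90]")
  if (any(!is.finite(lakes$lon)) || any(abs(lakes$lon) > 180))
    stop("longitude must be finite and within [-180, 180]")
  if (is.null(origin)) origin <- c(min(lakes$lat), min(lakes$lon))
  ref_lat <- mean(lakes$lat) * pi / 180
  s2 <- .wgs84_e2 * sin(ref_lat)^2
  m_rad <- .wgs84_a * (1 - .wgs84_e2) / (1 - s2)^1.5     # meridional radius
  n_rad <- .wgs84_a / sqrt(1 - s2)                       # normal radius
  out <- data.frame(
    lake_id = lakes$lake_id,
    x = n_rad * cos(ref_lat) * (lakes$lon - origin[2]) * pi / 180,
    y = m_rad * (lakes$lat - origin[1]) * pi / 180,
    stringsAsFactors = FALSE
  )
  attr(out, "origin") <- origin
  attr(out, "ref_lat") <- ref_lat * 180 / pi
  out
}

#' Euclidean distance matrix between projected lakes
#'
#' @param coords output of [project_to_cartesian()], or any data frame with
#'   `lake_id`, `x`, `y` in km.
#' @return a [stats::dist] object labelled by lake id, in km.
#' @export
lake_distances <- function(coords) {
  stopifnot(all(c("lake_id", "x", "y") %in% names(coords)))
  if (nrow(coords) < 2L) stop("need at least two lakes")
  d <- stats::dist(cbind(coords$x, coords$y))
  attr(d, "Labels") <- as.character(coords$lake_id)
  d
}

#' Longest edge of the minimum spanning tree
#'
#' The canonical truncation distance for PCNM construction and the
#' connectivity threshold: using it guarantees the threshold graph is
#' connected.
#'
#' @param d distance matrix (`dist` object or symmetric matrix), km.
#' @return the maximum edge length (km) of a minimum spanning tree of the
#'   complete graph on the lakes.
#' @export
mst_threshold <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) stop("need at least two lakes for a spanning tree")
  if (any(!is.finite(d))) stop("distances must be finite")
  max(vegan::spantree(d)$dist)
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Builds spatial eigenvector predictors from a truncated distance matrix:
#' distances above the threshold `t` are replaced by `4 * t`, the resulting
#' matrix is Gower double-centred (`B = H (-d^2/2) H`), and the positive
#' eigenvectors of `B` are retained as orthogonal, unit-norm spatial
#' predictors ordered from broad to fine scale by decreasing eigenvalue.
#'
#' @param d distance matrix (`dist` or symmetric matrix), km.
#' @param threshold truncation distance `t` in km, typically
#'   [mst_threshold()]. Must be positive.
#' @param cut_large,cut_small eigenvalue cuts passed to [classify_scale()].
#' @param tol relative positivity tolerance: axes are retained when their
#'   eigenvalue exceeds `tol * max(eigenvalue)`, so numerical zeros are
#'   never kept.
#' @return an object of class `spatial_basis`: a list with `vectors`
#'   (lakes x axes matrix, columns `PCNM_1 ...` unit-norm), `values`
#'   (descending eigenvalues on the km^2 scale of the centred matrix),
#'   `scale` (factor with levels large/medium/small), `threshold`, `ids`.
#' @seealso [classify_scale()], [connectivity_matrix()]
#' @export
pcnm_basis <- function(d, threshold, cut_large = 25000, cut_small = 1000,
                       tol = 1e-8) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive distance")
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  if (n < 3L) stop("need at least three lakes for a PCNM basis")
  if (all(dm < .Machine$double.eps))
    stop("degenerate input: all coordinates coincide")
  dm[dm > threshold] <- 4 * threshold
  diag(dm) <- 0
  a <- -0.5 * dm^2
  h <- diag(n) - matrix(1 / n, n, n)
  b <- h %*% a %*% h
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  if (!any(keep)) stop("no positive eigenvalues: degenerate geometry")
  vec <- e$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("PCNM_", seq_len(ncol(vec)))
  ids <- rownames(dm)
  if (!is.null(ids)) rownames(vec) <- ids
  out <- structure(
    list(vectors = vec, values = e$values[keep],
         scale = NULL, threshold = threshold, ids = ids, n = n),
    class = "spatial_basis"
  )
  classify_scale(out, cut_large = cut_large, cut_small = cut_small)
}

#' Label PCNM axes as large-, medium- or small-scale
#'
#' Axes with eigenvalue above `cut_large` are labelled `large`, below
#' `cut_small` labelled `small`, and `medium` on the closed interval in
#' between. Because eigenvalues are sorted, the labels always form three
#' contiguous blocks. The cuts are on the eigenvalue scale of the centred
#' matrix (km^2-based), where the defaults separate region-wide trends from
#' fine-grained structure for a domain a few hundred km across.
#'
#' @param basis a `spatial_basis` object (or a numeric eigenvalue vector).
#' @param cut_large,cut_small eigenvalue cuts; `cut_small` must not exceed
#'   `cut_large`.
#' @return the basis with its `scale` factor filled in (or, for a numeric
#'   input, the factor itself).
#' @export
classify_scale <- function(basis, cut_large = 25000, cut_small = 1000) {
  if (cut_small > cut_large) stop("cut_small must not exceed cut_large")
  values <- if (inherits(basis, "spatial_basis")) basis$values else basis
  if (is.unsorted(rev(values))) stop("eigenvalues must be in descending order")
  lab <- ifelse(values > cut_large, "large",
                ifelse(values < cut_small, "small", "medium"))
  lab <- factor(lab, levels = c("large", "medium", "small"))
  if (inherits(basis, "spatial_basis")) {
    basis$scale <- lab
    basis$cuts <- c(large = cut_large, small = cut_small)
    basis
  } else lab
}

#' Binary connectivity matrix under a distance threshold
#'
#' Two lakes are directly connected when their distance is at most the
#' threshold; with the MST threshold the resulting graph is connected, which
#' mirrors the assumption that a passive disperser reaches lakes within the
#' threshold in one step and farther lakes only via intermediates.
#'
#' @param d distance matrix (`dist` or symmetric matrix), km.
#' @param threshold connection distance in km, typically [mst_threshold()].
#' @return binary symmetric matrix with zero diagonal and attribute
#'   `threshold`. A warning names lakes with no neighbour.
#' @export
connectivity_matrix <- function(d, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive distance")
  dm <- as.matrix(stats::as.dist(d))
  w <- (dm <= threshold) * 1
  diag(w) <- 0
  isolated <- rowSums(w) == 0
  if (any(isolated)) {
    who <- rownames(dm)[isolated]
    if (is.null(who)) who <- which(isolated)
    warning("isolated lakes (no neighbour within threshold): ",
            paste(who, collapse = ", "))
  }
  attr(w, "threshold") <- threshold
  w
}

#' @export
print.spatial_basis <- function(x, ...) {
  cat("PCNM spatial basis:", ncol(x$vectors), "positive axes on", x$n,
      "lakes (truncation", format(x$threshold, digits = 4), "km)\n")
  cat("scale classes:", paste(sprintf("%s=%d", levels(x$scale),
                                      tabulate(x$scale, 3L)), collapse = ", "), "\n")
  cat("eigenvalue range:", format(min(x$values), digits = 4), "to",
      format(max(x$values), digits = 4), "\n")
  invisible(x)
}
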