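# Moran's I spatial autocorrelation with the normality test.

#' Moran's I under a binary connectivity matrix
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with expectation `-1/(n - 1)` under no autocorrelation and variance from
#' the normality assumption:
#' `Var = (n^2 S1 - n S2 + 3 S0^2) / (S0^2 (n^2 - 1)) - E[I]^2`, where
#' `S1 = 0.5 * sum_ij (w_ij + w_ji)^2` and
#' `S2 = sum_i (sum_j w_ij + sum_j w_ji)^2`. Weights are used as supplied
#' (binary, no row standardisation). The p-value is two-sided normal.
#'
#' @param x per-lake values (e.g. presence/absence), not constant.
#' @param w square weight matrix (zero diagonal), same order as `x`.
#' @return object of class `moran_test`: list with `observed`, `expected`,
#'   `sd`, `p_value`, `n`.
#' @export
morans_i <- function(x, w) {
  w <- as.matrix(w)
  n <- length(x)
  if (n < 3L) stop("need at least three observations")
  if (nrow(w) != n || ncol(w) != n) stop("w must be n x n")
  if (stats::var(x) == 0) stop("x is constant: Moran's I undefined")
  s0 <- sum(w)
  if (s0 <= 0) stop("weight matrix has zero total weight")
  z <- x - mean(x)
  obs <- (n / s0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  expected <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  v <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - expected^2
  sd <- sqrt(v)
  p <- 2 * stats::pnorm(-abs((obs - expected) / sd))
  structure(list(observed = obs, expected = expected, sd = sd,
                 p_value = p, n = n),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f), two-sided p = %.4g, n = %d\n",
              x$observed, x$expected, x$sd, x$p_value, x$n))
  invisible(x)
}

#' Moran's I for each eligible species
#'
#' @param presence lakes x species 0/1 matrix (all surveyed lakes).
#' @param w binary connectivity matrix from [connectivity_matrix()].
#' @param eligible optional character vector of species to test; others are
#'   reported as missing, mirroring the convention that species below the
#'   analysis filters get no autocorrelation statistic.
#' @return data frame `species`, `observed`, `expected`, `sd`, `p_value`.
#' @export
moran_table <- function(presence, w, eligible = colnames(presence)) {
  out <- data.frame(species = colnames(presence),
                    observed = NA_real_, expected = NA_real_,
                    sd = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(presence))) {
    if (!(colnames(presence)[i] %in% eligible)) next
    m <- morans_i(presence[, i], w)
    out[i, c("observed", "expected", "sd", "p_value")] <-
      c(m$observed, m$expected, m$sd, m$p_value)
  }
  out
}
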