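# Deviance partitioning of the merged per-subset GLM selections.

#' Partition adjusted deviance across predictor subsets
#'
#' Merges the variables selected independently for each subset (typically
#' large/medium/small-scale PCNMs, environment and altitude) into one full
#' binomial GLM, then attributes to each subset the adjusted deviance lost
#' when its own variables are removed from the union (leave-subset-out).
#' The remainder, `shared = total - sum(unshared)`, is explanatory power
#' the subsets cannot claim uniquely; both shared and unshared fractions
#' may legitimately be negative because adj-D2 penalises parameters.
#' Subsets that selected nothing get an unshared value of exactly 0. The
#' adjustment of each reduced model uses its own coefficient count.
#'
#' @param y 0/1 response.
#' @param pool data frame holding (at least) every selected predictor
#'   column.
#' @param subsets named list of character vectors: the variables selected
#'   for each subset (may be empty). Duplicated columns across subsets are
#'   dropped from the union with a warning before fitting.
#' @param eps boundary tolerance passed to [fit_binomial()].
#' @return object of class `deviance_partition`: list with `total`,
#'   `shared` and named vector `unshared`, all in percent, plus the full
#'   fit. `shared + sum(unshared) == total` to numerical precision.
#' @export
partition_deviance <- function(y, pool, subsets, eps = 1e-10) {
  stopifnot(is.list(subsets), !is.null(names(subsets)))
  vars <- unlist(subsets, use.names = FALSE)
  if (anyDuplicated(vars)) {
    warning("variables selected in more than one subset; duplicates dropped from the union: ",
            paste(unique(vars[duplicated(vars)]), collapse = ", "))
    vars <- unique(vars)
  }
  missing_cols <- setdiff(vars, names(pool))
  if (length(missing_cols))
    stop("pool is missing selected column(s): ", paste(missing_cols, collapse = ", "))
  fit_on <- function(v) {
    if (length(v) == 0L) return(fit_binomial(y, NULL, eps = eps))
    X <- pool[, v, drop = FALSE]
    qx <- qr(cbind(1, as.matrix(X)))
    if (qx$rank < ncol(X) + 1L) {
      drop_n <- colnames(X)[qx$pivot[(qx$rank + 1L):(ncol(X) + 1L)] - 1L]
      warning("rank-deficient union design; dropping: ",
              paste(drop_n, collapse = ", "))
      X <- X[, setdiff(colnames(X), drop_n), drop = FALSE]
    }
    fit_binomial(y, X, eps = eps)
  }
  full <- fit_on(vars)
  total <- 100 * full$adj_d2
  unshared <- vapply(names(subsets), function(s) {
    if (length(subsets[[s]]) == 0L) return(0)
    red <- fit_on(setdiff(vars, subsets[[s]]))
    total - 100 * red$adj_d2
  }, numeric(1))
  structure(list(total = total, shared = total - sum(unshared),
                 unshared = unshared, fit = full),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, digits = 2, ...) {
  cat("adjusted-D2 partition (%):\n")
  print(round(c(total = x$total, shared = x$shared, x$unshared), digits))
  invisible(x)
}

#' Assemble a partition table across species
#'
#' @param partitions named list of `deviance_partition` objects (names are
#'   species).
#' @return data frame with one row per species: `species`, `total`,
#'   `shared`, then one unshared column per subset.
#' @export
partition_table <- function(partitions) {
  rows <- lapply(names(partitions), function(sp) {
    p <- partitions[[sp]]
    cbind(data.frame(species = sp, total = p$total, shared = p$shared,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p$unshared)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
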