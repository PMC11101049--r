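# Cross-species trait analyses: Spearman rank correlation, smoothing-spline
# GAM on Moran's I, and abundance sanity checks.

#' Spearman rank correlation with the t approximation
#'
#' Pearson correlation of average-ranked data (ties share mean ranks), with
#' a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Pairs with missing values are
#' deleted first.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least three complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Gaussian GAM with a fixed-df smoothing spline
#'
#' Fits `y ~ spline(x)` with an identity link: a cubic smoothing spline
#' whose penalty is tuned so the smoother contributes `df` effective
#' degrees of freedom beyond the intercept (hat-matrix trace `df + 1`,
#' checked to within 0.1). Reports the Gaussian deviance fractions
#' (`D2 = 1 - RSS/TSS`, adjusted with the effective parameter count), a
#' BIC on the profile `n log(RSS/n) + df_total log(n)`, the t-test p-value
#' of the linear (parametric) component, and the F-test p-value of the
#' nonparametric departure from that line,
#' `F = ((RSS_linear - RSS_smooth)/(df - 1)) / (RSS_smooth/(n - df - 1))`.
#'
#' @param x predictor with at least `df` distinct values.
#' @param y Gaussian response (e.g. per-species Moran's I values).
#' @param df target effective df of the smoother beyond the intercept
#'   (default 4; the infinite-penalty limit is the least-squares line).
#' @param lambda optional explicit penalty overriding the df targeting
#'   (a very large value reproduces the ordinary linear fit).
#' @return object of class `gam_spline`: list with `edf`, `df_total`,
#'   `fitted`, `rss`, `tss`, `d2`, `adj_d2`, `bic`, `parametric_p`,
#'   `nonparametric_p`, `n`, `spline`.
#' @export
gam_spline <- function(x, y, df = 4, lambda = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L) stop("need at least eight observations")
  if (length(unique(x)) < max(df, 4)) stop("too few distinct x values for the requested df")
  df_total <- df + 1
  if (is.null(lambda)) {
    ss <- stats::smooth.spline(x, y, df = df_total, cv = FALSE)
    if (abs(ss$df - df_total) > 0.1)
      warning(sprintf("realised smoother df %.3f misses target %.1f", ss$df - 1, df))
  } else {
    ss <- stats::smooth.spline(x, y, lambda = lambda)
    df_total <- ss$df
  }
  fitted <- stats::predict(ss, x)$y
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  d2 <- 1 - rss / tss
  adj_d2 <- 1 - ((n - 1) / (n - df_total)) * (1 - d2)
  lin <- stats::lm(y ~ x)
  par_p <- summary(lin)$coefficients["x", "Pr(>|t|)"]
  np_p <- NA_real_
  if (df > 1) {
    rss_lin <- sum(stats::residuals(lin)^2)
    fstat <- ((rss_lin - rss) / (df - 1)) / (rss / (n - df_total))
    np_p <- stats::pf(max(fstat, 0), df - 1, n - df_total, lower.tail = FALSE)
  }
  structure(list(edf = ss$df - 1, df_total = df_total, fitted = fitted,
                 rss = rss, tss = tss, d2 = d2, adj_d2 = adj_d2,
                 bic = n * log(rss / n) + df_total * log(n),
                 parametric_p = par_p, nonparametric_p = np_p,
                 n = n, spline = ss),
            class = "gam_spline")
}

#' @export
print.gam_spline <- function(x, ...) {
  cat(sprintf("smoothing-spline GAM: edf %.2f, adj-D2 %.1f%%, BIC %.2f\n",
              x$edf, 100 * x$adj_d2, x$bic))
  cat(sprintf("parametric (linear) p = %.4g, nonparametric p = %.4g, n = %d\n",
              x$parametric_p, x$nonparametric_p, x$n))
  invisible(x)
}

#' Abundance versus explanatory power: Spearman screening
#'
#' Correlates three abundance summaries per species (mean over occupied
#' lakes, mean over all lakes, and maximum) with each unshared adj-D2
#' column and with Moran's I, to check whether local density rather than
#' dispersal traits drives the spatial signal.
#'
#' @param counts long counts table (`lake_id`, `taxon`, `abundance`, ...).
#' @param n_lakes total number of surveyed lakes (for the all-lakes mean).
#' @param partitions partition table from [partition_table()] (`species`
#'   plus unshared columns).
#' @param moran Moran table with `species` and `observed`.
#' @return data frame with one row per (abundance measure, response):
#'   `measure`, `response`, `rho`, `p_value`, `n`.
#' @export
abundance_checks <- function(counts, n_lakes, partitions, moran) {
  sp <- partitions$species
  ab <- lapply(sp, function(s) counts$abundance[counts$taxon == s & counts$abundance > 0])
  meas <- list(
    mean_occupied = vapply(ab, mean, numeric(1)),
    mean_all = vapply(ab, sum, numeric(1)) / n_lakes,
    max = vapply(ab, max, numeric(1))
  )
  resp_cols <- setdiff(names(partitions), c("species", "total", "shared"))
  resp <- c(stats::setNames(lapply(resp_cols, function(cn) partitions[[cn]]), resp_cols),
            list(moran_i = moran$observed[match(sp, moran$species)]))
  rows <- list()
  for (m in names(meas)) for (r in names(resp)) {
    s <- spearman_rho(meas[[m]], resp[[r]])
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, response = r, rho = s$rho, p_value = s$p_value, n = s$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Cross-species trait regressions on the deviance partition
#'
#' For each variable subset, regresses the species' unshared adj-D2
#' fractions (divided by 100; negative values clamped to 0, with the count
#' of clamped entries recorded) on a trait via the zoib Delta-criterion
#' selection, alongside the complementary Spearman test.
#'
#' @param partitions partition table from [partition_table()].
#' @param trait named numeric vector or data frame column aligned with
#'   `partitions$species`.
#' @param subsets unshared columns to analyse (default: all except
#'   altitude, which is dropped from trait comparisons).
#' @param criterion,delta passed to [select_zoib()].
#' @return data frame with one row per subset: chosen design, criterion
#'   improvement, Spearman rho and p, and the number of clamped values.
#' @export
trait_deviance_models <- function(partitions, trait,
                                  subsets = setdiff(names(partitions),
                                                    c("species", "total", "shared", "altitude")),
                                  criterion = "bic", delta = 4) {
  rows <- lapply(subsets, function(cn) {
    y <- pmax(partitions[[cn]], 0) / 100
    clamped <- sum(partitions[[cn]] < 0)
    ch <- select_zoib(y, trait, criterion = criterion, delta = delta)
    sel <- ch$candidate[ch$chosen]
    sp <- spearman_rho(trait, pmax(partitions[[cn]], 0))
    data.frame(subset = cn, chosen = sel,
               delta_best = min(ch$delta_to_null[ch$candidate != "null"]),
               rho = sp$rho, rho_p = sp$p_value, n_clamped = clamped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
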