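# Zero-one inflated beta regression: likelihood, ML fit, Delta-criterion
# model choice, and an optional seeded Metropolis sampler for DIC.
#
# Mixture density on [0, 1]:
#   P(y = 0) = p0;  P(y = 1) = (1 - p0) p1;
#   y in (0, 1): (1 - p0)(1 - p1) Beta(y; mu phi, (1 - mu) phi).
# logit(p0), logit(p1) and logit(mu) are each linear in the design;
# log(phi) is intercept-only. Parts are dropped (mass fixed at 0) when the
# data contain no exact zeros / ones.

.zoib_design <- function(x, design, n) {
  switch(design,
         null = matrix(1, n, 1),
         linear = cbind(1, x),
         quadratic = cbind(1, x, x^2),
         stop("unknown design: ", design))
}

.zoib_ll <- function(y, Z, gamma0, gamma1, beta, delta) {
  mu <- stats::plogis(drop(Z %*% beta))
  phi <- exp(delta)
  p0 <- if (is.null(gamma0)) rep(0, length(y)) else stats::plogis(drop(Z %*% gamma0))
  p1 <- if (is.null(gamma1)) rep(0, length(y)) else stats::plogis(drop(Z %*% gamma1))
  ll <- numeric(length(y))
  i0 <- y == 0; i1 <- y == 1; ii <- !i0 & !i1
  ll[i0] <- log(p0[i0])
  ll[i1] <- log1p(-p0[i1]) + log(p1[i1])
  ll[ii] <- log1p(-p0[ii]) + log1p(-p1[ii]) +
    stats::dbeta(y[ii], mu[ii] * phi, (1 - mu[ii]) * phi, log = TRUE)
  sum(ll)
}

#' Log-likelihood of the zero-one inflated beta model
#'
#' @param y response values in `[0, 1]`.
#' @param x covariate (ignored for the null design).
#' @param params list with elements `gamma0` (zero-part coefficients or
#'   `NULL` to disable the point mass at 0), `gamma1` (likewise for 1),
#'   `beta` (beta-mean coefficients) and `delta` (log precision). Each
#'   coefficient vector must match the design's column count.
#' @param design one of `"null"`, `"linear"`, `"quadratic"`.
#' @return the summed log-likelihood (`-Inf` when a disabled part is needed).
#' @export
zoib_loglik <- function(y, x = NULL, params, design = "linear") {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  Z <- .zoib_design(x, design, length(y))
  .zoib_ll(y, Z, params$gamma0, params$gamma1, params$beta, params$delta)
}

#' Maximum-likelihood fit of the zero-one inflated beta regression
#'
#' Quasi-Newton (BFGS) maximisation from a moment-based start plus fixed
#' deterministic perturbations; the covariate is centred and scaled
#' internally for numerical stability (criteria and fitted values are
#' unaffected). The zero (one) part is included only when the data contain
#' exact zeros (ones).
#'
#' @param y response in `[0, 1]`, `length(y) >= 10`.
#' @param x covariate (required unless `design = "null"`).
#' @param design `"null"`, `"linear"` or `"quadratic"` (the quadratic
#'   design always includes the linear term).
#' @return object of class `zoib_fit`: list with `par` (list `gamma0`,
#'   `gamma1`, `beta`, `delta` on the scaled-covariate coordinates),
#'   `loglik`, `k` (parameter count), `aic`, `bic`, `n`, `design`,
#'   `has_zero`, `has_one`, `converged`, `x_center`, `x_scale`.
#' @export
zoib_fit <- function(y, x = NULL, design = c("linear", "null", "quadratic")) {
  design <- match.arg(design)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  xc <- 0; xs <- 1
  if (design != "null") {
    if (is.null(x)) stop("x is required for non-null designs")
    stopifnot(length(x) == n)
    xc <- mean(x); xs <- stats::sd(x)
    if (!is.finite(xs) || xs == 0) xs <- 1
  }
  z <- if (design == "null") NULL else (x - xc) / xs
  Z <- .zoib_design(z, design, n)
  q <- ncol(Z)
  has0 <- any(y == 0); has1 <- any(y == 1)

  yi <- y[y > 0 & y < 1]
  mu0 <- if (length(yi)) min(max(mean(yi), 0.02), 0.98) else 0.5
  v0 <- if (length(yi) > 1) stats::var(yi) else mu0 * (1 - mu0) / 3
  phi0 <- min(max(mu0 * (1 - mu0) / max(v0, 1e-6) - 1, 0.5), 500)
  pad <- function(a) c(a, rep(0, q - 1))
  clampp <- function(p) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  base <- c(if (has0) pad(stats::qlogis(clampp(mean(y == 0)))),
            if (has1) pad(stats::qlogis(clampp(mean(y == 1)))),
            pad(stats::qlogis(mu0)), log(phi0))
  starts <- list(base)
  if (q > 1) {
    for (s in c(0.5, -0.5)) {
      st <- base
      st[length(st) - q + 1 + 1] <- s  # slope of the beta-mean part
      starts[[length(starts) + 1L]] <- st
    }
  } else {
    starts[[2]] <- base + c(rep(0, length(base) - 1), 1)
  }

  unpack <- function(par) {
    i <- 0
    g0 <- if (has0) par[i + seq_len(q)] else NULL; if (has0) i <- i + q
    g1 <- if (has1) par[i + seq_len(q)] else NULL; if (has1) i <- i + q
    list(gamma0 = g0, gamma1 = g1,
         beta = par[i + seq_len(q)], delta = par[i + q + 1])
  }
  nll <- function(par) {
    p <- unpack(par)
    ll <- .zoib_ll(y, Z, p$gamma0, p$gamma1, p$beta, p$delta)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      stats::optim(st, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("zoib fit failed from every start")
  k <- length(best$par)
  ll <- -best$value
  structure(list(
    par = unpack(best$par), loglik = ll, k = k,
    aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    n = n, design = design, has_zero = has0, has_one = has1,
    converged = best$convergence == 0 && ll >=
      .zoib_ll(y, Z, unpack(base)$gamma0, unpack(base)$gamma1,
               unpack(base)$beta, unpack(base)$delta) - 1e-6,
    x_center = xc, x_scale = xs
  ), class = "zoib_fit")
}

#' @export
print.zoib_fit <- function(x, ...) {
  cat(sprintf("zoib fit (%s design): loglik %.3f, BIC %.3f, n = %d\n",
              x$design, x$loglik, x$bic, x$n))
  cat(sprintf("parts: zero %s, one %s; precision phi = %.3f\n",
              if (x$has_zero) "on" else "off",
              if (x$has_one) "on" else "off", exp(x$par$delta)))
  invisible(x)
}

#' Choose among null, linear and quadratic zoib models
#'
#' The lowest-criterion candidate among the linear and quadratic designs is
#' selected over the null model only when its criterion value is at least
#' `delta` units lower than the null's; otherwise the null is retained.
#'
#' @param y,x response and covariate as in [zoib_fit()].
#' @param criterion `"bic"` (default, from the ML fits), `"aic"`, or
#'   `"dic"` (runs the seeded Metropolis sampler via [zoib_dic()]).
#' @param delta required improvement over the null (default 4).
#' @param seed seed for the sampler when `criterion = "dic"`.
#' @return object of class `zoib_choice`: data frame with one row per
#'   candidate (`candidate`, `criterion`, `delta_to_null`, `chosen`), with
#'   the fits attached as attribute `fits`.
#' @export
select_zoib <- function(y, x, criterion = c("bic", "aic", "dic"), delta = 4,
                        seed = 1L) {
  criterion <- match.arg(criterion)
  designs <- c("null", "linear", "quadratic")
  fits <- lapply(designs, function(d) zoib_fit(y, x, design = d))
  names(fits) <- designs
  crit <- switch(criterion,
                 bic = vapply(fits, `[[`, numeric(1), "bic"),
                 aic = vapply(fits, `[[`, numeric(1), "aic"),
                 dic = vapply(designs, function(d)
                   zoib_dic(y, x, design = d, seed = seed)$dic, numeric(1)))
  d_null <- crit - crit[["null"]]
  cand <- which.min(crit[c("linear", "quadratic")]) + 1L
  chosen <- if (crit[cand] <= crit[["null"]] - delta) designs[cand] else "null"
  out <- data.frame(candidate = designs, criterion = unname(crit),
                    delta_to_null = unname(d_null),
                    chosen = designs == chosen, stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  class(out) <- c("zoib_choice", "data.frame")
  out
}

#' Deviance information criterion via random-walk Metropolis
#'
#' Samples the zoib posterior under independent normal priors (mean 0,
#' sd `prior_sd`) with a fixed-seed random-walk Metropolis started at the
#' ML solution, and reports `DIC = Dbar + pD` with
#' `pD = Dbar - D(posterior mean)`. Sampler- and prior-dependent by nature;
#' intended for the Delta-criterion selection rule, not for reproducing any
#' particular magnitude.
#'
#' @param y,x,design as in [zoib_fit()].
#' @param n_iter,burn total and discarded iterations.
#' @param prior_sd prior standard deviation (default 10).
#' @param proposal_sd random-walk step standard deviation.
#' @param seed RNG seed (restored on exit).
#' @return list with `dic`, `pd`, `dbar`, `accept` (acceptance rate).
#' @export
zoib_dic <- function(y, x = NULL, design = "linear", n_iter = 4000,
                     burn = 1000, prior_sd = 10, proposal_sd = 0.15,
                     seed = 1L) {
  ml <- zoib_fit(y, x, design = design)
  z <- if (design == "null") NULL else (x - ml$x_center) / ml$x_scale
  Z <- .zoib_design(z, design, length(y))
  pack <- unlist(ml$par[!vapply(ml$par, is.null, logical(1))])
  q <- ncol(Z)
  unpack <- function(par) {
    i <- 0
    g0 <- if (ml$has_zero) par[i + seq_len(q)] else NULL; if (ml$has_zero) i <- i + q
    g1 <- if (ml$has_one) par[i + seq_len(q)] else NULL; if (ml$has_one) i <- i + q
    list(gamma0 = g0, gamma1 = g1, beta = par[i + seq_len(q)],
         delta = par[i + q + 1])
  }
  lpost <- function(par) {
    p <- unpack(par)
    ll <- .zoib_ll(y, Z, p$gamma0, p$gamma1, p$beta, p$delta)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dnorm(par, 0, prior_sd, log = TRUE))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cur <- pack; lp_cur <- lpost(cur)
  keep <- matrix(NA_real_, n_iter - burn, length(pack))
  dev <- numeric(n_iter - burn)
  acc <- 0L
  for (it in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(length(cur), 0, proposal_sd)
    lp_prop <- lpost(prop)
    if (log(stats::runif(1)) < lp_prop - lp_cur) {
      cur <- prop; lp_cur <- lp_prop; acc <- acc + 1L
    }
    if (it > burn) {
      j <- it - burn
      keep[j, ] <- cur
      p <- unpack(cur)
      dev[j] <- -2 * .zoib_ll(y, Z, p$gamma0, p$gamma1, p$beta, p$delta)
    }
  }
  dbar <- mean(dev)
  pm <- unpack(colMeans(keep))
  d_at_mean <- -2 * .zoib_ll(y, Z, pm$gamma0, pm$gamma1, pm$beta, pm$delta)
  pd <- dbar - d_at_mean
  list(dic = dbar + pd, pd = pd, dbar = dbar, accept = acc / n_iter)
}
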