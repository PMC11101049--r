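# Binomial presence/absence GLM, adjusted D2, deviance chi-square test and
# three-condition BIC forward selection with variable substitution.

#' Fit a binomial (logit) presence/absence GLM
#'
#' Thin wrapper around [stats::glm.fit] that records everything the
#' selection and partitioning machinery needs: deviances, BIC
#' (`deviance + p * log(n)`, which equals `-2 loglik + p log n` for
#' Bernoulli data), convergence, and whether any fitted probability sits on
#' the boundary (numerically indistinguishable from 0 or 1, a symptom of
#' separation/overfitting).
#'
#' @param y 0/1 response vector.
#' @param X design matrix or data frame of predictors (no intercept column),
#'   or `NULL` for the intercept-only model.
#' @param eps boundary tolerance: the fit is flagged when any fitted
#'   probability is below `eps` or above `1 - eps`.
#' @return object of class `binom_fit`: list with `coefficients`, `fitted`,
#'   `deviance`, `null_deviance`, `n`, `p`, `bic`, `d2`, `adj_d2`,
#'   `converged`, `boundary`, `terms`.
#' @export
fit_binomial <- function(y, X = NULL, eps = 1e-10) {
  if (!all(y %in% c(0, 1))) stop("y must be a 0/1 vector")
  n <- length(y)
  if (is.null(X) || NCOL(X) == 0L) {
    xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    terms <- character(0)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != n) stop("X and y lengths differ")
    xm <- cbind("(Intercept)" = 1, X)
    terms <- colnames(X)
    qx <- qr(xm)
    if (qx$rank < ncol(xm)) {
      bad <- colnames(xm)[qx$pivot[(qx$rank + 1L):ncol(xm)]]
      stop("design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  p <- fit$rank
  dev <- fit$deviance
  nulldev <- fit$null.deviance
  d2 <- if (nulldev > 0) (nulldev - dev) / nulldev else 0
  structure(list(
    coefficients = fit$coefficients,
    fitted = fit$fitted.values,
    deviance = dev,
    null_deviance = nulldev,
    n = n, p = p,
    bic = dev + p * log(n),
    d2 = d2,
    adj_d2 = if (n > p) 1 - ((n - 1) / (n - p)) * (1 - d2) else NA_real_,
    converged = isTRUE(fit$converged),
    boundary = any(fit$fitted.values < eps | fit$fitted.values > 1 - eps),
    terms = terms
  ), class = "binom_fit")
}

#' Adjusted deviance (adj-D2) of a GLM fit
#'
#' Deviance analogue of adjusted R-squared:
#' `1 - ((n - 1) / (n - p)) * (1 - D2)`, penalising the number of estimated
#' coefficients `p`. Zero for the null model; may be negative.
#'
#' @param fit a `binom_fit`, or a raw `D2` value when `n` and `p` are given.
#' @param n,p sample size and coefficient count (only when `fit` is numeric).
#' @return adjusted D2 as a fraction.
#' @export
adjusted_d2 <- function(fit, n = NULL, p = NULL) {
  if (inherits(fit, "binom_fit")) {
    d2 <- fit$d2; n <- fit$n; p <- fit$p
  } else d2 <- fit
  if (n <= p) stop("adjusted D2 requires n > p")
  1 - ((n - 1) / (n - p)) * (1 - d2)
}

#' Chi-square test comparing two nested binomial fits
#'
#' Deviance-table test: the drop in residual deviance is referred to a
#' chi-square with degrees of freedom equal to the difference in coefficient
#' counts.
#'
#' @param fit_small,fit_big nested `binom_fit` objects on the same response
#'   (the smaller model's terms must be a subset of the larger's).
#' @return two-sided upper-tail p-value (1 when the models coincide).
#' @export
deviance_chisq <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "binom_fit"), inherits(fit_big, "binom_fit"))
  if (fit_small$n != fit_big$n) stop("fits are on different data")
  if (!all(fit_small$terms %in% fit_big$terms))
    stop("models are not nested: ",
         paste(setdiff(fit_small$terms, fit_big$terms), collapse = ", "),
         " absent from the larger model")
  df <- fit_big$p - fit_small$p
  stat <- max(fit_small$deviance - fit_big$deviance, 0)
  if (df <= 0) return(1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Forward selection of GLM predictors under three acceptance conditions
#'
#' At each step the remaining candidates are ranked by the BIC of the model
#' that includes them; walking down that list, a candidate is accepted when
#' (i) it lowers the current BIC, (ii) the deviance chi-square test against
#' the current model is significant at `alpha`, and (iii) the fit converges
#' without boundary fitted probabilities. A candidate failing only (iii) is
#' skipped and the next one on the BIC list considered (substitution rule);
#' a candidate failing (i) or (ii) stops the walk and the selection.
#' Fitting errors (e.g. collinearity with already-selected variables) count
#' as condition-(iii) failures. An empty selection is a valid result.
#'
#' @param y 0/1 response.
#' @param candidates data frame or matrix of candidate predictors with
#'   unique column names; column order breaks BIC ties.
#' @param alpha significance level for condition (ii) (default 0.05).
#' @param eps boundary tolerance passed to [fit_binomial()].
#' @return object of class `forward_selection`: list with `variables`
#'   (ordered accepted names), `fit` (final `binom_fit`), `steps` (per-step
#'   audit: candidate ranking with BIC, p-values and rejection reasons) and
#'   `alpha`.
#' @export
forward_select <- function(y, candidates, alpha = 0.05, eps = 1e-10) {
  candidates <- as.data.frame(candidates)
  nm <- names(candidates)
  if (anyDuplicated(nm)) stop("candidate names must be unique")
  cur <- character(0)
  cur_fit <- fit_binomial(y, NULL, eps = eps)
  steps <- list()
  repeat {
    rem <- setdiff(nm, cur)
    if (length(rem) == 0L) break
    evals <- lapply(rem, function(v) {
      tryCatch(fit_binomial(y, candidates[, c(cur, v), drop = FALSE], eps = eps),
               error = function(e) e)
    })
    bic <- vapply(evals, function(f)
      if (inherits(f, "binom_fit")) f$bic else Inf, numeric(1))
    ord <- order(bic, match(rem, nm))
    audit <- data.frame(candidate = rem[ord], bic = bic[ord],
                        p_value = NA_real_, reason = NA_character_,
                        stringsAsFactors = FALSE)
    accepted <- NULL
    for (k in seq_along(ord)) {
      f <- evals[[ord[k]]]
      if (!inherits(f, "binom_fit")) {
        audit$reason[k] <- paste0("fit_error: ", conditionMessage(f))
        next
      }
      if (!(f$bic < cur_fit$bic)) { audit$reason[k] <- "bic_not_lower"; break }
      pv <- deviance_chisq(cur_fit, f)
      audit$p_value[k] <- pv
      if (pv >= alpha) { audit$reason[k] <- "not_significant"; break }
      if (!f$converged) { audit$reason[k] <- "not_converged"; next }
      if (f$boundary) { audit$reason[k] <- "boundary_fit"; next }
      audit$reason[k] <- "accepted"
      accepted <- list(var = rem[ord[k]], fit = f)
      break
    }
    steps[[length(steps) + 1L]] <- audit
    if (is.null(accepted)) break
    cur <- c(cur, accepted$var)
    cur_fit <- accepted$fit
  }
  structure(list(variables = cur, fit = cur_fit, steps = steps, alpha = alpha),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  if (length(x$variables) == 0L) {
    cat("forward selection: no variable accepted (intercept-only)\n")
  } else {
    cat("forward selection:", paste(x$variables, collapse = " + "), "\n")
    cat(sprintf("final BIC %.3f, adj-D2 %.3f\n", x$fit$bic, x$fit$adj_d2))
  }
  invisible(x)
}
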