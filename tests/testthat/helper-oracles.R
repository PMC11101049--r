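# Independent oracles: deliberately naive implementations used only to
# check the package's results, never sharing code with them.

# exhaustive Kruskal: longest edge of a minimum spanning tree
oracle_mst_max <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  edges <- which(upper.tri(dm), arr.ind = TRUE)
  edges <- edges[order(dm[edges]), , drop = FALSE]
  comp <- seq_len(n)
  longest <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (comp[i] != comp[j]) {
      longest <- max(longest, dm[i, j])
      comp[comp == comp[j]] <- comp[i]
      if (length(unique(comp)) == 1L) break
    }
  }
  longest
}

# double-loop Moran's I
oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Newton-Raphson logistic regression (with intercept)
oracle_logit <- function(y, X, iter = 200) {
  X <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X))
  for (k in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    wt <- pmax(p * (1 - p), 1e-12)
    step <- solve(crossprod(X, X * wt), crossprod(X, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  names(b) <- c("(Intercept)", colnames(as.matrix(X))[-1])
  b
}

# breadth-first search connectivity of a binary graph
oracle_connected <- function(w) {
  n <- nrow(w)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# zoib density composed directly from mixture weights and dbeta
oracle_zoib_density <- function(y, p0, p1, mu, phi) {
  if (y == 0) return(p0)
  if (y == 1) return((1 - p0) * p1)
  (1 - p0) * (1 - p1) * stats::dbeta(y, mu * phi, (1 - mu) * phi)
}

# random scattered lake geometry for property tests
random_lakes <- function(n, seed, extent = c(200, 40)) {
  set.seed(seed)
  data.frame(lake_id = sprintf("s%02d", seq_len(n)),
             lat = 42.3 + runif(n, 0, extent[2] / 111),
             lon = -0.8 + runif(n, 0, extent[1] / 82),
             stringsAsFactors = FALSE)
}
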