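# Independent oracles used across the test suite. These deliberately use
# different algorithms/data structures from the package implementation.

# All-pairs shortest paths by exhaustive enumeration of simple paths.
# Exponential; only for graphs with <= 12 vertices.
enumerate_shortest_paths <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 12)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  recurse <- function(v, target, visited, len) {
    if (len >= best[visited[1], target]) return(invisible())
    if (v == target) {
      best[visited[1], target] <<- len
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!(u %in% visited) && is.finite(W[v, u])) {
        recurse(u, target, c(visited, u), len + W[v, u])
      }
    }
    invisible()
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) recurse(i, j, i, 0)
  }
  best
}

# Random sparse symmetric weight matrix (Inf for non-edges, 0 diagonal).
random_weight_graph <- function(n, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  W <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 0.1, 5)
  }
  diag(W) <- 0
  W
}

# Brute-force per-vertex nu-nearest-neighbour sets with index tie-breaking.
brute_knn_sets <- function(Z, nu) {
  dm <- as.matrix(dist(Z))
  n <- nrow(dm)
  lapply(seq_len(n), function(i) {
    ord <- order(dm[i, ], seq_len(n))
    setdiff(ord, i)[seq_len(nu)]
  })
}

# Optimal rigid alignment (rotation/reflection + translation) residual between
# two configurations, via the orthogonal Procrustes solution.
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  k <- min(ncol(X), ncol(Y))
  X <- X[, seq_len(k), drop = FALSE]
  Y <- Y[, seq_len(k), drop = FALSE]
  s <- svd(crossprod(X, Y))      # X'Y = U D V'
  R <- s$u %*% t(s$v)            # optimal rotation mapping X onto Y
  sc <- sum(s$d) / sum(X^2)      # least-squares scale
  sqrt(sum((Y - sc * X %*% R)^2) / nrow(X))
}

# One-way ANOVA F and p from first principles (sums of squares by hand).
brute_one_way_F <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

# Balanced two-way main-effect sums of squares by direct mean decomposition.
brute_two_way_ss <- function(y, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  grand <- mean(y)
  ss_a <- sum(tapply(y, a, function(v) length(v) * (mean(v) - grand)^2))
  ss_b <- sum(tapply(y, b, function(v) length(v) * (mean(v) - grand)^2))
  ss_tot <- sum((y - grand)^2)
  cell_means <- tapply(y, list(a, b), mean)
  ss_cells <- sum(table(a, b) * (cell_means - grand)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_tot = ss_tot,
       ss_inter = ss_cells - ss_a - ss_b,
       ss_resid = ss_tot - ss_cells)
}
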