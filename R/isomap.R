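# Pairwise Euclidean distances via the Gram-matrix identity
# |x - y|^2 = |x|^2 + |y|^2 - 2 x.y, so the O(n^2 d) work runs in BLAS.
# Tiny negative squared distances from cancellation are clamped to zero.
euclidean_distances <- function(Z) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  sq <- rowSums(Z * Z)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  dm
}

#' Build the nu-nearest-neighbour graph of a data matrix
#'
#' Each point is linked to its `nu` closest points in ambient Euclidean
#' distance; the edge set is the symmetric union of the per-vertex relations
#' (an edge exists if either endpoint is among the other's `nu` nearest).
#' Distance ties are broken by ascending row index, so the graph is
#' deterministic. Non-adjacent pairs are assigned weight `Inf`, preventing
#' shortest paths from jumping between branches of the underlying manifold.
#'
#' @param Z `n x d` numeric matrix (rows are points; for video, flattened
#'   frames in pixel space).
#' @param nu number of nearest neighbours, `1 <= nu < n`.
#' @return Object of class `neighbor_graph`: list with `weights` (`n x n`
#'   matrix, Euclidean distance for edges, 0 diagonal, `Inf` otherwise) and
#'   `nu`.
#' @export
build_knn_graph <- function(Z, nu) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  check_scalar(nu, "nu")
  if (nu < 1 || nu != round(nu)) stop("nu must be an integer >= 1")
  if (nu >= n) stop("nu must be smaller than the number of points (n = ", n, ")")
  dm <- euclidean_distances(Z)
  W <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))        # ties broken by ascending index
    nb <- setdiff(ord, i)[seq_len(nu)]
    W[i, nb] <- dm[i, nb]
  }
  W <- pmin(W, t(W))                          # union symmetrisation
  diag(W) <- 0
  structure(list(weights = W, nu = as.integer(nu)), class = "neighbor_graph")
}

#' Geodesic (shortest-path) distance matrix of a neighbour graph
#'
#' All-pairs shortest-path lengths along the weighted graph, approximating
#' on-manifold geodesic distances. `"floyd"` runs Floyd–Warshall (the
#' reference solver); `"dijkstra"` runs a binary-heap Dijkstra from every
#' source, which is much faster on sparse neighbour graphs and agrees with
#' Floyd–Warshall to numerical precision. Vertices in different connected
#' components are at distance `Inf`.
#'
#' @param graph a [build_knn_graph()] result.
#' @param method `"dijkstra"` (default) or `"floyd"`.
#' @return `n x n` matrix of geodesic distances.
#' @export
geodesic_matrix <- function(graph, method = c("dijkstra", "floyd")) {
  stopifnot(inherits(graph, "neighbor_graph"))
  method <- match.arg(method)
  W <- graph$weights
  if (method == "floyd") floyd_warshall_cpp(W) else dijkstra_all_cpp(W)
}

#' Restrict a neighbour graph to its largest connected component
#'
#' ISOMAP is undefined across disconnected components (their geodesic
#' distance is infinite), so the embedding is computed on the largest
#' component. Component-size ties are broken in favour of the component
#' containing the lowest-index vertex. If the retained fraction falls below
#' `min_fraction` the data are declared too sparse for the chosen `nu`.
#'
#' @param graph a `neighbor_graph`.
#' @param min_fraction minimum tolerated fraction of retained vertices.
#' @return List with `graph` (induced subgraph) and `retained` (original
#'   indices of the kept vertices, ascending).
#' @export
largest_component <- function(graph, min_fraction = 0.90) {
  stopifnot(inherits(graph, "neighbor_graph"))
  W <- graph$weights
  n <- nrow(W)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(is.finite(W[v, ]) & comp == 0L)
      nb <- nb[nb != v]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))[1]       # ties: lowest-index component
  keep <- which(comp == best)
  frac <- length(keep) / n
  if (frac < min_fraction) {
    stop(sprintf(
      "largest connected component retains only %.1f%% of points (< %.0f%%): data too sparse for nu-NN graph",
      100 * frac, 100 * min_fraction))
  }
  sub <- structure(list(weights = W[keep, keep, drop = FALSE], nu = graph$nu),
                   class = "neighbor_graph")
  list(graph = sub, retained = keep)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centres the squared distances (`B = -1/2 J D^2 J`), takes the
#' eigendecomposition, and returns coordinates `v_k sqrt(lambda_k)` for the
#' `d_max` largest eigenvalues in descending order. Negative eigenvalues
#' (non-Euclidean distances) contribute zero coordinates. Each coordinate
#' column's sign is fixed so that its largest-magnitude entry is positive,
#' making embeddings reproducible across runs and linear-algebra backends.
#'
#' @param D `n x n` finite symmetric distance matrix (run
#'   [largest_component()] first if the graph may be disconnected).
#' @param d_max number of embedding coordinates to return.
#' @return `n x d_max` coordinate matrix with attribute `"eigenvalues"`.
#' @export
classical_mds <- function(D, d_max) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!all(is.finite(D))) {
    stop("D contains non-finite entries; extract the largest connected component first")
  }
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  check_scalar(d_max, "d_max")
  if (d_max < 1 || d_max != round(d_max)) stop("d_max must be an integer >= 1")
  d_max <- min(as.integer(d_max), n)
  D2 <- D * D
  # double centering without forming J explicitly
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (sweep(sweep(D2, 1, rm_), 2, rm_) + gm)
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values[seq_len(d_max)]
  V <- e$vectors[, seq_len(d_max), drop = FALSE]
  scale <- sqrt(pmax(lam, 0))
  X <- sweep(V, 2, scale, "*")
  for (j in seq_len(ncol(X))) {
    k <- which.max(abs(X[, j]))
    if (X[k, j] < 0) X[, j] <- -X[, j]
  }
  attr(X, "eigenvalues") <- e$values
  X
}

#' Residual variances of nested MDS embeddings
#'
#' `R(d) = 1 - rho^2`, where `rho` is the Pearson correlation between the
#' geodesic distances (upper triangle of `D`) and the pairwise Euclidean
#' distances of the first `d` embedding coordinates. `R(d) = 0` means the
#' d-dimensional embedding reproduces the geodesics perfectly; `R(d) = 1` is
#' the worst approximation. The proportion of geodesic structure left
#' unexplained decreases as coordinates are added.
#'
#' @param D `n x n` geodesic distance matrix.
#' @param coordinates `n x d_max` nested MDS coordinates.
#' @return Numeric vector `R(1..d_max)`.
#' @export
residual_variances <- function(D, coordinates) {
  D <- as.matrix(D)
  X <- as.matrix(coordinates)
  if (nrow(D) != nrow(X)) stop("D and coordinates must have matching rows")
  ut <- upper.tri(D)
  g <- D[ut]
  if (sd(g) == 0) {
    warning("geodesic distances are constant; residual variances set to 1")
    return(rep(1, ncol(X)))
  }
  R <- numeric(ncol(X))
  # accumulate squared embedding distances one coordinate at a time
  acc <- matrix(0, nrow(X), nrow(X))
  for (d in seq_len(ncol(X))) {
    acc <- acc + outer(X[, d], X[, d], "-")^2
    emb <- sqrt(acc[ut])
    if (sd(emb) == 0) {
      warning("embedding distances constant at d = ", d, "; R(d) set to 1")
      R[d] <- 1
    } else {
      R[d] <- 1 - cor(g, emb)^2
    }
  }
  R
}

#' Embedding-manifold dimensionality from the residual-variance curve
#'
#' The dimensionality is the smallest `d` with `R(d) < threshold`
#' (0.05 by default). If no inspected dimension passes, the trial is
#' censored: the returned integer is `d_max + 1` with attribute
#' `censored = TRUE`, the value such trials carry into downstream statistics
#' (12 for the default `d_max = 11`, the top of the observer CBM scale).
#'
#' @param R numeric vector of residual variances `R(1..d_max)`.
#' @param threshold acceptance threshold on `R(d)`.
#' @param d_max number of inspected dimensions (defaults to `length(R)`).
#' @return Integer dimensionality, with attribute `censored`.
#' @seealso [is_censored()]
#' @export
embedding_dimensionality <- function(R, threshold = 0.05, d_max = length(R)) {
  if (length(R) < 1L) stop("R must be non-empty")
  if (any(R < -1e-12) || any(R > 1 + 1e-12)) stop("residual variances must lie in [0, 1]")
  d_max <- min(as.integer(d_max), length(R))
  hit <- which(R[seq_len(d_max)] < threshold)
  if (length(hit)) {
    structure(as.integer(hit[1]), censored = FALSE)
  } else {
    structure(as.integer(d_max + 1L), censored = TRUE)
  }
}

#' Is a dimensionality estimate censored?
#'
#' @param d a result of [embedding_dimensionality()] (or an `isomap` result's
#'   `dimensionality` field).
#' @return Logical.
#' @export
is_censored <- function(d) isTRUE(attr(d, "censored"))

#' ISOMAP embedding and dimensionality estimate
#'
#' The full isometric-mapping pipeline on a data matrix: build the
#' `nu`-nearest-neighbour graph, keep the largest connected component,
#' compute graph geodesic distances, embed with classical MDS, compute the
#' residual-variance curve `R(1..d_max)` and read off the manifold
#' dimensionality as the smallest `d` with `R(d) < threshold`. Defaults
#' (`nu = 11`, `d_max = 11`, `threshold = 0.05`) match the video analysis;
#' the estimated dimensionality is insensitive to `nu` over roughly 7..15.
#'
#' @param Z `n x d` matrix (rows are points, e.g. flattened video frames), or
#'   a [frame_stack()].
#' @param nu number of nearest neighbours.
#' @param d_max maximum embedding dimension inspected.
#' @param threshold residual-variance threshold defining the dimensionality.
#' @param geodesic shortest-path solver, `"dijkstra"` or `"floyd"`.
#' @param min_fraction minimum fraction of points retained in the largest
#'   component.
#' @return Object of class `isomap_embedding`: list with `coordinates`
#'   (`n_kept x d_max`), `residuals` (`R(1..d_max)`), `dimensionality`
#'   (integer, see [embedding_dimensionality()]), `eigenvalues`, `retained`
#'   (kept row indices), `retained_fraction`, `n`, `nu`, `d_max`,
#'   `threshold`.
#' @examples
#' cloud <- make_manifold_cloud("plane", n = 120, ambient_dim = 10, seed = 3)
#' emb <- isomap(cloud$points, nu = 8, d_max = 5)
#' emb$dimensionality   # 2
#' @export
isomap <- function(Z, nu = 11, d_max = 11, threshold = 0.05,
                   geodesic = c("dijkstra", "floyd"), min_fraction = 0.90) {
  if (inherits(Z, "frame_stack")) Z <- Z$data
  Z <- as.matrix(Z)
  geodesic <- match.arg(geodesic)
  g <- build_knn_graph(Z, nu)
  lc <- largest_component(g, min_fraction = min_fraction)
  D <- geodesic_matrix(lc$graph, method = geodesic)
  X <- classical_mds(D, d_max)
  R <- residual_variances(D, X)
  dim_hat <- embedding_dimensionality(R, threshold = threshold, d_max = d_max)
  structure(list(
    coordinates = X, residuals = R, dimensionality = dim_hat,
    eigenvalues = attr(X, "eigenvalues"), retained = lc$retained,
    retained_fraction = length(lc$retained) / nrow(Z),
    n = nrow(Z), nu = as.integer(nu), d_max = as.integer(d_max),
    threshold = threshold
  ), class = "isomap_embedding")
}

#' @export
print.isomap_embedding <- function(x, ...) {
  cat("ISOMAP embedding of", x$n, "points (nu =", x$nu,
      ", retained", sprintf("%.1f%%", 100 * x$retained_fraction), ")\n")
  cat("Residual variances R(1..", x$d_max, "): ",
      paste(sprintf("%.3f", x$residuals), collapse = " "), "\n", sep = "")
  if (is_censored(x$dimensionality)) {
    cat("Dimensionality: censored (R(d) >= ", x$threshold, " for all d <= ",
        x$d_max, "); recorded as ", as.integer(x$dimensionality), "\n", sep = "")
  } else {
    cat("Dimensionality:", as.integer(x$dimensionality),
        sprintf("(R(%d) = %.3f < %.2f)", as.integer(x$dimensionality),
                x$residuals[as.integer(x$dimensionality)], x$threshold), "\n")
  }
  invisible(x)
}

#' Scree plot of residual variances
#'
#' @param x an `isomap_embedding`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.isomap_embedding <- function(x, ...) {
  graphics::plot(seq_along(x$residuals), x$residuals, type = "b", pch = 19,
                 xlab = "embedding dimension d", ylab = "residual variance R(d)",
                 ylim = c(0, max(x$residuals, 0.1)), ...)
  graphics::abline(h = x$threshold, lty = 2)
}

#' Write an ISOMAP embedding to disk
#'
#' Persists the coordinates and residual-variance curve as CSV and a one-line
#' JSON summary (`n`, `nu`, `d_max`, `threshold`, `dimensionality`,
#' `censored`, `retained_fraction`).
#'
#' @param embedding an `isomap_embedding`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_embedding <- function(embedding, dir, prefix = "embedding") {
  stopifnot(inherits(embedding, "isomap_embedding"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fc <- file.path(dir, paste0(prefix, "_coordinates.csv"))
  fr <- file.path(dir, paste0(prefix, "_residuals.csv"))
  fj <- file.path(dir, paste0(prefix, "_summary.json"))
  write.csv(as.data.frame(embedding$coordinates), fc, row.names = FALSE)
  write.csv(data.frame(d = seq_along(embedding$residuals),
                       R = embedding$residuals), fr, row.names = FALSE)
  summary <- list(n = embedding$n, nu = embedding$nu, d_max = embedding$d_max,
                  threshold = embedding$threshold,
                  dimensionality = as.integer(embedding$dimensionality),
                  censored = is_censored(embedding$dimensionality),
                  retained_fraction = embedding$retained_fraction)
  jsonlite::write_json(summary, fj, auto_unbox = TRUE, digits = NA)
  invisible(c(coordinates = fc, residuals = fr, summary = fj))
}
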