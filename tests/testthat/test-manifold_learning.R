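test_that("knn graph matches brute-force neighbour enumeration", {
  set.seed(17)
  Z <- matrix(runif(60), 30, 2)
  g <- build_knn_graph(Z, 4)
  sets <- brute_knn_sets(Z, 4)
  dm <- as.matrix(dist(Z))
  for (i in 1:30) {
    expected <- sort(unique(c(sets[[i]], which(vapply(sets, function(s) i %in% s, TRUE)))))
    expected <- setdiff(expected, i)
    got <- which(is.finite(g$weights[i, ]) & seq_len(30) != i)
    expect_equal(got, expected)
    expect_equal(g$weights[i, got], dm[i, got], ignore_attr = TRUE, tolerance = 1e-6)
  }
  expect_true(isSymmetric(g$weights))
  expect_equal(diag(g$weights), rep(0, 30))
})

test_that("knn graph degenerate cases: collinear points and complete graph", {
  Z <- cbind(c(0, 1, 2, 3, 4), 0)
  g1 <- build_knn_graph(Z, 1)
  # interior points gain both neighbours by union symmetrisation
  expect_true(is.finite(g1$weights[2, 1]) && is.finite(g1$weights[2, 3]))
  expect_true(is.finite(g1$weights[3, 2]))
  # ties at distance 1 broken by ascending index: vertex 3 links left first
  expect_equal(which(is.finite(g1$weights[1, ])), c(1L, 2L))

  gfull <- build_knn_graph(Z, 4)
  expect_true(all(is.finite(gfull$weights)))
  expect_equal(gfull$weights, as.matrix(dist(Z)), ignore_attr = TRUE)
  expect_error(build_knn_graph(Z, 5), "smaller")
})

test_that("geodesic distances match exhaustive path enumeration on small graphs", {
  # hand-built path graph: D(1,3) = 2 through the middle vertex
  W <- matrix(Inf, 3, 3); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  g <- structure(list(weights = W, nu = 1L), class = "neighbor_graph")
  expect_equal(geodesic_matrix(g, "floyd")[1, 3], 2)

  # disconnected singletons stay at infinity
  W2 <- matrix(Inf, 2, 2); diag(W2) <- 0
  g2 <- structure(list(weights = W2, nu = 1L), class = "neighbor_graph")
  expect_equal(geodesic_matrix(g2, "floyd")[1, 2], Inf)

  for (seed in 1:6) {
    W <- random_weight_graph(sample(6:12, 1), p_edge = 0.4, seed = seed)
    g <- structure(list(weights = W, nu = 1L), class = "neighbor_graph")
    expect_equal(geodesic_matrix(g, "floyd"), enumerate_shortest_paths(W))
  }
})

test_that("Dijkstra agrees with Floyd-Warshall on random graphs", {
  for (seed in 1:100) {
    W <- random_weight_graph(25, p_edge = 0.2, seed = 1000 + seed)
    g <- structure(list(weights = W, nu = 1L), class = "neighbor_graph")
    expect_lt(max(abs(geodesic_matrix(g, "dijkstra") - geodesic_matrix(g, "floyd")),
                  na.rm = TRUE), 1e-9)
  }
})

test_that("geodesic matrices dominate ambient chords and satisfy the triangle inequality", {
  set.seed(2)
  Z <- matrix(rnorm(40), 20, 2)
  g <- build_knn_graph(Z, 5)
  D <- geodesic_matrix(g)
  amb <- as.matrix(dist(Z))
  fin <- is.finite(D)
  expect_true(all(D[fin] >= amb[fin] - 1e-9))
  for (k in 1:20) {
    expect_true(all(D <= outer(D[, k], D[k, ], "+") + 1e-9))
  }
})

test_that("largest component retains the majority and honours tie rules", {
  # components {1..7} and {8..10}
  W <- matrix(Inf, 10, 10); diag(W) <- 0
  for (i in 1:6) W[i, i + 1] <- W[i + 1, i] <- 1
  for (i in 8:9) W[i, i + 1] <- W[i + 1, i] <- 1
  g <- structure(list(weights = W, nu = 1L), class = "neighbor_graph")
  lc <- largest_component(g, min_fraction = 0.5)
  expect_equal(lc$retained, 1:7)

  # tie in sizes: the component containing vertex 1 wins
  W2 <- matrix(Inf, 4, 4); diag(W2) <- 0
  W2[1, 2] <- W2[2, 1] <- 1; W2[3, 4] <- W2[4, 3] <- 1
  g2 <- structure(list(weights = W2, nu = 1L), class = "neighbor_graph")
  expect_equal(largest_component(g2, min_fraction = 0.4)$retained, 1:2)

  expect_error(largest_component(g, min_fraction = 0.95), "too sparse")
  gc <- build_knn_graph(matrix(rnorm(30), 15, 2), 4)
  expect_equal(largest_component(gc)$retained, 1:15)  # connected: identity
})

test_that("classical MDS reproduces planar configurations exactly", {
  # two points at distance 2 split symmetrically
  D <- matrix(c(0, 2, 2, 0), 2, 2)
  X <- classical_mds(D, 1)
  expect_equal(sort(X[, 1]), c(-1, 1))

  set.seed(8)
  P <- matrix(runif(20), 10, 2)
  D <- as.matrix(dist(P))
  X <- classical_mds(D, 2)
  expect_lt(max(abs(as.matrix(dist(X)) - D)), 1e-8)   # distances reproduced
  expect_lt(procrustes_residual(P, X), 1e-8)          # rigid match to original
  ev <- attr(X, "eigenvalues")
  expect_lt(max(abs(ev[3:10])), 1e-8)                 # planar: rank 2

  # collinear points: single positive eigenvalue
  line <- cbind(seq(0, 5, length.out = 8), 1)
  evl <- attr(classical_mds(as.matrix(dist(line)), 3), "eigenvalues")
  expect_gt(evl[1], 0)
  expect_lt(max(abs(evl[-1])), 1e-8)

  expect_error(classical_mds(matrix(c(0, Inf, Inf, 0), 2, 2), 1), "non-finite")
})

test_that("MDS agrees with the base cmdscale oracle up to sign convention", {
  set.seed(12)
  P <- matrix(rnorm(36), 12, 3)
  D <- as.matrix(dist(P))
  X <- classical_mds(D, 3)
  ref <- cmdscale(D, k = 3)
  for (j in 1:3) {
    expect_true(max(abs(X[, j] - ref[, j])) < 1e-8 ||
                max(abs(X[, j] + ref[, j])) < 1e-8)
    k <- which.max(abs(X[, j]))
    expect_gte(X[k, j], 0)                            # documented sign fix
  }
})

test_that("residual variances are 1 - rho^2 against an independent correlation", {
  set.seed(3)
  P <- matrix(runif(30), 15, 2)
  D <- as.matrix(dist(P))
  X <- classical_mds(D, 4)
  R <- residual_variances(D, X)
  expect_true(all(R >= -1e-12 & R <= 1 + 1e-12))
  expect_lt(R[2], 1e-10)                              # exact planar embedding
  # independent oracle: direct correlation on the upper triangle at d = 1
  ut <- upper.tri(D)
  e1 <- as.matrix(dist(X[, 1]))[ut]
  expect_equal(R[1], 1 - cor(D[ut], e1)^2, tolerance = 1e-12)
  # scree is non-increasing on this fixture
  expect_true(all(diff(R) <= 1e-9))
})

test_that("constant distances yield residual 1 with a warning", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  X <- matrix(0, 4, 2)
  expect_warning(R <- residual_variances(D * 0, X), "constant")
  expect_equal(R, c(1, 1))
})

test_that("dimensionality is the first threshold crossing, censored otherwise", {
  d1 <- embedding_dimensionality(c(0.31, 0.04, 0.03), threshold = 0.05)
  expect_equal(as.integer(d1), 2L)
  expect_false(is_censored(d1))

  d2 <- embedding_dimensionality(rep(0.2, 11), threshold = 0.05)
  expect_equal(as.integer(d2), 12L)
  expect_true(is_censored(d2))

  expect_equal(as.integer(embedding_dimensionality(c(0, 0.5))), 1L)
  expect_error(embedding_dimensionality(numeric(0)), "non-empty")
  expect_error(embedding_dimensionality(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("isomap recovers known intrinsic dimensions", {
  li <- make_manifold_cloud("line", n = 200, ambient_dim = 5, seed = 4)
  expect_equal(as.integer(isomap(li$points, nu = 11)$dimensionality), 1L)

  pl <- make_manifold_cloud("plane", n = 400, ambient_dim = 100, seed = 2)
  e_pl <- isomap(pl$points, nu = 11)
  expect_equal(as.integer(e_pl$dimensionality), 2L)
  expect_equal(e_pl$retained_fraction, 1)
})

test_that("swiss roll embeds at dimension 2, stable over the nu range", {
  sw <- make_manifold_cloud("swiss_roll", n = 1000, seed = 3)
  dims <- sapply(c(7, 9, 11, 13, 15), function(nu) {
    as.integer(isomap(sw$points, nu = nu)$dimensionality)
  })
  expect_true(all(dims == 2L))
})

test_that("swiss roll dimensionality matches an independent reference implementation", {
  skip_if_not_installed("vegan")
  sw <- make_manifold_cloud("swiss_roll", n = 600, seed = 6)
  mine <- isomap(sw$points, nu = 11, d_max = 5)
  # reference: vegan geodesics + base cmdscale, residuals computed directly
  Dv <- as.matrix(vegan::isomapdist(dist(sw$points), k = 11))
  Xv <- cmdscale(Dv, k = 5)
  ut <- upper.tri(Dv)
  Rv <- sapply(1:5, function(d) {
    1 - cor(Dv[ut], as.matrix(dist(Xv[, 1:d, drop = FALSE]))[ut])^2
  })
  expect_equal(mine$residuals, Rv, tolerance = 1e-6)
  expect_equal(as.integer(mine$dimensionality),
               which(Rv < 0.05)[1])
})

test_that("isomap dimensionality is invariant under rigid motions of the cloud", {
  pl <- make_manifold_cloud("plane", n = 150, ambient_dim = 6, seed = 9)
  base <- isomap(pl$points, nu = 8, d_max = 5)
  set.seed(10)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  moved <- sweep(pl$points %*% Q, 2, runif(6, -5, 5), "+")
  rot <- isomap(moved, nu = 8, d_max = 5)
  expect_equal(as.integer(base$dimensionality), as.integer(rot$dimensionality))
  expect_equal(base$residuals, rot$residuals, tolerance = 1e-8)
})

test_that("line clouds have chordal geodesics and exact 1-D structure", {
  li <- make_manifold_cloud("line", n = 50, ambient_dim = 4, seed = 5)
  D_euc <- as.matrix(dist(li$points))
  arc <- abs(outer(li$latent, li$latent, "-"))
  expect_equal(D_euc, arc, tolerance = 1e-9, ignore_attr = TRUE)
  # centred point matrix has rank 1
  s <- svd(scale(li$points, scale = FALSE))$d
  expect_lt(s[2] / s[1], 1e-10)
})

test_that("embedding files round-trip through CSV and JSON", {
  pl <- make_manifold_cloud("plane", n = 60, ambient_dim = 4, seed = 13)
  e <- isomap(pl$points, nu = 6, d_max = 4)
  dir <- withr::local_tempdir()
  files <- write_embedding(e, dir)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(files[["summary"]])
  expect_equal(js$dimensionality, as.integer(e$dimensionality))
  expect_equal(js$nu, 6L)
  back <- as.matrix(read.csv(files[["coordinates"]]))
  expect_equal(unname(back), unname(e$coordinates), tolerance = 1e-12,
               ignore_attr = TRUE)
})
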