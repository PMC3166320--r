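pairNet <- interactionNetwork(
  data.frame(gene_a = "A", gene_b = "B", weight = 1))
triNet <- interactionNetwork(
  data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
             weight = 1))

test_that("maxPhi equals the reciprocal spectral radius", {
  expect_equal(maxPhi(pairNet), 1.0)
  expect_equal(maxPhi(triNet), 0.5, tolerance = 1e-9)
  # dense eigendecomposition oracle on random weighted graphs
  for (seed in 1:5) {
    net <- randomNetwork(10, p = 0.4, seed = seed)
    rho <- max(abs(eigen(as.matrix(weightMatrix(net)),
                         symmetric = TRUE)$values))
    expect_equal(maxPhi(net), 1 / rho, tolerance = 1e-8)
  }
  # edgeless network: unbounded phi
  lonely <- new("InteractionNetwork", genes = c("A", "B"),
                weights = Matrix::sparseMatrix(i = integer(), j = integer(),
                                               x = numeric(), dims = c(2, 2)))
  expect_equal(maxPhi(lonely), Inf)
})

test_that("solveScores matches closed forms and the dense oracle", {
  s <- scoreValues(solveScores(pairNet, c(A = 0.5, B = 0), phi = 0, eta = 2))
  expect_equal(unname(s), c(2, 1))
  # (I - 0.5 W)^-1 d on the unit 2-node graph: s = (2, 2)
  s <- scoreValues(solveScores(pairNet, NULL, phi = 0.5, eta = 0))
  expect_equal(unname(s), c(2, 2))
  # Jacobi vs dense direct solve on a random 20-node instance
  net <- randomNetwork(20, p = 0.25, seed = 99)
  set.seed(100)
  x <- setNames(runif(20), genes(net))
  phi <- 0.8 * maxPhi(net)
  sv <- solveScores(net, x, phi = phi, eta = 5)
  expect_lt(max(abs(scoreValues(sv) - denseScoreOracle(net, x, phi, 5))),
            1e-8)
  expect_gt(sv@iterations, 1)
  expect_lt(sv@residual, 1e-10)
})

test_that("phi at or above the spectral bound is rejected before iterating", {
  expect_error(solveScores(pairNet, NULL, phi = 1, eta = 0), "maxPhi")
  expect_error(solveScores(pairNet, NULL, phi = 1.7, eta = 0), "maxPhi")
})

test_that("known-gene scores follow the x1 + x2 construction", {
  # phi = 0: s1 is exactly x1 + x2
  x <- c(A = 1, B = 0, C = 0.5)
  s1 <- scoreValues(solveScoresWithKnown(triNet, x, known = "B",
                                         phi = 0, eta = 2))
  x1 <- (1 + 2 * x) / max(1 + 2 * x)
  expect_equal(unname(s1), unname(x1 + c(0, 1, 0)))

  # empty known set with eta = 0 reduces to the plain score with eta = 0
  expect_warning(
    s0 <- solveScoresWithKnown(triNet, NULL, known = character(),
                               phi = 0.3, eta = 0),
    "empty known-gene set")
  plain <- solveScores(triNet, NULL, phi = 0.3, eta = 0)
  expect_equal(scoreValues(s0), scoreValues(plain))

  # known genes absent from the network are dropped with a warning
  expect_warning(solveScoresWithKnown(triNet, NULL, known = c("A", "ZZ"),
                                      phi = 0, eta = 0), "ZZ")

  # sum-normalization alternative
  sSum <- scoreValues(solveScoresWithKnown(triNet, x, known = "B", phi = 0,
                                           eta = 2, normalize = "sum"))
  x1s <- (1 + 2 * x) / sum(1 + 2 * x)
  expect_equal(unname(sSum), unname(x1s + c(0, 1, 0)))
})

test_that("seeding a known gene lifts its direct neighbors (dense oracle)", {
  net <- randomNetwork(15, p = 0.2, seed = 7)
  phi <- 0.2 * maxPhi(net)
  known <- genes(net)[1]
  s1 <- scoreValues(solveScoresWithKnown(net, NULL, known = known,
                                         phi = phi, eta = 0))
  base <- scoreValues(suppressWarnings(
    solveScoresWithKnown(net, NULL, known = character(),
                         phi = phi, eta = 0)))
  # oracle: the lift is the known gene's column of the dense inverse
  w <- as.matrix(weightMatrix(net))
  lift <- solve(diag(15) - phi * w)[, 1]
  expect_equal(unname(s1 - base), unname(lift), tolerance = 1e-8)
  nb <- which(w[, 1] > 0)
  far <- setdiff(which(w[, 1] == 0), 1)
  # at small phi, first-order propagation dominates: direct neighbors of
  # the seeded gene gain strictly more than non-neighbors
  expect_gt(min((s1 - base)[nb]), max((s1 - base)[far]))
})

test_that("score vectors combine elementwise and reject mismatched universes", {
  sv <- solveScores(triNet, NULL, phi = 0.1, eta = 0)
  expect_equal(scoreValues(combineScores(list(sv))), scoreValues(sv))
  two <- combineScores(list(sv, sv))
  expect_equal(scoreValues(two), 2 * scoreValues(sv))
  three <- combineScores(list(sv, sv, sv))
  expect_equal(scoreValues(three), 3 * scoreValues(sv))
  other <- solveScores(pairNet, NULL, phi = 0, eta = 0)
  expect_error(combineScores(list(sv, other)), "symmetric difference")
})

test_that("ranking reduces to classical Katz centrality in the eta -> Inf limit", {
  for (seed in 1:5) {
    net <- randomNetwork(12, p = 0.3, seed = seed, binary = TRUE)
    phi <- 0.5 * maxPhi(net)
    xd <- setNames(rep(1, 12), genes(net))
    # with x = d the score is (1 + eta) (I - phi W)^-1 d for every eta, so
    # the ranking already equals its eta -> Inf limit
    s <- scoreValues(solveScores(net, xd, phi = phi, eta = 5))
    # independent oracle: truncated walk series sum_k phi^k W^k 1
    w <- as.matrix(weightMatrix(net))
    v <- rep(1, 12); katz <- numeric(12)
    for (k in 1:200) { v <- phi * (w %*% v); katz <- katz + v }
    expect_equal(rank(-s), rank(-katz), ignore_attr = TRUE)
  }
})

test_that("alpha centrality agrees with the solver on an unweighted graph", {
  skip_if_not_installed("igraph")
  net <- randomNetwork(10, p = 0.35, seed = 21, binary = TRUE)
  phi <- 0.4 * maxPhi(net)
  g <- igraph::graph_from_adjacency_matrix(
    as.matrix(weightMatrix(net)), mode = "undirected")
  ac <- igraph::alpha_centrality(g, alpha = phi, exo = 1)
  s <- scoreValues(solveScores(net, NULL, phi = phi, eta = 0))
  expect_equal(unname(s), unname(ac), tolerance = 1e-7)
})

test_that("score invariants hold: floor, monotonicity, eta affinity, equivariance", {
  set.seed(5)
  for (seed in 1:5) {
    net <- randomNetwork(15, p = 0.25, seed = seed)
    gn <- genes(net)
    x <- setNames(runif(15), gn)
    phi <- 0.7 * maxPhi(net)
    s <- scoreValues(solveScores(net, x, phi = phi, eta = 3))
    expect_true(all(s >= 1))                        # floor at delta = 1
    # raising one activity never lowers any score
    x2 <- x; x2[4] <- x2[4] + 1
    s2 <- scoreValues(solveScores(net, x2, phi = phi, eta = 3))
    expect_true(all(s2 >= s - 1e-12))
    # s(eta) - s(0) is linear in eta
    s0 <- scoreValues(solveScores(net, x, phi = phi, eta = 0))
    s1 <- scoreValues(solveScores(net, x, phi = phi, eta = 1))
    s6 <- scoreValues(solveScores(net, x, phi = phi, eta = 6))
    expect_equal(s6 - s0, 6 * (s1 - s0), tolerance = 1e-6)
    # permutation equivariance under gene relabeling
    perm <- sample(15)
    wperm <- as.matrix(weightMatrix(net))[perm, perm]
    pn <- gn[perm]
    ia <- which(upper.tri(wperm) & wperm > 0, arr.ind = TRUE)
    netP <- interactionNetwork(
      data.frame(gene_a = pn[ia[, 1]], gene_b = pn[ia[, 2]],
                 weight = wperm[ia]), genes = pn)
    sP <- scoreValues(solveScores(netP, x[pn], phi = phi, eta = 3))
    expect_equal(sP, s[pn], tolerance = 1e-8)
  }
})
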