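pathGraph3 <- function() {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  adjToNetworkGraph(adj, c("a", "b", "c"))
}

test_that("region correlation matrix recovers planted structure", {
  sp <- singleNetworkPhantom(200, rngSeed = 17, grid = c(8L, 8L, 8L))
  # two regions on the same latent network, a = 1, noise sd 1:
  # region means average noise down, population r close to
  # (1)/(sqrt(1 + 1/m)) per region pair
  scans <- simulateBold(sp)
  atlas <- atlasFromSpec(sp)
  cm <- regionCorrelationMatrix(scans, atlas)
  v <- corValues(cm)
  expect_equal(diag(v), c(seed = 1, target = 1))
  expect_equal(v, t(v))
  m1 <- nrow(sp@regions[[1]]@voxels); m2 <- nrow(sp@regions[[2]]@voxels)
  rho <- 1 / (sqrt(1 + 1 / m1) * sqrt(1 + 1 / m2))
  expect_equal(v["seed", "target"], rho, tolerance = 0.05 / rho)
  expect_equal(cm@nSubjects, 200L)
})

test_that("two-block phantom separates within- from between-block r", {
  nets <- list(networkSpec("n1"), networkSpec("n2"))
  regs <- list(
    regionSpec("a1", voxelCube(1L, 1L, 1L, 2L), c(n1 = 1)),
    regionSpec("a2", voxelCube(5L, 1L, 1L, 2L), c(n1 = 1)),
    regionSpec("b1", voxelCube(1L, 5L, 1L, 2L), c(n2 = 1)),
    regionSpec("b2", voxelCube(5L, 5L, 1L, 2L), c(n2 = 1)))
  sp <- phantomSpec(c(8L, 8L, 4L), 40, regions = regs, networks = nets,
                    rngSeed = 23)
  cm <- regionCorrelationMatrix(simulateBold(sp), atlasFromSpec(sp))
  v <- corValues(cm)
  within <- c(v["a1", "a2"], v["b1", "b2"])
  between <- c(v["a1", "b1"], v["a1", "b2"], v["a2", "b1"], v["a2", "b2"])
  expect_gt(mean(within), mean(between) + 0.3)
})

test_that("zero-variance regions contribute r = 0 and are flagged", {
  d <- array(rnorm(4 * 4 * 4 * 16), dim = c(4, 4, 4, 16))
  d[1, 1, 1, ] <- 2                      # constant region
  scans <- list(boldScan(d, gridAffine(), 3),
                boldScan(d + rnorm(length(d)), gridAffine(), 3))
  m1 <- array(FALSE, dim = c(4, 4, 4)); m1[1, 1, 1] <- TRUE
  m2 <- array(FALSE, dim = c(4, 4, 4)); m2[3, 3, 3] <- TRUE
  atlas <- nodeAtlas(c("flat", "noise"), list(m1, m2), rep("seed", 2))
  cm <- regionCorrelationMatrix(scans, atlas)
  expect_gte(qcFlags(cm)$zero_variance_region_subjects, 1)
  expect_true(all(is.finite(corValues(cm))))
  # the flat subject contributes z = 0, so |pooled r| is at most
  # tanh(z_max / 2) where z_max comes from the one informative subject
  expect_lte(abs(corValues(cm)["flat", "noise"]), 1)
})

test_that("hierarchical clustering cuts are exact at the extremes", {
  set.seed(31)
  n <- 6
  v <- cov2cor(crossprod(matrix(rnorm(n * n * 4), ncol = n)))
  cm <- new("CorrelationMatrix", labels = letters[1:n], values = v,
            nSubjects = 10L, qc = list())
  singletons <- hierarchicalCluster(cm, k = n)
  expect_length(unique(singletons$cluster), n)
  one <- hierarchicalCluster(cm, k = 1)
  expect_equal(unique(one$cluster), 1L)
  expect_error(hierarchicalCluster(cm, 0), "between 1 and")
  expect_error(hierarchicalCluster(cm, n + 1), "between 1 and")
})

test_that("two-block matrix is recovered as the best 2-partition", {
  # exact block matrix: within r = 0.8, between 0
  blocks <- rep(c(1, 2), each = 3)
  v <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0))
  diag(v) <- 1
  cm <- new("CorrelationMatrix", labels = paste0("r", 1:6), values = v,
            nSubjects = 10L, qc = list())
  got <- hierarchicalCluster(cm, k = 2)$cluster

  # oracle: enumerate all 2-partitions, score by total within-cluster
  # squared Euclidean row distance
  D <- as.matrix(dist(v))^2
  best <- NULL; bestScore <- Inf
  for (part in allTwoPartitions(6)) {
    if (!any(part) || all(part)) next
    score <- sum(D[part, part]) + sum(D[!part, !part])
    if (score < bestScore) { bestScore <- score; best <- part }
  }
  expect_equal(got[best][1] == got[best][2], TRUE)
  expect_length(unique(got[best]), 1L)
  expect_length(unique(got[!best]), 1L)
  expect_false(got[best][1] == got[!best][1])
})

test_that("graph construction drops anticorrelations and self-loops", {
  v <- matrix(c(1, 0.5, -0.4,
                0.5, 1, 0.2,
                -0.4, 0.2, 1), 3, 3)
  cm <- new("CorrelationMatrix", labels = c("x", "y", "z"), values = v,
            nSubjects = 5L, qc = list())
  ng <- buildGraph(cm, displayCutoff = 0.3)
  g <- graphObj(ng)
  expect_equal(igraph::ecount(g), 2L)                    # -0.4 edge absent
  expect_false(igraph::are_adjacent(g, "x", "z"))
  expect_equal(igraph::any_loop(g), FALSE)
  el <- igraph::as_edgelist(g)
  w <- setNames(igraph::E(g)$weight, paste(el[, 1], el[, 2]))
  expect_equal(unname(w["x y"]), 0.5)
  expect_equal(unname(w["y z"]), 0.2)

  # complete graph on equal weights
  v4 <- matrix(0.5, 4, 4); diag(v4) <- 1
  cm4 <- new("CorrelationMatrix", labels = letters[1:4], values = v4,
             nSubjects = 5L, qc = list())
  g4 <- graphObj(buildGraph(cm4))
  expect_equal(igraph::ecount(g4), 6L)
  expect_true(all(igraph::E(g4)$weight == 0.5))
})

test_that("path and star centralities match hand calculations", {
  ng <- pathGraph3()
  b <- betweennessCentrality(ng)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))
  cl <- closenessCentrality(ng)
  expect_equal(unname(cl["b"]), 1)
  expect_equal(unname(cl["a"]), 2 / 3)

  # star with 4 leaves: center carries all C(4,2) = 6 pair paths
  adj <- matrix(0, 5, 5)
  adj[1, 2:5] <- adj[2:5, 1] <- 1
  star <- adjToNetworkGraph(adj, c("center", paste0("leaf", 1:4)))
  bs <- betweennessCentrality(star)
  expect_equal(unname(bs["center"]), 6)
  expect_true(all(bs[-1] == 0))

  # unweighted triangle: all closeness 1
  adj3 <- matrix(1, 3, 3); diag(adj3) <- 0
  tri <- adjToNetworkGraph(adj3, c("p", "q", "r"))
  expect_equal(as.numeric(closenessCentrality(tri)), rep(1, 3))
})

test_that("centralities match the exhaustive path oracle on random graphs", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    adj <- randomConnectedAdj(n)
    ng <- adjToNetworkGraph(adj)
    oracle <- bruteForceCentralities(adj)
    expect_equal(as.numeric(betweennessCentrality(ng)), oracle$betweenness,
                 tolerance = 1e-10)
    expect_equal(as.numeric(closenessCentrality(ng)), oracle$closeness,
                 tolerance = 1e-10)
  }
})

test_that("disconnected graphs are analyzed per component with a flag", {
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1; adj[2, 3] <- adj[3, 2] <- 1
  adj[4, 5] <- adj[5, 4] <- 0.5
  ng <- adjToNetworkGraph(adj)
  b <- betweennessCentrality(ng)
  cl <- closenessCentrality(ng)
  expect_true(attr(b, "disconnected"))
  expect_true(attr(cl, "disconnected"))
  expect_equal(unname(b[2]), 1)                 # within its component
  expect_equal(unname(cl[4]), 1 / 2)            # (2-1)/d, d = 1/0.5
  oracle <- bruteForceCentralities(adj)
  expect_equal(as.numeric(cl), oracle$closeness, tolerance = 1e-10)
})

test_that("z-scoring standardizes and handles constant vectors", {
  expect_equal(unname(zscoreCentralities(c(1, 2, 3))), c(-1, 0, 1))
  zc <- zscoreCentralities(c(a = 2, b = 2, c = 2))
  expect_equal(as.numeric(zc), c(0, 0, 0))
  expect_true(isTRUE(attr(zc, "constant")))
  set.seed(4)
  for (i in 1:5) {
    z <- zscoreCentralities(rnorm(10, 5, 3))
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("relabeling nodes permutes all outputs consistently", {
  set.seed(55)
  adj <- randomConnectedAdj(6)
  labels <- paste0("R", 1:6)
  perm <- sample(6)
  ngA <- adjToNetworkGraph(adj, labels)
  ngB <- adjToNetworkGraph(adj[perm, perm], labels[perm])
  tabA <- centralityTable(ngA)
  tabB <- centralityTable(ngB)
  rownames(tabA) <- rownames(tabB) <- NULL
  a <- tabA[order(tabA$node), ]; b <- tabB[order(tabB$node), ]
  expect_equal(a$betweenness, b$betweenness, tolerance = 1e-12)
  expect_equal(a$closeness_z, b$closeness_z, tolerance = 1e-12)
})

test_that("a planted connector hub attains the top centrality z-scores", {
  hits <- vapply(1:5, function(i) {
    sp <- hubPhantom(25, rngSeed = 300 + i)
    cm <- regionCorrelationMatrix(simulateBold(sp), atlasFromSpec(sp))
    tab <- centralityTable(buildGraph(cm))
    hub <- tab[tab$node == "hub", ]
    hub$betweenness_z == max(tab$betweenness_z) &&
      hub$closeness_z == max(tab$closeness_z)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
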