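# Independent brute-force oracles. These never call the code paths they
# check: centralities come from exhaustive simple-path enumeration,
# clustering recovery from enumeration of all 2-partitions.

# all simple paths between two nodes of a weighted adjacency matrix
# (0 = absent edge); edge length = 1 / weight
.allSimplePaths <- function(lenMat, from, to) {
  n <- nrow(lenMat)
  res <- list()
  recurse <- function(path, node, acc) {
    if (node == to) {
      res[[length(res) + 1L]] <<- list(path = path, len = acc)
      return()
    }
    for (k in seq_len(n))
      if (is.finite(lenMat[node, k]) && !(k %in% path))
        recurse(c(path, k), k, acc + lenMat[node, k])
  }
  recurse(from, from, 0)
  res
}

# exhaustive betweenness (fractional credit over tied shortest paths,
# unnormalized unordered-pair counts), closeness ((n_c - 1) / sum d within
# the node's component), and the distance matrix
bruteForceCentralities <- function(adj, tol = 1e-9) {
  n <- nrow(adj)
  lenMat <- ifelse(adj > 0, 1 / adj, Inf)
  diag(lenMat) <- Inf
  D <- matrix(Inf, n, n); diag(D) <- 0
  btw <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    paths <- .allSimplePaths(lenMat, i, j)
    if (length(paths) == 0L) next
    lens <- vapply(paths, `[[`, 0, "len")
    m <- min(lens)
    D[i, j] <- D[j, i] <- m
    sel <- paths[lens <= m + tol]
    for (p in sel) {
      interior <- setdiff(p$path, c(i, j))
      btw[interior] <- btw[interior] + 1 / length(sel)
    }
  }
  clo <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(D[i, ]) & seq_len(n) != i)
    if (length(reach) == 0L) return(0)
    length(reach) / sum(D[i, reach])
  }, 0)
  list(betweenness = btw, closeness = clo, distances = D)
}

# random connected weighted graph as a symmetric adjacency matrix
randomConnectedAdj <- function(n, edgeProb = 0.5, wMin = 0.1, wMax = 1) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (runif(1) < edgeProb)
        adj[i, j] <- adj[j, i] <- runif(1, wMin, wMax)
    lenMat <- ifelse(adj > 0, 1, Inf)
    # connectivity by reachability closure
    reach <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(is.finite(lenMat[frontier[1L], ])), reach)
      reach <- c(reach, nxt)
      frontier <- c(frontier[-1L], nxt)
    }
    if (length(reach) == n) return(adj)
  }
}

adjToNetworkGraph <- function(adj, labels = NULL, displayCutoff = 0.3) {
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  new("NetworkGraph", graph = g, displayCutoff = displayCutoff)
}

# all 2-partitions of n items (as logical membership of part 1)
allTwoPartitions <- function(n) {
  out <- list()
  for (code in 1:(2^(n - 1L) - 1L)) {
    bits <- as.logical(bitwAnd(code, 2^(0:(n - 1L))))
    out[[length(out) + 1L]] <- bits
  }
  out
}
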