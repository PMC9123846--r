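#' @include AllClasses.R constructors.R
NULL

#' Region-by-region functional connectivity matrix
#'
#' For every subject, each region's mean time course is extracted and all
#' pairwise Pearson correlations computed; the per-subject correlations are
#' Fisher-z transformed, averaged across subjects, and back-transformed.
#' The diagonal is set to 1. A region with a zero-variance time course in
#' some subject contributes r = 0 for that subject's pairs and is counted
#' in the QC flag `zero_variance_region_subjects`.
#'
#' @param scans list of [BoldScan-class] (at least 2).
#' @param atlas a [NodeAtlas-class] with at least 2 regions.
#' @return A [CorrelationMatrix-class].
#' @export
regionCorrelationMatrix <- function(scans, atlas) {
  labels <- atlasLabels(atlas)
  nr <- length(labels)
  if (nr < 2L) stop("need at least 2 atlas regions")
  if (length(scans) < 2L) stop("need at least 2 subjects")
  d <- dim(mapData(atlas))
  idxList <- lapply(seq_len(nr), function(i) which(mapData(atlas) == i))
  lim <- 1 - 1e-7
  nZeroVar <- 0L
  zsum <- matrix(0, nr, nr)
  for (scan in scans) {
    ds <- dim(mapData(scan))
    if (!.sameGrid(d, mapAffine(atlas), ds[1:3], mapAffine(scan)))
      stop("scan grid does not match atlas grid")
    mat <- matrix(mapData(scan), nrow = prod(ds[1:3]))
    tcs <- vapply(idxList, function(ix)
      colMeans(mat[ix, , drop = FALSE]), numeric(ds[4L]))
    sds <- apply(tcs, 2L, sd)
    zero <- sds == 0
    nZeroVar <- nZeroVar + sum(zero)
    r <- suppressWarnings(cor(tcs))
    r[!is.finite(r)] <- 0        # zero-variance pairs contribute r = 0
    diag(r) <- 1
    zsum <- zsum + atanh(pmin(lim, pmax(-lim, r)))
  }
  v <- tanh(zsum / length(scans))
  v <- (v + t(v)) / 2
  diag(v) <- 1
  new("CorrelationMatrix", labels = labels, values = v,
      nSubjects = length(scans),
      qc = list(zero_variance_region_subjects = nZeroVar))
}

#' Agglomerative clustering of the correlation matrix
#'
#' Hierarchical clustering on Euclidean distances between the rows of the
#' correlation matrix (each region's connectivity profile), tree cut at
#' `k` clusters. Deterministic for a given matrix.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param k number of clusters, `1 <= k <= n_regions`.
#' @param linkageMethod agglomeration method passed to [stats::hclust()];
#'   default "complete".
#' @return data.frame with columns `region` and `cluster`, plus attributes
#'   `k` and `linkage_method`.
#' @export
hierarchicalCluster <- function(cm, k, linkageMethod = "complete") {
  n <- length(cm@labels)
  if (k < 1L || k > n)
    stop("k must lie between 1 and the number of regions (", n, ")")
  hc <- hclust(dist(corValues(cm)), method = linkageMethod)
  cl <- cutree(hc, k = k)
  out <- data.frame(region = cm@labels, cluster = as.integer(cl),
                    row.names = NULL)
  attr(out, "k") <- as.integer(k)
  attr(out, "linkage_method") <- linkageMethod
  out
}

#' Build the weighted network graph from a correlation matrix
#'
#' Undirected graph with one edge per region pair with positive
#' correlation, weighted by the correlation. Anticorrelated pairs
#' (r <= 0) are excluded. Edges weaker than `displayCutoff` are retained
#' for all computation and only flagged for rendering.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param displayCutoff rendering threshold (default 0.3; the figure-level
#'   alternative 0.2 is equally valid -- the choice never affects
#'   centralities).
#' @return A [NetworkGraph-class].
#' @export
buildGraph <- function(cm, displayCutoff = 0.3) {
  v <- corValues(cm)
  diag(v) <- 0                       # no self-loops
  v[v <= 0] <- 0                     # drop anticorrelations
  g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  new("NetworkGraph", graph = g, displayCutoff = displayCutoff)
}

# shortest-path edge lengths: strong correlation = short distance
.edgeLengths <- function(g, edgeLengthMode = c("inverse", "one_minus")) {
  edgeLengthMode <- match.arg(edgeLengthMode)
  w <- igraph::E(g)$weight
  if (edgeLengthMode == "inverse") 1 / w else 1 - w
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness on shortest paths with edge length `1 / weight`
#' (strongly correlated regions are close). Equal-length path
#' multiplicities receive fractional credit; values are unnormalized pair
#' counts. Disconnected graphs are computed per component and flagged.
#'
#' @param ng a [NetworkGraph-class] with at least 3 nodes.
#' @param edgeLengthMode "inverse" (1/weight, default) or "one_minus"
#'   (1 - weight).
#' @return Named numeric vector; attribute `disconnected` flags a graph
#'   analyzed per component.
#' @export
betweennessCentrality <- function(ng, edgeLengthMode = "inverse") {
  g <- graphObj(ng)
  if (igraph::vcount(g) < 3L) stop("betweenness needs at least 3 nodes")
  b <- igraph::betweenness(g, weights = .edgeLengths(g, edgeLengthMode),
                           normalized = FALSE)
  attr(b, "disconnected") <- !igraph::is_connected(g)
  b
}

#' Weighted closeness centrality
#'
#' `(n - 1) / sum(d)` over shortest-path lengths `d` with edge length
#' `1 / weight`. On a disconnected graph each node is scored within its
#' own component (`(n_c - 1) / sum(d within component)`) and the result is
#' flagged; isolated nodes score 0.
#'
#' @inheritParams betweennessCentrality
#' @param ng a [NetworkGraph-class] with at least 2 nodes.
#' @return Named numeric vector; attribute `disconnected` as above.
#' @export
closenessCentrality <- function(ng, edgeLengthMode = "inverse") {
  g <- graphObj(ng)
  n <- igraph::vcount(g)
  if (n < 2L) stop("closeness needs at least 2 nodes")
  dm <- igraph::distances(g, weights = .edgeLengths(g, edgeLengthMode))
  comp <- igraph::components(g)$membership
  cl <- vapply(seq_len(n), function(i) {
    same <- which(comp == comp[i] & seq_len(n) != i)
    if (length(same) == 0L) return(0)
    length(same) / sum(dm[i, same])
  }, 0)
  names(cl) <- igraph::V(g)$name
  attr(cl, "disconnected") <- !igraph::is_connected(g)
  cl
}

#' Standardize centrality values to z-scores
#'
#' `(x - mean) / sd` with the sample standard deviation. A constant input
#' vector returns all zeros with attribute `constant = TRUE`.
#'
#' @param values numeric vector of raw centralities (length >= 2).
#' @return z-scored vector of the same length and names.
#' @export
zscoreCentralities <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- sd(values)
  if (s == 0) {
    out <- rep(0, length(values))
    names(out) <- names(values)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (values - mean(values)) / s
  names(out) <- names(values)
  attr(out, "disconnected") <- NULL
  out
}

#' Centrality table with raw and z-scored betweenness and closeness
#'
#' @param ng a [NetworkGraph-class].
#' @param edgeLengthMode see [betweennessCentrality()].
#' @return data.frame with columns `node`, `betweenness`, `closeness`,
#'   `betweenness_z`, `closeness_z`, sorted by descending betweenness z.
#' @export
centralityTable <- function(ng, edgeLengthMode = "inverse") {
  b <- betweennessCentrality(ng, edgeLengthMode)
  cl <- closenessCentrality(ng, edgeLengthMode)
  df <- data.frame(node = igraph::V(graphObj(ng))$name,
                   betweenness = as.numeric(b),
                   closeness = as.numeric(cl),
                   betweenness_z = as.numeric(zscoreCentralities(b)),
                   closeness_z = as.numeric(zscoreCentralities(cl)),
                   row.names = NULL)
  df[order(-df$betweenness_z, df$node), , drop = FALSE]
}
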