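#' @include AllClasses.R constructors.R
NULL

#' Intersect binarized connectivity maps
#'
#' Voxelwise logical AND across maps: the overlap territory shared by all
#' targets' suprathreshold patterns, used to outline the common network.
#'
#' @param maps list of at least two binary [StatMap-class] objects on a
#'   shared grid.
#' @return A binary [StatMap-class]; its QC carries the overlap voxel
#'   count.
#' @export
intersectMaps <- function(maps) {
  if (length(maps) < 2L) stop("need at least two maps to intersect")
  d <- dim(mapData(maps[[1L]]))
  aff <- mapAffine(maps[[1L]])
  acc <- array(1, dim = d)
  for (m in maps) {
    if (mapKind(m) != "binary") stop("all maps must be binary StatMaps")
    if (!.sameGrid(d, aff, dim(mapData(m)), mapAffine(m)))
      stop(sprintf("grid mismatch: %s vs %s", paste(d, collapse = "x"),
                   paste(dim(mapData(m)), collapse = "x")))
    acc <- acc * mapData(m)
  }
  statMap("binary", acc, aff,
          sourceSeed = paste(vapply(maps, function(m)
            if (is.na(m@sourceSeed)) "?" else m@sourceSeed, ""),
            collapse = "&"),
          qc = list(overlap_voxels = sum(acc)))
}

# neighbor offsets for 6- or 26-connectivity in 3D
.neighborOffsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  as.matrix(g)
}

#' Connected components of a binary map as labeled network nodes
#'
#' Maximal connected components of the foreground under a 6- or
#' 26-neighborhood; components smaller than `minVoxels` are discarded.
#' Labeling is deterministic: components are numbered by descending voxel
#' count, ties broken by the smallest linear voxel index (column-major
#' order).
#'
#' @param map a binary [StatMap-class].
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @param minVoxels smallest component retained.
#' @param labelPrefix prefix for generated region names.
#' @return A [NodeAtlas-class] with provenance "overlap". An empty input
#'   yields an empty atlas (flagged), not an error.
#' @export
extractComponents <- function(map, connectivity = 26L, minVoxels = 5L,
                              labelPrefix = "overlap") {
  if (mapKind(map) != "binary") stop("extractComponents expects a binary map")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(mapData(map))
  fg <- which(mapData(map) != 0)
  emptyAtlas <- function() {
    a <- new("NodeAtlas", labels = character(0),
             labelArray = array(0L, dim = d), provenance = character(0),
             affine = mapAffine(map))
    attr(a, "empty_input") <- TRUE
    a
  }
  if (length(fg) == 0L) return(emptyAtlas())

  rank <- array(0L, dim = d)
  rank[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  offs <- .neighborOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[i, ], nrow(coords), 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    if (!any(ok)) next
    nbIdx <- .linIndex(nb[ok, , drop = FALSE], d)
    nbRank <- rank[nbIdx]
    hit <- nbRank > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nbRank[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)

  keep <- which(comp$csize >= minVoxels)
  if (length(keep) == 0L) return(emptyAtlas())
  minIdx <- vapply(keep, function(k) min(fg[comp$membership == k]), 0)
  ord <- keep[order(-comp$csize[keep], minIdx)]

  lab <- array(0L, dim = d)
  for (j in seq_along(ord))
    lab[fg[comp$membership == ord[j]]] <- j
  new("NodeAtlas",
      labels = sprintf("%s_%d", labelPrefix, seq_along(ord)),
      labelArray = lab,
      provenance = rep("overlap", length(ord)),
      affine = mapAffine(map))
}

#' Assemble the network node atlas from seeds and overlap components
#'
#' The common network's nodes are the anatomical DBS-target seeds plus the
#' overlap components. Where an overlap component intersects a seed, the
#' seed takes precedence (seeds are the anchored anatomy); components left
#' empty after seed absorption are dropped.
#'
#' @param seeds list of [SeedMask-class] objects.
#' @param overlapAtlas a [NodeAtlas-class] from [extractComponents()].
#' @return A [NodeAtlas-class] with pairwise-disjoint, nonempty regions;
#'   seeds first, then surviving overlap components.
#' @export
assembleNetworkNodes <- function(seeds, overlapAtlas) {
  if (length(seeds) == 0L) stop("need at least one seed")
  d <- dim(mapData(overlapAtlas))
  aff <- mapAffine(overlapAtlas)
  seedNames <- vapply(seeds, function(s) s@name, "")
  if (anyDuplicated(c(seedNames, atlasLabels(overlapAtlas))))
    stop("duplicate region names across seeds and overlap components")
  for (s in seeds)
    if (!.sameGrid(d, aff, dim(mapData(s)), mapAffine(s)))
      stop("seed '", s@name, "' is not on the atlas grid")

  seedUnion <- array(FALSE, dim = d)
  masks <- list(); labels <- character(0); prov <- character(0)
  for (s in seeds) {
    m <- mapData(s)
    if (any(seedUnion & m)) stop("seed masks overlap each other")
    seedUnion <- seedUnion | m
    masks <- c(masks, list(m)); labels <- c(labels, s@name)
    prov <- c(prov, "seed")
  }
  for (i in seq_along(atlasLabels(overlapAtlas))) {
    m <- mapData(overlapAtlas) == i
    m[seedUnion] <- FALSE  # seeds take precedence
    if (!any(m)) next      # fully absorbed by a seed
    masks <- c(masks, list(m))
    labels <- c(labels, atlasLabels(overlapAtlas)[i])
    prov <- c(prov, "overlap")
  }
  nodeAtlas(labels, masks, prov, aff)
}
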