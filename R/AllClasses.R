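#' @import methods
#' @importFrom stats cor cutree dist hclust pt qt rnorm sd setNames fft mvfft
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Diagonal voxel-to-mm affine with origin at the grid corner
#'
#' @param voxelSizeMm physical edge length of an isotropic voxel, in mm.
#' @return A 4x4 affine matrix.
#' @export
gridAffine <- function(voxelSizeMm = 3.0) {
  stopifnot(is.numeric(voxelSizeMm), length(voxelSizeMm) == 1L, voxelSizeMm > 0)
  diag(c(rep(voxelSizeMm, 3L), 1))
}

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      any(!is.finite(affine)))
    return("affine must be a finite 4x4 matrix")
  NULL
}

.sameGrid <- function(dimA, affA, dimB, affB, tol = 1e-4) {
  all(dimA == dimB) && max(abs(affA - affB)) <= tol
}

#' RegionSpec: a named voxel set with loadings on latent networks
#'
#' Defines one planted region of a synthetic phantom: which voxels it
#' occupies (1-based integer indices into the grid) and the amplitude with
#' which each latent network signal is mixed into those voxels.
#'
#' @slot name region label.
#' @slot voxels integer matrix with one row per voxel and columns (x, y, z).
#' @slot networkLoadings named numeric vector; names are network labels,
#'   values are mixing amplitudes.
#' @export
setClass("RegionSpec",
  representation(name = "character", voxels = "matrix",
                 networkLoadings = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    v <- object@voxels
    if (!is.numeric(v) || ncol(v) != 3L || nrow(v) < 1L)
      msg <- c(msg, "voxels must be a non-empty matrix with 3 columns")
    else if (any(v != round(v)) || any(v < 1))
      msg <- c(msg, "voxel indices must be positive integers (1-based)")
    if (length(object@networkLoadings) &&
        (is.null(names(object@networkLoadings)) ||
         any(!nzchar(names(object@networkLoadings)))))
      msg <- c(msg, "networkLoadings must be named by network")
    if (any(!is.finite(object@networkLoadings)))
      msg <- c(msg, "networkLoadings must be finite")
    if (length(msg)) msg else TRUE
  })

#' NetworkSpec: one latent band-limited signal shared across regions
#'
#' @slot name network label.
#' @slot cutoffHz upper frequency bound of the latent signal (Hz).
#' @slot signalSd standard deviation of the latent time course.
#' @export
setClass("NetworkSpec",
  representation(name = "character", cutoffHz = "numeric",
                 signalSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    if (length(object@cutoffHz) != 1L || object@cutoffHz <= 0)
      msg <- c(msg, "cutoffHz must be a single positive number")
    if (length(object@signalSd) != 1L || object@signalSd < 0)
      msg <- c(msg, "signalSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: full description of a synthetic resting-state phantom
#'
#' Encodes the acquisition geometry (grid, voxel size, TR, number of time
#' points), the cohort size, the planted latent networks and regions, the
#' noise level, and the RNG seed. A fixed seed makes [simulateBold()]
#' bit-identical across runs.
#'
#' @slot gridShape integer vector of voxel counts per axis (x, y, z).
#' @slot voxelSizeMm voxel edge in mm (default 3).
#' @slot nSubjects number of simulated subjects.
#' @slot nTimepoints time points per run (default 124).
#' @slot trSeconds repetition time in seconds (default 3).
#' @slot regions list of [RegionSpec-class] objects.
#' @slot networks list of [NetworkSpec-class] objects.
#' @slot noiseSd per-voxel white-noise standard deviation.
#' @slot rngSeed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 nSubjects = "integer", nTimepoints = "integer",
                 trSeconds = "numeric", regions = "list",
                 networks = "list", noiseSd = "numeric",
                 rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be three voxel counts, all >= 1")
    if (object@nTimepoints < 8L)
      msg <- c(msg, "nTimepoints must be >= 8")
    if (object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be > 0")
    if (object@noiseSd <= 0)
      msg <- c(msg, "noiseSd must be > 0")
    if (object@nSubjects < 1L)
      msg <- c(msg, "nSubjects must be >= 1")
    if (!all(vapply(object@regions, is, TRUE, "RegionSpec")))
      msg <- c(msg, "regions must all be RegionSpec objects")
    if (!all(vapply(object@networks, is, TRUE, "NetworkSpec")))
      msg <- c(msg, "networks must all be NetworkSpec objects")
    nyq <- 1 / (2 * object@trSeconds)
    for (nw in object@networks)
      if (is(nw, "NetworkSpec") && nw@cutoffHz > nyq)
        msg <- c(msg, sprintf(
          "network '%s': cutoffHz %.4g exceeds Nyquist %.4g",
          nw@name, nw@cutoffHz, nyq))
    rn <- vapply(object@regions, function(r) r@name, "")
    if (anyDuplicated(rn))
      msg <- c(msg, "region names must be unique")
    seen <- integer(0)
    for (r in object@regions) {
      if (!is(r, "RegionSpec")) next
      if (any(t(r@voxels) > object@gridShape))
        msg <- c(msg, sprintf("region '%s' has voxels outside the grid",
                              r@name))
      idx <- .linIndex(r@voxels, object@gridShape)
      if (any(idx %in% seen))
        msg <- c(msg, sprintf("region '%s' overlaps another region", r@name))
      seen <- c(seen, idx)
      bad <- setdiff(names(r@networkLoadings),
                     vapply(object@networks, function(n) n@name, ""))
      if (length(bad))
        msg <- c(msg, sprintf("region '%s' loads on unknown network(s): %s",
                              r@name, paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' BoldScan: one subject's 4D BOLD volume
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot affine 4x4 voxel-to-mm transform.
#' @slot trSeconds sampling interval in seconds.
#' @export
setClass("BoldScan",
  representation(data = "array", affine = "matrix", trSeconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array (x, y, z, t)")
    else if (dim(object@data)[4L] < 8L)
      msg <- c(msg, "time dimension must be >= 8")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "data must contain only finite values")
    msg <- c(msg, .checkAffine(object@affine))
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' SeedMask: a binary 3D region definition
#'
#' @slot name target label (e.g. "ANT", "CMT", "HC").
#' @slot mask 3D logical array on the scan grid.
#' @slot affine 4x4 voxel-to-mm transform, matching the scans it is
#'   applied to.
#' @export
setClass("SeedMask",
  representation(name = "character", mask = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3D array")
    else {
      if (!is.logical(object@mask))
        msg <- c(msg, "mask must be logical")
      else if (!any(object@mask))
        msg <- c(msg, "mask must contain at least one voxel")
    }
    msg <- c(msg, .checkAffine(object@affine))
    if (length(msg)) msg else TRUE
  })

.statKinds <- c("r", "z", "t", "binary")

#' StatMap: a voxelwise statistic volume
#'
#' A single container threaded through the thresholding chain: seed-to-voxel
#' correlation maps (`kind = "r"`), Fisher-z maps (`"z"`), group one-sample
#' t-maps (`"t"`, with degrees of freedom), and binarized maps (`"binary"`).
#'
#' @slot kind one of "r", "z", "t", "binary".
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-to-mm transform.
#' @slot df degrees of freedom (t-maps; `NA` otherwise).
#' @slot sourceSeed label of the seed that produced the map.
#' @slot qc named list of QC flags and counts accumulated along the chain.
#' @export
setClass("StatMap",
  representation(kind = "character", data = "array", affine = "matrix",
                 df = "numeric", sourceSeed = "character", qc = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@kind) != 1L || !object@kind %in% .statKinds)
      msg <- c(msg, sprintf("kind must be one of: %s",
                            paste(.statKinds, collapse = ", ")))
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    else {
      if (object@kind == "r" &&
          any(object@data < -1 | object@data > 1, na.rm = TRUE))
        msg <- c(msg, "r-map values must lie in [-1, 1]")
      if (object@kind == "binary" && !all(object@data %in% c(0, 1)))
        msg <- c(msg, "binary map values must be exactly 0 or 1")
    }
    if (object@kind == "t") {
      if (length(object@df) != 1L || is.na(object@df) || object@df < 1)
        msg <- c(msg, "t-maps must carry df >= 1")
    }
    msg <- c(msg, .checkAffine(object@affine))
    if (length(msg)) msg else TRUE
  })

#' EfficacyMap: outcome-weighted combination of binarized target maps
#'
#' Voxel values are percent seizure reduction: with `mode = "mean"` the
#' average weight of the targets covering a voxel, with `mode = "sum"` the
#' weight total. Zero where no target map covers the voxel.
#'
#' @slot data 3D numeric array of percent-improvement values.
#' @slot affine 4x4 voxel-to-mm transform.
#' @slot contributingTargets labels of the combined targets.
#' @slot mode "mean" or "sum".
#' @export
setClass("EfficacyMap",
  representation(data = "array", affine = "matrix",
                 contributingTargets = "character", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!object@mode %in% c("mean", "sum"))
      msg <- c(msg, "mode must be 'mean' or 'sum'")
    if (any(object@data < 0))
      msg <- c(msg, "efficacy values must be >= 0")
    msg <- c(msg, .checkAffine(object@affine))
    if (length(msg)) msg else TRUE
  })

#' NodeAtlas: labeled, pairwise-disjoint network regions
#'
#' Integer-coded label volume plus per-region metadata. Region `i` occupies
#' the voxels where `labelArray == i`. Provenance records whether a region
#' came in as an anatomical seed or was extracted as an overlap component.
#'
#' @slot labels region names, in label-code order.
#' @slot labelArray 3D integer array; 0 is background.
#' @slot provenance one of "seed" or "overlap" per region.
#' @slot affine 4x4 voxel-to-mm transform.
#' @export
setClass("NodeAtlas",
  representation(labels = "character", labelArray = "array",
                 provenance = "character", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labelArray)) != 3L)
      msg <- c(msg, "labelArray must be a 3D array")
    n <- length(object@labels)
    if (anyDuplicated(object@labels))
      msg <- c(msg, "region labels must be unique")
    if (length(object@provenance) != n ||
        !all(object@provenance %in% c("seed", "overlap")))
      msg <- c(msg, "provenance must be 'seed'/'overlap', one per region")
    codes <- sort(unique(as.integer(object@labelArray)))
    codes <- codes[codes != 0L]
    if (n > 0L && !identical(codes, seq_len(n)))
      msg <- c(msg, "labelArray must use codes 1..n_regions (0 background), each nonempty")
    msg <- c(msg, .checkAffine(object@affine))
    if (length(msg)) msg else TRUE
  })

#' CorrelationMatrix: region-by-region functional connectivity
#'
#' Pearson correlations between region mean time courses, aggregated across
#' subjects by Fisher-z averaging and back-transformed.
#'
#' @slot labels region names.
#' @slot values symmetric correlation matrix with unit diagonal.
#' @slot nSubjects number of subjects underlying the estimate.
#' @slot qc named list of QC flags.
#' @export
setClass("CorrelationMatrix",
  representation(labels = "character", values = "matrix",
                 nSubjects = "integer", qc = "list"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    n <- length(object@labels)
    if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
      msg <- c(msg, "values must be an n x n numeric matrix")
    else {
      if (max(abs(v - t(v))) > 1e-12)
        msg <- c(msg, "values must be symmetric")
      if (any(abs(diag(v) - 1) > 1e-12))
        msg <- c(msg, "diagonal must be 1")
      if (any(v < -1 - 1e-12 | v > 1 + 1e-12))
        msg <- c(msg, "entries must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' NetworkGraph: weighted undirected graph over network regions
#'
#' Edges connect region pairs with positive correlation; anticorrelated
#' pairs are excluded. Edge weights are the correlations. The display
#' cutoff flags weak edges for rendering only and never affects centrality
#' computation.
#'
#' @slot graph an igraph object (undirected, positive weights, no loops).
#' @slot displayCutoff correlation threshold below which edges are flagged
#'   as below-cutoff for rendering.
#' @export
setClass("NetworkGraph",
  representation(graph = "ANY", displayCutoff = "numeric"),
  validity = function(object) {
    msg <- character()
    g <- object@graph
    if (!igraph::is_igraph(g))
      msg <- c(msg, "graph must be an igraph object")
    else {
      if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
      if (igraph::any_loop(g))
        msg <- c(msg, "graph must not contain self-loops")
      w <- igraph::E(g)$weight
      if (igraph::ecount(g) > 0 && (is.null(w) || any(w <= 0)))
        msg <- c(msg, "all edge weights must be > 0")
    }
    if (length(object@displayCutoff) != 1L || object@displayCutoff < 0)
      msg <- c(msg, "displayCutoff must be a single number >= 0")
    if (length(msg)) msg else TRUE
  })

#' AnalysisConfig: tunable parameters of the mapping pipeline
#'
#' @slot tThreshold absolute-t cutoff for binarization (default 5.1, the
#'   Bonferroni-corrected whole-brain threshold at alpha 0.05). When `NA`,
#'   the threshold is derived from `alpha`, `brainVoxelCount` and the
#'   t-map's degrees of freedom via [bonferroniTThreshold()].
#' @slot alpha family-wise error level (default 0.05).
#' @slot brainVoxelCount number of voxelwise tests for the Bonferroni
#'   correction (default 67000, approximately a 3 mm in-brain grid).
#' @slot edgeDisplayCutoff correlation magnitude below which graph edges are
#'   flagged for rendering (default 0.3).
#' @slot nClusters number of clusters cut from the dendrogram (default 5).
#' @slot negativeEdgePolicy fixed to "drop": anticorrelations are excluded
#'   from the graph.
#' @slot efficacyMode "mean" or "sum" combination of outcome weights.
#' @slot componentConnectivity 6 or 26 neighborhood for connected
#'   components.
#' @slot minComponentVoxels smallest component retained as a network node.
#' @slot rmapAggregation "per_subject_t" (per-subject Fisher-z then
#'   one-sample t) or "average_r" (average r, one transform).
#' @slot linkageMethod agglomeration method for hierarchical clustering.
#' @export
setClass("AnalysisConfig",
  representation(tThreshold = "numeric", alpha = "numeric",
                 brainVoxelCount = "integer", edgeDisplayCutoff = "numeric",
                 nClusters = "integer", negativeEdgePolicy = "character",
                 efficacyMode = "character",
                 componentConnectivity = "integer",
                 minComponentVoxels = "integer",
                 rmapAggregation = "character",
                 linkageMethod = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@tThreshold) != 1L ||
        (!is.na(object@tThreshold) && object@tThreshold <= 0))
      msg <- c(msg, "tThreshold must be > 0 (or NA to derive from alpha)")
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must lie strictly between 0 and 1")
    if (object@brainVoxelCount < 1L)
      msg <- c(msg, "brainVoxelCount must be >= 1")
    if (object@nClusters < 1L)
      msg <- c(msg, "nClusters must be >= 1")
    if (!identical(object@negativeEdgePolicy, "drop"))
      msg <- c(msg, "negativeEdgePolicy is fixed to 'drop'")
    if (!object@efficacyMode %in% c("mean", "sum"))
      msg <- c(msg, "efficacyMode must be 'mean' or 'sum'")
    if (!object@componentConnectivity %in% c(6L, 26L))
      msg <- c(msg, "componentConnectivity must be 6 or 26")
    if (object@minComponentVoxels < 1L)
      msg <- c(msg, "minComponentVoxels must be >= 1")
    if (!object@rmapAggregation %in% c("per_subject_t", "average_r"))
      msg <- c(msg, "rmapAggregation must be 'per_subject_t' or 'average_r'")
    if (length(msg)) msg else TRUE
  })
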