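#' @include AllClasses.R
NULL

#' Define a phantom region
#'
#' @param name region label.
#' @param voxels integer matrix of 1-based (x, y, z) voxel indices, or a
#'   list/vector coercible to one row.
#' @param networkLoadings named numeric vector of mixing amplitudes, one
#'   entry per latent network the region loads on. Empty means pure noise.
#' @return A [RegionSpec-class] object.
#' @export
regionSpec <- function(name, voxels, networkLoadings = numeric(0)) {
  if (!is.matrix(voxels)) voxels <- matrix(voxels, ncol = 3L, byrow = TRUE)
  storage.mode(voxels) <- "integer"
  new("RegionSpec", name = name, voxels = voxels,
      networkLoadings = networkLoadings)
}

#' Define a latent network signal
#'
#' @param name network label.
#' @param cutoffHz upper frequency bound of the band-limited latent signal,
#'   in Hz (default 0.08, the low-frequency BOLD band).
#' @param signalSd standard deviation of the latent time course (default 1).
#' @return A [NetworkSpec-class] object.
#' @export
networkSpec <- function(name, cutoffHz = 0.08, signalSd = 1.0) {
  new("NetworkSpec", name = name, cutoffHz = cutoffHz, signalSd = signalSd)
}

#' Specify a synthetic resting-state phantom
#'
#' Defaults mirror a typical 3 T resting-state acquisition: 124 time points
#' at TR = 3 s on a 3 mm isotropic grid, with latent signals band-limited
#' below 0.08 Hz.
#'
#' @param gridShape voxel counts per axis.
#' @param nSubjects number of subjects to simulate.
#' @param regions list of [regionSpec()] objects.
#' @param networks list of [networkSpec()] objects.
#' @param nTimepoints time points per run.
#' @param trSeconds repetition time in seconds.
#' @param voxelSizeMm voxel edge in mm.
#' @param noiseSd white-noise standard deviation per voxel.
#' @param rngSeed integer seed; fixed seed gives bit-identical simulations.
#' @return A validated [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridShape, nSubjects, regions = list(),
                        networks = list(), nTimepoints = 124L,
                        trSeconds = 3.0, voxelSizeMm = 3.0, noiseSd = 1.0,
                        rngSeed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSizeMm = voxelSizeMm, nSubjects = as.integer(nSubjects),
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      regions = regions, networks = networks, noiseSd = noiseSd,
      rngSeed = as.integer(rngSeed))
}

#' Construct a BoldScan
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm transform.
#' @param trSeconds repetition time in seconds.
#' @return A [BoldScan-class] object.
#' @export
boldScan <- function(data, affine = gridAffine(), trSeconds = 3.0) {
  new("BoldScan", data = data, affine = affine, trSeconds = trSeconds)
}

#' Construct a SeedMask
#'
#' @param name target label.
#' @param mask 3D logical array (anything numeric is coerced via `!= 0`).
#' @param affine 4x4 voxel-to-mm transform.
#' @return A [SeedMask-class] object.
#' @export
seedMask <- function(name, mask, affine = gridAffine()) {
  if (!is.logical(mask)) {
    d <- dim(mask)
    mask <- array(as.logical(mask != 0), dim = d)
  }
  new("SeedMask", name = name, mask = mask, affine = affine)
}

#' Construct a StatMap
#'
#' Mostly produced by the pipeline; the constructor is exported for building
#' fixtures and for loading maps from disk.
#'
#' @param kind one of "r", "z", "t", "binary".
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-mm transform.
#' @param df degrees of freedom (t-maps only).
#' @param sourceSeed seed label.
#' @param qc named list of QC flags.
#' @return A [StatMap-class] object.
#' @export
statMap <- function(kind, data, affine = gridAffine(), df = NA_real_,
                    sourceSeed = NA_character_, qc = list()) {
  new("StatMap", kind = kind, data = data, affine = affine, df = df,
      sourceSeed = sourceSeed, qc = qc)
}

#' Pipeline configuration
#'
#' All tunable parameters of the mapping chain with their defaults: the
#' published whole-brain Bonferroni threshold |t| = 5.1 (alpha 0.05 over a
#' nominal 67,000-voxel brain), efficacy maps averaged on the percent scale,
#' 26-connectivity components of at least 5 voxels, anticorrelations dropped
#' from the graph, display cutoff 0.3, and a 5-cluster complete-linkage cut.
#'
#' @param tThreshold absolute-t binarization cutoff; `NA` derives it from
#'   `alpha` and `brainVoxelCount` at the t-map's df.
#' @param alpha family-wise error level.
#' @param brainVoxelCount number of voxelwise tests for Bonferroni.
#' @param edgeDisplayCutoff rendering cutoff for graph edges.
#' @param nClusters clusters cut from the dendrogram.
#' @param efficacyMode "mean" or "sum".
#' @param componentConnectivity 6 or 26.
#' @param minComponentVoxels smallest retained component.
#' @param rmapAggregation "per_subject_t" or "average_r".
#' @param linkageMethod hclust agglomeration method.
#' @return A validated [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(tThreshold = 5.1, alpha = 0.05,
                           brainVoxelCount = 67000L,
                           edgeDisplayCutoff = 0.3, nClusters = 5L,
                           efficacyMode = "mean",
                           componentConnectivity = 26L,
                           minComponentVoxels = 5L,
                           rmapAggregation = "per_subject_t",
                           linkageMethod = "complete") {
  new("AnalysisConfig", tThreshold = as.numeric(tThreshold),
      alpha = alpha, brainVoxelCount = as.integer(brainVoxelCount),
      edgeDisplayCutoff = edgeDisplayCutoff,
      nClusters = as.integer(nClusters), negativeEdgePolicy = "drop",
      efficacyMode = efficacyMode,
      componentConnectivity = as.integer(componentConnectivity),
      minComponentVoxels = as.integer(minComponentVoxels),
      rmapAggregation = rmapAggregation, linkageMethod = linkageMethod)
}

#' Construct a NodeAtlas from per-region masks
#'
#' @param labels region names.
#' @param masks list of 3D logical arrays, one per label, pairwise disjoint.
#' @param provenance "seed" or "overlap" per region.
#' @param affine 4x4 voxel-to-mm transform.
#' @return A [NodeAtlas-class] object.
#' @seealso [atlasLabels()], [regionMask()]
#' @export
nodeAtlas <- function(labels, masks, provenance, affine = gridAffine()) {
  stopifnot(length(labels) == length(masks),
            length(labels) == length(provenance))
  if (length(masks) == 0L)
    stop("nodeAtlas requires at least grid information; use an empty ",
         "labelArray constructor instead")
  d <- dim(masks[[1L]])
  lab <- array(0L, dim = d)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!all(dim(m) == d)) stop("mask grids differ within atlas")
    if (any(lab[m] != 0L)) stop("region masks must be pairwise disjoint")
    lab[m] <- i
  }
  new("NodeAtlas", labels = labels, labelArray = lab,
      provenance = provenance, affine = affine)
}
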