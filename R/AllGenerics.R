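#' @include AllClasses.R
NULL

# 1-based (x, y, z) rows -> linear index into an array of dim gridShape
.linIndex <- function(voxels, gridShape) {
  as.integer(voxels[, 1L] +
             (voxels[, 2L] - 1L) * gridShape[1L] +
             (voxels[, 3L] - 1L) * gridShape[1L] * gridShape[2L])
}

#' @describeIn mapData Extract the voxel data array of a map-like object
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' Accessors for map-like objects
#'
#' `mapData()` returns the data array, `mapAffine()` the 4x4 voxel-to-mm
#' transform, `mapKind()` the statistic kind of a [StatMap-class], and
#' `qcFlags()` the accumulated QC list.
#'
#' @param x a SeedConnectome object.
#' @name mapData
#' @export
setGeneric("mapAffine", function(x) standardGeneric("mapAffine"))

#' @rdname mapData
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname mapData
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

setMethod("mapData", "StatMap", function(x) x@data)
setMethod("mapData", "BoldScan", function(x) x@data)
setMethod("mapData", "EfficacyMap", function(x) x@data)
setMethod("mapData", "SeedMask", function(x) x@mask)
setMethod("mapData", "NodeAtlas", function(x) x@labelArray)
setMethod("mapAffine", "StatMap", function(x) x@affine)
setMethod("mapAffine", "BoldScan", function(x) x@affine)
setMethod("mapAffine", "EfficacyMap", function(x) x@affine)
setMethod("mapAffine", "SeedMask", function(x) x@affine)
setMethod("mapAffine", "NodeAtlas", function(x) x@affine)
setMethod("mapKind", "StatMap", function(x) x@kind)
setMethod("qcFlags", "StatMap", function(x) x@qc)
setMethod("qcFlags", "CorrelationMatrix", function(x) x@qc)

#' @rdname nodeAtlas
#' @param x a `NodeAtlas`.
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))
setMethod("atlasLabels", "NodeAtlas", function(x) x@labels)

#' @rdname nodeAtlas
#' @param label region name.
#' @export
setGeneric("regionMask", function(x, label) standardGeneric("regionMask"))
setMethod("regionMask", "NodeAtlas", function(x, label) {
  i <- match(label, x@labels)
  if (is.na(i)) stop("no region named '", label, "' in atlas")
  x@labelArray == i
})

#' @rdname regionCorrelationMatrix
#' @param x a `CorrelationMatrix`.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
setMethod("corValues", "CorrelationMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@labels, x@labels)
  v
})

#' @rdname buildGraph
#' @param x a `NetworkGraph`.
#' @export
setGeneric("graphObj", function(x) standardGeneric("graphObj"))
setMethod("graphObj", "NetworkGraph", function(x) x@graph)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s grid, %d subjects x %d timepoints (TR %gs)\n",
    paste(object@gridShape, collapse = "x"), object@nSubjects,
    object@nTimepoints, object@trSeconds))
  cat(sprintf("  %d region(s), %d latent network(s), noise sd %g, seed %d\n",
              length(object@regions), length(object@networks),
              object@noiseSd, object@rngSeed))
})

setMethod("show", "BoldScan", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldScan: %dx%dx%d voxels, %d timepoints, TR %gs\n",
              d[1], d[2], d[3], d[4], object@trSeconds))
})

setMethod("show", "SeedMask", function(object) {
  cat(sprintf("SeedMask '%s': %d voxels on a %s grid\n", object@name,
              sum(object@mask), paste(dim(object@mask), collapse = "x")))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap (%s): %s grid, seed '%s'%s\n", object@kind,
              paste(dim(object@data), collapse = "x"),
              if (length(object@sourceSeed)) object@sourceSeed else "?",
              if (object@kind == "t") sprintf(", df = %g", object@df) else ""))
  if (length(object@qc))
    cat("  qc:", paste(names(object@qc), unlist(lapply(object@qc, paste,
        collapse = ",")), sep = "=", collapse = "; "), "\n")
})

setMethod("show", "EfficacyMap", function(object) {
  cat(sprintf("EfficacyMap (%s) over targets: %s\n", object@mode,
              paste(object@contributingTargets, collapse = ", ")))
  nz <- sum(object@data > 0)
  cat(sprintf("  %d covered voxels, max %.2f%%\n", nz,
              if (nz) max(object@data) else 0))
})

setMethod("show", "NodeAtlas", function(object) {
  cat(sprintf("NodeAtlas: %d regions on a %s grid\n", length(object@labels),
              paste(dim(object@labelArray), collapse = "x")))
  if (length(object@labels)) {
    counts <- tabulate(object@labelArray, nbins = length(object@labels))
    info <- paste0(object@labels, " (", object@provenance, ", ",
                   counts, " vox)")
    cat(" ", paste(info, collapse = "; "), "\n")
  }
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d regions, %d subjects\n",
              length(object@labels), object@nSubjects))
})

setMethod("show", "NetworkGraph", function(object) {
  g <- object@graph
  cat(sprintf(
    "NetworkGraph: %d nodes, %d positive-weight edges (display cutoff %g)\n",
    igraph::vcount(g), igraph::ecount(g), object@displayCutoff))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  cat(sprintf("  t threshold: %s (alpha %g over %d tests)\n",
              ifelse(is.na(object@tThreshold), "derived",
                     format(object@tThreshold)),
              object@alpha, object@brainVoxelCount))
  cat(sprintf("  efficacy %s; components: %d-connectivity, min %d voxels\n",
              object@efficacyMode, object@componentConnectivity,
              object@minComponentVoxels))
  cat(sprintf("  graph: drop negative edges, display cutoff %g, k = %d (%s linkage)\n",
              object@edgeDisplayCutoff, object@nClusters,
              object@linkageMethod))
})
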