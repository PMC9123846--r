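#' @include AllClasses.R constructors.R seedmap.R efficacy.R overlap.R graphnet.R io.R
NULL

.logStage <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, stage,
                  msg))
}

#' Run the full target-network mapping pipeline
#'
#' Orchestrates the chain seed mapping -> outcome-weighted efficacy map ->
#' multi-seed overlap and node extraction -> graph analysis, writing every
#' artifact under `outdir` and returning (and writing) a machine-readable
#' run manifest with config echo, file checksums and per-stage QC.
#'
#' @param scans list of [BoldScan-class], or a [PhantomSpec-class] that is
#'   simulated first (its seed masks are then available by region name).
#' @param seeds list of [SeedMask-class]; with a `PhantomSpec` input,
#'   a character vector of region names is also accepted.
#' @param studies study-outcome data.frame (see [readStudyTable()]) or a
#'   path to one; must cover every seed label.
#' @param config an [AnalysisConfig-class].
#' @param outdir output directory.
#' @param poolingWeighting passed to [outcomeTable()].
#' @return Invisibly, the manifest list (also written as
#'   `run_manifest.yaml`).
#' @export
runPipeline <- function(scans, seeds, studies, config = analysisConfig(),
                        outdir, poolingWeighting = "simple") {
  validObject(config)
  if (missing(outdir) || !nzchar(outdir)) stop("outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create outdir: ", outdir)

  inputFiles <- character(0)
  if (is.character(studies)) {
    inputFiles <- c(inputFiles, studies)
    studies <- readStudyTable(studies)
  }
  phantomSeedNames <- NULL
  if (is(scans, "PhantomSpec")) {
    spec <- scans
    .logStage("phantom", sprintf("simulating %d subjects on a %s grid",
                                 spec@nSubjects,
                                 paste(spec@gridShape, collapse = "x")))
    if (is.character(seeds))
      seeds <- lapply(seeds, phantomSeedMask, spec = spec)
    scans <- simulateBold(spec)
    phantomSeedNames <- vapply(seeds, function(s) s@name, "")
  }
  if (!length(seeds)) stop("no seeds supplied")
  seedNames <- vapply(seeds, function(s) s@name, "")

  outputs <- list(); qc <- list()

  # --- stage 1: per-seed mapping chain -------------------------------
  .logStage("seedmap", sprintf("mapping %d seed(s) across %d subjects",
                               length(seeds), length(scans)))
  seedResults <- lapply(seeds, function(s)
    seedConnectivityMap(scans, s, config))
  names(seedResults) <- seedNames
  for (nm in seedNames) {
    fT <- file.path(outdir, sprintf("seed_%s_tmap.nii.gz", nm))
    fB <- file.path(outdir, sprintf("seed_%s_binary.nii.gz", nm))
    writeMap(seedResults[[nm]]$tmap, fT)
    writeMap(seedResults[[nm]]$binary, fB)
    outputs[[paste0("tmap_", nm)]] <- fT
    outputs[[paste0("binary_", nm)]] <- fB
    qc[[paste0("seedmap_", nm)]] <- qcFlags(seedResults[[nm]]$binary)
  }

  # --- stage 2: outcome-weighted efficacy map ------------------------
  .logStage("efficacy", "pooling outcomes and combining weighted maps")
  pooled <- outcomeTable(studies, weighting = poolingWeighting)
  missing <- setdiff(seedNames, pooled$target)
  if (length(missing))
    stop("efficacy stage: no outcome data for target(s): ",
         paste(missing, collapse = ", "))
  weights <- setNames(pooled$mean_seizure_reduction, pooled$target)
  binaries <- lapply(seedResults, `[[`, "binary")
  eff <- combineWeighted(binaries, weights[seedNames],
                         mode = config@efficacyMode)
  fE <- file.path(outdir, "efficacy_map.nii.gz")
  writeMap(eff, fE)
  outputs$efficacy_map <- fE
  fP <- file.path(outdir, "pooled_outcomes.tsv")
  write.table(pooled, fP, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$pooled_outcomes <- fP
  qc$efficacy <- list(mode = config@efficacyMode,
                      covered_voxels = sum(mapData(eff) > 0))

  # --- stage 3: overlap and node extraction --------------------------
  .logStage("overlap", "intersecting maps and extracting components")
  common <- intersectMaps(binaries)
  fO <- file.path(outdir, "overlap_map.nii.gz")
  writeMap(common, fO)
  outputs$overlap_map <- fO
  comps <- extractComponents(common, config@componentConnectivity,
                             config@minComponentVoxels)
  atlas <- assembleNetworkNodes(seeds, comps)
  fA <- file.path(outdir, "network_atlas.nii.gz")
  fL <- file.path(outdir, "network_atlas_labels.tsv")
  writeAtlas(atlas, fA, fL)
  outputs$atlas_image <- fA
  outputs$atlas_labels <- fL
  qc$overlap <- c(qcFlags(common),
                  list(n_components = sum(atlas@provenance == "overlap"),
                       n_regions = length(atlasLabels(atlas))))

  # --- stage 4: graph analysis ---------------------------------------
  .logStage("graphnet", "correlation matrix, clustering and centralities")
  cm <- regionCorrelationMatrix(scans, atlas)
  fM <- file.path(outdir, "correlation_matrix.tsv")
  writeCorrelationMatrix(cm, fM)
  outputs$correlation_matrix <- fM
  k <- min(config@nClusters, length(atlasLabels(atlas)))
  clusters <- hierarchicalCluster(cm, k, config@linkageMethod)
  fC <- file.path(outdir, "clusters.tsv")
  write.table(clusters, fC, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$clusters <- fC
  ng <- buildGraph(cm, config@edgeDisplayCutoff)
  fEd <- file.path(outdir, "graph_edges.tsv")
  fG <- file.path(outdir, "graph.graphml")
  writeGraph(ng, fEd, fG)
  outputs$graph_edges <- fEd
  outputs$graphml <- fG
  cent <- centralityTable(ng)
  fCt <- file.path(outdir, "centrality.tsv")
  write.table(cent, fCt, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$centrality <- fCt
  qc$graphnet <- c(qcFlags(cm),
                   list(n_nodes = igraph::vcount(graphObj(ng)),
                        n_edges = igraph::ecount(graphObj(ng)),
                        k_clusters = k))

  # --- manifest -------------------------------------------------------
  manifest <- list(
    software = list(package = "SeedConnectome",
                    version = as.character(packageVersion("SeedConnectome"))),
    config = list(
      t_threshold = config@tThreshold, alpha = config@alpha,
      brain_voxel_count = config@brainVoxelCount,
      edge_display_cutoff = config@edgeDisplayCutoff,
      n_clusters = config@nClusters,
      negative_edge_policy = config@negativeEdgePolicy,
      efficacy_mode = config@efficacyMode,
      component_connectivity = config@componentConnectivity,
      min_component_voxels = config@minComponentVoxels,
      rmap_aggregation = config@rmapAggregation,
      linkage_method = config@linkageMethod,
      pooling_weighting = poolingWeighting),
    seeds = as.list(seedNames),
    phantom_seeds = as.list(phantomSeedNames),
    thresholds = lapply(seedResults, `[[`, "threshold"),
    inputs = if (length(inputFiles))
      lapply(inputFiles, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))) else list(),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    qc = qc)
  fMan <- file.path(outdir, "run_manifest.yaml")
  yaml::write_yaml(manifest, fMan)
  .logStage("done", sprintf("%d artifacts written to %s",
                            length(outputs), outdir))
  invisible(manifest)
}
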