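#' @include AllClasses.R constructors.R
NULL

#' NIfTI-1 volume input/output
#'
#' Thin wrappers around RNifti providing lossless round trips of the data
#' array (written as float64) and the voxel-to-mm affine (stored in the
#' sform, code 2). 3D and 4D volumes are supported.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readNiftiVolume` returns a list with elements `data` (plain
#'   array), `affine` (4x4 matrix) and `trSeconds` (4th pixdim; `NA` for 3D
#'   volumes).
#' @name niftiIO
#' @export
readNiftiVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   imagedim = NULL, code = NULL)
  pd <- RNifti::pixdim(img)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))  # drop RNifti header attributes
  list(data = dat, affine = matrix(as.numeric(aff), 4L, 4L),
       trSeconds = if (length(dim(img)) >= 4L && length(pd) >= 4L)
         pd[4L] else NA_real_)
}

#' @rdname niftiIO
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param trSeconds optional repetition time stored in the 4th pixdim of 4D
#'   volumes.
#' @export
writeNiftiVolume <- function(data, affine, path, trSeconds = NA_real_) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  vdim <- abs(c(affine[1, 1], affine[2, 2], affine[3, 3]))
  pixdim <- if (nd == 4L) c(vdim, if (is.na(trSeconds)) 1 else trSeconds)
            else vdim
  img <- RNifti::asNifti(data)
  img <- RNifti::`pixdim<-`(img, pixdim)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  ok <- try(RNifti::writeNifti(img, path, datatype = "double"),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write NIfTI file: ", path)
  invisible(path)
}

#' Read a BoldScan from a 4D NIfTI file
#'
#' @param path NIfTI file with a 4D array.
#' @param trSeconds repetition time; defaults to the file's 4th pixdim.
#' @return A [BoldScan-class].
#' @export
readBoldScan <- function(path, trSeconds = NULL) {
  v <- readNiftiVolume(path)
  if (length(dim(v$data)) != 4L)
    stop(path, " is not a 4D volume")
  if (is.null(trSeconds)) trSeconds <- v$trSeconds
  if (is.na(trSeconds)) stop("TR not recorded in file; pass trSeconds")
  boldScan(v$data, v$affine, trSeconds)
}

#' Read a SeedMask from a 3D NIfTI file
#'
#' Nonzero voxels become mask members.
#'
#' @param path NIfTI file with a 3D array.
#' @param name seed label; defaults to the file basename.
#' @return A [SeedMask-class].
#' @export
readSeedMask <- function(path, name = NULL) {
  v <- readNiftiVolume(path)
  if (length(dim(v$data)) != 3L) stop(path, " is not a 3D volume")
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  seedMask(name, v$data != 0, v$affine)
}

#' Write a StatMap or EfficacyMap to NIfTI
#'
#' @param map a [StatMap-class] or [EfficacyMap-class].
#' @param path output file.
#' @export
writeMap <- function(map, path) {
  writeNiftiVolume(mapData(map), mapAffine(map), path)
}

#' Read the per-study seizure-outcome table
#'
#' Expects tab- or comma-delimited text with columns `target`,
#' `n_patients`, `outcome_value` (percent seizure reduction in
#' \[-100, 100\]), `outcome_kind` ("mean" or "median"; medians are accepted
#' as means when pooling) and `followup_months`.
#'
#' @param path delimited text file.
#' @return data.frame of study records, one row per study.
#' @export
readStudyTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("target", "n_patients", "outcome_value", "outcome_kind",
                "followup_months")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("study table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$n_patients < 1, na.rm = TRUE))
    stop("n_patients must be >= 1")
  bad <- !is.na(df$outcome_value) &
    (df$outcome_value < -100 | df$outcome_value > 100)
  if (any(bad))
    stop("outcome_value must lie in [-100, 100] percent")
  if (!all(df$outcome_kind %in% c("mean", "median", NA)))
    stop("outcome_kind must be 'mean' or 'median'")
  df
}

#' The bundled synthetic study-outcome table
#'
#' A synthetic stand-in for a per-study outcome list, constructed so that
#' its per-target marginals (study counts, total patients, simple-mean
#' pooled seizure reduction) match published per-target summaries for the
#' three clinically established epilepsy DBS targets (ANT, CMT, HC). The
#' individual rows are synthetic; only the marginals are calibrated.
#'
#' @return data.frame as from [readStudyTable()].
#' @export
syntheticStudyTable <- function() {
  readStudyTable(system.file("extdata", "study_outcomes_synthetic.tsv",
                             package = "SeedConnectome", mustWork = TRUE))
}

#' Correlation matrix text input/output
#'
#' Square delimited text with region labels as header and row names.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param path file path.
#' @name correlationMatrixIO
#' @export
writeCorrelationMatrix <- function(cm, path) {
  v <- corValues(cm)
  df <- data.frame(region = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname correlationMatrixIO
#' @param nSubjects number of subjects recorded on the loaded object.
#' @export
readCorrelationMatrix <- function(path, nSubjects = NA_integer_) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1L]]
  v <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(v) <- NULL
  v <- (v + t(v)) / 2  # absorb decimal-rounding asymmetry from text form
  diag(v) <- 1
  new("CorrelationMatrix", labels = labels, values = v,
      nSubjects = as.integer(nSubjects), qc = list())
}

#' Export a NetworkGraph as edge list and GraphML
#'
#' The edge list is tab-delimited (`from`, `to`, `weight`,
#' `below_display_cutoff`); GraphML is written through igraph and carries
#' the same attributes.
#'
#' @param ng a [NetworkGraph-class].
#' @param edgelistPath,graphmlPath output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the written paths.
#' @export
writeGraph <- function(ng, edgelistPath = NULL, graphmlPath = NULL) {
  g <- graphObj(ng)
  if (!is.null(edgelistPath)) {
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     weight = igraph::E(g)$weight,
                     below_display_cutoff =
                       igraph::E(g)$weight < ng@displayCutoff)
    write.table(df, edgelistPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  invisible(c(edgelistPath, graphmlPath))
}

#' Write a NodeAtlas as an integer label image plus a label table
#'
#' @param atlas a [NodeAtlas-class].
#' @param imagePath NIfTI output for the label volume.
#' @param tablePath delimited-text output (`id`, `name`, `voxel_count`,
#'   `provenance`).
#' @export
writeAtlas <- function(atlas, imagePath, tablePath) {
  writeNiftiVolume(mapData(atlas) * 1, mapAffine(atlas), imagePath)
  counts <- tabulate(mapData(atlas), nbins = length(atlasLabels(atlas)))
  df <- data.frame(id = seq_along(atlasLabels(atlas)),
                   name = atlasLabels(atlas), voxel_count = counts,
                   provenance = atlas@provenance)
  write.table(df, tablePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(imagePath, tablePath))
}
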