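#' @include AllClasses.R constructors.R
NULL

#' Mean seed time course of one subject
#'
#' Arithmetic mean over the seed's voxels at each time point.
#'
#' @param scan a [BoldScan-class].
#' @param seed a [SeedMask-class] on the same grid and affine.
#' @return Numeric time course of length `dim(scan)[4]`.
#' @export
extractSeedTimecourse <- function(scan, seed) {
  d <- dim(mapData(scan))
  if (!.sameGrid(d[1:3], mapAffine(scan), dim(mapData(seed)),
                 mapAffine(seed)))
    stop(sprintf(
      "seed grid (%s) does not match scan grid (%s) within tolerance",
      paste(dim(mapData(seed)), collapse = "x"),
      paste(d[1:3], collapse = "x")))
  idx <- which(mapData(seed))
  if (length(idx) == 0L) stop("seed mask selects no voxels")
  mat <- matrix(mapData(scan), nrow = prod(d[1:3]))
  colMeans(mat[idx, , drop = FALSE])
}

#' Seed-to-voxel Pearson correlation map for one subject
#'
#' Correlates the seed time course with every voxel's time course. Voxels
#' with zero temporal variance get r = 0 and are counted in the QC flag
#' `zero_variance_voxels`; the map never contains non-finite values.
#'
#' @param scan a [BoldScan-class].
#' @param seedTc seed mean time course (same length as the scan's time
#'   dimension).
#' @param sourceSeed label recorded on the output map.
#' @return A [StatMap-class] of kind "r".
#' @export
seedToVoxelRmap <- function(scan, seedTc, sourceSeed = NA_character_) {
  d <- dim(mapData(scan))
  if (length(seedTc) != d[4L])
    stop("seed time course length does not match scan time dimension")
  if (sd(seedTc) == 0)
    stop("seed time course has zero variance")
  mat <- matrix(mapData(scan), nrow = prod(d[1:3]))
  vc <- mat - rowMeans(mat)
  sc <- seedTc - mean(seedTc)
  num <- as.vector(vc %*% sc)
  den <- sqrt(rowSums(vc^2)) * sqrt(sum(sc^2))
  r <- ifelse(den == 0, 0, num / den)
  r <- pmin(1, pmax(-1, r))  # guard rounding at |r| = 1
  nZero <- sum(den == 0)
  statMap("r", array(r, dim = d[1:3]), mapAffine(scan),
          sourceSeed = sourceSeed,
          qc = list(zero_variance_voxels = nZero))
}

#' Fisher z (variance-stabilizing) transform of an r-map
#'
#' `z = atanh(r)`; correlations at exactly |r| = 1 are clamped to
#' 1 - 1e-7 before the transform and counted in the QC flag
#' `clamped_unit_r`.
#'
#' @param rmap a [StatMap-class] of kind "r".
#' @return A [StatMap-class] of kind "z".
#' @export
fisherZ <- function(rmap) {
  if (mapKind(rmap) != "r") stop("fisherZ expects an r-map")
  r <- mapData(rmap)
  clamped <- sum(abs(r) >= 1)
  lim <- 1 - 1e-7
  r <- array(pmin(lim, pmax(-lim, r)), dim = dim(r))
  statMap("z", atanh(r), mapAffine(rmap), sourceSeed = rmap@sourceSeed,
          qc = c(rmap@qc, list(clamped_unit_r = clamped)))
}

#' Group one-sample t-map from per-subject z-maps
#'
#' Voxelwise one-sample t statistic of the subjects' Fisher-z values
#' against zero, with df = n - 1. Voxels with zero cross-subject variance
#' become `+/-Inf` (nonzero mean) or 0 (zero mean) and are counted in the
#' QC flags `infinite_t_voxels` / `zero_variance_zero_mean_voxels`.
#'
#' @param zmaps list of [StatMap-class] of kind "z", one per subject, on a
#'   shared grid.
#' @return A [StatMap-class] of kind "t" with `df = n - 1`.
#' @export
groupTmap <- function(zmaps) {
  n <- length(zmaps)
  if (n < 2L) stop("groupTmap needs at least 2 subjects")
  kinds <- vapply(zmaps, mapKind, "")
  if (!all(kinds == "z")) stop("all inputs must be z-maps")
  d <- dim(mapData(zmaps[[1L]]))
  aff <- mapAffine(zmaps[[1L]])
  for (m in zmaps[-1L])
    if (!.sameGrid(d, aff, dim(mapData(m)), mapAffine(m)))
      stop("z-maps must share grid shape and affine")
  zs <- matrix(unlist(lapply(zmaps, function(m) as.vector(mapData(m)))),
               nrow = prod(d))
  mu <- rowMeans(zs)
  s <- sqrt(rowSums((zs - mu)^2) / (n - 1))
  t <- ifelse(s > 0, mu / (s / sqrt(n)),
              ifelse(mu > 0, Inf, ifelse(mu < 0, -Inf, 0)))
  statMap("t", array(t, dim = d), aff, df = n - 1,
          sourceSeed = zmaps[[1L]]@sourceSeed,
          qc = list(n_subjects = n,
                    infinite_t_voxels = sum(is.infinite(t)),
                    zero_variance_zero_mean_voxels =
                      sum(s == 0 & mu == 0)))
}

#' Bonferroni-corrected two-tailed t threshold
#'
#' Smallest |t| whose two-tailed tail probability under the t distribution
#' with `df` degrees of freedom is at most `alpha / nTests`. With
#' alpha 0.05, a whole-brain test count near 67,000 and df = 999 this
#' reproduces the conventional |t| = 5.1 whole-brain cutoff.
#'
#' @param alpha family-wise error level, in (0, 1).
#' @param nTests number of voxelwise tests.
#' @param df degrees of freedom.
#' @return The critical t value.
#' @examples
#' bonferroniTThreshold(0.05, 67000, 999)  # about 5.0
#' @export
bonferroniTThreshold <- function(alpha, nTests, df) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1, df >= 1)
  qt(1 - alpha / (2 * nTests), df = df)
}

#' Threshold and binarize a t-map
#'
#' Voxels with `|t| >= tThreshold` become 1, all others 0. The
#' suprathreshold count is recorded in the QC flag
#' `suprathreshold_voxels`.
#'
#' @param tmap a [StatMap-class] of kind "t".
#' @param tThreshold positive cutoff.
#' @return A [StatMap-class] of kind "binary".
#' @export
thresholdBinarize <- function(tmap, tThreshold) {
  if (mapKind(tmap) != "t") stop("thresholdBinarize expects a t-map")
  if (!is.finite(tThreshold) || tThreshold <= 0)
    stop("tThreshold must be > 0")
  b <- (abs(mapData(tmap)) >= tThreshold) * 1
  statMap("binary", b, mapAffine(tmap), sourceSeed = tmap@sourceSeed,
          qc = c(tmap@qc, list(t_threshold = tThreshold,
                               suprathreshold_voxels = sum(b))))
}

#' Full per-seed mapping chain: r-maps to a binarized group map
#'
#' Runs the chain for one seed across all subjects: per-subject seed time
#' course, seed-to-voxel r-map, Fisher z, group one-sample t-map, and
#' Bonferroni-thresholded binarization. With
#' `config@rmapAggregation = "average_r"` the per-subject r-maps are first
#' averaged on the Fisher-z scale into a single mean r-map (the "average
#' correlation across the dataset" view); the statistic is then the z-test
#' of the mean Fisher z against zero with its known sampling variance
#' `1 / (n_subjects * (T - 3))`, carried as a t-map with df
#' `n_subjects * (T - 3)`. Both routes share the same thresholding.
#'
#' @param scans list of [BoldScan-class].
#' @param seed a [SeedMask-class].
#' @param config an [AnalysisConfig-class]; if `config@tThreshold` is `NA`
#'   the cutoff is derived with [bonferroniTThreshold()] at
#'   `df = n_subjects - 1` over `config@brainVoxelCount` tests.
#' @return Named list: `binary`, `tmap` (both [StatMap-class]),
#'   `threshold` (the cutoff used), and with `"average_r"` aggregation
#'   also `meanRmap`, the dataset-mean r-map.
#' @export
seedConnectivityMap <- function(scans, seed, config = analysisConfig()) {
  validObject(config)
  zmaps <- lapply(scans, function(scan) {
    tc <- extractSeedTimecourse(scan, seed)
    fisherZ(seedToVoxelRmap(scan, tc, sourceSeed = seed@name))
  })
  meanRmap <- NULL
  if (config@rmapAggregation == "per_subject_t") {
    tmap <- groupTmap(zmaps)
  } else {
    n <- length(zmaps)
    tpts <- dim(mapData(scans[[1L]]))[4L]
    zbar <- Reduce(`+`, lapply(zmaps, mapData)) / n
    meanRmap <- statMap("r", tanh(zbar), mapAffine(zmaps[[1L]]),
                        sourceSeed = seed@name)
    tmap <- statMap("t", zbar * sqrt(n * (tpts - 3)),
                    mapAffine(zmaps[[1L]]), df = n * (tpts - 3),
                    sourceSeed = seed@name,
                    qc = list(n_subjects = n, aggregation = "average_r"))
  }
  thr <- if (is.na(config@tThreshold))
    bonferroniTThreshold(config@alpha, config@brainVoxelCount, tmap@df)
  else config@tThreshold
  out <- list(binary = thresholdBinarize(tmap, thr), tmap = tmap,
              threshold = thr)
  if (!is.null(meanRmap)) out$meanRmap <- meanRmap
  out
}
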