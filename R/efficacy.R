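#' @include AllClasses.R constructors.R
NULL

#' Pool per-study seizure reduction into a per-target mean
#'
#' Averages the studies' reported percent seizure reduction for one DBS
#' target. Study medians are accepted as means without distributional
#' correction, following the pooling convention of the clinical review
#' literature. Rows without a numeric outcome are excluded.
#'
#' @param studies data.frame as from [readStudyTable()].
#' @param target target label to pool (e.g. "ANT").
#' @param weighting "simple" (unweighted mean over studies, the default)
#'   or "by_n" (weighted by each study's patient count).
#' @return Pooled mean seizure reduction in percent (unrounded).
#' @examples
#' df <- data.frame(target = "ANT", n_patients = c(10, 20, 30),
#'                  outcome_value = c(50, 60, 70),
#'                  outcome_kind = "mean", followup_months = 12)
#' poolSeizureReduction(df, "ANT")                      # 60
#' poolSeizureReduction(df, "ANT", weighting = "by_n")  # 63.33
#' @export
poolSeizureReduction <- function(studies, target,
                                 weighting = c("simple", "by_n")) {
  weighting <- match.arg(weighting)
  rows <- studies[studies$target == target &
                  !is.na(studies$outcome_value), , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no studies with numeric outcomes for target '", target, "'")
  if (weighting == "simple")
    mean(rows$outcome_value)
  else
    sum(rows$outcome_value * rows$n_patients) / sum(rows$n_patients)
}

#' Pooled outcome table for all targets
#'
#' @param studies data.frame as from [readStudyTable()].
#' @param weighting pooling convention, see [poolSeizureReduction()].
#' @return data.frame with one row per target: `target`,
#'   `mean_seizure_reduction` (percent), `n_studies`, `n_patients`.
#' @export
outcomeTable <- function(studies, weighting = c("simple", "by_n")) {
  weighting <- match.arg(weighting)
  targets <- unique(studies$target)
  rows <- lapply(targets, function(tg) {
    sub <- studies[studies$target == tg & !is.na(studies$outcome_value), ,
                   drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(target = tg,
               mean_seizure_reduction =
                 poolSeizureReduction(studies, tg, weighting),
               n_studies = nrow(sub), n_patients = sum(sub$n_patients))
  })
  do.call(rbind, rows)
}

#' Combine binarized target maps weighted by seizure outcomes
#'
#' Assigns each target's mean seizure reduction as a weight to its
#' binarized connectivity map and combines the maps voxelwise into an
#' efficacy map of percent improvement. `mode = "sum"` gives
#' `sum_i w_i * b_i(v)`; `mode = "mean"` divides that sum by the number of
#' covering maps, keeping values on the percent scale. Voxels covered by
#' no map are 0.
#'
#' @param maps named list of binary [StatMap-class] objects, one per
#'   target, on a shared grid; names are target labels.
#' @param weights named numeric vector of percent seizure reduction per
#'   target, covering every map name (e.g. from [outcomeTable()]).
#' @param mode "mean" (default) or "sum".
#' @return An [EfficacyMap-class].
#' @examples
#' b <- array(1, dim = c(2, 2, 2))
#' maps <- list(ANT = statMap("binary", b), CMT = statMap("binary", b),
#'              HC = statMap("binary", b))
#' eff <- combineWeighted(maps, c(ANT = 60, CMT = 69, HC = 65))
#' mapData(eff)[1, 1, 1]  # (60 + 69 + 65) / 3
#' @export
combineWeighted <- function(maps, weights, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (length(maps) < 1L) stop("need at least one map")
  targets <- names(maps)
  if (is.null(targets) || any(!nzchar(targets)))
    stop("maps must be a named list of target maps")
  missing <- setdiff(targets, names(weights))
  if (length(missing))
    stop("missing weight for target(s): ", paste(missing, collapse = ", "))
  d <- dim(mapData(maps[[1L]]))
  aff <- mapAffine(maps[[1L]])
  for (m in maps) {
    if (mapKind(m) != "binary") stop("all maps must be binary StatMaps")
    if (!.sameGrid(d, aff, dim(mapData(m)), mapAffine(m)))
      stop(sprintf("grid mismatch: %s vs %s",
                   paste(d, collapse = "x"),
                   paste(dim(mapData(m)), collapse = "x")))
  }
  wsum <- array(0, dim = d)
  cover <- array(0, dim = d)
  for (tg in targets) {
    b <- mapData(maps[[tg]])
    wsum <- wsum + weights[[tg]] * b
    cover <- cover + b
  }
  data <- if (mode == "sum") wsum else {
    out <- array(0, dim = d)
    pos <- cover > 0
    out[pos] <- wsum[pos] / cover[pos]
    out
  }
  new("EfficacyMap", data = data, affine = aff,
      contributingTargets = targets, mode = mode)
}
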