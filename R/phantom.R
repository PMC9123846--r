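#' @include AllClasses.R constructors.R
NULL

#' Band-limiting low-pass filter for BOLD time courses
#'
#' Hard frequency-domain (FFT brick-wall) filter: the series is transformed
#' with the DFT, every bin at or above `cutoffHz` is zeroed, and the series
#' is transformed back. The zero-frequency (DC) component is always
#' retained, so a constant series passes unchanged. At DFT bin frequencies
#' the stopband attenuation is total; off-bin sinusoids leak a small
#' fraction of their variance across bins (below a few percent for the
#' 124-point, TR = 3 s regime this emulates). The filter is exactly linear.
#'
#' @param series numeric time course of length >= 8.
#' @param cutoffHz cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * trSeconds)`.
#' @param trSeconds sampling interval in seconds.
#' @return Filtered series of the same length.
#' @examples
#' tt <- seq(0, by = 3, length.out = 124)
#' x <- sin(2 * pi * 0.15 * tt)   # above the 0.08 Hz band
#' y <- lowpassFilter(x, 0.08, 3)
#' var(y) / var(x)                # almost all variance removed
#' @export
lowpassFilter <- function(series, cutoffHz, trSeconds) {
  n <- length(series)
  if (n < 8L) stop("series must have length >= 8")
  nyquist <- 1 / (2 * trSeconds)
  if (!is.finite(cutoffHz) || cutoffHz <= 0)
    stop("cutoffHz must be positive")
  if (cutoffHz >= nyquist)
    stop(sprintf("cutoffHz (%g) must be below Nyquist (%g)",
                 cutoffHz, nyquist))
  if (any(!is.finite(series))) stop("series must be finite")
  k <- 0:(n - 1L)
  freq <- pmin(k, n - k) / (n * trSeconds)  # folded (two-sided) frequencies
  keep <- freq < cutoffHz
  Re(fft(fft(series) * keep, inverse = TRUE)) / n
}

# Unit-variance band-limited latent signal: white Gaussian, filtered,
# centered and rescaled to sample sd 1, then scaled by signalSd.
.latentSignal <- function(n, cutoffHz, trSeconds, signalSd) {
  x <- lowpassFilter(rnorm(n), cutoffHz, trSeconds)
  s <- sd(x)
  if (s == 0) return(rep(0, n))
  signalSd * (x - mean(x)) / s
}

#' 3D logical mask of a phantom region
#'
#' @param region a [RegionSpec-class].
#' @param gridShape voxel counts per axis.
#' @return 3D logical array.
#' @export
regionMaskArray <- function(region, gridShape) {
  m <- array(FALSE, dim = gridShape)
  m[.linIndex(region@voxels, gridShape)] <- TRUE
  m
}

#' SeedMask for a named phantom region
#'
#' @param spec a [PhantomSpec-class].
#' @param name region name.
#' @return A [SeedMask-class] on the phantom grid.
#' @export
phantomSeedMask <- function(spec, name) {
  nm <- vapply(spec@regions, function(r) r@name, "")
  i <- match(name, nm)
  if (is.na(i)) stop("no region named '", name, "' in phantom spec")
  seedMask(name, regionMaskArray(spec@regions[[i]], spec@gridShape),
           gridAffine(spec@voxelSizeMm))
}

#' Simulate multi-subject resting-state BOLD with planted covariance
#'
#' Each voxel's time course is a linear mixture of independent band-limited
#' latent network signals plus white Gaussian noise:
#' `x_v(t) = sum_k a_vk * s_k(t) + noiseSd * eps_v(t)`. Latent signals are
#' drawn fresh per subject, band-limited below each network's cutoff, and
#' re-standardized to unit sample variance, which makes the population
#' seed-to-voxel correlation of a single-network voxel the closed form
#' `a * sigma_s / sqrt(a^2 * sigma_s^2 + sigma^2)`. Voxels outside all
#' regions carry pure noise. Output is bit-identical for a fixed
#' `rngSeed`.
#'
#' @param spec a validated [PhantomSpec-class].
#' @return List of [BoldScan-class] objects, one per subject.
#' @examples
#' net <- networkSpec("dmn")
#' seed <- regionSpec("seed", cbind(1:2, 1, 1), c(dmn = 1))
#' sp <- phantomSpec(c(4, 4, 4), nSubjects = 2, regions = list(seed),
#'                   networks = list(net), nTimepoints = 24, rngSeed = 7)
#' scans <- simulateBold(sp)
#' dim(mapData(scans[[1]]))
#' @export
simulateBold <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  nvox <- prod(gs)
  nt <- spec@nTimepoints
  affine <- gridAffine(spec@voxelSizeMm)
  netNames <- vapply(spec@networks, function(n) n@name, "")

  set.seed(spec@rngSeed)
  lapply(seq_len(spec@nSubjects), function(i) {
    latents <- lapply(spec@networks, function(nw)
      .latentSignal(nt, nw@cutoffHz, spec@trSeconds, nw@signalSd))
    names(latents) <- netNames
    mat <- matrix(rnorm(nvox * nt, sd = spec@noiseSd), nrow = nvox)
    for (r in spec@regions) {
      idx <- .linIndex(r@voxels, gs)
      for (k in seq_along(r@networkLoadings)) {
        a <- r@networkLoadings[[k]]
        if (a == 0) next
        s <- latents[[names(r@networkLoadings)[k]]]
        mat[idx, ] <- mat[idx, ] + rep(a * s, each = length(idx))
      }
    }
    boldScan(array(mat, dim = c(gs, nt)), affine, spec@trSeconds)
  })
}

#' Write a phantom to disk as NIfTI volumes plus a manifest
#'
#' One 4D NIfTI per subject, one 3D binary mask per region, and a YAML
#' manifest describing the planted structure. Volumes are written as
#' float64 so a round-trip read reproduces the arrays exactly.
#'
#' @param scans list of [BoldScan-class] from [simulateBold()].
#' @param spec the [PhantomSpec-class] that produced them.
#' @param directory output directory (created if missing).
#' @return Invisibly, a named list with `scans`, `masks` and `manifest`
#'   file paths.
#' @export
writePhantom <- function(scans, spec, directory) {
  if (length(scans) != spec@nSubjects)
    stop("number of scans does not match spec@nSubjects")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)

  scanFiles <- vapply(seq_along(scans), function(i) {
    f <- file.path(directory, sprintf("subject_%03d_bold.nii.gz", i))
    writeNiftiVolume(mapData(scans[[i]]), mapAffine(scans[[i]]), f,
                     trSeconds = spec@trSeconds)
    f
  }, "")
  maskFiles <- vapply(spec@regions, function(r) {
    f <- file.path(directory, sprintf("region_%s_mask.nii.gz", r@name))
    writeNiftiVolume(regionMaskArray(r, spec@gridShape) * 1,
                     gridAffine(spec@voxelSizeMm), f)
    f
  }, "")

  manifest <- list(
    grid_shape = as.integer(spec@gridShape),
    voxel_size_mm = spec@voxelSizeMm,
    n_subjects = spec@nSubjects,
    n_timepoints = spec@nTimepoints,
    tr_seconds = spec@trSeconds,
    noise_sd = spec@noiseSd,
    rng_seed = spec@rngSeed,
    networks = lapply(spec@networks, function(n)
      list(name = n@name, cutoff_hz = n@cutoffHz, signal_sd = n@signalSd)),
    regions = lapply(spec@regions, function(r)
      list(name = r@name, n_voxels = nrow(r@voxels),
           network_loadings = as.list(r@networkLoadings))),
    files = list(scans = basename(scanFiles), masks = basename(maskFiles)))
  manifestFile <- file.path(directory, "phantom_manifest.yaml")
  yaml::write_yaml(manifest, manifestFile)
  invisible(list(scans = scanFiles, masks = maskFiles,
                 manifest = manifestFile))
}
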