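# Shared fixture builders: all phantoms are generated in code at test time.

# voxel block as an n x 3 index matrix
voxelCube <- function(x0, y0, z0, w = 2L, wy = w, wz = w) {
  as.matrix(expand.grid(x0:(x0 + w - 1L), y0:(y0 + wy - 1L),
                        z0:(z0 + wz - 1L)))
}

# one seed region driving one latent network, plus target voxels with a
# given loading; everything else pure noise
singleNetworkPhantom <- function(nSubjects, rngSeed, grid = c(10L, 10L, 10L),
                                 loading = 1, noiseSd = 1, signalSd = 1,
                                 nTimepoints = 124L) {
  seedW <- min(5L, min(grid))
  targetW <- min(4L, min(grid) - seedW)
  stopifnot(targetW >= 1L)
  t0 <- grid - targetW + 1L  # opposite corner, disjoint from the seed
  phantomSpec(
    grid, nSubjects = nSubjects,
    regions = list(
      regionSpec("seed", voxelCube(1L, 1L, 1L, seedW), c(net = 1)),
      regionSpec("target",
                 voxelCube(t0[1L], t0[2L], t0[3L], targetW),
                 c(net = loading))),
    networks = list(networkSpec("net", signalSd = signalSd)),
    noiseSd = noiseSd, nTimepoints = nTimepoints, rngSeed = rngSeed)
}

# all-null phantom: one seed region, zero loadings everywhere
nullPhantom <- function(nSubjects, rngSeed, grid = c(12L, 12L, 12L),
                        nTimepoints = 124L) {
  phantomSpec(
    grid, nSubjects = nSubjects,
    regions = list(regionSpec("seed", voxelCube(5L, 5L, 5L, 2L))),
    networks = list(), nTimepoints = nTimepoints, rngSeed = rngSeed)
}

# three single-network seeds plus one territory loading on all three
# networks; population seed-to-common r = 1/sqrt(1 + 3) = 0.5 at unit
# loadings and unit noise
tripleOverlapPhantom <- function(nSubjects, rngSeed,
                                 grid = c(12L, 12L, 12L)) {
  phantomSpec(
    grid, nSubjects = nSubjects,
    regions = list(
      regionSpec("ANT", voxelCube(1L, 1L, 1L, 3L), c(nA = 1)),
      regionSpec("CMT", voxelCube(1L, 9L, 1L, 3L), c(nB = 1)),
      regionSpec("HC", voxelCube(9L, 1L, 1L, 3L), c(nC = 1)),
      regionSpec("common", voxelCube(9L, 9L, 9L, 3L),
                 c(nA = 1, nB = 1, nC = 1))),
    networks = list(networkSpec("nA"), networkSpec("nB"),
                    networkSpec("nC")),
    rngSeed = rngSeed)
}

# connector-hub phantom: the hub loads on every latent network, each spoke
# on exactly one
hubPhantom <- function(nSubjects, rngSeed, nSpokes = 4L) {
  nets <- lapply(seq_len(nSpokes), function(k)
    networkSpec(sprintf("net%d", k)))
  hubLoad <- setNames(rep(1, nSpokes), sprintf("net%d", seq_len(nSpokes)))
  regions <- c(
    list(regionSpec("hub", voxelCube(1L, 1L, 1L, 3L), hubLoad)),
    lapply(seq_len(nSpokes), function(k)
      regionSpec(sprintf("spoke%d", k),
                 voxelCube(1L + 4L * k, 1L, 1L, 3L),
                 setNames(1, sprintf("net%d", k)))))
  phantomSpec(c(4L * nSpokes + 3L, 3L, 3L), nSubjects = nSubjects,
              regions = regions, networks = nets, rngSeed = rngSeed)
}

atlasFromSpec <- function(spec) {
  masks <- lapply(spec@regions, regionMaskArray, gridShape = spec@gridShape)
  nodeAtlas(vapply(spec@regions, function(r) r@name, ""), masks,
            rep("seed", length(masks)), gridAffine(spec@voxelSizeMm))
}

# constant-free white-noise BoldScan for plumbing tests
noiseScan <- function(dim4 = c(4L, 4L, 4L, 20L), sd = 1, seed = 1L,
                      trSeconds = 3) {
  set.seed(seed)
  boldScan(array(rnorm(prod(dim4), sd = sd), dim = dim4),
           gridAffine(), trSeconds)
}
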