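---
title: "Mapping the common network of neuromodulation targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the common network of neuromodulation targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeedConnectome)
```

## The problem

Deep brain stimulation (DBS) for drug-resistant epilepsy uses several
anatomically distinct targets — most prominently the anterior thalamic
nucleus (ANT), the centromedian thalamic nucleus (CMT) and the
hippocampus (HC) — yet all three reduce seizures in a substantial fraction
of patients. A natural hypothesis is that they engage one shared
cortico-subcortical network. SeedConnectome implements the analysis chain
that operationalizes this hypothesis on a normative resting-state fMRI
cohort:

1. **Seed mapping** — for each target seed, whole-brain seed-to-voxel
   Pearson r-maps per subject, Fisher-z transformed, aggregated into a
   group one-sample t-map, Bonferroni-thresholded and binarized.
2. **Efficacy weighting** — per-target mean seizure reduction (pooled from
   a study table) assigned as a weight to each binarized map; maps
   combined into a voxel efficacy map of percent improvement.
3. **Overlap** — voxelwise intersection of the binarized maps outlines the
   common territory; connected components become named network nodes
   alongside the seeds.
4. **Graph analysis** — region-by-region correlation matrix, hierarchical
   clustering, a positive-weight graph (anticorrelations dropped), and
   betweenness/closeness centralities reported as z-scores.

Because the full 1000-subject normative connectome and real anatomical
seeds cannot be bundled, the package ships a synthetic resting-state
phantom generator whose planted covariance structure makes every stage
verifiable by parameter recovery.

## The statistical chain

Per subject $i$ and voxel $v$, the seed correlation is
$r_{iv} = \mathrm{cor}(\bar{x}_{i,\mathrm{seed}}, x_{iv})$ where
$\bar{x}_{i,\mathrm{seed}}$ is the arithmetic mean time course over seed
voxels. Values are variance-stabilized with the Fisher transform
$z = \operatorname{atanh} r$ and the group statistic is the one-sample t

$$ t_v = \frac{\bar z_v}{s_v / \sqrt{n}}, \qquad \mathrm{df} = n - 1 . $$

The binarization cutoff is the two-tailed Bonferroni threshold: the
smallest $t^\*$ with $2 P(T_{\mathrm{df}} \le -t^\*) \le \alpha / m$ over
$m$ voxelwise tests. At $\alpha = 0.05$, $m = 67{,}000$ (a nominal 3 mm
in-brain grid) and df = 999 this gives $t^\* \approx 5.0$, consistent
with the conventional whole-brain cutoff $|t| = 5.1$ used as the package
default; the default `tThreshold = 5.1` is a direct override, and setting
it to `NA` derives the cutoff from `alpha`, `brainVoxelCount` and the
observed df.

The source texts for this style of analysis describe the aggregation only
as an "average correlation" that is "converted to t-maps", without the
formula. Two defensible readings are implemented behind
`analysisConfig(rmapAggregation = )`:

* `"per_subject_t"` (default): per-subject Fisher z, one-sample t across
  subjects, df = n − 1. This is the standard normative-connectome recipe
  and makes the t-map's null distribution exact under per-subject
  exchangeability.
* `"average_r"`: the per-subject z-maps are averaged into a single mean
  r-map (reported alongside), and the statistic is the z-test of
  $\bar z$ with its known sampling variance $1/(n(T-3))$, carried with
  df $= n(T-3)$.

Both routes share thresholding and everything downstream. Where one or
two functional runs per subject exist, runs are combined by averaging
Fisher-z maps — equivalent to treating runs as exchangeable replicates —
since no canonical combination rule exists; the phantom emulates a single
run per subject.

Zero-variance voxels (possible at phantom edges or in masked data) yield
r = 0 with a QC count instead of an error, so the map chain never
produces non-finite values; correlations at exactly $|r|=1$ are clamped
to $1 - 10^{-7}$ before the z transform and flagged.

## Outcome pooling and the efficacy map

Per-target mean seizure reduction (SR, percent) is the mean of per-study
outcomes; study *medians* are accepted as means without distributional
correction, which mirrors how such clinical summaries are pooled in
practice. Pooling weight is a flag: `"simple"` (unweighted across
studies; the default) or `"by_n"` (patient-weighted). The bundled table
`inst/extdata/study_outcomes_synthetic.tsv` is a **synthetic** per-study
list: the real per-study supplementary data are not redistributable here,
so the table is constructed to match the published per-target marginals —
23 ANT studies (330 patients, pooled 59.6%), 8 CMT studies (90 patients,
69.3%), and 13 HC studies (107 patients, 64.6%) — under simple-mean
pooling, which is therefore the documented default. These round to the
headline 60/69/65% weights.

Where binarized maps overlap, the efficacy map can either **sum** the
weights, $\sum_i w_i b_i(v)$, or **average** them over the covering maps.
The default is `mean`: the map is described as percent improvement, and
averaging keeps voxel values on the percent scale (bounded by the largest
target weight) rather than letting three overlapping 60–70% weights
stack to ~200. `sum` is retained for users who want coverage-weighted
emphasis.

## Overlap nodes

The intersection map is a plain logical AND. Discrete nodes are the
connected components of that map; the neighborhood (6 or 26) and the
minimum component size are configurable with defaults 26 and 5 voxels
(≈135 mm³ at 3 mm isotropic) — large enough to suppress single-voxel
speckle, small enough to keep subcortical nodes. Components are labeled
deterministically by descending size, ties broken by the smallest
column-major voxel index. When components and seeds claim the same
voxels, seeds win: they are the anchored anatomy, and the final atlas is
pairwise disjoint by construction. The size-averaging of two particular
regions described in the source analyses (a display normalization) is
deliberately not reproduced; regions enter at native size.

## Graph analysis

The region correlation matrix is computed per subject from region-mean
time courses, Fisher-z averaged across subjects and back-transformed.
Clustering is agglomerative on Euclidean distances between matrix rows;
the linkage is `"complete"` by default because that is the default of the
heat-map tooling this analysis style standardized on, and it is
configurable. The graph keeps only positively correlated pairs — the
standard practice of excluding anticorrelations from weighted graph
metrics — with edge weight = r.

For shortest-path measures, edge **length** is `1/weight` (the
convention of the common graph toolkits; `1 - weight` is available).
Betweenness is unnormalized Brandes pair counting with fractional credit
over tied shortest paths; closeness is $(n_c-1)/\sum d$ within each
node's component, so disconnected graphs are analyzed per component and
flagged rather than rejected. Both measures are reported raw and as
z-scores $(x - \bar x)/s$; a constant vector z-scores to all zeros with a
flag. The display cutoff (0.3 by default; the alternative 0.2 appears in
the same source literature and both are honest choices) affects *only*
the `below_display_cutoff` flag in exported edge lists — never the
centralities, since silently thresholding the graph would change shortest
paths in uncontrolled ways.

## The synthetic phantom

Each voxel's time course is
$x_v(t) = \sum_k a_{vk}\, s_k(t) + \sigma\, \varepsilon_v(t)$:
independent latent network signals $s_k$ (white Gaussian series,
band-limited below 0.08 Hz, re-standardized to unit sample variance and
drawn fresh per subject) mixed by region loadings, plus i.i.d. Gaussian
noise. Defaults mirror the emulated acquisition: TR = 3 s, 124 time
points, 3 mm isotropic voxels, signals below 0.08 Hz. The
re-standardization makes the population seed-to-voxel correlation of a
single-network voxel the exact closed form

$$ \rho = \frac{a\,\sigma_s}{\sqrt{a^2 \sigma_s^2 + \sigma^2}}, $$

which is the oracle used throughout the tests (e.g. $a=\sigma_s=\sigma=1
\Rightarrow \rho = 1/\sqrt2$).

The band-limiting filter is a hard FFT brick wall: DFT bins at or above
the cutoff are zeroed and the series inverted back. This choice is exactly
linear, preserves DC exactly, has total stopband attenuation at bin
frequencies, and keeps the unit-variance re-standardization exact; off-bin
sinusoids leak a few percent of variance across bins, which the spectral
tests bound explicitly (a 0.15 Hz sinusoid retains under 5% of its
variance, a 0.02 Hz sinusoid at least 90%).

What the phantom deliberately does **not** emulate: hemodynamic response
shape, physiological (cardiac/respiratory) noise, head motion, spatial
autocorrelation/smoothing, and multi-echo acquisition. Passing tests
therefore demonstrate the *statistical* correctness of the chain —
thresholds calibrated, closed forms recovered, planted structure found —
not robustness to the artifacts of real fMRI.

One consequence of the seed-to-voxel design is worth noting: on an
all-null phantom the seed's own voxels still correlate with the seed mean
time course (each voxel is part of the average, $r \approx 1/\sqrt m$),
so family-wise error control is evaluated over voxels *outside* the seed
mask, where the null actually holds.

## Validation problem sizes

The shipped validation uses sizes at which every property is sharply
testable on a single CPU in minutes: 200 all-null datasets of 50 subjects
on a 12×12×12 grid for family-wise error (the binomial 95% bound around
$\alpha = 0.05$ is ±0.030); 100 subjects for closed-form correlation
recovery (tolerance ±0.03 around $1/\sqrt2$); 500 random weighted graphs
of up to 8 nodes against an exhaustive simple-path oracle; 50 connector-
hub datasets of 25 subjects; and a 100-subject three-seed phantom with a
planted common territory at population r = 0.5 for overlap recovery
(Dice ≥ 0.9). `scripts/acceptance.R` recomputes all of these from
scratch.

## Known limitations

* No spatial resampling or registration: scans, masks and maps must share
  the grid and affine to within $10^{-4}$ mm, or the run aborts.
* Bonferroni only — no FDR, cluster-extent or permutation alternatives,
  by design.
* Pooling is a plain (optionally n-weighted) mean; no random-effects
  meta-analysis or responder-rate modeling.
* The mapping from overlap territory to *named* anatomical structures is
  out of scope; components are labeled by size order, not anatomy.
* Betweenness/closeness are the only centralities; community structure
  beyond the hierarchical cut is not computed.

## A minimal worked run

```{r example, eval = FALSE}
spec <- phantomSpec(
  c(12L, 12L, 12L), nSubjects = 20,
  regions = list(
    regionSpec("ANT", as.matrix(expand.grid(1:3, 1:3, 1:3)), c(nA = 1)),
    regionSpec("CMT", as.matrix(expand.grid(1:3, 10:12, 1:3)), c(nB = 1)),
    regionSpec("HC", as.matrix(expand.grid(10:12, 1:3, 1:3)), c(nC = 1)),
    regionSpec("common", as.matrix(expand.grid(10:12, 10:12, 10:12)),
               c(nA = 1, nB = 1, nC = 1))),
  networks = list(networkSpec("nA"), networkSpec("nB"), networkSpec("nC")),
  rngSeed = 42)

manifest <- runPipeline(
  spec, seeds = c("ANT", "CMT", "HC"),
  studies = system.file("extdata", "study_outcomes_synthetic.tsv",
                        package = "SeedConnectome"),
  config = analysisConfig(), outdir = tempfile("run"))
```

The run directory then contains per-seed t-maps and binarized maps, the
efficacy map, the overlap map and node atlas, the correlation matrix,
cluster assignment, edge list/GraphML exports, the centrality table, and
`run_manifest.yaml` with config echo, checksums and QC counters.
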