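# dynetfnc

Temporal and spatial dynamic functional network connectivity (FNC) analysis
for multi-subject resting-state fMRI, with a fully seeded synthetic-data
generator for end-to-end validation.

Resting-state connectivity varies within a scan on two axes, and this
package implements an estimator for each:

- **Temporal dynamics** — group independent component analysis by temporal
  concatenation (per-subject PCA → group PCA → extended Infomax ICA under
  ICASSO stability selection → dual-regression back-reconstruction and
  template labeling), followed by static FNC (whole-series Pearson
  correlation between component time courses), sliding-window dynamic FNC
  (width 18 TRs, step 1 TR), and two-stage k-means clustering of the
  windowed matrices into recurring connectivity states with occupancy and
  dwell-time metrics.
- **Spatial dynamics** — each subject's T = 192-TR series is segmented into
  L = 7 windows of t = 48 TRs at 50 % overlap, and all M × L datasets
  `x[m,l] = A[m,l] s[m,l]` are decomposed **jointly** by independent vector
  analysis (IVA-GL: a multivariate-Gaussian solution, IVA-G, refined under a
  multivariate-Laplacian prior, IVA-L). The n-th source component vector
  (SCV) collects row n of every dataset; maximizing independence *between*
  SCVs while preserving dependence *within* them keeps components aligned
  across subjects and windows and lets the spatial maps themselves vary.
  Dependence between the resulting spatially dynamic components (SDCs) is
  measured per (subject, window) by normalized mutual information
  `r* = sqrt(1 - exp(-2 I))` — exactly 0 at independence, in [0, 1), equal
  to |ρ| for Gaussian pairs — and its standard deviation across windows
  quantifies spatial connectivity variability.

Group statistics mirror the two branches: pooled-variance two-sample
t-tests on static and per-state dynamic FNC (subjects with fewer than 10
windows of a state are not members of it), Mann–Whitney U tests on the
across-window STD of normalized MI, Benjamini–Hochberg FDR at α = 0.05,
and Pearson correlation of significant features with clinical scores
(severity score, disease duration).

The package is aimed at researchers studying state-dependent and
spatially-evolving connectivity differences between a patient group and
controls at small cohort sizes (the defaults mirror a 12 + 12 pediatric
design), and at methodologists who need a fully specified, seeded synthetic
benchmark for such pipelines.

## Worked example

Generate a 6-subject synthetic dataset with 3 connectivity states, a planted
group difference (Δr = 0.5 on edge 1–2 in state 2), decompose it, and
measure spatial connectivity variability:

```r
library(dynetfnc)

ds <- generateDataset(nSubjects = 6, nTimepoints = 192, nSources = 4,
                      kStates = 3, snr = 5, spatialJitter = 0.15,
                      plantedEffects = list(
                        groupDeltaR = list(state = 2, edge = c(1, 2),
                                           delta = 0.5)),
                      seed = 1)
ds$series[[1]]
#> BoldSeries 'sub01': 192 TRs x 1736 voxels (TR = 2 s, grid 16x16x16)

red <- reduceAndConcat(ds$series, nSubjectPCs = 8, nGroupPCs = 4)
ic <- icassoSelect(red$groupData, nComponents = 4, nRuns = 8,
                   minClusterSize = 6, seed = 1)
ic$clusterInfo
#>   component size        iq stable
#> 1         1    8 0.9921650   TRUE
#> 2         2    8 0.9915900   TRUE
#> 3         3    8 0.9911648   TRUE
#> 4         4    8 0.9911474   TRUE
```

Every ICASSO cluster is full (8/8 runs) with stability index iq ≈ 0.99:
the four components are reliably re-estimated from any seed. They match the
planted source maps almost perfectly:

```r
m <- matchComponents(spatialMaps(ic$components), spatialMaps(ds$truth))
round(abs(m$r), 3)
#> [1] 0.999 0.999 0.999 0.999
```

The spatial branch decomposes the 6 × 7 windowed datasets jointly and
summarizes across-window variability of the normalized-MI connectivity
(patient-group mean below; entries are STDs of a quantity in [0, 1), zero
diagonal by convention — nonzero values reflect the planted per-window
spatial jitter):

```r
segs <- lapply(ds$series, segmentWindows)   # 48 TRs, 50% overlap -> L = 7
scv <- ivaGL(segs, nComponents = 4, seed = 1)
scv
#> SCVSet: N = 4 components over 42 (subject, window) datasets

mi <- miConnectivity(scv)
ev <- edgeVariability(mi, groups = clinicalTable(ds$truth)$group)
round(ev$groupMeanStd$TS, 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.000 0.068 0.050 0.084
#> [2,] 0.068 0.000 0.040 0.047
#> [3,] 0.050 0.040 0.000 0.067
#> [4,] 0.084 0.047 0.067 0.000
```

`runPipeline(pipelineConfig(...), outDir)` chains all stages (simulate →
gica → tdfnc → iva → sdfnc → stats) from one configuration and one seed,
persists every intermediate, and writes the state assignments, occupancy
metrics, MI tables and statistical results as CSV plus a reproducibility
manifest; reruns are byte-identical. A thin command-line front end is at
`inst/scripts/dynetfnc.R`:

```sh
Rscript inst/scripts/dynetfnc.R all --config config.yaml --seed 1 --out results/
```

See the methods vignette (`vignettes/dynamic-fnc-methods.Rmd`) for the
models, parameter meanings, numerical choices, and what the synthetic
generator does and does not emulate.

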