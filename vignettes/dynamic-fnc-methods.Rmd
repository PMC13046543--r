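---
title: "Temporal and spatial dynamic FNC: models, parameters and design choices"
author: "dynetfnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal and spatial dynamic FNC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dynetfnc)
```

# The analysis in one page

Resting-state fMRI connectivity is dynamic on two axes. *Temporal* dynamics:
the coupling between the time courses of large-scale networks changes over the
scan, and recurring coupling patterns ("brain states") can be identified by
clustering sliding-window correlation matrices. *Spatial* dynamics: the
spatial maps of the networks themselves change across time windows, which a
fixed-map decomposition such as group ICA cannot express. `dynetfnc`
implements both branches over a common input — one preprocessed 4-D BOLD
volume per subject, a brain mask, and a clinical covariate table — and a
synthetic-data generator with planted ground truth so that every stage can be
validated end to end.

The temporal branch is classical group ICA (GICA): per-subject PCA in the
time dimension, temporal concatenation, group PCA, extended Infomax ICA run
many times under ICASSO, dual-regression back-reconstruction, template-based
labeling, then static FNC (whole-series Pearson correlation between component
time courses), sliding-window dynamic FNC (width 18 TRs, step 1 TR), and
two-stage k-means clustering of the windowed matrices into states.

The spatial branch segments each subject's series into L = 7 windows of
t = 48 TRs at 50% overlap (so T = 192 TRs tiles exactly: window duration
96 s at TR = 2 s) and decomposes the resulting M x L datasets *jointly* by
independent vector analysis. Writing `x[m,l] = A[m,l] s[m,l]` per dataset,
IVA estimates all demixing matrices `W[m,l]` at once so that the n-th source
component vector (SCV) — row n collected across all datasets — is maximally
independent of the other SCVs while its members stay mutually dependent.
That dependence is what keeps component n aligned across subjects and
windows without any post-hoc matching; it is the property that distinguishes
IVA from running ICA separately per dataset, and the package tests it
directly (permutation-consistency checks on synthetic data). IVA-G models
SCVs as multivariate Gaussian (it exploits second-order cross-dataset
covariance only), IVA-L as multivariate Laplacian (higher-order statistics);
IVA-GL runs IVA-G and refines its solution under the Laplacian prior, which
is more robust than either alone. Pairwise dependence between the resulting
spatially dynamic components (SDCs) is measured per (subject, window) by
normalized mutual information, and its standard deviation across windows
quantifies spatial connectivity variability.

Statistics mirror the two branches: pooled-variance two-sample t-tests on
static and per-state dynamic FNC (a subject belongs to a state only with at
least 10 windows of it), Mann-Whitney U tests on the across-window STD of
spatial connectivity, Benjamini-Hochberg FDR at alpha = 0.05 within each
family, and Pearson correlation of significant features with clinical scores.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tdfnc$widthTrs`, `stepTrs` | 18, 1 | sliding-window width and step (TRs); 18 TRs = 36 s is about the shortest window with stable correlations at TR = 2 s |
| `tdfnc$k` | `"auto"` | number of states; automatic selection scans k = 2..10 |
| `tdfnc$minWindows` | 10 | state-membership rule: fewer windows = not a member |
| `iva$windowTrs`, `overlap` | 48, 0.5 | IVA window length (96 s) and overlap; T = 192 gives L = 7 |
| `iva$nComponents`, `keepSdcs` | 20, 9 | IVA model order and number of SDCs kept after screening |
| `gica$nComponents` | 100 | ICA model order at study scale |
| `gica$icassoRuns`, `minClusterSize` | 100, 80 | ICASSO restarts and minimum stable-cluster size |
| `gica$artifactR` | 0.2 | minimum template correlation for a network label |
| `stats$alpha` | 0.05 | FDR level |

Desk-scale analyses (tests, examples) reduce the model orders (3-4
components, 4-8 ICASSO runs) and the subject count (2-12); all algorithmic
paths are identical.

# Numerical choices

**Extended Infomax.** The unmixing matrix follows the natural-gradient
direction `(I - K tanh(U)U'/V - U U'/V) W` with the standard sub/super-
Gaussian switch `K = diag sign(E[sech^2 u] E[u^2] - E[u tanh u])`. Instead of
a fixed learning rate with annealing, every step must not decrease the
matching log-likelihood `log|det W| + sum_n E[-u_n^2/2 - k_n log cosh u_n]`
(backtracking halves the step otherwise) and iteration stops when the
natural-gradient norm falls below 1e-6 (cap 2048 iterations). The annealed
variant can enter limit cycles on some initializations — the weight change
shrinks because the learning rate decays, not because a stationary point was
reached — and then reports spurious "converged" mixtures; the monotone line
search removes that failure mode while keeping the same update direction and
fixed points. Components carry a deterministic sign convention (non-negative
map skewness).

**ICASSO.** Similarity between pooled component maps is absolute Pearson
correlation; clustering is average-linkage agglomerative, cut at the model
order; the cluster representative is the centrotype (member with maximal
within-cluster similarity sum); `iq` = mean intra-cluster minus mean
extra-cluster similarity. Clusters smaller than the minimum size are kept
but flagged unstable, never silently dropped.

**Back-reconstruction** is dual (spatial-temporal) regression. The study-
style GICA back-projection through the PCA operators is a special case when
the reduction is lossless; dual regression is the variant that needs no
stored operators and recovers the noiseless case exactly, which the tests
assert.

**IVA-G / IVA-L.** Both run on per-dataset whitened data (sample covariance
exactly identity) and minimize the IVA maximum-likelihood cost
(`sum_n 1/2 log det Sigma_n - sum_k log|det W^(k)|` for the Gaussian prior;
`sum_n E[||y_n||_2] - sum_k log|det W^(k)|` for the Laplacian prior, with an
1e-12 floor inside the score to avoid division blowups) by natural-gradient
steps with a backtracking line search, so the cost is non-increasing across
accepted iterations. Convergence is a 1e-6 gradient-norm tolerance with a
1024-iteration cap; IVA-G on realistic window data often uses the full cap
— its partially converged solution is exactly what IVA-GL needs as a warm
start, and the run is flagged (`converged`) rather than hidden.

**Window normalization before IVA.** Each voxel is demeaned within each
window. Per-voxel *variance* normalization within windows is available
(`normalize = "voxel"`) but not the default: scaling every voxel separately
reshapes the spatial maps the decomposition is supposed to estimate, and on
matched synthetic data it lowers SCV-to-truth map correlation from ~0.97 to
~0.82. Voxel-wise variance equalization is already applied once per series
at load time, where it belongs.

**Normalized MI.** Mutual information between two maps is estimated from a
joint histogram of equal-frequency (rank) bins with
`nBins = max(8, floor(V^(1/3)))` and the Miller-Madow bias correction
(clamped at zero), then mapped through the information coefficient of
correlation `r* = sqrt(1 - exp(-2I))`. This mapping is exactly 0 at
independence, lives in [0, 1), and equals |rho| for bivariate Gaussian
inputs — which gives a closed-form oracle the tests exploit (estimates at
rho = 0.6 land within 0.05). Rank binning makes the estimate exactly
invariant to strictly monotone transforms of either map. The across-window
STD uses the n-1 denominator.

**State clustering.** Window matrices are Fisher-z transformed and
vectorized (upper triangle). High-variance exemplar windows (strict local
maxima of the across-edge variance; endpoints count with one neighbor; the
first global maximum is the fallback for flat sequences) are clustered first
(best of 10 k-means++ seeded Lloyd runs), and those centroids initialize a
Lloyd pass over all windows, whose fixed point satisfies centroid = mean of
assigned vectors. Automatic k scans 2..10 and takes the elbow of the
within/between dispersion ratio — the point farthest below the chord joining
the curve's endpoints. Rectangular (boxcar) windows, no taper; plain sample
Pearson per window without covariance regularization (at study scale, 18-TR
windows with ~50 components make individual window estimates noisy — a
documented limitation, mitigated by clustering many windows).

**Statistics.** The t-test pools variances (Student) by default with a
Welch switch; the Mann-Whitney U test uses the exact null distribution for
combined n <= 20 without ties and the tie-corrected normal approximation
otherwise (the exact branch is verified against full rank-arrangement
enumeration in the tests); BH q-values are monotone by cumulative minimum
and an edge is significant iff q < alpha. The FDR family is all edges within
one state by default (`fdrFamily = "global"` pools all states). The
per-state duration measure reported is the total window count per state
(with mean dwell alongside), since "duration of a state" is ambiguous
between total occupancy and mean dwell; the membership rule uses total
windows.

# What the synthetic generator emulates — and what it does not

`generateDataset()` mirrors the target study design: 24 subjects (12 "TS"
patients, 12 "N" controls), T = 192 TRs at TR = 2 s, K = 3 connectivity
states, a clinical severity score (mean 44.66, SD 17.96, clipped to 10-79)
and disease duration (1-12 months for patients). Choices the study does not
pin down were fixed once at realistic values: a 16x16x16 grid with an
ellipsoidal mask (V ~ 1700 voxels — large enough for stable spatial ICA and
MI histograms, small enough for desk-scale runs), N = 4 Gaussian-blob
sources (z-scaled; a few soft decorrelation sweeps keep pairwise |r| < 0.2,
the artifact-screen threshold, at the cost of the shallow negative surround
real ICA maps also show), a Markov dwell process with geometric segment
lengths of mean 50 TRs (100 s, in the range reported for dFNC states; the
first K segments visit every state so each label occurs), signal-to-noise
variance ratio 5, and per-window spatial jitter 0.15 implemented as smooth
multiplicative modulation fields (random quadratic polynomials of the voxel
coordinates) applied per half-window block — spatial variation that IVA can
model and GICA averages over.

Planted effects are the generator's testing hooks: `groupDeltaR` shifts one
edge of one state's covariance by a chosen delta in the patient group;
`clinicalR` perturbs one edge per subject and builds the clinical score from
the realized edge values at a chosen correlation (between-subject edge SD
0.15). Clinical-correlation validation uses a single-state configuration:
with K > 1 states, between-subject variability in state occupancy dominates
any static measurement of an edge whose baseline differs across states, so
the static estimate attenuates for reasons unrelated to the correlation
machinery under test. Power checks run the group comparison on the
generator's own time courses and state sequences (windowed through the same
`slidingWindowFNC`/`compareStateFNC` path) so that 100-replicate simulations
stay within desk-scale budgets.

The generator does **not** simulate head motion, physiological or AR(1)
noise, scanner drift, slice timing, or spatial resampling — noise is i.i.d.
Gaussian per voxel-timepoint. Passing tests therefore demonstrate the
correctness of the estimators and the pipeline plumbing under the stated
generative model, not robustness to real-data artifacts.

# Degenerate inputs and tie-breaks

Constant time courses or maps are errors, named per component; empty masks,
grid mismatches and non-finite voxels fail at load with counts; segmentation
parameters that do not tile T exactly are rejected with the nearest valid
lengths; template-matching ties break by template order; exemplar ties fall
back to the first global maximum; k-means ties are resolved by the seeded
k-means++ initialization, and all randomness in the package flows from
explicit integer seeds (one master seed fans out to per-stage substreams in
`runPipeline()`, so stage-wise and all-at-once execution produce
byte-identical CSVs).

# Problem sizes used in validation

Deterministic contracts run at study scale (T = 192, window arithmetic,
exact oracles). Monte-Carlo validation uses: BSS recovery at M = 6 subjects,
L = 7 windows, N = 4 sources, snr = 5; state recovery at 12 subjects; power
and calibration at 24 subjects (12 per group) x 100 replicates on the
generator's time courses; MI closed-form checks at V = 50000. These sizes
make the whole suite reproducible on a laptop in a few minutes while keeping
every estimator at its intended operating point.

# Known limitations

- Visual artifact inspection of SDCs is replaced by template-ranking
  (`screenSDCs`); with real data the ranking should be reviewed.
- No covariate adjustment in the group statistics (none is modeled).
- No L1-regularized windowed covariance; short-window estimates are noisy at
  high model orders.
- Spectral/temporal artifact features are not implemented; artifact
  screening is template correlation plus the optional gray-matter energy
  rule.
- Map-change divergence measures (e.g. KL-based) between window maps are out
  of scope.
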