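---
title: "Methods: exposure-connectivity analysis with high-dimensional mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-connectivity analysis with high-dimensional mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdefc)
```

`pbdefc` implements the computational chain of a prospective-cohort
neuroimaging analysis relating gestational PBDE (polybrominated diphenyl
ether) serum concentrations to adolescent resting-state functional
connectivity: exposure preparation, fMRI denoising, voxelwise local and
global correlation mapping, exposure-connectivity cluster inference, and
univariate plus high-dimensional multivariate mediation. Because cohort
data of this kind are restricted, the package ships a seeded synthetic
cohort generator with known planted effects; every stage is tested against
that generator and against independent oracles. This vignette records the
models, the parameters that matter, the numerical choices, and the design
decisions that were genuinely open.

## Exposure model

Five congeners (BDE-28, -47, -99, -100, -153) are measured in maternal
serum and expressed in ng/g lipid. Preparation follows standard practice
for lipophilic analytes:

* **Lipid normalization** divides the wet-weight serum concentration
  (ng/mL) by serum total lipids (g/L), times 1000. Total lipids can be
  derived from cholesterol and triglycerides by the enzymatic summation
  formula TL = 2.27 TC + TG + 0.623 (g/L). The normalization formula is a
  design choice (direct division), since lipid adjustment conventions vary.
* **Limit-of-detection substitution** replaces values below the assay LOD
  with LOD/sqrt(2), the usual single-imputation for left-censored
  exposures. Substitution is idempotent and applied per congener;
  per-sample LODs are supported but the generator uses per-congener
  constants (batch-varying LODs were an open question; constants are the
  simpler default).
* **Sigma5BDE** is the arithmetic sum of the five congener concentrations.
  A missing congener excludes the participant from Sigma5BDE analyses; no
  imputation.
* **log2 transformation** of every analyte, so each regression coefficient
  corresponds to a doubling of concentration.

Descriptive summaries report the geometric mean with a 95% CI computed as
a t-interval on the natural-log scale, back-transformed. The CI method is
a design choice (the convention is rarely stated in cohort tables); it is
exact under log-normality. Exposure-outcome screening uses bivariate
Pearson correlations with two-sided p-values from the t transform of r on
n - 2 degrees of freedom; two-sided because associations of either sign
are interpretable.

## Denoising chain

Each participant contributes runs of volumetric BOLD time series on a
common grid (the generator's default: two runs of 100 frames, TR 2 s,
4 mm isotropic voxels) plus six rigid-body motion parameters and
white-matter / CSF noise-compartment masks. The chain, in fixed order:

1. **Framewise displacement**: FD_t is the sum of absolute frame-to-frame
   changes of the three translations plus 50 mm times the sum of absolute
   rotation changes; FD resets to 0 at run boundaries. The formula is the
   sum-of-absolute-differences convention with a 50 mm head radius; the
   originating tools do not print theirs, so this is a documented
   assumption chosen for testability.
2. **Outlier frames**: FD > 0.9 mm, or |z| > 5 of the frame-to-frame
   change of the within-mask mean signal (z-scored per run). The
   global-signal variant is likewise a documented assumption.
3. **Participant exclusion**: mean FD > 0.4 mm or more than 40% of frames
   censored.
4. **Nuisance regression**, per run: 6 motion parameters and their first
   differences, 5 CompCor components from each noise compartment
   (principal component time courses of the detrended,
   variance-normalized compartment voxels), one spike regressor per
   outlier frame (censored frames are absorbed exactly), a run constant
   and a linear term. Collinear columns are dropped with a message;
   residuals are orthogonal to every retained column by construction.
5. **Detrend + band-pass** 0.008-0.09 Hz, per run, as a hard
   frequency-domain mask after per-voxel linear detrending. A windowed
   FFT mask is bit-reproducible and its contract is stated as attenuation
   bounds (stop-band < 5%, pass-band > 90% at the frame counts used here)
   rather than as a filter family. Filtering happens after regression
   (sequential), a simplification relative to tools that do both
   simultaneously; the spike regressors already protect the regression
   from censored frames.
6. **Spatial smoothing** (Gaussian, FWHM in mm, truncated at 3 sigma,
   kernel renormalized to unit mass inside the mask) is available as its
   own step and as `smooth = TRUE` in `denoise_participant()`, but is
   **off by default**: voxel-level LCOR/GCOR are conventionally computed
   on unsmoothed residuals, because the LCOR neighborhood kernel performs
   the spatial integration and pre-smoothing blurs a focal effect into a
   suprathreshold halo around it. This placement matters: with
   pre-smoothing, a planted 27-voxel effect is detected together with a
   one-voxel shell of neighbors.

Runs are concatenated after per-run regression and filtering. Correlation
stages drop censored frames.

## Connectivity metrics

For denoised series, with each voxel's series centred and unit-normalized:

* **GCOR(v)** is the mean Pearson correlation between v and every other
  in-mask voxel, computed through the normalized-series inner-product
  identity (row sums of the correlation matrix without forming it).
* **LCOR(v)** is the Gaussian-weighted mean correlation between v and its
  neighbors, with weights exp(-d^2 / 2 sigma^2) on inter-voxel distance in
  mm, FWHM 25 mm, truncated at 3 sigma and renormalized.
* **Seed-to-voxel maps** correlate the unweighted mean series of a seed
  cluster with every voxel and apply the Fisher z (atanh) transform;
  correlations of exactly +-1 are clipped to +-(1 - 1e-7) and counted.

The self-voxel is excluded from both metrics (making "the rest of the
brain" literal); `include_self = TRUE` restores the other convention.
Zero-variance voxels are masked out and counted, not propagated. LCOR
weighting uses Pearson correlation (covariance weighting was an open
question; correlation is assumed). As the neighborhood grows with uniform
weights, LCOR converges to GCOR — kept as a tested invariant.

## Exposure-connectivity inference

A separate OLS model per voxel regresses the metric on one log2 exposure
with age, sex and maternal education as covariates (education coded as an
ordered integer 1-4 by default; indicator coding is available). Voxels
with two-sided p < 0.001 are split by the sign of t and grouped into
connected components (26-adjacency by default; 6 and 18 available).

Cluster-extent inference is by **permutation** rather than parametric
random-field theory: the exposure is residualized on the covariates,
shuffled, re-orthogonalized, and the voxelwise GLM re-fit; the maximum
cluster extent over both signs is recorded per permutation, and each
observed cluster gets p = (1 + #{null max >= size}) / (1 + n_perm)
(add-one convention), followed by Benjamini-Hochberg adjustment across the
candidate clusters. The permutation null is assumption-free, exact at desk
scale, and needs no smoothness estimation; it is a deliberate deviation
from parametric cluster p-values, and its alpha-calibration is verified in
the test suite.

Cluster effects are summarized as the **percent change per doubling**:
the participant-level cluster mean is regressed on the exposure and
covariates, and the exposure coefficient is divided by the adjusted
cluster mean — the model-implied mean at average exposure and covariates,
which under OLS equals the sample mean of cluster means. The denominator
convention was an open question; the adjusted mean is used and the CI
scales linearly with the coefficient CI. If the denominator is degenerate
(|mean| at machine-epsilon scale, possible for GCOR), the absolute change
per doubling is reported and flagged.

## Mediation

**Univariate.** For exposure x, scalar mediator m, outcome y, and the same
covariates as the GLM stage (their inclusion in every path is a design
choice; a flag disables them): a from m ~ x, b and c' from y ~ x + m, c
from y ~ x. The indirect effect ab = a * b equals c - c' identically for
least-squares fits on a common sample — kept as a machine-precision test
invariant. Inference is a percentile bootstrap over participants
(default 5000 resamples) with an add-one smoothed, doubled tail
probability. Participants whose imaging-to-assessment interval exceeds
3 months can be excluded via an interval column.

**Multivariate (principal directions of mediation).** Stacked seed-to-voxel
maps (Fisher z; whether to z-transform before reduction was an open
question, and the z-maps are used) are column-centred and reduced by SVD
to the smallest k components explaining 90% of variance. A PDM is a unit
vector w in the reduced space maximizing |a(w) b(w)| for the projected
mediator (scores) w, with paths fit exactly as in the univariate model,
subject to orthogonality with all previous directions; the sign convention
is a_k >= 0.

With least-squares paths the objective is a ratio of quadratic forms:
a(w) = alpha'w is linear, and b(w) = beta'w / w'Gw with G the Gram matrix
of the residualized scores. In the whitened metric the product becomes the
Rayleigh quotient of the rank-2 symmetric matrix (ab' + ba')/2, whose
extreme eigenpairs are closed-form. The package therefore solves each
direction **exactly and deterministically** instead of by iterated
gradient ascent with restarts — there is no convergence tolerance to tune,
|ab_k| is non-increasing by construction, and the first direction agrees
with a 0.5-degree exhaustive search in the rank-2 case (a test). Search
directions with zero residual mediator variance (an ill-posed b path) are
excluded by restricting to the positive eigenspace of G.

Model significance uses the sum of |ab_k| over all directions as the test
statistic, comparing against participant-wise shuffles of the mediator
matrix rows with the full PDM stack re-estimated per permutation (fixing
the directions would invalidate the null); p uses the add-one convention.
Voxel-weight significance uses a participant bootstrap: directions are
re-estimated per resample, matched to the originals by maximal absolute
inner product (greedy in original index order, which also breaks ties),
sign-aligned, back-projected through the orthonormal basis, and a voxel is
significant when its 95% percentile interval excludes zero; zero-variance
bootstrap distributions are flagged and never significant. Matching
replaces free label assignment to avoid label switching — an assumption
about, rather than a copy of, the reference toolbox's behavior. The
percent of the multivariate indirect effect per direction is
100 |ab_k| / sum |ab_j|.

## Synthetic cohort generator

The generator is the package's stand-in for restricted cohort data, and
its defaults are the study conditions for every test:

* **Exposures**: multivariate normal on the log scale, exponentiated.
  Geometric means 1.1, 22, 4.9, 4.0, 4.9 ng/g lipid; log-scale SDs derived
  from the published arithmetic/geometric mean ratios under log-normality
  (0.87-1.08); pairwise log correlations at the midpoint (0.695) of the
  published 0.46-0.93 range with the two named extreme pairs pinned
  (0.93, 0.46). Detection rates 88.8/99.4/99.4/97.6/97.1%; the LOD is the
  empirical quantile at (1 - detection rate) and censored values are
  stored at the LOD with a flag — substitution belongs to the exposure
  module, keeping measurement and statistics separable.
* **Covariates**: age N(12.3, 0.7) years, 58.7% female, maternal education
  in four ordered categories with published cohort probabilities.
* **Time series**: a low-rank latent-factor model — shared global latent,
  region latents, a nuisance latent shared with the corner noise
  compartments, per-voxel linear drift, white noise — not a biophysical
  BOLD simulator; it is the minimal structure the metrics and mediation
  respond to. The coupling of a planted 27-voxel cluster to the global
  latent equals the participant's latent mediator
  m1 = 0.8 - 0.29 (log2 Sigma5BDE - mean) + noise, calibrated so that a
  doubling of Sigma5BDE lowers cluster GCOR by roughly 22%. The planted
  local effect raises within-cluster coupling with log2 BDE-153
  **variance-preservingly** (the local latent replaces voxel noise,
  mu^2 + sigma^2 held constant): naively adding local variance lowers the
  cluster's correlation with its neighbors and flips the LCOR association
  negative. Under the corrected formula the coupling slope 0.22 per
  doubling targets roughly +5% LCOR per doubling. The planted effect is
  spatially uniform inside each mask (an open question; uniformity is the
  simplest assumption). Motion traces are slow random walks with spikes
  at rate 0.05/frame; spike frames also get a global signal artifact so
  both outlier criteria have something to catch.
* **Outcomes**: T-scores (mean 50, SD 10) from a linear structural model
  with direct effect c' = 1 per doubling, mediated effects through m1
  (b = -4.5) and a second planted direction m2 (a = 0.12, b = -6.75), and
  modest covariate effects; outcome noise SD 9 puts the total
  exposure-outcome correlation near published cohort magnitudes (~0.2).
  The mediator clamp is wide ([-1, 3]) because a tight lower clamp would
  bend the planted linear path within ~2 SD of exposure; negative
  couplings are physically meaningful anticorrelations.

A second, map-level generator (`generate_mediation_maps()`) draws
participant-by-voxel mediator maps whose planted indirect effect lies in
**exactly two orthogonal spatial directions plus isotropic noise**, with
path sizes at published multivariate-mediation magnitudes (a about 3.6 and
2.3, b about 0.78 and -0.76). It exists because the time-series route
cannot realize that low-rank condition: correlation is nonlinear in
coupling, so a planted coupling effect necessarily leaks into further
directions. Analyses of how the indirect effect concentrates in the
leading PDMs use this generator.

What the generator does **not** emulate: anatomy, hemodynamic response
shapes, scanner drift beyond linear trends, susceptibility artifacts,
multi-site effects, non-Gaussian exposure tails. Passing tests therefore
demonstrate the statistical machinery under the planted model, not
robustness to the full messiness of real cohort data.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to keep the whole
suite in minutes while leaving each check well-powered: brute-force metric
equivalence on a 6x6x4 grid with 10 participants and 120 frames
(tolerance 1e-8); cluster recovery over 20 seeded cohorts of n = 60 with
199 permutations; PDM null calibration over 200 replicates of n = 60 with
99 permutations; bootstrap coverage over 100 replicates of n = 300 with
500 resamples; the PDM concentration analysis at n = 300 with 15
directions. Add-one conventions are used for every resampling p-value.
Permutation and bootstrap seeds are explicit arguments everywhere;
identical seeds give bit-identical results, including end-to-end manifest
hashes in `run_pipeline()`.

Known limitations: the permutation null shuffles residualized exposure
(Freedman-Lane style) and is exact only under exchangeability of those
residuals; percentile bootstrap intervals slightly under-cover at modest
n; the PDM decomposition is conditional on the SVD basis, so directions
are comparable across cohorts only after back-projection; and the closed
form for PDMs relies on all paths being least squares — robust or
regularized path fits would need the iterative solver the closed form
replaces.
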