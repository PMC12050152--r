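---
title: "Morphology-function coupling: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-function coupling: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcoupling)
```

## The question the package addresses

Cortical anatomy and resting-state function are organized along partly
shared axes: regions with similar gray-matter morphology tend to be
functionally connected, and the strength of that correspondence varies
systematically across the cortex. `mfcoupling` quantifies this
morphology-function coupling (MFC) at the level of single subjects from two
subject-specific networks over a fixed parcellation of R cortical regions:

* a **morphological similarity network (MSN)**: for every pair of regions,
  the distributions of voxel-level gray-matter values are estimated by
  Gaussian kernel density estimation and compared with the similarity
  transform of the symmetric Kullback-Leibler divergence,

  $$\mathrm{KLS}(P, Q) = e^{-D_{KL}(P,Q)}, \qquad
    D_{KL}(P,Q) = \sum_{i=1}^{n} P_i \log\frac{P_i}{Q_i}
                + Q_i \log\frac{Q_i}{P_i},$$

  so that identical distributions score 1 and well-separated distributions
  score near 0;

* a **functional connectivity network (FCN)**: the Pearson correlation
  matrix of the regional BOLD time series.

Regional coupling for region $r$ is the Spearman rank correlation between
column $r$ of the MSN and column $r$ of the FCN, with the self-connection
excluded from both columns; the per-subject coupling map is the length-R
vector of these values. Global coupling applies the same rank correlation to
the $R(R-1)/2$ unique off-diagonal pairs of the two matrices. Group
inference (case versus control across sites) proceeds by empirical-Bayes
site harmonization, covariate residualization, Mann-Whitney tests at the
global, regional and network levels with Benjamini-Hochberg FDR control, and
partial correlation of network coupling with symptom severity in cases.

## Density estimation choices

**Grid.** Each pair of regions is compared on one shared, equally spaced
grid of $2^7 = 128$ points spanning the pooled range of the two samples,
padded by 10% of that range on each side. A shared grid is what makes the
divergence between the two discretized densities well defined. Whether the
reference methodology used one grid per subject or per pair is not
documented; the per-pair pooled grid is this package's choice, and
`build_msn()` exposes the grid size as `n_grid`.

**Bandwidth.** Bandwidths are selected automatically per region by the
diffusion estimator (the improved Sheather-Jones fixed point solved on a
discrete-cosine-transform representation of the binned sample). This
selector does not oversmooth multimodal distributions the way rules of
thumb do. If the fixed-point equation cannot be bracketed - which can
happen for tiny or heavily discretized samples - the code falls back to
Silverman's rule with a warning. The selector is implemented in compiled
code; `select_bandwidth()` exposes it directly, and the test suite verifies
that the returned bandwidth is a root of the R-level discrepancy equation
and lands within a factor of 1.5 of the asymptotic $1.06\,\hat\sigma
n^{-1/5}$ reference on Gaussian samples.

**Zeros.** The displayed divergence is undefined at zero probabilities, and
two regions with disjoint supports would otherwise produce infinities. Both
discretized densities are floored at $10^{-12}$ (per grid cell) and
renormalized before the divergence is computed; similarities therefore live
in $(0, 1]$, never exactly 0.

**Degenerate regions.** A region whose values are all identical has no
density estimate; rather than silently emitting a similarity of 1, the
package raises an error naming the offending regions, since zero-variance
extractions indicate an upstream segmentation problem.

**Fast path.** `build_msn()` evaluates each region's KDE once on a fine
2048-point grid and interpolates linearly onto the per-pair grids;
`exact = TRUE` performs the literal per-pair evaluation instead. The two
paths agree to about $10^{-4}$ on realistic samples (tested), while the fast
path makes whole-cohort runs feasible (a 96-region subject takes ~0.4 s).

## Coupling conventions

Ties receive average ranks (midranks) everywhere. Because the coupling
statistic is rank-based, any strictly increasing transform of either
network - a Fisher z-transform of the correlations, for instance - leaves
every coupling value unchanged; the package therefore stores raw
correlations and applies no thresholding, binarization, or absolute-value
transform. "Global" coupling is defined over the unique off-diagonal pairs;
the mean of the regional map is also reported (as an attribute) because the
two summaries answer slightly different questions and the literature uses
both.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates cohorts in which every downstream estimate has
a known target:

* **Gray-matter values** for region $r$ are Gaussian with location
  $\mu_r$ and scale $\sigma_r$. For Gaussians the similarity has the closed
  form $\exp\{-[(\sigma_1^2+\Delta\mu^2)/2\sigma_2^2 +
  (\sigma_2^2+\Delta\mu^2)/2\sigma_1^2 - 1]\}$ (`gaussian_kls()`), which the
  KDE pipeline must reproduce - the package's strongest end-to-end oracle.
  Defaults place $\mu_r$ on a gradient from 0.30 to 0.80 (modulated
  gray-matter volume units) with $\sigma_r = 0.15$, giving ground-truth
  similarities spanning essentially the whole $(0,1]$ range, plus a small
  between-subject jitter of the regional means (SD 0.005).
* **Functional covariance** tracks the ground-truth similarity matrix with
  per-region fidelity $\gamma_r \in [0,1]$ (default: a gradient from 0.15
  to 0.85). The target correlation for a subject blends, entry by entry, a
  fixed signal structure (a normal-scores transform of the similarity
  profiles, scaled to typical connectivity magnitude and repaired once)
  with a per-subject random factor-model noise correlation, at weight
  $(\gamma_i + \gamma_j)/2$. An earlier design mixed each *column*
  with independent noise and then symmetrized and repaired the matrix; at
  R = 96 and realistic connectivity magnitudes that matrix is far from
  positive semidefinite and the eigenvalue repair reshapes noise-dominated
  columns so strongly that the expected coupling is no longer monotone in
  $\gamma$. The entrywise blend of two valid correlation matrices needs
  only a mild repair and yields Spearman$(\mathbb{E}[\mathrm{MFC}],
  \gamma) \approx 0.98$. Time series are then independent multivariate
  normal rows (T = 200 volumes by default).
* **Site effects** shift (and optionally scale) the fidelities per
  acquisition site; **group effects** add a fixed increment (default 0.10)
  to $\gamma$ in designated networks (default VIS, SMN, DAN) for cases;
  **symptom scores** for cases follow
  $22 + \text{link}\times(\bar\gamma_{\text{net}} -
  \overline{\bar\gamma}) + \varepsilon$, clipped to the 17-item scale range
  $[0, 52]$. Covariates (age 35.8 ± 12.4 years clipped to 18-65, sex,
  education 12.5 ± 3.4 years, mean framewise displacement 0.13 ± 0.08 mm
  capped at 0.2) match a typical consortium cohort's summary table and
  confound nothing by default.

What the generator does **not** emulate: spatial autocorrelation of voxel
values within regions, non-Gaussian gray-matter distributions, head-motion
artifacts, hemodynamic autocorrelation of the BOLD series, or any
item-level symptom process. A green recovery test therefore establishes
that the estimators recover the planted structure under the stated model -
not that the model captures everything about real imaging data.

## Inference choices

* **Harmonization** is applied to the regional coupling features (site as
  batch, group plus covariates protected), not to the connectivity
  matrices. The implementation is the parametric empirical-Bayes
  location/scale model, written for this package because no harmonization
  library is available in the target environment. One deliberate
  convention: per-site scale estimates use the maximum-likelihood ($1/n$)
  form, consistent with the pooled variance, which makes a single-site call
  an exact no-op. When scale estimates are constant across features the
  inverse-gamma prior is degenerate and no scale shrinkage is applied.
* **Residualization** is fit on all subjects pooled, with group excluded
  from the design, then groups are compared on the residuals; this keeps
  the group contrast out of the nuisance projection. Rank-deficient designs
  are an error that names the collinear columns.
* **Mann-Whitney** uses midranks, tie-corrected variance and a continuity
  correction. The normal approximation is essentially exact at cohort
  scale; exhaustive enumeration shows its worst two-sided error is 0.088 at
  group sizes 2 vs 2 and below 0.05 once both groups have at least 3
  observations (the test suite documents this limit).
* **FDR families**: regions and networks are corrected separately, matching
  how such results are reported; symptom correlations are corrected over
  the tested networks. Two-sided tests throughout.
* **Spin test**: the observed Spearman correlation between two regional
  maps is compared with nulls obtained by applying a common random rotation
  to each hemisphere's region centroids (mirrored across the midline) and
  reassigning each region the value of its nearest rotated region,
  duplicates allowed - the standard parcel-level construction. The p-value
  is $(1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(n_{perm}+1)$, so it is
  never 0. With no centroids available the fallback is an exchangeable
  label permutation.
* **Summary-table tests**: the two-sample t from summary statistics
  defaults to the Welch form, which reproduces the published education
  comparison (t = -9.152) to three decimals; the pooled form is available.
  The 2x2 chi-square uses no continuity correction, matching the published
  sex comparison (3.301).

## Numerical details worth knowing

* All randomness flows through a single seed argument; cohorts regenerate
  bit-identically, and the RNG state of the caller is restored afterwards.
* The correlation repair (`nearest_correlation()`) alternates eigenvalue
  clipping at $10^{-8}$ with diagonal rescaling, at most 100 iterations;
  valid inputs are returned untouched.
* Matrices serialize at 6 significant digits and round-trip byte-for-byte;
  symmetry is validated on read to $10^{-9}$.
* Region indices are 1-based in every file; internal storage is by label
  (`R001`, `R002`, ...), and the boundary converts exactly once at I/O.

## Known limitations

* The per-pair pooled KDE grid and the spin-null construction are
  reasonable defaults, not reconstructions of undocumented upstream
  choices; alternative constructions (per-subject global grids,
  variogram-matched surrogates) could shift borderline results.
* Harmonization assumes additive/multiplicative site effects on the
  coupling features; site-by-group interactions are out of scope.
* The KDE similarity inherits a small smoothing bias (the effective scale
  is $\sqrt{\sigma^2 + h^2}$), visible as similarities slightly above the
  Gaussian oracle for close pairs; at 5000 voxels per region it stays
  within the 0.05 oracle tolerance enforced by the tests.
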