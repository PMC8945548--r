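---
title: "Identifying group brain networks by synchronization and tensor decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying group brain networks by synchronization and tensor decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintensor)
```

## The model

Resting-state BOLD recordings from different subjects share spatial network
structure but not temporal phase: spontaneous fluctuations are not
synchronized across individuals. `braintensor` therefore analyzes a group
in two stages.

**Synchronization.** Every subject's space × time matrix is first
normalized so each vertex/voxel time series has zero mean and unit norm
(`normalize_timeseries()`); on such data the full-window correlation
between two series is their inner product. Subjects are then aligned on the
time axis by orthogonal transforms. For a reference `Y` and a moving
subject `X`, the transform minimizing `||Y − XO||_F` over orthogonal `O` is
the orthogonal Procrustes solution `O = UVᵀ` from the SVD of `XᵀY`
(`pairwise_brainsync()`). The group variant (`group_brainsync()`) builds a
*virtual reference subject*: starting from the most central subject (the
one with the largest summed squared homologous-row correlation to all
others, which avoids an arbitrary reference choice), it alternates between
(i) aligning every subject to the reference and (ii) replacing the
reference by the row-renormalized mean of the aligned subjects. Both steps
are exact minimizers of the joint objective
`Σ_s ||X_s O_s − ref||²` (the second under the unit-row-norm constraint on
the reference), so the objective is non-increasing and is logged per
iteration. Orthogonality of the transforms guarantees that whole-window
connectivity — inner products between normalized rows — is exactly
preserved (`connectivity_preservation_check()`); synchronization changes
*when* things happen, never *how strongly* they co-fluctuate. Note that an
orthogonal temporal transform preserves row norms but not row means, so
synchronized data is unit-norm but not re-centered; all synchronization
code only assumes unit norms.

**Decomposition.** The synchronized subjects are stacked into a tensor
`X ∈ ℝ^{V×T×S}` (`build_tensor()`, which refuses unsynchronized input
because the low-rank model fails on asynchronous data) and modeled as a sum
of `R` rank-1 networks, `X ≈ Σ_r λ_r a_r ∘ b_r ∘ c_r`, with unit-norm
spatial (`a`), temporal (`b`) and subject-participation (`c`) factors and
nonnegative magnitudes `λ` sorted descending. No spatial constraint,
smoothness prior, orthogonality or non-negativity is imposed — negative
spatial weights (anti-correlated regions) are a finding, not an artifact,
and vertices are exchangeable (see *Shuffle invariance*).

## The solver

`nascar_decompose()` minimizes the squared reconstruction error with
rank-incremental warm starts: the rank-1 problem is solved first, and for
each rank `r` the previous `r − 1` components, kept at their optimized
scales, initialize the larger problem. Only the fresh component is random:
its temporal and subject factors start from seeded Gaussian draws and are
refined by alternating power iterations against the current residual
before joint optimization. Unlike the matrix power method, rank-1 tensor
iteration is only locally convergent — every component has a basin of
attraction, and a single random start lands in the basin of a weaker
component with non-negligible probability (for magnitudes 2:1 we measured
this directly; the joint optimizer then polishes the wrong component). The
initializer therefore refines several seeded starts (default 8) and keeps
the one capturing the most residual energy, which reliably orders recovery
by strength while keeping every run deterministic given the seed.

All factor entries are then updated jointly by full-gradient Nadam
(Nesterov-accelerated adaptive moment estimation; defaults: step 1e-2,
moment decays 0.9/0.999, ε = 1e-8, at most 1000 iterations per rank).
Adaptive-moment methods do not descend monotonically, so the solver tracks
the best iterate seen; when the best objective has not improved by a
relative `tol` (default 1e-6) for `patience` iterations, the step size is
decayed and optimization restarts from the best iterate, stopping at a
step-size floor. The logged per-rank trace is therefore the best-so-far
objective, monotone by construction, and the per-rank final relative errors
(`fit_history`) are non-increasing in rank. Full (not stochastic) gradients
are used: desk-scale tensors fit in memory and bit-reproducibility given
the seed is a requirement, not a nicety. After convergence factors are
renormalized, scale is folded into `λ`, the sign convention (largest-
magnitude spatial entry positive, compensated in the temporal factor) is
applied, and components are sorted by `λ`.

**Shuffle invariance.** The spatial patterns must reflect the data, not the
voxel ordering. Internally the solver reorders the space axis into a
canonical, data-derived ordering (lexicographic in the mode-1 fibers)
before any computation and maps the spatial factors back afterwards.
Because the canonical ordering is a function of row *content* only, running
the decomposition on shuffled voxels and un-shuffling the result is
bit-identical to the unshuffled run — floating-point reductions included —
which the test suite asserts with `identical()`.

**Rank.** `R` deliberately over-estimates the number of networks; at full
scale `R = 30` is conventional, while 5–8 suffices for the dominant
networks at the problem sizes used here (see *Problem sizes*). The
magnitude ordering is informative: the global physiological component is
expected strongest and the DMN second.

## Map extraction and ROI statistics

`select_network()` replaces visual identification with a deterministic
rule: the component whose cortical spatial part correlates most strongly
(in absolute value) with a supplied cortical template is selected, sign-
aligned to positive correlation; a best correlation below 0.3 is treated as
a decomposition failure. Its magnitude rank is reported so the "second
strongest" expectation stays checkable. The spatial map is split by
grayordinate index into cortical and subcortical parts, and the subcortical
part is divided by the 95% linear-interpolation quantile (R type 7) of the
*signed* cortical values — after sign alignment the cortical map is
predominantly positive, and the signed quantile is a stable positive scale.
The result is a unitless fraction of cortical network strength, invariant
to rescaling of the component. The subcortical map is scattered onto its
3-D grid and trilinearly upsampled with a voxel-center convention (input
centers at integers, output samples at `1 + (j−1)/factor`), so source
voxel centers retain their exact values and NaN marks everything outside
the subcortical support.

Each nucleus is then compared against its containing region (e.g. CL
against the entire thalamus *including* CL — the inclusion is deliberate,
matching how such contrasts are reported; `exclude_roi = TRUE` gives the
disjoint variant for sensitivity analysis) with a one-sided Welch t-test:
ROI and region sizes and variances differ grossly, so the unequal-variance
form is the defensible default, and "higher than the region" is the
hypothesis of interest (two-sided available). Multiple-comparison
correction uses random field theory: the resel count is `volume / FWHM³`
and the corrected p-value adds the 3-D Euler-characteristic density of a
t-field times the resel count to the raw tail probability, clamped below at
zero and above at 1. Only the volume (3-D) and tail (0-D) terms are used —
the formula stated for the resel computation involves only ROI volume and
FWHM — which is exact for boundaryless search regions and slightly liberal
otherwise; the lower-dimensional boundary terms are deliberately omitted
and this choice is validated by simulation on a periodic (boundaryless)
grid, where the prediction matches the empirical max-t tail within
Monte-Carlo error. The default FWHM is 2 mm, the smoothing applied by
standard minimal preprocessing; it is configurable because effective
smoothness typically exceeds applied smoothing. Mask utilities include
erosion by a physical-radius sphere (to pull adjacent nuclei such as
putamen and globus pallidus at least two voxels apart) and probability-map
thresholding that reports the percentile a threshold corresponds to.

## Seed-based comparison

`seed_correlation_map()` computes, per subject, the Pearson correlation
between a single cortical seed vertex and every subcortical voxel, with or
without global signal regression (GSR), and combines subjects by Fisher
z-averaging (variance-stabilized; the combination rule is a package
choice). Seed maps are computed on the raw normalized data, not the
synchronized data: orthogonal temporal transforms preserve inner products
between rows exactly (the connectivity the tests assert), but they shift
row means, so Pearson correlations that re-center after rotation can
differ slightly; defining the maps on the raw data keeps them free of that
ambiguity. GSR projects every row onto the orthogonal complement of
the mean grayordinate series; the output is exactly orthogonal to the
global signal. It is well known that this projection induces negative
correlations even when all true couplings are nonnegative, and the test
suite reproduces that property on synthetic data whose network weights are
all nonnegative at the relevant voxels. The tensor route instead captures
the global signal as its own (strongest) component, so anti-correlations in
the DMN map are interpretable rather than an artifact of preprocessing.

## The synthetic generator

`generate_dataset()` builds, per subject,
`X_s = (Σ_r λ_r c_{rs} a_r b_rᵀ) Q_s + ε_s`, then centers and
unit-normalizes rows. Its design choices:

* **Spatial maps** are smooth compact blobs — Gaussian bumps on a circular
  cortical coordinate and on the 3-D subcortical grid — because real
  networks appear as spatially contiguous blobs and smooth maps make ROI
  statistics meaningful. Network 1 is a near-uniform positive global
  component (magnitude largest); network 2 is the DMN-like target with
  positive weights in the toy "CL", "VTA" and "caudate" ROIs and negative
  weights in "putamen" and "GP" (the anti-correlated pair of the
  mesocircuit picture); further networks sit at deterministic alternative
  locations.
* **Temporal courses** are white noise band-passed to `temporal_band`
  (default 0.01–0.1 cycles/frame, the classic resting-state band at a 1 s
  frame interval), then QR-orthogonalized: CP recovery requires
  non-collinear factors, and orthogonal ground-truth courses make recovery
  guarantees testable.
* **Subject loadings** are lognormal (strictly positive participation),
  normalized per network.
* **Misalignment** transforms are Haar-distributed orthogonal matrices
  (QR of a Gaussian matrix, sign-fixed) — unbiased temporal asynchrony.
* **Noise** is i.i.d. Gaussian scaled per subject to the requested
  signal-to-noise variance ratio; the default `snr = 2` is a moderate
  regime chosen as the study condition for the end-to-end checks (real
  resting-state data is far noisier; see *Limitations*).

The toy atlas rasterizes named spheres into an integer label volume (later
entries overwrite earlier on overlap, so labels partition the volume),
emits Gaussian-fall-off probability maps per ROI, and records geometric
containment so "region including nucleus" voxel sets are well defined.

**What passing tests do and do not show.** The generator emulates the
*statistical* structure the analysis assumes — shared low-rank networks,
global component, misalignment, noise — not surface geometry, hemodynamics,
head motion, physiological confounds or registration error. End-to-end
passes demonstrate the machinery is correct under the model's assumptions;
they say nothing about violations of those assumptions in real data.

**A consequence of per-voxel normalization worth knowing.** Unit-norm
scaling divides each voxel's series by its own amplitude. In normalized
space the effective spatial profile of a network is its generating map
divided by the voxel-wise total rms, which *flattens* blob amplitudes, and
the per-subject dependence of those norms makes the normalized tensor only
approximately CP. Both effects grow with SNR (at high SNR the row norms are
signal-dominated); at the moderate default `snr = 2` they are mild. This is
why parameter-recovery congruence against the *generating* maps is bounded
around 0.85–0.9 on generated datasets even when the decomposition is
working perfectly — the solver recovers the normalized-space maps, not the
raw ones — and why the recovery contracts on *constructed* tensors (no
normalization) use the tight 0.99 thresholds while the end-to-end dataset
checks assert identification, sign structure and split-half agreement
instead. The split-half statistic compares two estimates of the same
normalized-space map and is unaffected by the flattening.

## Problem sizes and numerical choices

The validation suite runs end to end on one CPU: the split-half experiment
uses the generator defaults (V = 2000 grayordinates with 400 subcortical
voxels on a 10 × 10 × 4 grid, T = 300, S = 40, five networks, snr = 2,
rank-8 fits; a few minutes), the statistical-calibration checks use 10⁴
Welch-test replicates and 2000 replicates of a smooth t-field (df = 100,
20³ periodic grid, FWHM 4 voxels, continuum max estimated by parabolic
refinement of the lattice max), and unit tests use problems of a few dozen
to a few hundred variables. Other conventions: degenerate (zero-magnitude)
components keep unit-norm placeholder factors so invariants hold with
`λ = 0`; sign ties in the spatial convention resolve by the canonical
(data-derived) voxel order; repeated singular values in a Procrustes step
make the transform non-unique but never change the synced product, which is
the only quantity downstream contracts depend on; correlations are clipped
to ±(1 − 1e-12) before Fisher transforms; dead (constant) time series are a
hard error naming the row rather than a silent fix.

## Limitations

* Real 7 T group data has SNR far below the generator's default (rank-30
  decompositions of real data explain on the order of a tenth of the
  variance); desk-scale synthetic results do not calibrate real-data SNR.
* The RFT correction implements the volume-plus-tail approximation only; on
  small ROIs with large surface-to-volume ratio it is liberal relative to
  the full boundary-corrected expansion.
* Component selection needs a cortical template; with none available the
  magnitude-rank convention (second strongest) is a heuristic, and at small
  V the selected component can mix with the global component strongly
  enough to make its cortical quantile non-positive, which the pipeline
  reports as an error rather than silently re-signing.
* One session per subject is modeled; no hemodynamic response, motion, or
  registration error is simulated.
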