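---
title: "Modular facial heritability: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular facial heritability: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coherit)
```

# The problem

Facial shape is strongly familial, but a single number for "the
heritability of the face" hides where in the face the resemblance lives.
`coherit` implements a global-to-local analysis for one-parent
one-offspring designs: starting from corresponded dense landmark
configurations (one `K x 3` matrix per subject on a shared template), it
estimates narrow-sense heritability per landmark, co-heritability between
every landmark pair, a nested segmentation of the face into modules of
co-inheritance, and a multivariate heritability with permutation
significance for each module, separately for sons and daughters.

# Preprocessing: superimposition and symmetry

Raw configurations differ in position, orientation and size. A
generalized Procrustes analysis (`gpa()`) centers every configuration,
scales it to unit centroid size, and iteratively rotates it to the
running consensus until the consensus moves less than `tol = 1e-8` RMS
(at most 100 iterations). Rotations are solved by SVD with a determinant
correction, so the solver never produces a reflection — mirroring is
handled explicitly and only by `reflect_config()`, which negates the `x`
coordinate and swaps each bilateral landmark pair. The convention
throughout is that `x` spans left--right and the sagittal plane is
`x = 0`.

Faces are bilaterally structured, so analysis proceeds on the symmetric
component: `symmetrize()` runs one GPA over the `2n` set of originals
plus relabeled reflections, and the symmetric (asymmetric) component of
a subject is the half-sum (half-difference) of its aligned original and
aligned reflection. Two numerical choices matter here:

* the consensus is averaged with its own reflection at every update, so
  it is *exactly* mirror-symmetric. With a symmetric consensus the
  optimal rotation of a reflected configuration is the exact mirror
  conjugate of the original's rotation, which makes the symmetric
  component reflection-invariant to solver precision rather than only to
  GPA tolerance;
* the initial consensus is the first configuration rotated into its own
  most-symmetric pose (a short fixed-point iteration). Without this, a
  cohort handed over in an arbitrary global orientation would be
  averaged with a mirror image of a rotated shape, which flattens the
  initial consensus. This also makes the whole estimator invariant to a
  common rigid motion of all inputs, which the test suite asserts
  end-to-end.

Quality control mirrors common practice for dense facial scans: each
subject's Procrustes distance to the consensus is standardized and faces
with `z >= z_max` (default 2) are flagged; `preprocess_cohort()` drops
every pair containing a flagged face and re-runs the symmetrization.
With Gaussian data this removes a small tail (~1–2% of faces; the
distance distribution is a scaled chi, so the tail is below the Gaussian
2.3%) — harmless for estimation and a safeguard against gross mapping
failures in real data.

# Covariate adjustment

Age, sex and BMI all displace facial shape and differ systematically
between fathers and offspring, so the symmetric component is residualized
on the covariate block before any heritability estimation
(`adjust_covariates()`), for fathers and offspring separately. The fit
is a partial least squares regression with one component per retained
covariate; with a full-rank three-column predictor block this coincides
with ordinary multivariate least squares (verified against an OLS oracle
in the tests) while degrading gracefully if a covariate is collinear or
constant — sex in a single-sex stratum is dropped with a warning. The
consensus is added back, so adjustment changes deviations, not the mean
shape; it is idempotent to numerical precision.

# The heritability estimator

For paired blocks (fathers `X`, offspring `Y`) the estimator is:

1. **PLS regression** of `Y` on `X` (`plsr_fit()`, NIPALS, no scaling —
   aligned coordinates share one unit). PLS is preferred over ordinary
   multivariate regression because dense landmarks are almost perfectly
   collinear. The component count, when not fixed by the caller, is the
   minimizer of the 5-fold cross-validated MSE, capped at
   `min(15, n - 1, p)`; folds are interleaved deterministically so the
   choice is a function of the data alone.
2. **Shape coefficient of determination** `shape_r2()`:
   `R2 = 1 - sum ||y_i - yhat_i||^2 / sum ||y_i - ybar||^2`, squared
   deviations in the aligned shape space. This collapses to the
   classical R-squared for a univariate response.
3. **Transformation to a regression coefficient**:
   `b = sqrt(R2 * SS_offspring / SS_parent)`, the unique multivariate
   form that reproduces the univariate identity `b = r s_y / s_x`
   (checked against the OLS slope to 1e-6).
4. **Heritability**: `h2 = 2 b`, the one-parent one-offspring rule under
   purely additive inheritance. Values are reported raw — truncating at
   1 would hide estimation pathologies (self-regression legitimately
   gives 2).

One design choice deserves emphasis. A square-root-based estimator is
non-negative by construction and therefore biased upward under the null
(about `2 sqrt(p/n)`, i.e. ~0.12 at `p = 3`, `n = 800`). When the two
blocks share a dimension and column correspondence — paired landmark
coordinates, or scores on a common PC basis — `estimate_h2()` multiplies
the magnitude by the sign of the trace of the cross-covariance. Under a
broken (permuted) pairing the estimate then centers at zero, which is
what makes both the null calibration and the permutation test clean.
The landmark-pair **co-heritability matrix**
(`landmark_coheritability()`) stays unsigned: heritability there is
mapped as a positive quantity, and the local orientation of a
deformation field carries no information about inheritance.

The `K x K` matrix regresses each offspring landmark's 3D coordinates on
each father landmark's 3D coordinates. With three predictors the
full-rank PLS fit equals OLS, so the matrix is computed in closed form
from cross-product blocks (a pseudoinverse handles midline landmarks,
whose symmetric component is exactly planar); the tests assert entry-wise
agreement with looped `estimate_h2()` calls. Entry `(i, j)` with
`i = j` is the landmark heritability map; off-diagonal entries measure
co-inheritance. The matrix is then symmetrized, `(M + t(M)) / 2`.

# Segmentation into modules of co-inheritance

`build_hierarchy()` recursively bisects the symmetrized matrix five
times: 1, 2, 4, …, 32 segments per level, 63 segments in total, with
binary-heap ids (children of `s` are `2s`, `2s + 1`). Each bisection
(`spectral_bisect()`) clips negative entries to zero (spectral
clustering needs a non-negative affinity), forms the symmetric
normalized Laplacian, and splits along the second eigenvector. Because
the eigenvector sign split is only a relaxation, the split is refined by
seeded 2-means on the two-dimensional spectral embedding *and* by a
sweep over eigenvector-ordered thresholds, keeping whichever candidate
has the smallest normalized cut — on all small test matrices this
matches an exhaustive minimum-normalized-cut search. Disconnected
affinity graphs split by connected components; segments smaller than two
landmarks stop splitting and are carried down (flagged in the registry),
so the 63-segment registry is always well-defined. Segmentations are
compared with normalized mutual information (`nmi()`), normalized by the
mean of the two label entropies; the degenerate identical-single-cluster
case (both entropies zero) is defined as 1, so level-0 comparisons are
always 1.

# Modular heritability, significance, and multiple testing

Each segment gets its own shape space (`module_shape_space()`): the
module's landmarks from fathers and offspring pooled, re-aligned by a
fresh GPA (so only intrinsic module shape remains), decomposed by PCA,
with the retained dimension chosen by Horn's parallel analysis
(column-wise permutations, 100 iterations, 95th percentile; always at
least one PC). The retained PCs are used jointly, never one at a time:
`modular_h2()` runs `estimate_h2()` on the full father and offspring
score blocks, per cohort (sons / daughters).

Significance comes from `permutation_test()`: father rows are re-paired
uniformly at random, `h2` is recomputed per permutation with the
component count of the observed fit, and
`p = (1 + #{h2_perm >= h2_obs}) / (1 + n_perm)` — the add-one form, so
`p = 0` is impossible and the smallest achievable p-value is
`1 / (n_perm + 1)`. Permutations reuse the centered cross-products
(`X'X` is permutation-invariant), so the default `n_perm = 9999` is
cheap; raising it toward 10^6 is only needed to resolve p-values near a
very small threshold. Type-I error at the 5% level and approximate
uniformity of null p-values are asserted in the tests.

The 63 tests are strongly dependent (nested, overlapping modules), so
the family-wise threshold uses the effective number of tests: the RV
coefficient (a rotation-invariant matrix correlation, the natural choice
across shape spaces of different dimension) between every pair of
module score blocks gives a 63 x 63 correlation matrix, whose
eigenvalues yield the Li–Ji count
`m_eff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`, and
`alpha_adj = fwer / round(m_eff)` (the integer-division reporting
convention). Identity and rank-one matrices give `m_eff` of 63 and 1
exactly. Whether the RV blocks should pool fathers and offspring or use
one cohort is not determined by the method; pooling is the default, with
a switch.

`latent_morphs()` visualizes a fitted latent direction as shapes at ±k
standard deviations of the latent score (default 4) and as the
per-landmark displacement projected on template vertex normals;
`subsample_stability()` traces the estimate over random subsamples of
growing size, whose spread tightening shows where the estimate has
stabilized.

# The synthetic cohort generator

Real parent-offspring facial cohorts are access-controlled, so the
package ships a generator (`simulate_cohort()`) whose ground truth is
known exactly, making every downstream stage testable against closed
forms.

The template is a paraboloid "face" sampled on a mirrored grid (default
11 x 22, K = 242). Landmarks are partitioned into four bilaterally
symmetric modules (upper/lower x midline-near/far). Each factor group —
the four leaf modules plus, by default, nested super-module groups
(global face, upper pair, lower pair) — displaces its landmarks along
smooth loading fields: Gaussian bumps (the leading one module-wide,
later ones local), mirrored across the sagittal plane, directed along
symmetrized vertex normals, and orthonormalized within the group.
Father scores are `N(0, va)`; offspring scores are
`g_f / 2 + sqrt(3 va / 4) xi`, so the father-offspring covariance is
exactly `va / 2` and both marginals are `N(0, va)`; environmental scores
`N(0, ve)` are independent per individual. Covariate effects (linear in
age, sex, BMI along dedicated global fields), iid coordinate noise, and
a per-subject random rigid motion plus scale (default 10 degrees, 0.05
log-scale SD) complete the subject. Displacements are `effect_scale`
(default 0.05 template units) per unit score — a few percent of face
size, the scale of real facial variation. Everything is reproducible
bit-for-bit from the design seed, with per-subject counter-derived
sub-seeds.

Three generator choices were genuinely open and were settled on
separability grounds before being frozen:

* **Loading fields live in the Procrustes tangent space of their
  module's support.** A bump field has net translation/rotation/scale
  content; superimposition redistributes exactly that content over the
  whole face, planting spurious, nearly noise-free cross-module
  correlations (measured at co-heritability ~0.3 before the fix). Each
  field therefore gets a correction, supported on its own module, that
  cancels its projection on all seven global similarity modes.
* **One latent factor per leaf module by default.** The pairwise
  co-heritability between two landmarks depends on the cosine between
  their factor-loading profiles; with several factors per module,
  same-module landmarks in different bumps decorrelate and the planted
  partition stops being the matrix's own block structure. One dominant
  factor per module is also the cleanest formalization of "a set of
  landmarks that inherit together". Multi-factor designs remain fully
  supported (and are used to test parallel analysis).
* **Nested super-module factors.** With flat inter-module affinity the
  normalized cut is exactly degenerate between the 2+2 and 1+3 splits of
  four equal modules, so a recursive bisection cannot be expected to
  find the planted tree. The default design therefore adds global,
  upper-face and lower-face factors with lower variance than the leaf
  factors — which is also how the method's own results describe real
  faces (global-to-local gradients of co-inheritance).

`true_heritability()` returns the planted truth per module in closed
form from the generating loadings: all factor fields touching the module
are restricted to its landmarks, the module's own similarity modes are
projected out (the per-module GPA quotients them away), and the
population offspring-on-father regression over the resulting signal
subspace gives `R2`, hence `h2 = 2 sqrt(R2)`. For an isolated module
with a single factor group this reduces to
`va / (va + ve + (noise_sd / effect_scale)^2)`.

What the generator does *not* emulate: non-additive genetics (dominance,
epistasis), maternal and shared-environment effects, assortative mating,
registration error beyond iid noise, and the textured, curved anatomy of
real faces. Passing tests therefore demonstrate that the estimators and
the segmentation recover a known additive modular structure through the
full preprocessing chain — not that real facial heritability has that
structure.

# Problem sizes and determinism

The shipped tests and the acceptance script run the pipeline at
`K = 242`, `n = 300` (the full-face demonstration) and parameter
recovery at `n = 800` pairs over 20 replicate seeds per heritability
level, with 30–100 parallel-analysis iterations and 999–9999
permutations — sizes chosen so a complete validation runs on a laptop
in minutes while keeping Monte-Carlo error well inside the asserted
tolerances (±0.08 on recovered h2; [0.02, 0.08] on the null rejection
rate). All randomness flows from explicit seeds: cohort generation from
the design seed, each module's parallel analysis and permutation stream
from `seed + segment_id` offsets, so any module's result is reproducible
in isolation.

# Known limitations

* The estimator is regression-based; it does not partition variance via
  mixed models, and `h2` can exceed 1 in small samples or degenerate
  designs (reported raw, by design).
* Training-R2-based magnitudes carry a small positive bias at modest
  `n / p`; the orientation sign removes this under the null, but a weak
  true signal still tends to be slightly over-estimated (visible, and
  bounded, in the recovery tests).
* The asymmetric shape component is computed and returned but not
  analyzed further.
* Real-data use assumes configurations are already corresponded to a
  common template and roughly oriented with `x` as the left-right axis;
  surface registration is out of scope.
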