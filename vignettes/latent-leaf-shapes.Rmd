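---
title: "Latent leaf shapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent leaf shapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentleaf)
```

# The problem

A grapevine shoot displays two developmental processes at once. Each leaf
expands along its own ontogenetic trajectory — young leaves at the shoot
tip differ from fully expanded leaves below — and the shoot itself
matures, so that the *kind* of leaf initiated changes from node to node
(heteroblasty). On top of both, species differ in their characteristic
leaf shapes, and the organ opposite each leaf follows the vine's peculiar
series: flower clusters at basal nodes give way to tendrils above, with
every third node skipped.

`latentleaf` quantifies all three signals from 17 homologous landmarks
per leaf (petiolar junction, midvein tip, lobe tips, sinuses, vein
termini and branch points — see `landmark_names()`), indexed two ways
along the shoot: developmental stage **Sn** counted from the youngest
measurable leaf at the tip, and leaf number **Ln** counted from the first
leaf at the base. Within a vine, `Sn + Ln = total leaves + 1` for every
leaf; this bookkeeping is validated on import.

# Procrustes superimposition

All analyses operate on shapes, not placements. `gpa()` removes
translation, scale, rotation and (by default) reflection by generalized
Procrustes analysis: configurations are centered and scaled to unit
centroid size, a consensus is initialized from the first configuration,
and the set is iteratively rotated onto the consensus (optimal maps from
the SVD of the cross-covariance) with the consensus recomputed as the
re-normalized mean. Reflection is allowed by default because leaves are
scanned abaxial side down but may be digitized in either chirality;
`centroid_size()` is preserved separately so size analyses remain
possible.

Numerical choices:

* **Convergence**: tolerance `1e-10` on the root-sum-of-squares change of
  the consensus, 100-iteration cap — far below every downstream
  tolerance, and cheap: typical collections converge in well under ten
  iterations.
* **Frame fixing.** The Procrustes frame is arbitrary up to a joint
  rotation (and reflection). Outputs are standardized deterministically:
  the consensus petiole-to-midvein-tip axis (landmarks 1 to 2) is rotated
  onto the positive y axis, and, when reflections are allowed, the set is
  mirrored if needed so the first landmark clearly off that axis lies at
  negative x. This makes `gpa()` reproducible across runs and invariant
  (to 1e-8) under arbitrary placement of the input. When reflections are
  disallowed the input chirality is data and no mirroring is applied.
* **Degenerate input**: configurations whose landmarks all coincide are
  rejected by name; non-convergence reports the final consensus change.

# The tangent-space decision

Unit-size aligned shapes lie on a sphere, not in a linear subspace. The
similarity group removes four degrees of freedom from the 34 coordinates,
but only the two translations are removed *linearly*; the scale
constraint is curved, and in any realistic dataset its curvature leaves a
spurious "radial" variance direction roughly the square of the shape
variance — small, but far above numerical zero. Two consequences drove a
single design decision applied in both places:

* `fit_pca()` projects the deviations from the mean onto the tangent
  space at the consensus before the eigendecomposition (the component
  along the unit consensus vector is removed). This is the standard
  treatment in geometric morphometrics, and it makes the advertised rank
  bound — at most `min(n - 1, 30)` nonzero eigenvalues — hold exactly
  rather than approximately. Reconstruction from `mean + scores %*%
  t(axes)` is then exact (to 1e-9) on the tangent-projected coordinates
  the PCA consumes. `fit_pca(tangent = FALSE)` gives plain
  raw-coordinate behaviour for data not on the sphere.
* `fit_lda()` applies the same projection. Without it the radial
  direction enters the discriminant basis carrying (second-order)
  between-class offsets but essentially *no* within-class variance; the
  pooled covariance becomes near-singular and Mahalanobis posteriors
  collapse. Projecting it out removes the artifact at the source rather
  than papering over it with regularization.

# Morphospace and eigenleaves

`fit_pca()` is covariance PCA (all coordinates share units after
alignment), with a deterministic sign convention — each axis's
largest-magnitude loading is positive — so eigenleaves are reproducible;
PC signs are otherwise arbitrary. Eigenvalues below `1e-12` of the
largest are reported as exactly zero. `eigenleaf(space, i, k)`
reconstructs the shape at `k` standard deviations along axis `i`, the
usual way of rendering what a principal component means as a morph (for
example at ±3 SD). `project_shapes()` places new leaves, aligned in the
same frame, into an existing space without refitting.

# Latent shapes: discriminants of species and shoot position

`fit_lda()` is Gaussian equal-covariance linear discriminant analysis on
the (tangent-projected) Procrustes coordinates, fitted after a PCA
pre-reduction keeping eigenvalues above `rank_tol = 1e-8` of the maximum
— the aligned shape space is rank deficient and the reduction restores a
well-posed pooled covariance (divisor `n - g`), with a small ridge
(`1e-8 * trace/dim`) as a last-resort guard. Priors default to class
frequencies; `uniform` is available. Sn and Ln classes are treated as
unordered categories; ordinality enters only afterwards through the
relative-value arithmetic. Exact posterior ties go to the first class in
label order, deterministically.

`cross_stage()` implements cross-collection developmental staging: both
collections are restricted to the shoot-position window (default
positions 1–10, where sampling is dense), aligned together in a single
joint Procrustes analysis, and an LDA fitted on the training rows assigns
each test leaf an apparent integer Sn or Ln. Windowing both collections —
not just the training one — is deliberate: a leaf outside the window has
no defined apparent value under a windowed classifier, and matching shoot
positions across collections is how such analyses are composed. The
joint-GPA default avoids projecting new leaves into a foreign frame; a
`project` mode (test leaves superimposed onto the training consensus) is
provided for sensitivity checks.

# Heterochrony

For each classified leaf, the relative value is `apparent - actual`
(`relative_values()`): how many nodes ahead (+) or behind (−) the leaf
appears to be. An S5 leaf staged as S7 scores +2; an L4 leaf staged as L2
scores −2. Vine means (`vine_means()`) feed one-sample, two-tailed
t-tests per species (`species_offsets()`), using the exact t distribution
because vine counts are small; species with fewer than 3 vines or zero
variance among vine means are reported with reason codes instead of
tests. Raw p-values are reported alongside Benjamini–Hochberg adjusted
ones without asserting which a reader should prefer — the two-stage
averaging itself (leaves to vines to species) is the contract, not a
mixed-effects model.

`first_tendril_node()` scans each vine for the basal-most node whose
opposite organ is a tendril, indexed in the Ln frame: the
cluster-to-tendril transition runs base to tip, so a precocious vine
shows its first tendril at a lower Ln. Nodes carrying no organ (`N`,
every third node) are simply non-tendril; unknown codes are excluded with
a warning. An Sn-frame option exists for sensitivity analyses.
`tendril_correlation()` relates per-vine mean relative values to the
first tendril node by Spearman's rho.

# Supporting statistics

`spearman_cor()` computes rho as the Pearson correlation of midranks;
p-values use the exact permutation distribution for n ≤ 8 and the t
approximation above — sample sizes here range from a handful of vines to
thousands of leaves, so both regimes occur. `kruskal_wallis()` and
`bh_adjust()` delegate to the standard tie-corrected and step-up
implementations. `corr_matrix()` computes pairwise-complete Spearman
matrices with BH adjustment across the upper triangle, tracking the
number of complete pairs per cell; pairs with fewer than 4 complete
observations are reported as missing rather than failing. `hcluster()`
clusters trait columns on the distance `1 - r` — the simplest faithful
reading of a correlation-derived distance; the alternatives
`sqrt(2(1 - r))` and `1 - |r|` were considered and rejected as stronger
assumptions — with complete linkage by default and Spearman correlation
for consistency with `corr_matrix()` (Pearson is an option).
`to_newick()` exports dendrograms with branch lengths equal to height
differences, so two leaves merged at height h serialize as `(A:h,B:h);`.

# The synthetic shoot generator

`generate_shoots()` produces the study conditions every downstream test
assumes, with full ground truth. Its model, in the 34-dimensional
flattened shape space:

* a hard-coded bilaterally symmetric 17-landmark grape-like template
  (`leaf_template()`); tests depend only on its structure, never its
  exact coordinates;
* additive species effects `A_s` of configurable norm, and unit latent
  directions `u` (ontogeny) and `w` (heteroblasty), all drawn mutually
  orthonormal and orthogonal to the template's similarity directions so
  the effects survive Procrustes alignment and occupy separable subspaces
  by construction; a `confound_cos` option tilts `w` toward `u` to test
  robustness to confounded axes;
* saturating exponential trajectories, steepest near the shoot tip (Sn)
  and base (Ln), with decay constants `tau_S = tau_L = 3` nodes —
  node-to-node shape change concentrates where the biology changes
  fastest;
* a vine-level heterochronic shift `delta_v ~ N(mean, sd)` that displaces
  the whole developmental program: the leaf at node `l` takes the shape
  of effective node `l + delta_v`, equivalently effective stage
  `Sn - delta_v`. Treating the shift as one program (rather than
  attaching it to only one index) is what makes relative Sn and relative
  Ln inversely related, as they are in real shoots;
* shoot lengths `T_v ~ Poisson(25)` floored at 10 — long enough to
  populate both the S1–S10 and L1–L10 windows, and variable, which is
  precisely what decouples Sn from Ln;
* an organ series from the base with target first-tendril node
  `clamp(round(base - gamma * delta_v + N(0,1)), 1, T_v)`: clusters
  below, tendrils at and above, every third node organ-free regardless.
  Positive coupling `gamma` makes precocious vines show tendrils closer
  to the base;
* iid Gaussian landmark noise, and a random similarity transform
  (rotation, translation, scale, reflection with probability 1/2) applied
  to each raw configuration, emulating arbitrary scanner placement.

**Noise calibration.** The default `noise_sd` is a quarter of the mean
node-to-node latent-shape step across the L1–L10 window
(`effect_step_scale()`). The step — the displacement a one-node shift
produces — is the natural yardstick: what decides whether a node shift is
recoverable is noise relative to that step, not relative to the total
trajectory amplitude (under a saturating trajectory, steps in the tail
shrink exponentially, so noise fixed relative to the amplitude would make
adjacent high-window nodes indistinguishable at *any* effect size). A
quarter step corresponds to careful digitization of clean scans.

**Structure vs sampling seeds.** The latent structure (`A_s`, `u`, `w`)
is drawn under `structure_seed` (default: `seed`), the sampling under
`seed`. Two collections generated with the same `structure_seed` share a
morphospace while differing in vines, noise and placement — the
cross-collection staging scenario. Collections with different structure
seeds are mutually unstageable by construction, as different species
pairs would be.

**What the generator does not emulate.** Real leaves vary allometrically
(shape covaries with size), asymmetrically, and along many more than
three latent directions; landmark error in real scans is not isotropic;
and real heteroblastic change is not a single straight line in shape
space. Passing tests on synthetic shoots therefore demonstrate that the
*pipeline* is correct and well-calibrated under its own assumptions, not
that any particular biological effect size will be recovered from field
data.

# Recovery margins and known limitations

* **Window clipping.** A +2-shifted leaf at L9 or L10 has no L11/L12
  class inside the staging window: an ideal classifier recovers a mean
  relative value of +1.7, not +2. Together with spread in the saturated
  upper window, injected ±2-node shifts are recovered at about ±1.6 at
  the default study size (20 vines/species) — within half a node, but the
  shortfall is structural to any windowed classifier, and grows with
  |shift|.
* **Saturation.** Adjacent positions high in the window differ by a few
  hundredths of the trajectory amplitude; with 30 retained dimensions and
  tens of leaves per class, class-mean estimation error adds to the
  landmark noise there. Staging is most reliable in the lower two-thirds
  of the window — the same reason mid-shoot leaves are the usual choice
  for species-level comparisons (`select_positions(..., "midshoot")`).
* **In-sample accuracy is optimistic.** Training-set reallocation
  accuracy of an LDA is upward-biased by construction (at 30 dimensions
  and a few hundred leaves, a label-permuted dataset still reallocates
  well above chance in-sample). Null behaviour is therefore checked on
  held-out draws, and reported reallocation accuracies should be read as
  descriptive, as confusion matrices of this kind usually are.
* **Problem sizes.** The test suite and the acceptance script run the
  full pipeline at 3 species × 20 vines × ~25 leaves (~1500 leaves),
  which the package processes end-to-end in seconds; staging experiments
  pool a handful of generation seeds at 20–40 vines per condition. These
  sizes were chosen as representative of a single-collection study.
* **Out of scope.** No sliding semilandmarks, thin-plate splines or 3D;
  no mixed-effects modelling of the vine/species nesting; no bootstrap
  support on dendrograms; plotting is left to the user.
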