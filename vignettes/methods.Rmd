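---
title: "Models and numerical choices in osteomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in osteomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`osteomorph` analyzes how size and locomotor ecotype shape the external form
and internal structure of long bones. This vignette documents the models it
fits, the numerical conventions it adopts where several defensible choices
exist, what the synthetic-data generator does and does not emulate, and the
known limitations. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## Cross-sectional geometry from voxels

A bone is a binary occupancy grid with isotropic spacing $h$ (mm). After
`orient_volume()` aligns the dominant principal axis of the voxel cloud with
the slicing axis, `slice_profile()` measures each section:

* material area $\mathrm{CSA} = n h^2$ for $n$ occupied pixels;
* total area from the hole-filled outline (2D morphological fill via
  `EBImage::fillHull`), so compactness $= \mathrm{CSA}/\text{total}$ is the
  cortical fraction of the section. We chose the hole-filled outline as
  "total area" because it matches the intent of compactness for a cortical
  shell around a marrow cavity and closes open nutrient-foramen artifacts.
* the second-moment tensor about the material centroid,
  $$I_{xx} = \textstyle\sum (y-\bar y)^2 h^2 + n h^4/12,\quad
    I_{yy} = \sum (x-\bar x)^2 h^2 + n h^4/12,\quad
    I_{xy} = \sum (x-\bar x)(y-\bar y) h^2,$$
  whose eigenvalues give $I_{major} \ge I_{minor}$. The per-pixel
  self-moment $h^4/12$ is included deliberately: it makes axis-aligned
  rectangles exact (a $2\times2$-pixel block yields $s^4/12$ for side
  $s = 2h$) and accelerates convergence to the continuum values. Tools that
  treat pixels as point masses omit this term; comparisons should account
  for that.

Defining $I_{major}$ as the larger *eigenvalue* (rather than the moment
about an anatomical axis) forces the cross-sectional shape ratio
$\mathrm{CSS} = I_{major}/I_{minor} \ge 1$.

Three traits summarize a bone over the middle 40% of its functional length
$L$: global compactness **Cg** (mean slice compactness), diaphysis
elongation **DE** $= L/\sqrt{\mathrm{CSA}_{mid}}$, and **CSS** at the
midshaft. Conventions, where the underlying definitions are silent:

* functional length is the occupied extent along the dominant axis,
  `(last − first + 1) · h`. The anatomical definition (distance between
  articular surfaces) needs annotation a voxel grid does not carry; for the
  synthetic bones the two coincide by construction.
* slice positions are voxel centers measured from the proximal face of the
  first occupied slice; the inclusion window is
  $[(0.5 - f/2)L,\ (0.5 + f/2)L]$ with $f = 0.40$ by default.
* the midshaft is the occupied slice nearest $0.5L$, ties broken toward the
  proximal side.
* proximal = the heavier end (center of mass below mid-extent after
  orientation); a deterministic stand-in for anatomical polarity.

Accuracy: voxel summation converges to the closed forms first-order in $h$.
The test suite checks a solid ellipse with $a = 2b$ gives
$\mathrm{CSS} \to (a/b)^2 = 4$, an annulus with $r/R = 0.6$ gives
$Cg \to 0.64$, a solid cylinder gives $DE = 10/\sqrt{\pi}$ at $L = 100$,
$R = 10$, and that errors decrease monotonically when averaged over
sub-voxel placements (a single placement can be accidentally
super-convergent through lattice alignment). In-plane 90° rotations change
traits only at floating-point level; oblique orientations recovered by
resampling agree within a few percent at $h \le b/25$.

## Procrustes alignment and shape models

`gpa()` iterates center → scale to unit centroid size → rotate to the
consensus (proper rotations from the SVD, determinant $+1$; reflections are
handled upstream by `reflect_landmarks()`, mirroring right-side specimens
across a fixed plane). Iteration stops when the consensus moves less than
$10^{-10}$ or after 100 rounds, and centroid size is recorded before
scaling. Because the consensus orientation is otherwise arbitrary, the
aligned set is post-rotated to a canonical pose: principal axes of the
consensus, signs fixed by the consensus's own third moment along each axis
(an intrinsic property, unlike eigenvector component signs, which depend on
the input frame). This makes GPA output reproducible to machine precision
under arbitrary per-specimen rigid motions and scalings.

Linear models on shape (or any multivariate trait block) use sequential
(type I) sums of squares from nested least-squares fits. Significance comes
from the residual randomization permutation procedure: for each term,
residuals of the model *excluding* that term are permuted and added back to
the reduced fitted values, the statistic is recomputed, and
$p = (1 + \#\{F^* \ge F\})/(n_{perm} + 1)$ — the $+1$ convention avoids
$p = 0$. The effect size $Z$ is the raw z-score of the observed statistic
against the permutation distribution (no log transform, so signs are
directly interpretable). Exhaustive enumeration replaces sampling for
$n \le 8$ and anchors the sampled p-values in tests. Phylogenetic variants
premultiply response and design by the inverse symmetric square root of
$C(\lambda)$ (eigendecomposition), with $\lambda = 1$ for the
Brownian-motion option.

Pairwise ecotype tests measure Euclidean distances between group
least-squares means (numeric covariates at their means) and build the null
by permuting residuals of the reduced model with *every* term involving the
group factor removed — the omnibus and pairwise tests therefore share one
null. Pillai's trace is computed from hypothesis and error cross-product
matrices with a pseudoinverse, so degenerate (collinear) responses behave
continuously; it requires fewer response variables than residual degrees of
freedom, which for shape data means testing on leading principal components.
Two-block PLS takes the SVD of the cross-covariance of centered blocks;
$r_{PLS}$ is the absolute correlation of the first score pair and the null
permutes one block's specimen order.

CVA operates on principal-component scores retaining 95% of variance
(configurable), capped below $n - g$ so the pooled within-group covariance
stays invertible. Jackknife classification recomputes group means and the
pooled covariance without the held-out specimen and assigns it to the
nearest group by Mahalanobis distance; exact ties go to the smaller group
index for determinism. Reported accuracy is per group and overall (the
specimen-weighted mean).

## PGLS with jointly estimated Pagel's λ

For tips with Brownian covariance $C$ (shared root-to-MRCA branch lengths),
$C(\lambda)$ multiplies the off-diagonals by $\lambda \in [0, 1]$. Given
$\lambda$, the ML estimates are
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ and
$\hat\sigma^2 = e^\top C^{-1}e/n$, with
$\log L = -\tfrac12\!\left(n\log 2\pi\hat\sigma^2 + \log|C| + n\right)$.
The profile over $\lambda$ is scanned on an 11-point grid and refined by
bounded 1-D optimization in the bracketing interval; flat profiles (a star
phylogeny) are flagged unidentifiable and resolve to $\lambda = 0$, ties
toward smaller $\lambda$. On ultrametric trees all $C(\lambda)$ share the
eigenvectors of $C$, so the model is rotated once into that basis and each
$\lambda$ evaluation is a cheap weighted regression — this is what makes the
bootstrap and the simulation studies fast.

Conventions: ML (not REML) throughout, because AIC comparison across
designs with different fixed effects requires it; AICc with
$k = \#\beta + 2$ (counting $\sigma^2$ and $\lambda$), appropriate at
$n \approx 76$ with up to 8 mean parameters; $R^2$ is the GLS variance ratio
against the intercept-only GLS fit *at the same* $\hat\lambda$ (the
definition for λ-GLS fits is not standardized; this one is monotone in fit
and bounded in $[0,1]$). Equivalences verified in tests: $\lambda = 0$
reproduces OLS; a star tree reproduces OLS; the $\lambda = 1$ slope equals
the independent-contrasts regression-through-origin slope; the profile ML
matches `nlme::gls` with a Pagel correlation structure.

The five-design comparison (`null`, `size`, `ecotype`, `size+ecotype`,
`size*ecotype`) reports $\Delta$AIC, Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$, and a support flag at
$\Delta\mathrm{AIC} < 2$.

**Bootstrap.** Coefficient uncertainty uses a *parametric* bootstrap:
$y^* = X\hat\beta + \varepsilon^*$ with
$\varepsilon^* \sim N(0,\ s^2 C(\hat\lambda))$, refitting $\lambda$ per
replicate. Tips are not exchangeable under phylogenetic covariance, so case
resampling would be wrong here. Two deliberate choices: the simulation
variance $s^2$ is the df-corrected residual variance
$\hat\sigma^2 n/(n - p)$ — simulating from the downward-biased ML variance
produces intervals that systematically undercover — and intervals are
percentile (2.5/97.5) intervals of the replicate quantities. Per-ecotype
scaling slopes and least-squares means (at the grand-mean ln size, removing
size confounding from mean contrasts) are linear combinations of
coefficients, so their replicates come directly from the coefficient
ensemble. Allometry classification is a total function of the CI sign
pattern: entirely positive → positive allometry, entirely negative →
negative, spanning zero → isometric (the traits are dimensionless, so zero
slope is the isometric expectation). Even so, percentile intervals ignore
the small-$n$ $t$-correction, and simulation at the point estimate
$\hat\lambda$ ignores its sampling error; in the calibration study below the
achieved coverage sits near the lower edge of its nominal band
(≈92–94% across random trees) rather than at 95%.

The phylogenetic paired t-test models the tip-wise trait difference with an
intercept-only PGLS, estimating a single $\lambda$ for the difference vector
(simpler than a joint two-trait model — a deliberate simplification), and
refers $\hat\mu/\mathrm{SE}$ to $t_{n-1}$.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which everything else is validated.

* **Bones** are hollow elliptical frusta with solid, superellipse-blended
  flared caps: midshaft outer semi-axes $(a, b)$, cortical thickness $t$,
  so the midshaft section is an elliptical annulus with closed-form CSA
  $\pi(ab - (a-t)(b-t))$ and moments — the oracle for the voxel code.
  Tuberosity-like bumps are Gaussian radial perturbations at fixed
  parametric sites; the proximal half flares 1.3× more so polarity is
  recoverable. Landmarks sit on a fixed $(\theta, z)$ grid of the outer
  surface, so landmark $j$ corresponds across specimens by construction —
  replacing template-registration tooling while preserving all downstream
  math. Voxelization requires $h \le b/5$ and $t \ge 2h$.
* **Phylogenies** are pure-birth (`ape::rphylo`), ultrametric by
  construction, at 76 tips by default.
* **Ecotypes** are painted as unions of whole clades: randomly chosen
  internal nodes donate their descendant tips to new (then existing)
  labels, each ecotype keeping at least 2 tips. This reproduces the
  phylogenetic clustering of real locomotor ecotypes — the very feature
  that makes λ-aware and λ-free analyses disagree — and is measured by a
  nearest-neighbor clustering index that tests compare against label
  permutations.
* **Traits** follow $y = \beta_0(e) + \beta_1(e)\,x + \varepsilon$ with
  $x = \ln$ size Brownian from the root and
  $\varepsilon \sim N(0, \sigma^2 C(\lambda))$.
* **Shapes** are an ecotype mean configuration plus $x$ times an allometric
  displacement field plus Brownian per-coordinate deviations with
  tree-structured covariance across tips.

Default magnitudes are the package's own choice (no empirical effect sizes
exist for these signals): Brownian ln-size rate 0.5 — giving several
ln-units of size spread across the tree, comparable to real squirrel body
size ranges, and enough within-clade variation that per-ecotype slopes are
statistically identifiable — residual rates and λ per trait as in
`default_trait_params()`, and 60 landmarks (10 angles × 6 heights) so the
MANOVA/CVA stay in the $p < n$ regime; real humerus/femur templates with
hundreds of pseudolandmarks are supported but not the test default.

What the generator does *not* emulate: trabecular architecture, scanner
noise and segmentation error, measurement error in landmark placement,
non-Brownian evolution (no Ornstein–Uhlenbeck), and articular-surface
anatomy. Passing tests therefore demonstrate the *statistical machinery* is
correct under its assumptions, not that those assumptions hold for any real
dataset.

All randomness flows through stage-scoped substreams of one master seed
(`stage_seed`), so identical seeds give bit-identical datasets and adding a
pipeline stage never perturbs the others' streams.

## Pipeline and problem sizes

`run_pipeline()` sequences: synthesis (or loading) → per-bone structure
traits → GPA and centroid size → phylogenetic size ANOVA with bootstrap
pairwise CIs → shape models (Pillai MANOVA on PC scores, Procrustes ANCOVA
with and without the Brownian transform, pairwise ecotype tests) → the
five-model PGLS competition per trait and bone with bootstrap allometry
calls → two-block PLS (shape↔structure and bone↔bone) → CVA → phylogenetic
paired t-tests between bones. Stage failures are isolated and logged, never
fatal; reports are CSV tables plus a markdown summary, byte-stable given the
seed (the wall-clock stage log is the one deliberately non-deterministic
output).

Problem sizes in the shipped validation runs are chosen to keep the whole
suite comfortable on a single CPU: voxel oracles at 25–50 voxels per
semi-axis, the coverage study at 300 replicates × 500 bootstrap draws on a
76-tip tree, model recovery at 100 replicates per design, permutation
calibration at 500 null datasets × 499 permutations, and the end-to-end
determinism check at 76 tips with 199 permutations and 100 bootstrap draws.
The eigenbasis formulation of the λ-profile makes these sizes cheap; all
scale linearly if increased.

## Known limitations

* Functional length is an extent, not an articular-surface distance.
* `orient_volume()` resamples obliquely oriented volumes with
  nearest-neighbor lookup; very thin cortices (< 3 voxels) can alias.
* The λ-profile can be flat or multimodal on small trees; the grid-plus-
  bounded-search strategy with ties toward smaller λ is deterministic but,
  like any profile method, inherits the likelihood's weak identification.
* Percentile bootstrap CIs run slightly below nominal coverage at
  $n \approx 76$ (see above); users needing exact small-sample calibration
  should widen intervals or increase $n_{boot}$ and replicate counts.
* High-dimensional penalized multivariate GLS is out of scope; shape-model
  inference relies on RRPP and PC-reduced MANOVA instead.
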