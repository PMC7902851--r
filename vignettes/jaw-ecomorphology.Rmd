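---
title: "Diet from jaw shape and lever mechanics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet from jaw shape and lever mechanics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawmorph)
```

## The problem

Lower jaws are among the most commonly preserved mammalian fossil elements,
and jaw form tracks diet: herbivores tend to have short jaws with tall
ascending rami and forceful, slow bites; insectivores have long jaws, short
rami and fast bites; carnivores sit in between, with a strong temporalis.
`jawmorph` turns that observation into a quantitative pipeline. Extant taxa
of known diet train two complementary descriptions of the mandible — its
outline shape (geometric morphometrics) and its lever mechanics (mechanical
advantage of the two main adductor muscles) — and fossil taxa are then
placed in the same spaces and assigned dietary posterior probabilities by a
discriminant analysis that accounts for phylogenetic relatedness.

The pipeline has five stages, mirrored by the scripts in `analysis/`:

1. data assembly (or simulation with known ground truth);
2. generalized Procrustes superimposition with sliding semi-landmarks,
   PCA morphospace of the extant taxa, projection of the fossils;
3. mechanical advantage at two bite points;
4. permutation tests of diet-group separation (shape and mechanics);
5. phylogenetic flexible discriminant analysis (pFDA).

## Superimposition

Each jaw is a configuration of 64 2-D landmarks: 6 fixed anatomical points
(anterior tip, coronoid apex, condyle, angular region, ventral-border
midpoint, m1 position) and 58 sliding semi-landmarks in four chains along
the outline. GPA removes translation, scale and rotation: configurations
are centered, scaled to unit centroid size, and iteratively rotated to the
running consensus until the consensus root-mean-square change falls below
`tol = 1e-8` (cap 100 cycles). Rotations come from the standard SVD
construction with reflections disallowed — all jaws are digitized in the
same view, so a mirrored configuration indicates a data error that should
surface, not be absorbed.

Semi-landmarks slide only along the chord between their chain neighbours.
Under the default Procrustes-distance criterion the optimal slide is the
closed-form projection `t = d · (c − x)` of the residual to the consensus
point onto the unit tangent `d`; a thin-plate-spline bending-energy
criterion is available behind a flag (`criterion = "bending"`), solved
jointly over all sliders of a configuration. Each sliding sweep is followed
by re-centering, re-scaling and re-superimposition to convergence. Sweeps
stop when the total criterion improves by less than a relative `1e-6`
(cap 50 sweeps): semi-landmarks can otherwise creep along the outline
indefinitely at numerically irrelevant gain, so convergence is defined on
the criterion value, not on coordinate movement. The per-sweep criterion is
recorded (`criterion_trace`) and is non-increasing.

Fossils and extant taxa enter **one joint superimposition**. The morphospace
(PCA) is then fit on the extant subset only, centered on the extant mean,
and fossils are projected by multiplying their centered coordinates by the
extant loadings. This keeps a single consensus frame while preventing the
fossils from influencing the axes. The retained dimensionality is
`min(n − 1, 2k − 4)`; with the study-sized training set (n = 70, k = 64)
that is n − 1, and the reconstruction from all scores is exact. Axis signs
follow a largest-element-positive convention so repeated runs are
bit-comparable; for reporting, PC1 is additionally oriented so herbivores
score negative (short jaws at the negative end) — applied as a recorded
flip in the run manifest, never silently.

## Mechanical advantage

Mechanical advantage (MA) is the ratio of the muscle in-lever to the
out-lever about the jaw joint, a dimensionless measure of force versus
speed. Four values per taxon: masseter and temporalis in-levers, each over
the out-lever at the jaw tip and at the first lower molar (m1). In-levers
and out-levers are straight-line distances (condyle to attachment or bite
point), with the pitch axis assumed at the jaw joint in all taxa; the
attachment loci are configurable (`arms_from_landmarks()`), so a
perpendicular-lever-arm convention can be expressed by supplying different
points. The algebra gives two exact invariants used as test contracts:
MA at m1 exceeds MA at the tip (shorter out-lever), and
`MA_m1 / MA_tip = outlever_tip / outlever_m1` identically for both muscles.

## Permutation tests

Diet-group separation is tested two ways.

**Shape** — one-factor Procrustes ANOVA on the flattened aligned
coordinates with significance by residual randomization (RRPP): residuals
of the reduced (intercept) model are permuted and the pseudo-F refit. When
a phylogenetic covariance `C` is supplied, data and design are first
GLS-transformed by the inverse Cholesky factor of `C` (a PGLS-style fit)
and the randomization operates in the transformed space; with `C = I` this
reduces exactly to the ordinary fit. With a single factor, Type II
conditional sums of squares coincide with the ordinary sequential ones, so
the machinery accepts one factor only and documents this reduction.
Pairwise tables test each unordered diet pair on its own subset, with the
tree pruned to the pair (the Brownian covariance of a pruned tree is
exactly the corresponding submatrix, so this is equivalent to subsetting
`C`); p-values are reported uncorrected.

**Mechanics** — one-way PERMANOVA: Anderson's pseudo-F from the pairwise
squared Euclidean distance partition, with raw label permutation. For
univariate data this equals the classical ANOVA F exactly, which serves as
a cross-check, not as the implementation.

Conventions shared by both: the p-value counts the observed statistic in
numerator and denominator, so `p ≥ 1/(n_perm + 1)`; ties are resolved by
`≥` comparison; the effect size `Z` is the deviation of log F from the
permuted log-F distribution in SD units; all tests are bit-reproducible
given the seed, with pair-level sub-seeds derived by hashing so that input
row order is irrelevant. Exhaustive enumeration of label assignments is
available for small two-group problems (`exact = TRUE`). Default
permutation count is 999 in the analysis scripts and tests; 9999 for
full-scale runs.

## Phylogenetic flexible discriminant analysis

Classes are insectivore, carnivore and herbivore; omnivores are excluded
from the discriminant because they are not separable in the morphospace.
Predictors are the leading `n_pcs = 7` PC scores. The steps:

1. Build the Brownian covariance `C` of the time-scaled tree over all
   classified taxa (training **and** predict) and apply Pagel's lambda:
   off-diagonals times lambda, diagonal preserved.
2. Whiten the predictor block together with an intercept column by the
   inverse Cholesky factor `W` (so `W C W′ = I`). Rows are ordered
   training-first and alphabetically within block before factorization:
   the Cholesky factor depends on row order, so a canonical order makes
   results invariant to input permutation, and the lower-triangular `W`
   then never mixes predict rows into training rows.
3. Fit flexible discriminant analysis by optimal scoring on the whitened
   training rows — a multivariate regression of the whitened class
   indicators on the whitened predictors, followed by eigendecomposition
   of the scoring problem. The trivial constant scoring is fit perfectly
   through the whitened intercept (eigenvalue 1) and is removed.
4. Score **all** rows on the resulting discriminant variates, and model
   classes in that space as Gaussians with shared within-class covariance
   (the LDA-consistent model) under priors proportional to training class
   sizes (an equal-prior flag exists). Posteriors, argmax predictions and
   the training classification rate follow.

With an identity covariance (lambda 0 on a star phylogeny) the whitened
intercept is constant and the whole construction collapses exactly to an
ordinary linear discriminant — the package asserts 100% prediction
agreement with an independent LDA implementation in that limit.

Two properties of this construction deserve explicit documentation. First,
whitening mixes each row with its phylogenetic neighbours, so a fossil
surrounded by training taxa of a different class is partly "explained
away"; this is inherent to whitening-based pFDA, and is mild at the small
lambda values the method typically selects. Second, because the diagonal
of `C` is preserved under lambda, taxa with shorter root-to-tip paths
(older fossils on a non-ultrametric tree) are rescaled more strongly than
extant taxa; at large lambda this can bias fossil classification along the
direction of their own class mean. Both effects vanish as lambda
approaches 0 and are the reason lambda selection matters.

**Lambda selection** (`select_lambda()`) is a grid search minimizing the
count of misclassified training taxa, with ties broken toward the smallest
lambda — the weakest phylogenetic correction consistent with the data.
Fixed-lambda mode bypasses selection (the analysis scripts run both a fixed
0.08 and the grid). The selection criterion responds to phylogenetic
signal in the intended direction: when classes are interleaved across the
tree and Brownian noise dominates the class separation, whitening improves
training separation and large lambdas win; when the traits carry no
phylogenetic signal the criterion is flat and the tie-break returns the
smallest grid value. The packaged recovery experiment
(`simulate_brownian_traits()`) instantiates the strong-signal regime as:
40 tips, two classes alternating along the cladewise tip order (so sister
taxa usually differ in class), class separation `delta = 1`, Brownian rate
`sigma2_bm = 0.3` per Myr (root-to-tip deviate SD ≈ 8 on a ~230-Myr tree,
i.e. noise an order of magnitude above the separation), observation noise
0.1. Conversely, with classes concentrated in clades, whitening removes
the class signal itself and small lambdas win — that regime is a
documented non-goal of the selection criterion.

## Time-scaling and tree tools

Cladograms are dated from tip first-appearance dates (FADs; 0 for extant
tips) by the "equal" rule. Node ages are initialised to the oldest
descendant FAD, honouring any older node constraints; zero-length branches
are then removed by re-dividing the duration of the nearest ancestral
branch with positive slack equally along the zero-length chain. A chain
reaching the root draws on a `root_extension` (default 1 Myr, logged via
`root_extended`); with no extension available that is an error rather than
a silent fix. Tips are placed at their FAD, not their last appearance —
first appearances are what fossil databases date; LADs are carried for
reporting only. Polytomies are kept, not randomly resolved.

Pruning produces the induced subtree with all pairwise path lengths
preserved and — deliberately — retains the stem back to the original root
as a root edge, so that the Brownian covariance of a pruned tree is an
exact submatrix of the full-tree covariance. The Brownian covariance
itself is computed by explicit node-depth traversal
(`C[i, j]` = root-to-MRCA shared path) and is cross-checked in the tests
against an independent implementation.

## The synthetic data generator

`synthetic_spec()` defines the study conditions the tests run under:
70 extant training taxa (8 herbivores, 16 carnivores, 13 insectivores,
33 omnivores), 45 fossil taxa whose true diets are hidden from the
pipeline, the 6 + 58 landmark regimen, and fossil FADs uniform on
66–201 Ma. Jaw shapes are built from a schematic mandible template
deformed along two anatomically interpretable fields — jaw elongation and
ascending-ramus height, both unit-RMS — with class means encoding the
qualitative diet structure (herbivores short/tall, insectivores
long/short, carnivores intermediate-short, omnivores central), plus a
Brownian deviate of the two deformation coefficients along the tree, plus
iid digitization noise per coordinate, and finally a random similarity
transform so the superimposition has real work to do. Applying the
Brownian noise to deformation coefficients rather than raw landmarks keeps
configurations anatomically plausible and makes lambda-recovery tests
meaningful. Moment arms are Gaussian around diet-class means (herbivores
high MAM and MAT, carnivores low MAM / high MAT, insectivores low-medium
both), resampled on invariant violations.

Default magnitudes, chosen once: the template is ~10 units long;
digitization noise `sigma_obs = 0.04` per coordinate; class effect
`delta = 0.2` deformation units (five times the digitization noise — a
clear but not caricatured diet signal); Brownian rate `sigma2_bm = 1e-5`
per Myr, i.e. a root-to-tip deviate SD of ~0.05, a quarter of the class
effect. Fossil true diets are drawn from the three non-omnivore classes
(weighted toward insectivory), matching the faunivore-dominated character
of Mesozoic samples. Everything is deterministic under the seed, with
per-taxon substreams so taxon count does not shift the stream.

What the generator does **not** emulate: real within-class anatomical
diversity (a single template with two deformation fields), correlation
between shape and moment arms beyond their shared diet class, diets
clustered on the phylogeny (labels are assigned independently of the
tree), digitization error that is correlated along outlines, or the
strongly divergent allotherian jaw morphologies the study design excludes.
Green tests therefore demonstrate the machinery's correctness and power
under clean diet signal; they do not certify classification accuracy on
real Mesozoic material.

## Numerical choices and degenerate inputs

- GPA tolerance `1e-8` (consensus RMS change), sliding stop at relative
  criterion gain `1e-6`; non-convergence is a warning carrying the final
  change, not an error.
- PCA and discriminant axis signs by the largest-element-positive rule.
- Permutation ties counted by `≥`; p floors at `1/(n_perm + 1)`;
  degenerate F (constant data) is an error for PERMANOVA and yields
  `Z = NA` where the permuted distribution collapses.
- Singular covariances (duplicate tips, lambda 1 on trees with zero-length
  cherries) fail with advice to lower lambda or prune.
- TPS `SCALE=` factors are never applied silently; shape analysis is
  scale-free, and mechanics require explicit lengths.
- Zero-length out-levers, mixed landmark counts, chains without interior
  sliders, constraints younger than descendant tips: all hard errors
  naming the offender.

## Problem sizes in the test suite

The suite runs the full study-sized conditions (115 taxa, 64 landmarks)
where the contract is about the end-to-end result (diet recovery across
10 seeds), and smaller conditions (17 training + 8 fossil taxa; 999 or
fewer permutations; 50 lambda-recovery replicates of 40 tips) where the
contract is a property of the machinery. These sizes are the package's own
choices balancing statistical resolution against runtime; the conventions
(9999 permutations, 7 PCs, lambda 0.08) used for full-scale analysis are
the defaults of the corresponding functions.

## Known limitations

- 2-D only; no missing-landmark estimation; no reflection handling for
  asymmetric objects.
- One-factor designs only in the permutation machinery (the diet analyses
  need nothing more).
- Lambda selection by training misclassification is coarse (integer
  criterion) and, by design, prefers small lambda under clade-structured
  class signal.
- The pFDA fossil-row scaling effect on strongly non-ultrametric trees at
  large lambda, described above.
- Time-scaling implements the "equal" rule only (no minimum-branch-length
  or probabilistic calibration variants).
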