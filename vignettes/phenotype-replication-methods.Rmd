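---
title: "Methods: simulating and replicating breast-MRI imaging phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and replicating breast-MRI imaging phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceipr)
```

## The problem

Radiologists describe a breast cancer on dynamic contrast-enhanced MRI with a
small standardised vocabulary: its size (longest diameter), shape (round/oval
vs irregular), internal enhancement (homogeneous vs heterogeneous) and margin
(circumscribed, irregular, spiculated). These human-extracted imaging
phenotypes (HEIP) carry known inter-observer variability. Radiomics pipelines
compute quantitative features (computer-extracted imaging phenotypes, CEIP)
from the same images. Two questions follow naturally:

1. How well do readers agree with each other on each descriptor?
2. Can the quantitative features *replicate* each human descriptor — i.e.
   predict the consensus reading of a panel?

`ceipr` implements the full analysis chain for these questions — lesion
segmentation, a 24-feature CEIP inventory, agreement statistics, association
tests, and penalised replication models — together with a synthetic phantom
cohort generator and a simulated reader panel, so that every statistical
component can be exercised and validated end-to-end on data with known ground
truth.

## The phantom generator

A phantom lesion is a star-shaped solid whose surface radius is

$$ r(\theta, \varphi) = R\,\bigl(1 + a\,Y_\ell(\theta, \varphi)\bigr), $$

with base radius $R$ (mm), lobulation amplitude $a \in [0, 0.5]$ and $Y_\ell$ a
real spherical harmonic of degree $\ell$ (order $\lfloor \ell/2 \rfloor$,
max-normalised to 1). The harmonic family was chosen over random blobs because
the continuous surface has cheap, accurate quadrature oracles for volume and
surface area, against which the voxel-based feature extractors are tested. A
voxel belongs to the truth mask iff its centre lies inside the surface — a
deliberately simple, reproducible rasterisation rule.

The post-contrast volume is
`pre + blur(contrast * (1 + h) * mask) + noise`, where `h` is a Gaussian
random field (correlation length `texture_corr_mm`, standardised to standard
deviation `texture_sd` inside the lesion) modelling heterogeneous uptake, the
blur is an isotropic-in-mm Gaussian of width `margin_blur_mm`, and the noise
is white Gaussian. The default grid is anisotropic (0.7 mm in-plane, 2.5 mm
slice spacing), matching typical fat-suppressed T1 acquisitions, so every
geometric computation must be spacing-aware; isotropic grids are equally
supported.

Latent HEIP categories are defined by fixed thresholds on the *generating
parameters*, not by re-measuring the rasterised mask: shape is irregular at
$a \ge 0.12$, margin is irregular at $a \ge 0.12$ and spiculated at
$a \ge 0.25$, enhancement is heterogeneous at `texture_sd >= 0.10`. This keeps
the reader simulation strictly independent of the feature code under test.

### The reader model

Each of three readers reports `size = latent_size * exp(e)` with
`e ~ Normal(bias, sd^2)`, and draws each categorical rating from a confusion
matrix row conditional on the latent category. Defaults are calibrated a
priori from closed forms, not fitted to any test outcome:

* `size_log_sd = 0.13`: the pairwise probability that two readers agree within
  20% is $2\Phi\!\bigl(\ln 1.2 / (\sigma\sqrt{2})\bigr) - 1 \approx 0.679$ at
  $\sigma = 0.13$, the moderate agreement level typical of expert panels.
* binary confusion accuracies 0.86 (shape) and 0.77 (enhancement): for
  balanced latent classes, two independent readers agree with probability
  $1 - 2p(1-p)$, putting chance-corrected agreement near 0.5 and 0.3.
* a 3x3 margin confusion with 0.80 diagonal mass concentrated on adjacent
  categories.

With three readers, the rare all-distinct margin triple is redrawn, so a
simple-majority consensus always exists — real three-reader panels behave this
way, and it keeps the consensus rule total on generated data. Consensus takes
the majority category and the *median* size; the median is
majority-compatible for a continuous measurement and robust to one outlying
reader.

The full-image cohort draws lesion diameters log-uniformly from 8–28 mm so
the largest lobulated lesion still fits the default 64 x 64 x 28 grid with a
two-voxel margin; panel-only simulations (no images needed) use the full
clinical 8–60 mm span. All simulation sizes used in the test-suite were
chosen as the smallest cohorts at which the relevant Monte-Carlo error bands
are meaningful (2000 cases for agreement calibration, 20 phantom cases for
the end-to-end run, 50–150 repetitions for recovery rates).

### What the phantoms do not emulate

No fibroglandular background or parenchymal enhancement, no multi-focal
disease, no non-mass enhancement, no acquisition artefacts or bias fields.
Passing tests therefore demonstrate the *statistical machinery* is correct and
calibrated, not that segmentation or features are accurate on clinical images.

## Segmentation

The enhancement signal is the signed subtraction `post - pre` (robust when the
fat-suppressed background is near zero, where a ratio would explode). Scalar
two-class fuzzy c-means (fuzzifier $m = 2$, tolerance $10^{-5}$, at most 100
iterations) runs inside a cubic VOI around a user-supplied approximate lesion
centre; the VOI half-width defaults to twice the expected lesion radius.
Deliberate numerical choices:

* centroid initialisation at the 10th/90th intensity percentiles — fully
  deterministic, no random restarts;
* tumour class = higher centroid; membership binarised at 0.5 (for two scalar
  clusters at $m = 2$ this is the midpoint rule);
* 26-connectivity for the lesion component containing the seed, 6-connected
  background flood for hole filling;
* a constant VOI raises `"no contrast in VOI"`, a seed outside every
  suprathreshold component is an error rather than a silent empty mask.

The objective is non-increasing across iterations and the result is invariant
to adding a constant to the enhancement map; both are tested.

## The 24-feature inventory

Size (4): voxel volume; effective diameter $(6V/\pi)^{1/3}$; mesh surface
area; maximum linear size (largest pairwise distance between surface-voxel
centres, a 3D analogue of the longest-diameter rule — the human measurement is
in-plane, a difference we document rather than hide). Shape (3): sphericity,
irregularity, surface-to-volume ratio. Morphology (3): mean and variance of
margin sharpness, variance of the radial gradient histogram. Texture (14):
the classical Haralick features of one pooled 3D grey-level co-occurrence
matrix.

Design decisions worth spelling out:

* **Surface area** comes from a marching-tetrahedra mesh of the lightly
  smoothed (sigma = 1 voxel) indicator at level 0.5. The smoothing is
  anti-aliasing: meshing a raw binary staircase biases the area upward, while
  the smoothed level set tracks the true surface to within a curvature term
  of order $\sigma^2/r$. On digital spheres the area error is about 2% at
  $r = 10$ voxels and shrinks several-fold at $r = 20$.
* **Sphericity** is the overlap fraction between the lesion and the
  equal-volume ball centred at its centre of mass, voxelised on the same
  grid. **Irregularity** is the surface excess $1 - \pi d_\mathrm{eff}^2 / A$.
  Using an overlap-based sphericity keeps the two features from being
  deterministic functions of each other, which matters because both enter the
  inventory as separate phenotypes.
* The category counts are 4/3/3/14 with the surface-to-volume ratio placed
  under *shape*; inventories that list it under size conflate the two — the
  count-consistent assignment is used here.
* **Margin sharpness** is the absolute directional derivative of the
  post-contrast image along the outward radial unit vector from the centre of
  mass (central differences, per mm). The radial direction approximates the
  surface normal and is stable on thin anisotropic grids. The post-contrast
  volume (not the subtraction image) is differentiated by default;
  configurable.
* The **radial gradient histogram** collects
  $\hat r \cdot \nabla I / |\nabla I|$ over margin voxels into 40 bins on
  $[-1, 1]$; its variance attains the single-bin maximum
  $((1 - 1/40)^2 + 39/40^2)/40 \approx 0.0244$ when every margin gradient is
  radial (a resolved sphere edge) and decreases as spiculation disperses the
  gradient directions. It is a direction-coherence measure, not a blur
  measure.
* **GLCM**: intensities min-max quantised to 32 levels inside the mask,
  co-occurrences pooled over the 13 unique 3D directions at displacement 1,
  symmetrised, normalised. Pooling is standard for DCE-MRI radiomics where
  anisotropy makes per-direction matrices sparse. A constant lesion yields a
  defined degenerate single-cell GLCM (with a warning) so the downstream
  limits — energy 1, entropy 0, contrast 0 — stay testable.
* **Haralick formulas** use log base 2 and $0 \log 0 = 0$; sum variance is
  taken about the sum average, difference variance is the variance of the
  difference marginal, and the degenerate limits (correlation, the
  information measures, the maximal correlation coefficient) are defined as 0
  when a marginal concentrates on a single level. Every feature is checked
  against an independent direct-summation oracle to $10^{-10}$.

## Agreement statistics

Size agreement is the pooled pairwise coverage probability: the fraction of
same-case reader pairs whose sizes differ by a ratio under 1.20, i.e.
$|\ln s_i - \ln s_j| < \ln 1.2$ — a log-ratio statistic, invariant to global
rescaling. Pairs are pooled across cases (the "any two readers" reading)
rather than averaged per case. No intra-class correlation is computed: the
statistic of record for size is the coverage probability.

Categorical agreement is Krippendorff's alpha from the coincidence matrix,
with the nominal metric for the binary descriptors and the
cumulative-frequency ordinal metric for the graded margin scale. A panel in
which every rating is identical has zero expected disagreement; alpha is
defined as 1 there, with a warning. Confidence intervals are case-resampling
percentile bootstrap — cases, not rows, are the exchangeable unit — with the
statistic allowed to fail on at most 10% of replicates.

## Association testing

Size and margin (ordinal-coded) against their candidate CEIP use Kendall's
tau-b with permutation p-values (add-one rule, so p is never 0); tau-b is the
tie-corrected variant, necessary because a 3-level scale is nothing but ties.
The binary descriptors use the two-sided Mann-Whitney U test (exact
enumeration for small tie-free samples). Benjamini-Hochberg correction is
applied over the whole 24-row table by default (the most conservative family
choice; per-descriptor families are a config option). All alternatives are
two-sided.

## Replication models

Each descriptor is predicted from its own CEIP category: elastic-net linear
regression for size (metric: mean squared deviation), elastic-net logistic
classifiers for shape and enhancement (metric: AUC by the midrank formula,
ties at half credit), and an elastic-net proportional-odds model for margin
(metric: tau-b between the classifier score $X\beta$ and the observed level).
Note that tau-b between a continuous score and a tied 3-level response is
capped below 1 by the tie correction even for a perfectly ordering score —
$\sqrt{(n_0 - T_y)/n_0}$ is the attainable ceiling.

The linear and logistic fits are glmnet's; the penalised proportional-odds
model is fit by accelerated proximal gradient descent (FISTA with restart,
soft-thresholding the slopes so zeros are exact, thresholds unpenalised and
kept monotone by isotonic projection). Near the unpenalised limit it matches
`MASS::polr` to three decimals on simulated data.

Performance is estimated by nested ten-fold-by-ten-fold cross-validation:
inner folds select the mixing parameter and penalty strength, the model is
refit on the outer training split, and each case is predicted exactly once.
Fold assignment is stratified for categorical responses and is a
deterministic function of the data and seed in a *case-order-invariant* way
(cases are canonically ordered by their values before the seeded shuffle).
Predictive-signal p-values come from permutation tests that re-run the entire
nested pipeline per permutation with fresh fold assignment — the conservative
reading, since fold reuse leaks structure. The four p-values are
Benjamini-Hochberg corrected. The "chosen predictor" reported per descriptor
is the model tuned by single-level ten-fold CV on all cases and refit on all
cases; nested CV is used only for the performance estimate, keeping selection
and assessment separate.

**Selection rule.** The penalty is chosen by the one-standard-error rule
rather than the CV-loss minimiser. Measured on the canonical sparse-recovery
design ($y = 2x_1 - x_3 + \varepsilon$, $n = 200$, $\sigma = 0.5$, 150
repetitions), the minimiser recovers the exact support only ~20% of the time
(noise variables slip in at tiny penalties along a flat CV curve), while the
one-SE rule recovers it ~94% of the time at essentially identical prediction
error. Since the reported replication output includes the *selected feature
set*, support quality is part of the estimand and the sparser rule is the
right default; `selection = "min"` remains available. The penalty path length
(30 points over three decades) matters too: 20-point paths measurably degrade
support recovery by quantising the one-SE choice.

## Numerical conventions and degenerate inputs

All randomness descends from one user seed through named substreams; no
global RNG state is consumed. Permutation p-values use the add-one rule.
Empty masks, constant VOIs, flat margins, all-tied vectors, single-class AUC
and missing ordinal levels raise informative errors; constant-lesion GLCMs
and all-identical panels take documented limits instead. `NaN` is never
emitted from the feature extractor.

## Limitations

* The phantom family is star-shaped and single-lesion; infiltrative or
  multi-focal morphology is out of scope.
* Latent margin and shape share one generating parameter (the lobulation
  amplitude), so their simulated associations are more correlated than in
  clinical data.
* The maximum linear size is 3D, while human longest-diameter measurements
  are in-plane; a per-slice 2D variant is available for parity experiments.
* Agreement and replication behaviour on real multi-centre MRI depends on
  acquisition variation the simulator does not model.
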