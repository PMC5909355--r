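# ceipr

Quantitative radiomics of breast lesions on dynamic contrast-enhanced MRI, and
the question of whether computer-extracted imaging phenotypes (CEIP) can
replicate what radiologists report. Radiologist panels describe a lesion by
four descriptors — size (longest diameter), BI-RADS shape (round/oval vs
irregular), internal enhancement (homogeneous vs heterogeneous) and margin
(circumscribed / irregular / spiculated). `ceipr` implements the complete
analysis chain around those descriptors:

* **Synthetic cohorts** — 3D pre/post-contrast phantom pairs with star-shaped
  lesions (spherical-harmonic lobulation, margin blur, heterogeneous uptake,
  noise) on anisotropic grids, plus a simulated three-reader panel with a
  log-normal size error and per-descriptor confusion matrices.
* **Segmentation** — deterministic two-class fuzzy c-means on the enhancement
  signal (`post − pre`) inside a VOI around a seed point, with connected-
  component and hole-filling post-processing.
* **Features** — the 24-phenotype CEIP inventory: 4 size, 3 shape, 3
  morphology (margin sharpness, radial gradient histogram) and 14 Haralick
  texture features from a pooled 3D GLCM.
* **Agreement** — the pairwise 20% coverage probability π for size,
  Krippendorff's α (nominal/ordinal) for the categoricals, case-resampling
  bootstrap CIs, and majority/median consensus.
* **Association** — Kendall τ-b with permutation p-values, Mann–Whitney U,
  Benjamini–Hochberg correction, arranged as the 24-row descriptor × feature
  table.
* **Replication** — elastic-net linear / logistic / proportional-odds models
  per descriptor, assessed by nested ten-fold-by-ten-fold cross-validation
  (MSD, AUC, τ-b), with whole-pipeline permutation signal tests.

The core quantities, in the field's notation: size agreement is
π = P(|ln s_i − ln s_j| < ln 1.2) over same-case reader pairs; categorical
agreement is α = 1 − D_o/D_e from the coincidence matrix; replication models
minimise `(1/2n) Σ loss + λ (α‖β‖₁ + (1−α)/2 ‖β‖₂²)`.

## Worked example

```r
library(ceipr)

# a 20-case simulated cohort with a 3-reader panel
cohort <- generate_cohort(20, model = reader_model(), rng_seed = 7)

# segment each case from its enhancement map and extract the 24 features
feats <- cohort_features(cohort)
cons  <- reader_consensus(cohort$panel)

# inter-observer agreement summary
agreement_report(cohort$panel, B = 500, rng_seed = 7)[, 1:5]
#>             descriptor statistic  estimate       ci_lo     ci_hi
#> 1                 size        pi 0.5500000  0.45000000 0.6500000
#> 2                shape     alpha 0.4957265  0.12507456 0.7951389
#> 3 internal_enhancement     alpha 0.3881481 -0.02996619 0.7302971
#> 4               margin     alpha 0.8508312  0.69942560 0.9477030

# which features track the human size reading?
tab <- associate_features(cons, feats, n_perm = 2000, rng_seed = 7)
head(tab[tab$heip_descriptor == "size", c(2, 4, 5, 6)])
#>               ceip_name statistic        p_raw        p_bh
#> 1            volume_mm3 0.8105263 0.0004997501 0.002998501
#> 2 effective_diameter_mm 0.8105263 0.0004997501 0.002998501
#> 3      surface_area_mm2 0.8526316 0.0004997501 0.002998501
#> 4    max_linear_size_mm 0.8647489 0.0004997501 0.002998501
```

The agreement estimates sit in the moderate range the simulated reader model
is calibrated to (π is 0.55 on this small 20-case draw; its closed-form value
at the default σ = 0.13 is 0.679, and the bootstrap CI reflects the small
cohort). The τ-b values near 0.85 with BH-adjusted p ≈ 0.003 say the
size-category features almost perfectly rank-order the consensus size reading
on this synthetic cohort, as they should: the simulated readers measure a
noisy copy of the true diameter. `replicate_heip(cons, feats, ...)` then fits the four
penalised models and reports the nested-CV metric, permutation p and selected
features per descriptor.

A thin command-line wrapper over these functions ships in
`inst/cli/ceip.R` (subcommands `simulate`, `segment`, `extract`, `agree`,
`associate`, `replicate`, `run-all`).

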