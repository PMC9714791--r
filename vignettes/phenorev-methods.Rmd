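---
title: "phenorev: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenorev: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorev)
```

This vignette is the package's own account of its science: the models
behind each module, the parameters that matter, what the synthetic
generators establish (and what they cannot), and the numerical choices
made where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## 1. The reversal-probability classifier

### Model

A lowering study yields, per gene, two independent contrasts: disease
vs control ("disease effect" Δ~d~ ± σ~d~) and lowered vs disease
("treatment effect" Δ~t~ ± σ~t~), each summarised by a DE fitter as an
estimate and standard error. The treatment effect is expressed as a
multiple of the disease effect, Δ~t~ = αΔ~d~. Under this convention
α = −1 means the treatment moved expression exactly back to control,
α = 0 means no treatment effect, and α > 0 means the dysregulation was
amplified. Five classes of α are scored, with cut points at −1.3,
−0.7, −0.3 and +0.3: super-reversal, full reversal, partial reversal,
negligible reversal, exacerbation.

Treating the two estimates as independent normals, the posterior
probability that α lies in a class is the probability mass of the
bivariate normal over the corresponding wedge of the (Δ~d~, Δ~t~)
plane. `reversal_probs()` integrates this by quasi-Monte-Carlo: *n*
points at the equally spaced quantile levels (k − ½)/n of each
marginal (default n = 121, so 121 × 121 nodes), the ratio classified
at each node.

### Why equal weights on the quantile grid

Placing nodes at quantiles of each marginal already distributes them
according to the normal densities, so each node carries weight 1/n² —
the density acts as an *implicit* importance weight. The alternative
reading (equally spaced abscissae with explicit density weights) is
implemented behind `weighting = "density"`; the test suite checks the
two agree to well within the 0.01 quadrature tolerance, which is why
the simpler quantile placement is the default.

### Conventions at the edges

* **Class boundaries** are measure-zero events; they are assigned to
  the stronger-reversal side (α = −1.3 → super, −0.7 → full, −0.3 →
  partial, +0.3 → negligible). Any fixed rule would do; this one is
  fixed and documented.
* **Category ties** (after the negligible override fails to fire) are
  broken toward the stronger reversal: super > full > partial >
  exacerbation.
* **Nodes with Δ~d~ = 0** make the ratio diverge. They are classified
  as exacerbation when Δ~t~ ≠ 0 and negligible when both are zero —
  deliberately conservative against claiming rescue. Such nodes only
  arise when the disease estimate is within rounding of zero, where no
  reversal claim should be made anyway.
* **Override and significance**: a gene is negligibly reversed
  whenever P(negligible) ≥ 0.05 regardless of the other classes;
  otherwise the argmax of the remaining four wins. The overall
  reversal probability ORP = 1 − P(negligible) is called significant
  strictly above 0.95.

### Numerical behaviour

The suite checks three quantitative properties: agreement with a
10⁶-draw Monte-Carlo oracle within 0.01 per class across a sweep of
(Δ, σ) pairs including near-zero disease effects; stability of every
probability to 0.01 when the grid is refined from 121 to 301 points
per axis (301 already more than doubles the resolution; refining
further changes nothing at the tolerance of interest); and exact
symmetry under joint negation of both effects.

## 2. Signatures and set algebra

A gene enters a disease signature iff its BH-adjusted p-value is below
0.05 **and** its fold change is at least 20% in either direction,
interpreted symmetrically on the ratio scale as |log2FC| ≥ log2(1.2)
≈ 0.263. Genes responding to the inducer alone in control animals are
subtracted from the signature (`exclude_responders()`), using the same
thresholds for the responder contrast — one filtering rule throughout.
Signatures from two ages combine by union and intersection with a size
report; the suite checks the inclusion–exclusion identity and
threshold monotonicity on random inputs.

Two open choices are recorded rather than hidden: the fold-change
filter is applied to whatever `log2fc` column the caller provides
(shrunken or not — the provenance string says which padj source was
used), and a supplied `padj` column is trusted as-is while a missing
one is recomputed by the package's own step-up implementation
(`bh_adjust()`, tested against a hand oracle and `stats::p.adjust`).

## 3. Enrichment

Overrepresentation of a signature in a gene-set collection is the
upper-tail hypergeometric probability P(overlap ≥ k) given universe
size N, set size K and signature size n, with BH q-values across the
tested sets and gene ratio k/n for ranking. The universe is **all
genes observed in the DE table**, not the union of the collection:
that is the only universe the pipeline observes, and matches the usual
enricher default. The collection is any user-supplied GMT; nothing is
bundled. Per-set reversal percentages (`reversal_fraction_by_set()`)
report, for each scenario, the share of signature genes in the set
with ORP above the bar — the numbers a radar plot is drawn from.

## 4. Decorrelated ranked feature analysis

The reference procedure is proprietary and unpublished; every stage
here is an explicit, swappable choice, and no claim is made that any
printed index from a specific study is recoverable.

* **Decorrelation** — features are standardised and whitened by the
  pooled *within-group* covariance, so group separations are not
  whitened away. When the covariance is ill-conditioned (features
  outnumber subjects, duplicated features) an analytic Ledoit–Wolf
  shrinkage toward a scaled identity is applied; the intensity is
  estimated from the data and reported in the fitted object.
  `shrinkage = 0` enforces the exact whitening contract (transformed
  pooled covariance = identity to 1e-6, tested).
* **Ranking** — components are ordered by the subject-weighted
  variance of group means along each component; for two groups this
  reduces to the squared standardised mean difference (verified
  against a brute-force ordering in the tests).
* **Overlap** — the Bhattacharyya coefficient, closed-form for
  Gaussians, chosen for symmetry, boundedness in [0, 1] and exactness
  at the endpoints; the index 50 + 50·(1 − BC) hits exactly 50 for
  identical clouds and approaches 100 at large separation (for equal
  spherical covariances it equals 50 + 50·(1 − exp(−d²/8)), which the
  suite checks).
* **Permutation p-values** — the *entire* pipeline (space fit, cloud
  fit, index) is recomputed for each relabelling, so the p-value
  accounts for selection effects in the whitening and ranking; the
  add-one estimator keeps p > 0. Super-uniformity under the null is
  verified by simulation at reduced scale (150 null datasets × 60
  permutations rather than 200 × 1000, to keep the suite inside its
  runtime budget; the acceptance bound includes the coarser binomial
  resolution this implies).
* **Projection and rescue** — treated groups are mapped through the
  *fixed* reference transform (no refitting), compared with each
  reference cloud by distance and index, and scored per subject by
  orthogonal projection onto the disease-to-control axis, affinely
  scaled so the disease mean is 0 and the control mean 100. Scores
  are reported unclipped: values outside [0, 100] are information
  (overshoot or worsening), not errors.

## 5. Inclusion-body quantification

The recipe mirrors a scripted high-content analysis: all images are
floats in [0, 1].

* **Sliding parabola** (curvature 6): background is the grayscale
  opening with a parabolic structuring function, computed separably.
  The curvature setting originates from software operating on raw
  camera counts; the parabola height is therefore scaled by intensity
  range relative to a 16-bit full scale, so curvature 6 keeps its
  meaning (effective half-width ≈ 148 px) on normalised images. The
  tests require constants to map to zero, a linear ramp to vanish
  without moving blob peaks by more than 1 px, and near-idempotence.
* **Nuclei**: Otsu threshold on the background-removed nuclear
  channel, 8-connected components, hole filling, area floor 200 px.
  The vendor's detection algorithm is unpublished; Otsu + components
  is the standard open equivalent and is validated against simulated
  truth masks.
* **Texture filter**: the proprietary spot-texture operator is
  replaced by a documented centre-surround stand-in — difference of
  Gaussian blurs at the scale (3 px) and twice the scale, negatives
  clipped. The response is divided by 0.3, the closed-form peak
  response of that operator to a unit-amplitude Gaussian spot *at* the
  scale (s²/(s²+s²) − s²/(s²+4s²) = 0.3 for every s), so a spot of
  amplitude a scores ≈ a and the segmentation threshold 0.2 has
  meaningful units on normalised images. The stand-in is validated
  against simulated truth, not against the vendor implementation.
* **Filter cascade**: components of texture > 0.2; area ≥ 5 px; mean
  intensity ≥ 2× the global mean of the *unfiltered* spot channel (the
  raw normalised image, per the recipe's wording); mean intensity
  ≥ 1.3× the mean of a 4-px-wide surrounding ring, other candidate
  spots excluded from the ring so adjacent aggregates do not mask each
  other. Nuclear assignment is centroid-in-mask — the upstream rule is
  unstated, and the centroid is the only unambiguous single-pixel
  summary. Every retained record stores the measured quantities so
  the filters can be re-checked directly (the suite does).
* **Densities**: nuclear and extranuclear counts divided by the region
  area in mm², with area = pixels × (0.32 μm × 10⁻³)². Aggregation
  across sections/animals is left to a thin caller — the statistics on
  densities are routine and out of scope.

## 6. The synthetic generators: a stated world

The generators' defaults are fixed choices, made once, describing the
world the tests run in. They are not tuned to outcomes.

* **DE tables** — 5,000 genes, 20% dysregulated; true effect
  magnitudes from N(0.6, 0.25) folded at zero with random signs
  (typical effects just above the 20% fold-change threshold, where a
  realistic bulk contrast concentrates); per-gene SEs uniform on
  [0.05, 0.25], the range a well-powered bulk design produces;
  p-values are exact two-sided normal tails of estimate/SE. The
  treatment contrast is **lowered vs disease**, the only reading under
  which "full reversal at α ≈ −1" is coherent; the convention is
  recorded in the output attributes. What this does *not* emulate:
  count-level noise, dispersion shrinkage, correlated genes,
  independent filtering. A green parameter-recovery test therefore
  establishes that the classifier inverts the stated generative model,
  not that any particular biological dataset behaves this way.
* **Behavior** — groups of ≥ 3 subjects drawn from multivariate
  normals with unit variances, a common equicorrelation (default 0.3)
  and per-group standardised mean offsets. This is an explicit
  Gaussian stand-in for proprietary platform features whose real
  distributions are unpublished; the generator supports the overlap
  analysis, not claims about real feature shapes.
* **Images** — 256² px at 0.32 μm; 12 non-overlapping soft-edged
  nuclei of radius ≈ 14 px (area ≈ 600 px, comfortably above the
  200-px floor), placed with a 6-px gap so thresholded edges never
  bridge; spots as isotropic Gaussians of σ = 3 px (matching the
  texture scale the recipe is tuned to), amplitude 0.5 over a 0.05
  baseline, Poisson shot noise at a 2,000-count gain plus Gaussian
  read noise of 0.01 (SNR 50 by default; tests lower it when probing
  SNR behaviour). Nuclear spot counts are Poisson per nucleus;
  extranuclear counts Poisson per mm² of non-nuclear area. Generated
  spots keep a minimum mutual spacing of 6σ so truth matching in
  recall/precision tests is unambiguous — real aggregates do cluster,
  so measured recall here does not bound recall on clustered data.

## 7. Known limitations

* The reversal model assumes independent disease and treatment
  estimates; shared control samples would correlate them, and no
  moderation/shrinkage of the inputs is attempted.
* DRFA's decorrelation, ranking and overlap are principled choices,
  not reconstructions of the proprietary procedure; printed indices
  from specific studies (e.g. 64.8%) are not targets.
* The texture filter is a stand-in with matched scale and calibrated
  threshold, validated on simulated truth only.
* GMT collections, universes, and the column the fold-change filter
  applies to are caller responsibilities, recorded in provenance
  strings rather than enforced.
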