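---
title: "Methods: texture features and test–retest repeatability in texrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture features and test-retest repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`texrep` measures how repeatable radiomic texture features are when the
same tumor is imaged twice with no intervening biological change. This
vignette documents the models and estimators the package implements, the
choices made where the methodology is genuinely open, and what the
synthetic phantom does and does not establish about real data.

## The measurement model

A test–retest design images each subject on two consecutive days. Over
one day a tumor is assumed biologically static, so the paired feature
difference `d = x1 − x2` estimates pure measurement error: acquisition
noise, scanner signal-level drift, and the reader's re-delineation of the
tumor boundary. The package grades each feature by three complementary
statistics:

* **Bland–Altman limits of agreement** `mean(d) ± 1.96·SD(d)` (sample SD),
  with each limit's 95% CI taken as `limit ± t₀.₉₇₅,ₙ₋₁·√(3s²/n)` — the
  classical large-sample variance of an agreement limit.
* **Within-subject CV** `wCV = 100·s_w/mean(x)` with `s_w = √(Σd²/2n)`,
  the two-replicate pooled within-subject SD. The denominator pools all
  `2n` measurements; with complete pairs (enforced) this equals the mean
  of per-subject means. Features that are sign-mixed or zero-mean across
  the cohort (cluster shade is a typical case) make a CV meaningless; they
  are flagged `wcv_interpretable = FALSE` and excluded from grading rather
  than reported with a spurious class.
* **Repeatability coefficient** `r = 1.96·√(Σd²/n) = 1.96·√2·s_w`, the
  95% bound on a single subject's absolute difference under Gaussian
  error. The test suite verifies this coverage interpretation by direct
  Monte-Carlo simulation.

Reliability classes follow the conventional wCV bands: `[0,10]` good,
`(10,15]` acceptable, `(15,30)` intermediate, `[30,50)` moderate-poor,
`≥50` unreliable. Both boundary conventions (10 → good, 50 → unreliable)
are deliberate and tested. With two readers, all statistics are computed
independently per reader; no pooled inter-reader statistic is produced.

## Preprocessing

Each study is cropped to the mask bounding box (1-voxel pad), filtered
in-plane, and quantized:

* **Smoothing.** The filter is a per-slice 2D separable Gaussian with
  σ = 2 mm by default (a Laplacian-of-Gaussian variant and `none` are
  available). Per-slice filtering is forced by the acquisition geometry:
  with 6 mm sections and a 1.8 mm gap (7.8 mm pitch) a 3D kernel would mix
  tissue 8 mm apart with in-plane neighbours 0.68 mm apart. Kernels are
  renormalized at image edges so constant images are preserved exactly.
  The scale is a genuine open choice — "medium" smoothing is a
  software-specific notion — so it is a logged config entry rather than a
  constant.
* **Quantization.** Equal-width binning into G = 32 bins spanning the
  `[min, max]` of the in-mask intensities after filtering; the top bin is
  right-closed so the maximum maps to bin G. ROI-relative min–max binning
  is the dominant radiomics convention and makes every downstream feature
  invariant to positive affine intensity rescaling (tested by property).
  An intensity spread below `1e-8` relative is treated as constant: all
  voxels get bin 1 and a flag, which keeps a filtered constant image from
  being quantized on float rounding error. First-order mean/median/SD are
  computed on the stored pre-binning intensities (physical units), so a
  global signal-level change between studies is visible to them;
  entropy/energy and all texture matrices use the bins.
* No resampling, bias-field correction, or inter-study intensity
  normalization is applied. Features operate on the voxel lattice in
  index space; the anisotropic geometry is carried as metadata.

## Feature families and dialects

Exact formulas live in the function documentation; the points below are
the places where a dialect had to be chosen.

* **GLCM/GLDM** are in-plane (distance 1, the 4 unique directions),
  honouring the standard definition of second-order features as relations
  between adjacent in-plane voxels. Counts are pooled over directions and
  slices into one matrix before normalization, rather than averaging
  per-direction features: pooling is better conditioned for small masked
  regions. The GLDM is computed from the identical pair set, so it equals
  the `|i−j|` marginal of the GLCM and the two contrast features coincide
  — both identities are tested. Gray-level indices in moment-type features
  are bin numbers 1..G. All entropies are base-2 with `0·log 0 = 0`.
* **NGTDM, GLRLM, GLZSM** are 3D (26-neighbourhood, 13 run directions,
  26-connected zones), since high-order features are meant to couple
  multiplanar voxels; in-plane-only variants are a config switch.
  Run/zone statistics use raw counts normalized at feature level
  (Galloway/Thibault form). Naming maps to canonical definitions:
  run-length "intensity variability" ≡ gray-level nonuniformity; zone
  "intensity nonuniformity" ≡ gray-level nonuniformity over zones; zone
  "intensity variability" ≡ count-weighted variance of zone gray levels.
  NGTDM coarseness uses ε = 1e−12 and is capped at 1/ε.
* **Fractal features.** The box-counting dimension is differential box
  counting on the quantized intensity surface, per slice (dyadic scales
  2–16, least-squares slope), aggregated as mean and SD across slices —
  reporting both mean and SD implies per-slice estimation, and 2D
  per-slice estimation again avoids the anisotropic pitch. Lacunarity is
  the gliding-box statistic `1 + var/mean²` of in-mask box mass (intensity
  mass, not binary; boxes touching the mask boundary excluded), averaged
  over box sizes 2/4/8. The Hurst exponent is estimated from rescaled
  ranges of in-mask row/column profiles with the Anis–Lloyd–Peters
  small-sample correction: the plain R/S slope is biased to ≈0.55–0.6 at
  the profile lengths a tumor ROI offers, and the corrected estimator is
  unbiased at H = 0.5 by construction (verified on white noise).
* **The 46-feature panel** (7 histogram + 4 fractal + 12 GLCM + 3 GLDM +
  4 NGTDM + 7 GLRL + 9 GLZSM) contains every feature the source analysis
  names; the remaining slots are filled from the classical panels of each
  family. This composition is a documented reconstruction, not a verbatim
  published list.

## The synthetic phantom

The generator exists so that parameter recovery can be demonstrated with
known ground truth.

* **Base field**: white Gaussian noise convolved with a Gaussian kernel of
  width `correlation_length` (default 3 mm), affinely rescaled so the
  in-mask mean and SD are exactly the requested values (defaults 350 ± 60
  arbitrary T2 units). This is the simplest stationary field whose
  coarseness is tunable, and GLCM/NGTDM/run/zone features respond
  monotonically to `correlation_length` (tested). Default grid 96×96×10
  at 0.68×0.68×7.8 mm; default tumor an ellipsoid of 20×16×25 mm semi-axes
  (≈50 mm cranio-caudal extent, typical of locally advanced rectal tumors)
  with a band-limited radial boundary perturbation.
* **Test–retest error**: each day's intensities are the base field times
  `(1 + η)` with a global `η ~ N(0, noise_cv²)` and times a local
  `(1 + ε)` field, block-constant on in-plane squares of about one
  correlation length. The global gain term models scanner signal-level
  drift between sessions — the dominant multiplicative test–retest effect
  when no inter-study normalization is applied — and is what makes
  `noise_cv` recoverable: the volume mean of block-local noise averages
  out as `noise_cv/√K` over K blocks, and min–max quantization makes
  bin-unit features blind to any global factor, so without a gain term no
  feature could exhibit the nominal within-subject CV. Noise is drawn
  independently for *both* days, so the standard estimator
  `s_w = √(Σd²/2n)` recovers `noise_cv` exactly in expectation (a
  one-sided day-2-only perturbation would under-recover by √2). Block
  noise survives quantization where per-voxel noise would be absorbed by
  the 32-bin width.
* **Re-delineation jitter**: the day-2 (or second-reader) mask is
  perturbed per slice by a random morphological dilation or erosion of
  radius ≤ `mask_jitter`, mimicking slice-wise manual contouring. At the
  default geometry a 1-voxel jitter changes well under 20% of the mask.
* True biological day-to-day change is assumed nil (consecutive days);
  the generator deliberately exposes `noise_cv` instead of asserting a
  physiologic value.

**What the phantom does not emulate**: MR physics (Rician noise, coil
bias fields), partial-volume effects at the tumor boundary, non-stationary
intratumoral structure (necrotic cores, layered walls), or reader-specific
systematic bias. A feature that is repeatable on the phantom is therefore
not proven repeatable on patients; the phantom establishes that the
*pipeline* is correct (oracle equivalence, parameter recovery) and that
the *relative ordering* of feature classes under boundary jitter — global
features more stable than high-order zone/run features — emerges for
mechanistic reasons, not as an artifact of one dataset.

## Numerical choices and degenerate inputs

* Single-voxel or constant inputs: SD/skewness/kurtosis report 0 with a
  flag; entropy 0; energy 1; GLCM collapses to one diagonal cell;
  NGTDM contrast 0 and coarseness at its cap; lacunarity exactly 1.
* A feature family that errors (e.g. no valid voxel pair in a scattered
  mask) yields `NA` for its features plus a flag, never a silent absence
  and never an aborted study (per-family error isolation).
* Slices too small for 4 dyadic box scales are skipped in FD; profiles
  shorter than 16 voxels are skipped in the Hurst estimate; if nothing
  remains the feature is flagged missing.
* All pipeline stages are deterministic given the phantom- and
  retest-spec seeds; cohort seeds are drawn from a single user seed.

## Problem sizes used in validation

The shipped validation uses phantom cohorts sized for desk-scale runs:
oracle equivalence on ≥100 random 6×6×3 volumes at G ∈ {2,3,4} against
brute-force enumeration; wCV parameter recovery on 200 subjects at the
default geometry (estimate expected in 8–12% for a true 10% CV); the
class-ordering comparison on 24 subjects; and the 14-subject × 2-reader
workflow in `analysis/`. These sizes are the package's validation
defaults and can be scaled up freely.

## Known limitations

* The "medium smoothing filter" scale and the exact published feature
  composition are irrecoverable from the source text; both are explicit,
  logged configuration with documented defaults.
* Whether published run/zone statistics pooled or averaged directions is
  unknown; pooling is this package's declared dialect.
* The wCV divides by the pooled group mean; with complete pairs the
  day-1-mean alternative differs only trivially, but the choice is fixed
  and documented.
* Box-counting FD on small elliptical masks is scale-limited (4 dyadic
  scales); absolute FD values carry estimator bias and should be compared
  within-pipeline only — which is all a repeatability analysis requires.
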