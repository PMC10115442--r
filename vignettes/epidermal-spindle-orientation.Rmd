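---
title: "Methods: quantifying spindle orientation, cortical crescents and clone fates in stratifying epidermis"
author: "epiorient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spindle orientation, cortical crescents and clone fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiorient)
```

## The biological problem

During stratification of the embryonic mouse epidermis, basal keratinocytes
divide either within the plane of the basement membrane (planar, both
daughters stay basal) or perpendicular to it (one daughter is displaced
suprabasally and differentiates). Division orientation is read out as the
angle between the daughter-centroid axis and the basement membrane, binned
as planar (0–30°), oblique (30–60°) or perpendicular (60–90°). Two features
make this system quantitatively interesting:

1. **Cortical polarity.** The spindle-orientation scaffold LGN forms an
   apical cortical crescent in mitotic basal cells; its paralog AGS3 is
   cytoplasmic and antagonizes LGN. Crescent strength and placement are
   measured from fluorescence linescans around the cell perimeter.
2. **Telophase correction.** Many divisions *enter anaphase* at oblique
   angles and re-orient to planar or perpendicular over the following hour.
   The direction of this correction is genotype-dependent: with LGN absent
   obliques resolve almost exclusively to planar, while with AGS3 absent
   they are biased toward perpendicular.

Downstream, short-window lineage tracing classifies two-cell clones as
symmetric divisions (two basal cells), asymmetric divisions (one basal, one
suprabasal) or delamination (a single first-spinous suprabasal cell), and
the thickness of the K10-positive spinous layer indexes tissue-level
differentiation.

This package implements the full measurement chain for these analyses and
pairs it with a seeded synthetic-data generator, so that every stage can be
exercised against known ground truth without any imaging data.

## Crescent quantification from perimeter linescans

A segmented mitotic cell is reduced to its outer contour, ordered
counterclockwise and parameterized by arc length as *perimeter percent*:
position 0 is the basal-most contour point (minimal perpendicular distance
to the basement-membrane line, ties broken toward smaller x), position 50
the apex. The reporter intensity is sampled at 100 evenly spaced perimeter
positions; each sample is the mean over in-cell pixels within a 3-pixel
band half-width around the contour point. The cytoplasmic background —
the mean intensity of interior pixels more than one band-width away from
the cortex — is estimated per cell and subtracted.

From the background-subtracted profile and a signal threshold *t*
(default 20 AU), four scores are computed:

* **maximum F.I.** — the highest value of the profile;
* **cortical coverage** — the extent of the *longest circularly contiguous*
  run of samples strictly above *t*, in perimeter percent; a run of *k*
  samples spans *k − 1* unit intervals, so an isolated supra-threshold
  sample has zero coverage;
* **integrated F.I. (AUC)** — the trapezoid sum of threshold-subtracted
  values over that run, `sum((a_i + a_{i+1}) / 2)`;
* **position** — the circular midpoint of the run, reported modulo 100 so
  basal crescents crossing the 0/100 seam are handled.

Order of operations: the background is subtracted first and the threshold
then applied to the subtracted profile. The two quantities play different
roles — the background is a per-cell offset (≈ 12 AU cytoplasmic signal),
while the threshold is a fixed discriminator of cortical signal from
residual noise — and the AUC is defined on threshold-subtracted values.
The supra-threshold comparison is strict (`>`); at arbitrary-unit scales
equality has measure zero and the choice is immaterial.

Localization is classified from the metrics: `absent` when coverage is 0,
`unpolarized` when coverage exceeds 60% of the perimeter, `apical` when the
crescent position falls in the apical half (25–75), and `basal_polarized`
otherwise (collapsible into `unpolarized` for three-way tables). The
qualitative scoring this emulates was done by eye in the original workflow;
the numeric cutoffs here are this package's own stated rule.

### Properties and caveats

Coverage is monotonically non-increasing in the threshold for *any*
profile, because every supra-threshold run at a higher threshold is nested
in one at a lower threshold. The AUC shares this monotonicity only once the
threshold exceeds the noise ceiling: below it, the "longest run" can switch
from a merged noise run to the crescent as the threshold rises, and the AUC
can jump upward. This is a property of the longest-run definition itself,
not of the implementation; it is also the reason a threshold that
"discriminates signal from noise" is required at all. The test suite checks
coverage monotonicity on arbitrary multi-blob profiles and AUC monotonicity
for thresholds above the noise level.

Minor disjoint supra-threshold islands are ignored by coverage, AUC and
position (the longest run is used — "contiguous portion", singular) but
still count toward the maximum F.I.

## The synthetic cell generator and parameter recovery

`generate_cell_image()` paints a polygonal cell at the cytoplasmic
background level, a 3-pixel cortical band carrying
`background + amplitude * w(s)`, and additive Gaussian noise (clamped at
zero; a Poisson option exists). The window `w` over perimeter distance from
the crescent center is a raised cosine (Hann) of width `coverage` — real
antibody crescents have graded, not sharp, edges — with a rectangular
option retained for oracle tests, where the plateau makes expected linescan
values exact.

Because the Hann window has graded shoulders, the supra-threshold extent at
threshold *t* of a crescent with true width *C* and peak amplitude *a* is
`W = (2C/π)·acos(sqrt(t/a))`, not *C* itself. `recover_crescent_params()`
inverts this relationship (using the profile maximum as the amplitude
estimate) to recover the generative width from the measured metrics; for
the rectangular window the correction factor is 1. Over a seeded grid of
truths (coverage 10–60%, amplitude 30–100 AU, background 12 AU, noise at
amplitude/10), the acceptance suite requires median position error ≤ 2% of
perimeter and median coverage error ≤ 5%; observed values are well inside
(≈ 0.5% and ≈ 2.6%). Residual coverage bias comes from the sampling band
convolving the profile along the perimeter (±3 px ≈ ±1.5% on a 30-px-radius
cell) and from the 1% sampling grid.

## Division angles, ECDFs and the KS test

`division_angle()` returns the acute angle between the daughter-centroid
vector and the basement direction — symmetric under daughter swap and
invariant under global rotation. Binning is left-closed/right-open with the
top bin closed (`[0,30) / [30,60) / [60,90]`); measured angles are
continuous, so the tie rule is documented rather than material. Genotype
distributions are compared with the two-sample Kolmogorov–Smirnov test on
the angle ECDFs; the p-value uses the asymptotic Kolmogorov distribution at
effective size `n_a·n_b/(n_a + n_b)` by default, with an exact small-sample
option. Angles from live imaging are 2-D projection angles; no 3-D
correction is attempted.

## The paired-angle simulator

`simulate_division_angles()` draws the anaphase-onset bin from mixture
weights and the angle *uniformly within the bin* — the onset distribution
is only known to be "randomized", so uniform-within-bin is an explicit
modeling choice. Over the following hour, non-oblique angles persist with
clipped Gaussian jitter (sd 5° by default); each oblique independently
remains oblique with probability `p_stay_oblique` (default 0.05, "rare"),
otherwise corrects to a uniform draw in the perpendicular bin with
probability `p_perp_given_oblique`, else in the planar bin. The correction
is a memoryless Bernoulli event: within-hour kinetics (most correction in
the first 10–15 min) are deliberately not modeled, as no downstream
quantity depends on them.

Genotype presets are conveniences, not claims: `WT` uses equal onset
weights and `p_perp = 0.5`; `AGS3_KO` biases correction to perpendicular
(`p_perp = 0.72`, matching the observed 13/18); `LGN_KO` uses
`w_planar = 0.67` and `p_perp = 0.14` (≈ 12/14 planar correction), with the
remaining onset mass split (0.20, 0.13) between oblique and perpendicular —
the split itself is this package's choice, as only the planar share is
constrained. Note the idealized `WT` onset weights (⅓ each) differ from
observed wild-type onset fractions (≈ 41/26/33); the preset keeps the
symmetric form.

## Telophase-correction analysis

`classify_trajectory()` is a total function on `[0,90]²` with six mutually
exclusive categories; obliques resolve to `corrected_to_planar`,
`corrected_to_perpendicular` or `remained_oblique`, and non-oblique cells
are `stable_*` or `destabilized` (destination bin reported).
`correction_table()` builds the genotype × correction-direction table from
obliques only, excluding — but separately reporting — cells that remain
oblique. Genotypes are compared with the two-sided Fisher exact test
(probability-mass ordering, the common convention; sidedness is not
specified in the source workflow). The chi-square test is provided without
the Yates continuity correction by default, with a flag to enable it.

### Calibration of the Fisher test

The type-I error of the full chain (simulate → classify → tabulate → test)
is checked under a null in which both arms correct obliques to
perpendicular with probability 0.5. The per-arm count was fixed at 300
obliques *before* the check was first run, from an exact computation of the
conditional test's attained size under the hypergeometric null: Fisher's
exact test is conservative by discreteness at small samples (attained size
2.7% at n = 30/arm, 3.5% at 50, 4.0% at 100, ≈ 4.5% at 300 for nominal
5%), so a meaningful 5% ± 1% calibration check requires samples large
enough that discreteness is negligible. At 300/arm and 10,000 replicates
the observed rejection rate is ≈ 5%.

## Clone fates and spinous thickness

`classify_clone()` implements the two-cell rubric: (2 basal, 0 suprabasal)
→ SCD, (1,1) → ACD, (0,1) in the first spinous layer → delamination. All
other compositions are excluded with a stated reason — in particular,
single suprabasal cells *above* the first spinous layer (likely labelled
after differentiation rather than delaminating) and clones larger than two
cells (more than one division in the tracing window, outside the rubric).
Exclusions are never silently dropped; counts reconcile by construction.
`fate_proportions()` reports the SCD:ACD split among division clones and
the ACD:delamination split among differentiative clones, with all counts
emitted so either denominator convention can be applied.

`measure_thickness()` thresholds the K10 channel (Otsu by default on the
observed intensity range; a fixed-AU override exists), and divides the mask
area by the arc length of the basement-membrane polyline — an annotation
input, not inferred from the image. On synthetic sections with a flat
membrane the recovered thickness is exact to half a pixel; with a
sinusoidal membrane, thickness equals painted area / arc length within 2%,
and it is invariant to translation, zero-signal margins and resolution
doubling.

## Numerical conventions

* Images are `[y, x]` matrices, origin top-left, y down; intensities AU ≥ 0.
* Perimeter percent in `[0, 100)` is the canonical 1-D coordinate; all
  circular arithmetic (distances, midpoints) is modulo 100.
* Contours are ordered by positive shoelace area in stored coordinates and
  start at the basal-most vertex (ties → smaller x); the generator and the
  mask-based extractor share this canonicalization, so recovered crescent
  positions are directly comparable to generative ones.
* All simulators take integer seeds and are bit-reproducible; seeding is
  done via `withr::with_seed()` so the caller's RNG stream is untouched.
* CSV tables are comma-separated UTF-8 with headers; floating-point columns
  are written with 17 significant digits so tables round-trip
  bit-identically. TIFF images are 32-bit float with a fixed 65535-AU full
  scale (round-trip exact to ≈ 1e-5 AU).
* A full-perimeter supra-threshold profile has coverage 100 and its AUC
  includes the wrap interval; its "position" is reported at the profile
  maximum, though such profiles are classified `unpolarized` regardless.

## Problem sizes used by the test and acceptance harnesses

Oracle comparisons run on 1,000 random profiles; parameter recovery on a
200-point truth grid; KS and Fisher oracles on samples up to n = 50 and
tables with totals up to 30; convergence checks at n = 10⁴ against exact
99% binomial intervals; the Fisher calibration at 300 obliques/arm ×
10,000 replicates. These sizes were chosen so that sampling error is small
relative to the tolerances being checked while the full suite completes in
a few minutes on one CPU.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analyses assume —
crescents as smooth unimodal cortical bands over uniform background with
stationary Gaussian noise, angle dynamics as independent per-cell Bernoulli
corrections, clones as exact two-cell compositions. Real data violate all
of these in ways the synthetic tests cannot probe: segmentation error in
the E-cadherin boundary, non-stationary background and bleed-through,
embryo-level clustering of angles (cells are pooled here, as in the source
workflow), crescent shapes that are neither Hann nor rectangular, and
clones whose compositions reflect segmentation or merging ambiguity.
Passing the suite therefore certifies the measurement chain and its
statistics, not the biology of any particular image set.
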