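---
title: "Methods: automated footpad-dermatitis scoring and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated footpad-dermatitis scoring and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpdscore)
```

## The scoring model

Footpad dermatitis (FPD) severity is graded by the fraction of the
metatarsal footpad covered by lesioned (discoloured, dark) skin. The
five-level scale splits that area ratio $r$ at 10%, 25% and 50%:
level 0 is an intact foot (no lesion at all), level 1 covers $r < 0.10$,
level 2 $0.10 \le r < 0.25$, level 3 $0.25 \le r < 0.50$, and level 4
$r \ge 0.50$. The class definitions use a strict "<", so the boundaries
are half-open and a ratio of exactly 0.10 falls in level 2. Whether
exactly half the pad is "more than half" is not decidable from the scale's
wording; we assign 0.50 to level 4 so that the partition is total, and the
thresholds (`score_thresholds()`) are user-configurable.

The automated pipeline mirrors the industrial camera systems:

1. **Foot segmentation** (`segment_foot`). The foot contrasts with a blue
   backdrop. Pixels whose HSV hue lies in `background_hue_window` with
   saturation ≥ `min_saturation` are background; the largest 8-connected
   non-background component, holes filled, is the foot. A frame whose
   largest component covers less than 1% of the image (empty slaughter
   hook) raises `fpd_no_foot`; the end-to-end scorer converts such errors
   into QC flags rather than dropping frames, so exclusion counts stay
   auditable.
2. **Footpad localisation** (`locate_footpad`). A morphological opening
   with a disc of radius 2% of the image width removes the thin toe
   strips; the metatarsal pad is then estimated as the largest circle
   inscribed in the opened mask — the argmax of the Euclidean distance
   transform, with the maximal distance as radius. Ties are broken by the
   first maximum in row-major (reading) order. The footpad region is the
   filled circle intersected with the foot mask.
3. **Lesion detection** (`detect_lesions`). Lesions are footpad pixels
   darker than a fraction of the healthy-skin luminance (Rec. 601 luma).
   `AUT1` uses a single factor $k = 0.60$. `AUT2` is "sharper in total but
   more differentiated": candidates split into a dark stratum
   ($< k_\mathrm{dark} = 0.45$), kept subject only to the minimum
   component area, and an intermediate stratum
   ($0.45$–$k_\mathrm{int} = 0.65$) whose components must also pass
   pseudo-lesion filters — elongation (square root of the ratio of the
   second-moment eigenvalues) at most 6 and at most half of the component
   inside a 3-px inner annulus of the footpad circle. Thin dark arcs
   hugging the pad boundary (shadow artifacts) fail these filters and are
   discarded; compact dermatitis lesions pass.
4. **Classification** (`compute_area_ratio`, `classify_score`). The ratio
   of kept lesion area to footpad area, clamped to $[0,1]$, is binned as
   above; level 0 additionally requires that *no* lesion component
   survived (the floor is `min_lesion_px` = 9 px at a 512-px reference
   width, scaled quadratically with resolution).

Per line policy the left foot of each pair is scored, falling back to the
right foot when the left is unscorable (`select_foot`); the experimental
mode scores both.

### The healthy-skin reference

The natural reference for "darker than skin" would be the median footpad
luminance. That reference is self-defeating in exactly the severe class:
once a lesion covers more than half the pad, the median *is* lesion
luminance and the threshold collapses. We therefore use an upper quantile
(default 0.90) of footpad luminance as the healthy-skin estimate; it
coincides with the median's behaviour for small lesions and stays valid up
to ~85% coverage (the generator's feasibility cap). Setting
`reference_quantile = 0.5` restores the plain median.

### The hue window

"Blue background" is the only colour statement available. In the standard
HSV convention (used by `grDevices::rgb2hsv`) blue sits near 220–240°, so
the default window is $[170°, 270°]$ with saturation ≥ 0.25, spanning
cyan-to-blue industrial belts. (A window of 90–150° — sometimes quoted for
"blue" in other conventions — is green in this one and would classify the
backdrop as foot.) Both window and saturation floor are configuration,
not constants.

## Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `background_hue_window` | [170, 270] | degrees | backdrop hue range |
| `min_saturation` | 0.25 | — | backdrop saturation floor |
| `k` | 0.60 | × skin luminance | AUT1 lesion threshold |
| `k_dark`, `k_intermediate` | 0.45, 0.65 | × skin luminance | AUT2 strata |
| `max_elongation` | 6 | — | pseudo-lesion filter |
| `max_boundary_contact` | 0.5 | fraction | pseudo-lesion filter |
| `boundary_annulus_px` | 3 | px | rim width for boundary contact |
| `reference_quantile` | 0.90 | — | healthy-skin luminance estimate |
| `t1, t2, t3` | 0.10, 0.25, 0.50 | ratio | severity boundaries |
| `min_lesion_px` | 9 @ 512 px width | px | smallest counted component |
| `opening_radius_frac` | 0.02 | × image width | toe-suppression disc |

The AUT2 stratification factors and pseudo-lesion filters are declared
stand-ins: the commercial system's heuristics are not public. They are
chosen so the two variants differ in the documented direction — AUT2
detects more of the true alteration (its intermediate stratum reaches
lighter discolouration than AUT1's single threshold) while rejecting
boundary artifacts that AUT1 retains.

## The synthetic generator

`generate_foot()` renders a stylised foot: circular metatarsal pad
(radius 17% of the canvas), three forward toes with three phalange
segments each plus a hind toe, skin/backdrop colours with configurable
Gaussian sensor noise, and a lesion built as a union of 1–4 discs grown
iteratively to the target pad fraction (within ±0.02). Lesions have a
dark core and a lighter rim (luminance 0.30 → 0.55 × skin), as real
discolouration fades toward its margin. The canonical foot is a right
foot; left feet are mirrored.

Presentation skew of angle $\theta$ is modelled as out-of-plane rotation
about the vertical axis: horizontal compression by $\cos\theta$, plus two
documented failure mechanisms that switch on once the foot leaves the
camera's depth-of-focus cone (~8°):

* a **desaturated cast shadow** along the trailing edge, width
  $0.28\,R_0(\sin\theta - \sin 8°)$ — its low saturation makes it
  segment as foot, inflating and shifting the detected pad ("too big or
  slipped out of position");
* **grazing-light washout** of the lesion rim, a luminance lift of
  $0.8(\sin\theta - \sin 8°)$ × skin — progressively pushing rim pixels
  above the detection thresholds ("alteration too small").

The gains are design constants fixed so that both the slightly-skew
(10–25°) and skew (> 25°) classes exhibit the respective failure mode at
audit-visible magnitude, with strictly increasing error rates across the
classes; they encode the reported direction of the angle effect, they are
not fitted to any reported percentage.

`generate_flock()` draws i.i.d. foot specifications: severity marginals
default to the human-score margin of the large validation dataset
(1.67 / 10.96 / 66.02 / 19.32 / 2.03%), straight-presentation probability
0.772 for right feet and 0.424 for left feet (slaughter lines cut the
right foot first, leaving the left hanging skew), and 89.4% of skewed
presentations only slightly skew. All randomness flows from one seed via
deterministic per-foot splitting, so generation is order-independent and
bit-reproducible.

**What a green test establishes — and what it does not.** The generator
emulates geometry, colour contrast, and the two skew failure modes. It
does not render feathers, scald-water artifacts, dirt, motion blur,
specular highlights, or biological shape variation. Pipeline-recovery
results on synthetic feet validate the algorithmic chain (segmentation →
inscribed circle → thresholding → classification) against known truth;
they say nothing about performance on real slaughter-line images, which
is exactly why the published human-vs-machine tables are shipped and
re-analysed instead.

## Agreement statistics

Krippendorff's alpha is computed as $1 - D_o/D_e$ from the coincidence
matrix: every ordered pair of values within a unit contributes
$1/(m_u-1)$. For two complete raters the coincidence matrix is
$M + M^\top$ of the confusion matrix. The ordinal squared difference
between categories $c \le k$ is
$\bigl(\sum_{g=c}^{k} n_g - \tfrac{n_c + n_k}{2}\bigr)^2$ over the
coincidence marginals; nominal is 0/1; interval uses squared numeric
differences. Degenerate data (all values identical, $D_e = 0$) returns
`NA` with a warning rather than a number.

The bootstrap resamples *units* with replacement (equivalently: a
multinomial draw over the distinct per-unit rating patterns, which makes
5,000 replicates cheap) and reports a percentile interval. This is
simpler than the bespoke pair-resampling of the original SAS macro; since
no published interval exists to match, the well-defined scheme is
preferred and seeded for bit-reproducibility.

One-vs-rest performance measures follow the usual 2×2 collapse per level
with standard errors $\sqrt{p(1-p)/m}$. Published validation tables mix
denominator conventions between levels, so the orientation (which axis is
the gold standard) is an explicit argument and both directions are
reported by the CLI; undefined measures (zero denominators) are `NA`,
never coerced to 0 or 1.

## Detection audit

The audit grades detections against ground truth the way human auditors
grade them against their visual judgement. Footpad: excess detected area
outside the true pad, measured in units of the mean toe-segment area —
below 0.1 segment (and relative deficit ≤ 5%) scores 0; under half a
segment scores 1; at least half a segment scores 2; an undersized
detection scores 3. A 2-px dilation of the true pad is tolerated on the
excess side, operationalising the manual scale's explicit allowance for
the pad–toe interspace (without it, the half-pixel quantisation of the
inscribed circle would grade perfect detections as "too big").
Alteration: detected vs true lesion area with a 15% relative tolerance
(0 correct / 1 too big / 3 too small; the manual scale has no level 2
there, and the gap is preserved). Angle: 0 at ≤ 10°, 1 at 10–25°, 2
above — conventions, since the manual audit never defined degrees.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based (row, col), origin top-left, row-major;
  reported circle centres follow this convention.
* The Euclidean distance transform treats everything outside the image
  as background, so border-touching masks stay finite; dilation measures
  distance *to* the mask with no such padding (an empty mask dilates to
  an empty mask).
* Inscribed-circle ties: first maximum in row-major order. Mirroring an
  image can therefore move the centre by a pixel on exact ties, but the
  score is mirror-invariant (tested).
* `classify_score` is total and monotone in the ratio; vectorised with
  recycling.
* Unscorable frames (no foot, vanishing pad, zero pad area) surface as
  condition classes (`fpd_no_foot`, `fpd_footpad_not_found`,
  `fpd_degenerate_footpad`) and as QC flags in batch records.
* PNG I/O is a self-contained baseline codec (8-bit grey/RGB/RGBA, no
  interlacing) over base R's zlib; alpha channels are dropped with a
  warning; TIFF is not supported.
* Configuration files are JSON; the resolved configuration is written
  next to every CLI run's outputs, and re-running from that file is
  bit-identical.

## Known limitations

* The pseudo-lesion filters and AUT2 strata are plausible stand-ins for
  undisclosed commercial heuristics, not a reconstruction.
* The generator's skew model is parametric; it reproduces the direction
  and monotonicity of angle/laterality effects, not their published
  magnitudes, which depend on unavailable real images.
* Severity scoring assumes a single foot per frame; multi-foot frames
  are only handled as unscorable.
* Alpha's bootstrap interval is percentile-based; small-sample coverage
  is approximate.
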