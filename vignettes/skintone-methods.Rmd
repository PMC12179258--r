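---
title: "Automated skin tone assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated skin tone assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintone)
```

## The measurement model

Skin tone varies along a continuum, and the Individual Typology Angle (ITA)
is the standard colorimetric summary of that continuum. For a colour in
CIELAB space,

$$\mathrm{ITA} = \arctan\!\left(\frac{L^* - 50}{b^*}\right)\cdot\frac{180}{\pi},$$

so a colour lighter than mid-gray ($L^* > 50$) with a yellow cast
($b^* > 0$) has a positive angle, and darker skin drives the angle negative.
Typical values run from above 55° (very light) to below −30° (very dark).

The package measures ITA from ordinary sRGB images in three steps:

1. **Colorimetry.** Pixels are converted from 8-bit sRGB to CIELAB under the
   IEC 61966-2-1 transfer function, D65 illuminant and 2° observer — the
   universal conventions for consumer digital images. The conversion is
   delegated to the `farver` colour backend.
2. **Regions.** Only anatomically standardised skin is sampled: the left and
   right lower arms, identified by part labels 19 and 20 of a dense-pose body
   part label map, and the nasal bridge, identified by landmarks 27–30 of the
   68-point facial landmark convention. The nasal bridge is used because it
   is central, rarely occluded, usually free of facial hair and uniformly
   lit. The package consumes the label-map and landmark file formats produced
   by any detector; it never runs the neural models itself.
3. **Aggregation and classification.** Per-pixel ITA values in a region are
   averaged to one regional ITA (`mean_of_itas`, the default). The
   alternative `ita_of_mean_lab` — ITA of the channel-wise mean Lab colour —
   is also implemented, because both conventions circulate in the
   colorimetry literature; they differ on heterogeneous regions since ITA is
   nonlinear in $(L^*, b^*)$. The regional ITA is then classified on every
   configured scale.

### Handling the degenerate denominator

The ITA formula divides by $b^*$, which can vanish (neutral grays) or go
negative (non-physiological for skin, but possible pixel-wise in noisy
shadows). We compute the quadrant-aware two-argument arctangent of
$(L^*-50,\, b^*)$ and clamp to $[-90°, 90°]$: at $b^*=0$ the angle saturates
at $\pm 90°$ by the sign of $L^*-50$, for $b^*<0$ it likewise saturates, and
$L^*=50$ maps to 0° for every nonzero $b^*$. This makes the function total
and continuous on the physically relevant half-plane while agreeing with the
textbook formula wherever $b^* > 0$.

## Scale calibration

The Monk Skin Tone Scale defines ten reference swatches, tone 1 (lightest)
to tone 10 (darkest). We compute the ITA of each swatch and put the boundary
between adjacent tones at the midpoint of their ITA values, yielding nine
descending thresholds:

```{r}
monk <- monk_scale()
round(monk$boundaries, 2)
```

Under the stated colorimetric conventions these reproduce the published
Monk–ITA correlation table to two decimals. Every swatch classifies back to
its own tone by construction, and classification is a non-increasing step
function of ITA. An ITA exactly equal to a boundary is assigned to the
lighter tone whose interval lists it as a lower bound (so 30.61° is tone 5);
exact hits are a measure-zero event, the rule only fixes the tie
deterministically. Serialized tables carry the conventional ±100 outer
sentinels for fidelity, although the arctangent cannot leave ±90°.

For the Fitzpatrick phototypes no palette exists — the scale predates
colorimetry — so the package ships the widely used published ITA bands
(55, 41, 28, 10, −30 for types I–VI) as overridable defaults. Any ordered
palette can be calibrated the same way via `derive_thresholds()`, with a
validation error naming the first adjacent pair whose ITAs fail to decrease.

## Evaluation metrics

Classification quality is scored with tolerance margins on the ordinal class
scale. A prediction is correct under margin $m$ when
$|\hat{k} - k| \le \lfloor m \cdot K\rfloor$: with $m = 0.10$ that is one
tone on the 10-class Monk scale but an exact match on the 6-class
Fitzpatrick scale, and with $m = 0.20$ ("sufficient accuracy") two Monk
tones or one Fitzpatrick type. This class-fraction reading makes the 20%
margin approximately one Fitzpatrick class, which is how the margins are
used in practice; an alternative reading that puts the margin on the ITA
axis itself ($m \times 200°$) is available through the `semantics` argument
of `tolerance_accuracy()`. Balanced accuracy is the mean of per-class
recalls under the same margin, computed only over classes that actually
occur in the gold standard; it is the imbalance-robust companion to plain
accuracy. Plain accuracy can never exceed sufficient accuracy, and the test
suite asserts this ordering across random cohorts.

Two auxiliary statistics support validation studies: Fleiss' kappa for
interrater agreement among human annotators (implemented directly from the
observed-versus-chance-agreement definition, as no installed package
provides it; verified against an independent reference implementation), and
the Mann–Whitney U test for subgroup comparisons (delegated to
`stats::wilcox.test`: exact enumeration when both groups have at most eight
untied observations, tie-corrected normal approximation with continuity
correction otherwise). `subgroup_compare()` feeds the test per-image 0/1
correctness indicators by default; absolute class deviations are the
configurable alternative, since the literature does not pin down the input
variable. When all indicators are identical in both groups the test is
degenerate and is reported as $p = 1$ rather than NaN.

## The synthetic cohort generator

`make_cohort()` renders images with a fixed body layout — two lower-arm
rectangles (part labels 19/20) and a face patch with landmarks 27–30 running
down the nasal bridge — painted in a Monk reference colour plus Gaussian
noise in Lab space. Noise is Gaussian in Lab rather than RGB because Lab is
closer to perceptually uniform, so one sigma means the same visual
perturbation at every tone; the default sigma of 2 Lab units approximates
the within-region texture of smooth, evenly lit skin. An optional
multiplicative $L^*$ ramp emulates uneven illumination, and a configurable
fraction of images omits arm labels to exercise the exclusion path
(emulating clothing or posture making the forearm undetectable).

The gold mean Lab of each image is the reference swatch itself, so the gold
ITA and gold class are exact by construction, and with sigma = 0 the whole
pipeline must recover them perfectly — the end-to-end identity the
acceptance tests check at $n = 100$. The generator emulates a standardized
AI-generated photo cohort: uniform pose, known layout, no occlusion,
erythema, tattoos, hair or makeup. Passing tests therefore demonstrate the
correctness of the colorimetric and statistical machinery, not robustness to
the segmentation errors, lighting extremes and skin pathology of clinical
photographs; performance on clinical data must be validated against human
annotations of that data.

## Numerical and design choices

- **8-bit quantisation.** Synthetic colours survive a Lab → sRGB → Lab round
  trip exactly for the bundled swatches; arbitrary colours may shift by up
  to one 8-bit step per channel, which is why pixel-level identities in the
  tests allow sub-degree slack while swatch-level identities are exact.
- **Gamut clipping.** The Lab → sRGB converter saturates at the gamut
  boundary, so `lab_to_srgb()` detects clipping by a round-trip error larger
  than one Lab unit and reports the clipped fraction; `make_patch()` warns
  when more than 1% of channels clip.
- **Exclusion policy.** Regions with no detected pixels and arm samples
  below `min_arm_pixels` (default 50 — the literature excludes undetectable
  forearms without naming a threshold) are flagged and skipped, never
  silently dropped; curated exclusions (e.g. human-identified erythema,
  which an ITA pipeline cannot judge) enter via `run_config(exclude_ids=)`.
- **Determinism.** All generators take a mandatory seed and restore the
  caller's RNG state; batch runs are bit-reproducible from (manifest,
  config, seed).
- **Problem sizes.** The test suite and the acceptance script run cohorts of
  40–150 images at 96 × 96 pixels, which exercises every code path with
  hundreds of region samples while keeping a full run within seconds on one
  CPU.

## Known limitations

- Image decoding covers PNG; other formats must be decoded by the caller
  into plain `h × w × 3` arrays (all public functions accept these).
- One person per image is assumed; overlapping detections from multiple
  people are out of scope, as is pose normalisation.
- ITA summarises pigmentation only. Scales whose definition includes
  non-colorimetric traits (the Fitzpatrick types were designed around UV
  response, hair and eye colour) map poorly onto any pure colour measure,
  and the package's Fitzpatrick output should be read with that caveat.
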