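---
title: "Micro-CT volumetry of the mouse tarsus: method, phantom design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-CT volumetry of the mouse tarsus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarsalct)
```

## The measurement

In mouse models of rheumatoid arthritis, disease activity in the hind paw has
two structural signatures: erosion of the small tarsal bones and swelling of
the surrounding soft tissue. Both can be read from a single in vivo micro-CT
acquisition. `tarsalct` implements that quantification:

1. **Reorientation.** The reconstructed volume is binarised at the bone
   threshold and the second-moment (inertia) principal axes of the
   above-threshold voxel cloud are computed. The volume is rotated by the
   minimal rotation taking the first principal axis to +z, so the
   metatarsal/tarsal column is vertical and slices are orthogonal
   cross-sections. Intensities are resampled trilinearly onto a grid padded
   to the rotated bounding box; a detected tilt below 0.5 degrees skips
   resampling entirely so already-aligned volumes pass through bit-identical.
2. **VOI.** A slab of 100 consecutive slices (1.8 mm at the 18 um isotropic
   voxel size) starting at the first slice of the most proximal tarsal body.
   On synthetic phantoms this landmark slice is detected as the first slice
   whose above-threshold count rises from zero; on real anatomy the start
   slice is observer-defined and must be supplied explicitly.
3. **Bone.** Every voxel with raw intensity strictly greater than 3500 AU.
   No smoothing is applied to the bone channel.
4. **Soft tissue.** The intensities are smoothed with an isotropic Gaussian
   of SD 0.1 mm (converted to voxels per axis, kernel truncated at 4 SD,
   edges replicated), windowed inclusively to [-300, 1500] AU, and the bone
   mask is subtracted so the compartments are disjoint (bone is treated as
   extraneous tissue).
5. **Volumes.** Bone volume (BV) and soft-tissue volume (STV) are voxel
   counts times the voxel volume, in mm^3, over the same VOI.

```{r quantify-example, eval = FALSE}
spec <- default_tarsal_spec()
phantom <- make_phantom(spec, seed = 1)
result <- quantify(phantom$volume)
result
```

## The phantom: a stated world with exact ground truth

No raw scans accompany the study this package models, so every claim is
validated against synthetic phantoms whose ground truth is known exactly.
The default tarsal phantom is five ellipsoidal bone bodies (semi-axes
0.28 x 0.25 x 0.15 mm) stacked along z with 0.09 mm joint gaps, spanning
1.85 mm axially — slightly more than the 1.8 mm VOI, as in the real anatomy
where the tarsal column continues distally — inside an ellipsoidal
soft-tissue envelope (semi-axes 1.70 x 1.60 x 1.70 mm, giving an STV near
the published untreated-group values), on a 200 x 194 x 200 grid of 18 um
voxels. Ground-truth masks are the noiseless voxel-centre rasterisations;
recorded volumes are exact voxel counts.

**Intensities are chosen so the fixed thresholds are half-maximum.** The
segmentation thresholds are fixed by the analysis protocol (3500 AU;
[-300, 1500] AU). Threshold volumetry is unbiased under partial-volume
averaging, interpolation, or smoothing only when the threshold sits at the
half-maximum of the edge it cuts: a threshold at fraction q of the edge
moves the recovered surface by about (q - 0.5) of the edge width, and the
volume error scales with the surface area. The phantom therefore uses air
-900 AU, soft tissue 300 AU and bone 6700 AU: the bone threshold 3500 is
exactly (300 + 6700) / 2 and the soft window's lower bound -300 is exactly
(-900 + 300) / 2. With bone at, say, 5000 AU the 3500 AU threshold would sit
at 68% of the soft-to-bone edge and any reorientation (trilinear resampling)
would systematically erode the recovered bone volume by 3-4% for bones of
this size — an artefact of the phantom, not of the method. Default noise is
additive Gaussian with SD 50 AU, far from every threshold (the bone margin
is 64 SDs), matching the cleanly separated histogram modes of real
reconstructions at this resolution.

**Disease effects.** `apply_disease()` models erosion as spherical pits
(radius 0.035 mm) carved at seeded random positions on the bone surface
until the ground-truth bone volume has dropped by the requested fraction;
with a fixed seed a larger fraction carves a superset of pits, so erosion is
monotone by construction. Swelling rescales the envelope semi-axes so the
soft volume (envelope minus bone, computed analytically) grows by the
requested factor; if the swollen envelope would escape the grid, the grid is
enlarged symmetrically, which changes no physical volume.

**What the phantom does not emulate.** Reconstruction physics (beam
hardening, streaks, the Hann/Shepp-Logan filter response), anatomically
shaped bones, contact between bones, motion, and intensity calibration
drift. A green phantom-recovery test therefore establishes that the
geometry, thresholds, filtering and bookkeeping of the implementation are
correct — not that the thresholds themselves are right for any particular
scanner's AU scale; that step remains the histogram inspection the protocol
prescribes (`compute_histogram()` plus `suggest_threshold()`, which runs
Otsu's criterion on the soft/bone part of the histogram and is advisory
only).

## The cohort simulator

`cohort_design()` encodes the study layout: groups of 10 naive, 6 untreated
and 6 prednisolone-treated animals measured on days 0, 7, 14 and 21. Each
animal's trajectory for caliper thickness, BV and STV is the group/day mean
plus a Gaussian animal-level random intercept plus Gaussian residual noise —
the minimal structure that makes a mixed-effects analysis meaningful.
Day-21 means are the published group means (caliper 2.6 vs 2.08 mm, BV 1.4
vs 2.1 mm^3, STV 19.5 vs 10.7 mm^3, untreated vs treated); earlier days
follow the published trajectory shapes (disease peaks at day 7, treatment
from day 7) but their exact means and all SDs for intermediate days are not
printed anywhere, so the defaults interpolate and are synthetic. The
animal-level and residual SDs are set equal, summing to roughly the printed
day-21 spreads. Terminal histopathology scores (0-4) are drawn per group
from ordinal distributions massed at 0 (naive), centred at 3 (untreated)
and at 1-2 (treated), reproducing the published ordering without inventing
unprinted means.

Ex vivo pairs invert the published agreement line in_vivo = 0.7 ex_vivo +
0.4: the simulator draws ex_vivo = (in_vivo - 0.4) / 0.7 plus Gaussian noise
(default SD 0.05 mm^3) so that regressing in vivo on ex vivo — the study's
orientation — recovers the line, exactly in the noise-free limit. Because
the noise sits on the predictor, the fitted slope carries a small
attenuation bias (about 0.004 at the default spread), well inside the
recovery tolerance.

## Statistical layer: choices where the protocol is silent

- **Two-way ANOVA** (caliper): fixed effects group, day and group x day on
  the change from the day-0 baseline — the study plots change in paw
  thickness, and whether raw or change scores were tested is not stated;
  both are supported, change is the default for caliper only.
- **Mixed effects** (in vivo BV/STV): the same fixed effects plus a random
  intercept per animal, fitted by REML with `lme4`. The original analysis
  ran in a commercial package whose covariance structure and degrees of
  freedom are unspecified; contrasts here use containment df (animals minus
  groups), which is exact for balanced between-group contrasts and slightly
  conservative otherwise. Satterthwaite approximations are not available in
  this dependency set. Under the null design the day-21 contrast rejects at
  0.04-0.05 at nominal 0.05 (500 replicates), inside the calibration band.
- **Per-day contrasts** compare each group to the untreated control with
  Bonferroni adjustment over the comparisons at that day, mirroring the
  study's comparisons; one-way ANOVA on terminal ex vivo BV uses the pooled
  error term and Bonferroni-adjusted pairwise contrasts.
- **Ordinal scores**: Kruskal-Wallis with midranks and tie correction
  (scores 0-4 are heavily tied), then Dunn's z against the untreated group,
  Bonferroni over the comparisons performed. Note that the standard Dunn
  statistic pools the rank variance over *all* groups, so adding a group
  changes existing z values slightly; only the comparison count enters the
  adjustment. A fully tied sample is reported as H = 0, p = 1, not as an
  error.
- **Unbalanced cells** (the naive group's n changes across days in the
  study) are handled by unbalanced fitting, never imputation.

## Numerical choices and degenerate inputs

- Rasterisation is by voxel-centre membership — simple, and exactly
  checkable by a brute-force point-in-ellipsoid loop.
- Reorientation requires at least 10 foreground voxels (degenerate-input
  error) and a first-to-second principal moment ratio of at least 1.05
  (ambiguous-axis error for near-spherical foreground, e.g. a uniform
  ball). The axis sign is fixed by pointing the principal axis toward +z,
  which recovers the inverse of any applied tilt below 90 degrees; the
  in-plane spin about z is deliberately left free, since slab VOIs and
  volumes are invariant to it.
- Intensities are stored as signed 16-bit integers in both NIfTI-1 and TIFF
  output: the AU range used here (-900 to ~6700 plus noise) fits with a
  wide margin and it fixes round-trip semantics exactly. NIfTI spacing is
  authoritative; TIFF stacks carry no reliable spacing and demand an
  explicit value.
- Masks are never resampled; segmentation always runs after any resampling,
  avoiding mask aliasing.
- The full-slice slab VOI is the default in-plane footprint. The terminal
  ex vivo protocol describes a manually drawn cylinder instead; which
  footprint the in vivo analysis used is not resolvable from the protocol
  text, and the slab is the reproducible choice. Volumes enter the
  agreement regression identically either way.
- Run configurations are JSON (this environment provides no YAML parser);
  a single global seed is expanded into fixed per-stage offsets so stages
  rerun in isolation reproduce their outputs.

## Known limitations

- The smoothed soft-tissue window inherently misclassifies a shell around
  each tissue interface: near bone, smoothing pulls intensities above
  1500 AU out to roughly 0.9 sigma (0.09 mm) from the bone surface, and
  convex interfaces shift by about sigma^2 times the mean curvature. The
  resulting STV deficit scales with interface area over compartment volume
  — about 2% on the default phantom, but larger for small envelopes (the
  reduced test phantom runs at ~6%) and, by the same argument, for any real
  paw with extensive bone surface. STV is therefore best read as a
  longitudinal, internally controlled measure, which is how the study uses
  it.
- Landmark auto-detection is defined for synthetic phantoms only; real
  data require the anatomist's start slice.
- The mixed-model p-values reproduce a reasonable df convention, not the
  exact output of the original commercial software; late-decimal
  differences on real data are expected.
- Tilts at or beyond 90 degrees cannot be disambiguated from their
  mirror by the second-moment method.
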