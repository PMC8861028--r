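# tarsalct

In vivo micro-CT volumetry of the mouse tarsal region, for preclinical
arthritis studies.

In rodent models of rheumatoid arthritis (e.g. collagen-induced arthritis),
disease activity shows up as erosion of the small tarsal bones and swelling
of the surrounding soft tissue. Both can be quantified longitudinally from a
single in vivo µCT acquisition, replacing subjective caliper scoring and
reducing animal numbers. `tarsalct` implements the quantification and its
statistical layer for R users who run such studies:

- **Per-image pipeline** — reorient the volume so the metatarsal/tarsal axis
  lies along z (principal-axis analysis, trilinear resampling); extract a
  100-slice (1.8 mm at 18 µm voxels) volume of interest anchored at the most
  proximal tarsal body; segment bone as raw intensity > 3500 AU; segment
  soft tissue as the −300…1500 AU window after Gaussian smoothing with
  SD 0.1 mm, excluding bone; report BV and STV in mm³ as voxel counts ×
  voxel volume:

  BV = |{v : I(v) > 3500}| · h³,  STV = |{v : −300 ≤ (G₀.₁ ∗ I)(v) ≤ 1500}
  \ bone| · h³

- **Synthetic phantoms with exact ground truth** — stacks of ellipsoidal
  bones inside a soft envelope, seeded noise, rigid misalignment, erosion
  pits, swelling; every downstream claim is testable without scanner data.
- **Cohort statistics** — mixed-effects (random intercept per animal) and
  two-way ANOVA group-by-day contrasts, one-way ANOVA on terminal ex vivo
  BV, Kruskal–Wallis + Dunn tests on ordinal (0–4) histopathology scores,
  and the in vivo ~ ex vivo agreement regression (study line:
  y = 0.7x + 0.4, R² = 0.98).
- **I/O** — NIfTI-1 (`.nii`, `.nii.gz`) and multi-page 16-bit TIFF volumes
  (TIFF requires explicit voxel spacing), long-format cohort CSVs.

## Worked example

```r
library(tarsalct)

spec <- default_tarsal_spec()          # 5 tarsal-like bones, soft envelope, 18 µm grid
phantom <- make_phantom(spec, seed = 1)
result <- quantify(phantom$volume)     # reorient -> VOI -> segment -> volumes
result
#> <segmentation_result> BV 0.2176 mm^3, STV 13.4478 mm^3 (VOI slices 50-149, tilt 0.00 deg)

design <- cohort_design(n_naive = 9)   # 21 animals: 9 naive, 6 untreated, 6 prednisolone
cohort <- simulate_cohort(design, seed = 1)
pairs  <- simulate_ex_vivo_pairs(cohort, link = design$ex_vivo_link, seed = 2)
fit_agreement_regression(pairs)
#> <agreement_fit> in_vivo = 0.6950 * ex_vivo + 0.4020, R^2 = 0.9936 (n = 21)

res <- compare_groups_longitudinal(cohort, "bv_mm3", method = "mixed_effects")
res[res$day == 21, c("contrast", "mean1", "mean2", "p_adjusted")]
#>                   contrast    mean1    mean2   p_adjusted
#>         naive vs untreated 2.507794 1.393681 1.369179e-14
#>  prednisolone vs untreated 2.122555 1.393681 9.055193e-11
```

The quantified BV equals the phantom's ground truth exactly (the noise SD of
50 AU is 64 SDs below the bone threshold), the STV sits ~2% below ground
truth because the smoothed window misclassifies a thin shell at tissue
interfaces (see the vignette), the regression recovers the generating
agreement line, and the day-21 contrasts recover the designed treatment
effect: prednisolone-treated animals hold ~2.1 mm³ of tarsal bone versus
~1.4 mm³ untreated.

A thin command-line wrapper with `phantom`, `quantify`, `cohort`, `stats`,
`agree`, `validate` and `run-all` subcommands is installed at
`inst/cli/tarsalct`; `run_pipeline()` / `run-all` executes the whole chain
from one JSON config and writes every intermediate plus a reproducible
manifest.

## Self-validation

`run_validation_suite()` checks the pipeline against known ground truth
(phantom recovery, erosion linearity, rotation robustness, regression
recovery, type-I calibration) and returns a machine-readable pass/fail
report.

`scripts/acceptance.R` re-runs the main computation from scratch against the
installed package — renders the default phantom, quantifies it against
ground truth, simulates the 21-animal cohort, fits the agreement regression,
and runs the day-21 contrasts — logging the headline numbers to stderr:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The vignette (`vignettes/tarsal-volumetrics.Rmd`) documents the method, the
phantom's design rationale (including why the phantom's tissue intensities
place the fixed thresholds at edge half-maximum), the statistical
conventions, and known limitations.
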