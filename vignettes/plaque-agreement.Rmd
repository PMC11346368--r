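---
title: "Quantifying coronary plaque on CT and IVUS phantoms: models, thresholds and agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying coronary plaque on CT and IVUS phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

plaquekit implements the full measurement chain used when a CT-based
coronary plaque analysis is validated against intravascular ultrasound
(IVUS): cross-sectional quantification along a vessel centerline,
Hounsfield-unit (HU) plaque characterization with an adaptive calcium
threshold, Simpson's-rule volumetrics, emulation and quantification of the
paired IVUS pullback, anchored 1D co-registration of the two modalities,
and the per-lesion agreement battery (Pearson correlation with regression,
intraclass correlation, Bland–Altman limits of agreement, paired *t*,
ROC analysis for low-attenuation-plaque presence).  Because patient imaging
cannot be redistributed, the package ships a digital vessel-phantom
generator with exact analytic ground truth, so every stage of the chain is
verifiable end to end.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
experiments demonstrate.

## The CT-side measurement model

A vessel is quantified along its centerline.  At each arclength station
(default step 0.5 mm) a plane orthogonal to the local tangent is sampled on
a square grid (default pitch 0.1 mm).  Membership is decided by the
segmentation label at the sample center — no anti-aliasing — so lumen area
is the count of lumen-labeled samples times the pitch squared, vessel area
counts lumen-or-wall samples, and plaque area is vessel minus lumen by
construction.  The label-at-center rule makes the per-station identity
`plaque = vessel - lumen` exact, which in turn makes `lumen + plaque =
vessel` exact after integration (Simpson's rule is linear).

Wall samples carry the trilinearly interpolated HU value of the image and
are classified into plaque components with half-open windows:

* excluded: HU < −30 (below the low-attenuation window; tallied separately,
  never part of total plaque volume),
* low-attenuation plaque (LAP): −30 ≤ HU < 30,
* non-calcified plaque (NCP window): 30 ≤ HU < CP threshold,
* calcified plaque (CP): HU ≥ CP threshold.

The CP threshold adapts to lumen contrast: `max(350, mean + SD)` of the
lumen HU samples, with the sample SD on n−1.  The branch matters on both
sides: well-enhanced scans push the threshold above 350 HU so bright lumen
is not mistaken for calcium; poorly enhanced scans fall back to the 350 HU
floor.  Lumen samples are taken per vessel from the lumen mask after a
one-voxel 6-neighbor erosion, which suppresses partial-volume contamination
at the lumen boundary; per-vessel (rather than per-slice or per-scan)
adaptation is a documented package choice.

Half-open windows make the partition exact: at every station CP + NCP +
LAP + excluded areas equal plaque area to the last bit.  Total plaque
volume (TPV) is the sum of the classified component volumes; *reported*
NCP is TPV − CP, so LAP is a sub-component of NCP and the CP/NCP
percentages of TPV sum to 100.

### Simpson volumetrics

Volumes integrate per-station areas with composite Simpson's rule on
uniform stations.  When the interval count is odd the final three intervals
use the Simpson 3/8 rule, keeping the composite rule exact for quadratic
and cubic profiles at any station count.  Sub-interval volumes (lesions)
restrict the profile, resample it to a uniform grid by linear
interpolation, and integrate the same way; integration is exactly additive
when a split lands on a station with an even interval count on each side.
Non-uniform input is resampled before integration — composite Simpson
requires uniform nodes.

## The IVUS-side model

IVUS quantification consumes the per-millimetre pullback table a core
laboratory produces: lumen and vessel (external elastic membrane) areas at
1 mm stations, plus qualitative calcified and attenuated arcs in degrees.
Plaque burden is `100 (vessel - lumen) / vessel`.  A lesion is a maximal
run of consecutive stations with burden ≥ 40% spanning at least 2 mm.
Stations are point measurements, so a run of *k* stations spans (k−1) mm:
**three** consecutive qualifying stations are needed at 1 mm spacing.  This
discrete-length convention changes lesion counts and is applied uniformly;
runs are strictly contiguous (no gap bridging — no merge rule is defined in
the field), and lesion boundaries sit on the first/last qualifying station
rather than extending a half-spacing outward.

Ultrasound cannot see behind calcium or attenuated plaque, so qualitative
component areas use the full-thickness assumption: a component occupying an
arc of θ degrees is assigned `(θ/360)(vessel − lumen)` of the wall.  This
is the standard trade-off of IVUS tissue reading and tends to overestimate
calcified/attenuated volumes; it is applied as stated, and the emulated
pullbacks copy deposit sector widths into the arcs so the assumption is
exact on phantoms.

## Co-registration

The two modalities are aligned through their 1D lumen-area profiles.
Anchor landmarks — pullback start, bifurcations in order, pullback end —
must match one-to-one; the base warp is piecewise-linear through the anchor
pairs and is the base contract (refinement is an optional layer, off by
default in `build_warp()`, on by default in `run_study()`).

With refinement, each inter-anchor segment is subdivided by knots every
~2.5 mm chosen by a monotone dynamic program.  Candidate shifts are bounded
to ±20% of the segment length; each candidate is scored by matching a 5 mm
window of the globally z-scored IVUS lumen profile against the CCTA profile
(resampled at 0.25 mm; the CCTA window is stretched by the anchored segment
slope so both windows cover corresponding anatomy).  The window score is
the negative mean squared difference of the z-scored profiles.  A
per-window-normalized cross-correlation was evaluated first and rejected:
on smooth, ramp-like lumen profiles two monotone ramps correlate near 1 at
any shift, so NCC cannot localize; the amplitude-sensitive squared
difference can, and measured mean lesion-boundary mapping error dropped
from ≈0.6 mm to ≈0.3 mm under the default warp family.  A small quadratic
shift penalty (λ = 0.01 mm⁻²) pulls featureless stretches back to the
anchored linear map, and the DP's minimum-slope margin (0.2) guarantees the
refined map is strictly increasing and anchor-exact — knots can never cross
an anchor.

## Agreement statistics

Per-lesion paired volumes (TPV, CP, NCP, LAP, lumen, vessel) are compared
with:

* Pearson r with a two-sided p, and the OLS regression of the CT value on
  the IVUS value — IVUS on the abscissa, the reference-standard convention
  for method-comparison scatter plots (the regression orientation is a
  documented choice);
* Bland–Altman: differences are CT − IVUS (so CT underestimation is a
  negative bias), limits of agreement are mean ± 1.96 × SD (sample SD,
  n−1), exactly;
* ICC(A,1): two-way, absolute agreement, single measure, from the
  mean-squares decomposition
  `(MSR − MSE) / (MSR + (k−1) MSE + k/n (MSC − MSE))` with k = 2.  It is
  implemented directly (no reliability package is a dependency) and tested
  against an independent aov-based oracle.  Absolute agreement penalizes
  systematic offsets that Pearson r ignores;
* paired *t* on the differences with n−1 degrees of freedom;
* LAP presence: lesions are labeled positive when IVUS LAP volume meets a
  threshold (2, 4, 8 mm³), and an ROC curve is swept over the CT LAP
  volume.  Tied scores are grouped into single ROC steps and AUC is the
  trapezoid area, which equals the Mann–Whitney probability with half
  credit for ties (property-tested against brute force).  Because no
  single operating cutoff is canonical, two rows are reported per
  threshold: the Youden-optimal cutoff (reported for audit) and the fixed
  rule "CT LAP > 0".  No multiple-testing correction is applied; α = 0.05
  two-sided throughout.

## The phantom generator

A phantom is an analytic vessel: straight or helical centerline, baseline
lumen radius with raised-cosine stenoses, baseline outer-wall radius with
raised-cosine bulges, and plaque deposits occupying axial-by-angular
sectors of the wall at full thickness.  Deposits must be pairwise disjoint
— the wall outside any deposit is NCP tissue — so component areas partition
the wall exactly and the ground truth needs no precedence rules.  Ground
truth (per-station areas, component volumes over any interval) comes from
the closed-form radius profiles via dense fixed-step quadrature (0.01 mm);
it never touches the voxel grid, so refining the voxel size changes ground
truth by exactly zero.

Rendering voxelizes the geometry with 3× supersampling per axis (27
sub-samples per voxel, averaged to occupancy — the partial-volume model;
3 per axis is a fixed accuracy/cost trade-off), draws one HU value per
region per voxel from the region's distribution, mixes them by occupancy,
convolves with a Gaussian point-spread function and adds voxel noise.  The
voxel grid is snapped to integer voxel multiples so the vessel axis passes
through voxel centers; this avoids a half-voxel quantization bias in
measured areas (≈3% on a 1.5 mm lumen otherwise).  Labels are taken from
the analytic geometry at voxel centers and are noise-free, standing in for
a perfect segmentation: the package validates the *measurement chain*, not
a segmentation algorithm.

Default HU distributions — lumen N(450, 60), CP N(700, 100) truncated below
at the nominal adaptive threshold (so rendered calcium stays in the CP
window by construction), NCP N(80, 30), LAP N(0, 15), background
N(−50, 20) — were chosen once so that default phantoms exercise all three
HU windows and both branches of `max(350, mean + SD)`; all are overridable.
Imaging defaults (0.4 mm isotropic voxels, 0.3 mm PSF sigma, 15 HU noise)
sit in the typical range of contrast-enhanced cardiac CT reconstructions.

The emulated pullback warps arclength into pullback distance with a
monotone piecewise-cubic (Hyman) spline through random knots, per-segment
slopes drawn from [0.8, 1.25] — mimicking pullback-speed variation while
staying invertible.  Station areas are analytic truth at the warp-inverse
position times multiplicative lognormal noise with unit mean (areas are
positive; a 5% coefficient of variation is the default measurement noise).
Vessel area is floored at lumen area after noise.  Note a consequence faced
by any real pullback too: volumes integrated on the pullback axis inherit
the local pullback-speed factor, so IVUS lesion volumes carry a
per-case ±10–25% length distortion that the co-registered CT volumes do
not — this, not the area noise, dominates CT–IVUS scatter in the synthetic
study.

Cohort sampling (`sample_cohort()`) draws one focal lesion per vessel:
concentric stenosis plus outward bulge, optional CP and LAP deposits in
disjoint sectors (presence probabilities 0.6 and 0.5), two bifurcation
landmarks, and a random warp.  Size ranges are calibrated so per-lesion
total plaque volumes show the dispersion typical of clinical IVUS lesion
cohorts — median near 155 mm³, quartiles around 79 and 255 mm³, with a long
tail of large lesions — because agreement statistics are only meaningful at
a realistic between-lesion spread.

What the generator does **not** emulate: cardiac motion, beam hardening,
scanner-specific reconstruction kernels, ultrasound speckle or frame-level
echo appearance, and imperfect lumen/wall segmentation.  Passing phantom
tests therefore demonstrates the correctness of the quantification,
co-registration and statistics — not robustness to segmentation error or
acquisition artefacts on patient data.

## Numerical choices and degenerate inputs

* Arclength runs proximal→distal, zero at the ostium; intervals are
  closed-open `[start, end)`.
* All randomness flows from one explicit seed through a private RNG stream
  (`.Random.seed` is saved and restored), so identical spec + seed means
  bit-identical output and no global state leaks.
* Simpson integration refuses fewer than 3 stations or negative areas;
  zero-length intervals, lesions outside the pullback, mismatched or
  out-of-order anchors, non-monotone warps, lumen > vessel, and arcs
  summing past 360° all raise immediate errors naming the offending
  station or segment.
* Stations whose sampling plane exits the image are dropped and counted
  (`n_excluded` attribute), mirroring how a core lab excludes
  non-analyzable frames.
* Zero-TPV vessels report undefined (NA) component percentages rather
  than dividing by zero.
* ROC ties are grouped; the Youden cutoff reports the achieved operating
  point alongside the full confusion counts for audit.

## Known limitations

* **LAP partial volume.**  HU-window classification erodes low-attenuation
  tissue adjacent to the contrast-enhanced lumen: across a 0→450 HU
  interface the interpolated value leaves the [−30, 30) window about 93%
  of the way to the boundary, so a voxel-wide rim of true LAP reads as NCP.
  On a clean 2 mm-thick deposit this measured ≈ −13% at 0.25 mm voxels,
  improving roughly linearly with voxel size; CP and TPV recover within a
  few percent at the same resolution.  This asymmetry is intrinsic to
  HU-threshold characterization and is the synthetic counterpart of LAP
  being the weakest-agreeing component clinically.
* The IVUS emulation is a table-level model (areas and arcs), not an
  image-level one; operator variability in tracing is summarized by a
  single lognormal CV.
* Co-registration refinement needs profile structure; on featureless
  segments it falls back to the anchored linear map, and accuracy there is
  bounded by anchor spacing.
* The per-vessel adaptive threshold is one defensible choice; per-slice
  adaptation would interact differently with slow contrast gradients.

## Problem sizes used by the test-suite experiments

The packaged experiments run at desk scale, chosen as the smallest sizes at
which the statistics stabilize: a 50-lesion cohort for the end-to-end
agreement study (Pearson r for TPV ≈ 0.98, |bias| ≈ 1–3% of mean true TPV
across seeds), 100 cases for warp recovery (mean boundary error ≈ 0.3 mm),
1000 random burden profiles for the lesion-detection equivalence property,
and a 0.2 mm-voxel annular tube for analytic recovery (TPV within 0.5% of
the closed form).

```{r, eval = FALSE}
library(plaquekit)
res <- run_study(study_config(n_lesions = 50, seed = 1))
tidy(res)                      # per-measure agreement statistics
glance(res)                    # one-row summary
plot_correlation(res, "tpv")   # scatter with regression
plot_bland_altman(res, "tpv")  # bias and limits of agreement
plot_lap_roc(res)              # ROC per IVUS LAP threshold
```
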