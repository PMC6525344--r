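---
title: "Methods: ONL deformation morphometry from OCT segmentation surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ONL deformation morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onlshape)
```

## The measurement problem

An epiretinal membrane (ERM) contracts tangentially on the retinal
surface and drags the underlying layers with it. Metamorphopsia — the
perceived distortion this causes — is directional: the MCHART instrument
scores it separately for horizontal (MH) and vertical (MV) dot lines, in
viewing-angle degrees from 0.2° to 2° (0 means no detectable
distortion). The scientific question this package operationalizes is
whether the *direction and anisotropy* of outer-nuclear-layer (ONL)
deformation, measured from volumetric OCT, predicts the *direction* of
metamorphopsia as captured by the ratio MH/MV.

The pipeline consumes already-segmented boundary surfaces: the ONL/OPL
boundary and the RPE line, each a depth (axial pixel) per A-scan on a
49 B-scan × 512 A-scan grid covering a 20° (6.7 × 6.7 mm) macular field
with 400-pixel axial depth. Segmentation itself (and its manual
correction) is upstream and out of scope; crossing surfaces (RPE above
the ONL boundary anywhere) are rejected as a hard error rather than
repaired.

## From surfaces to the height image

ONL height is the per-A-scan distance `rpe_depth − onl_depth`, in axial
pixels. The 49 B-scan rows are upsampled to 512 by exact two-point
linear interpolation (`interpolate_rows()`); interpolation runs on pixel
heights, and micrometre values are a pure scalar multiply afterwards, so
histogram quantization is not disturbed by the unit conversion. The
axial scale defaults to 3.87 µm/px. The nominal geometry (1.5 mm over
400 px) would give 3.75 µm/px; the explicitly documented acquisition
constant is preferred, and the scale is a plain argument for instruments
that differ.

The *reference plane* is the modal height: heights are binned at 1 px
width (bins centred on integer multiples of the width; both the width
and whether zero-height pixels are included are configurable), and the
centre of the highest-count bin is taken, ties resolved to the lower bin
— the reference plane anchors the *base* of the layer, so the
conservative choice is downward. The per-subject scalar "ONL height" is,
by default, this reference level in micrometres: a base/background
thickness statistic of the layer rather than its foveal peak, which is
the reading consistent with clinical values near 54 µm for healthy eyes
(the foveal maximum of an ONL-to-RPE map is several times larger).
`mean` and `max` modes are selectable where a different convention is
wanted.

## Selecting the ONL-Base

The reference-plane iso-contour itself is too ragged to characterize
morphologically — the B-scan direction is 10× sparser than the A-scan
direction, and near the modal level the superlevel set percolates
through background noise. The analysis region (ONL-Base) is therefore
the *lowest* admissible iso-contour at or above the reference level,
scanned upward in 1-px steps (up to 95 % of the peak height). At each
candidate level the sub-pixel iso-contour is traced by linear
interpolation along grid edges (marching-squares style via
`grDevices::contourLines`); pixel-boundary tracing is deliberately
avoided because staircase boundaries bias any perimeter-based statistic.
Among the traced loops, the one enclosing the global height maximum (the
foveal peak — the only landmark available from the height map alone) is
kept, with the largest enclosing loop taken when loops nest; interior
holes are thereby filled, and a component clipped by the image border is
flagged rather than closed.

Admissibility is the conjunction of four criteria, evaluated on the raw
traced contour:

| criterion | quantity | bound | default |
|---|---|---|---|
| 1 | boundary inside the height image | closed, no border contact | — |
| 2 | concave portion (convex-hull area − region area) | ≤ | 20 000 px² |
| 3 | hull area / region area (A/A0) | ≤ | 1.2 |
| 4 | Fourier restorability A1/A0, min over 100/50/25 points | ≥ | 0.95 |

Two readings here were genuinely open. "Area of the concave portion" is
implemented as the convex-hull deficit, and "A/A0" as hull area over
region area — this makes criterion 3 a solidity bound (region at least
83 % of its hull), which is the interpretation that actually
discriminates irregular contours; alternatives (largest single
concavity, hull area alone) are either strictly weaker or dimensionally
inconsistent with the 1.2 bound. And the selection rule among passing
levels is *lowest-first*: it maximizes the captured ONL volume, is
deterministic, and reduces to the reference plane itself whenever that
level is admissible. Both thresholds and the search step are exposed in
`run_config()` because they are calibrated to a 512 × 512 grid and do
not transfer unchanged to other resolutions.

## Elliptic Fourier restorability

`efd_fit()` computes elliptic Fourier descriptors of the closed polygon
under cumulative arc-length parameterization, with the standard closed
forms for the harmonic and DC coefficients of a piecewise-linear
contour. Restorability (`restore_ratio()`) resamples the contour to m
equally spaced boundary points (m = 100, 50, 25), fits five harmonics,
reconstructs densely, and compares restored to original area; the
minimum ratio over m is tested against 0.95. The ratio is raw and
unclamped — smoothing of concavities can push it slightly above 1.

Two numerical properties of this construction are worth knowing. First,
under arc-length parameterization an ellipse is *not* exactly a
single-harmonic curve: a 2:1 ellipse carries about 0.6 % of its energy
above harmonic 1. The higher terms matter for fidelity, which is why
five harmonics restore ellipses to ratios above 0.98 at all three point
counts. Second, the restored-*area* ratio is insensitive to
area-symmetric boundary ripple: a sinusoidal radial ripple of amplitude
`a` changes the enclosed area by the factor `1 + a²/2` while the
five-harmonic reconstruction collapses to approximately the mean
contour, so A1/A0 ≈ 1/(1 + a²/2) — about 0.985 at a = 0.2, crossing the
0.95 bound only near a ≈ 0.38. The criterion therefore rejects contours
with *area-asymmetric* roughness (spikes, fingers — the failure mode of
noisy reference-level contours) far more readily than symmetric
crenellation. Tests exercise the discriminating regime (a = 0.4,
12 lobes) rather than a regime where the bound provably cannot bite.

## The equivalent ellipse and shape parameters

Region moments are computed *analytically* from the polygon via
Green's-theorem line integrals — area, centroid, and normalized second
central moments — avoiding rasterization bias entirely; a dense
pixel-rasterization covariance oracle guards the implementation in the
test suite (agreement ≤ 0.5 % in axes, ≤ 0.5° in angle over random
convex fixtures). The equivalent ellipse uses full axis lengths
`a = 4√λ₊`, `b = 4√λ₋` of the moment eigenvalues, so a disk of radius r
reports a = b = 2r and cohort-scale axis ratios land near 1.5. The
major-axis angle `θ = ½·atan2(2µ₁₁, µ₂₀−µ₀₂)` is wrapped to (−90°, 90°].

Angles are reported in the left-eye fundus frame, counterclockwise
positive: right-eye (OD) angles are negated (`apply_laterality()`, a
mirror about the vertical meridian). Whether the original clinical
convention mirrored right eyes or used per-eye raw angles is not
determinable from the available description; mirroring is the default
because it makes OD/OS pairs of the same physical deformation agree, and
it can be disabled (`mirror_od = FALSE`).

Of the three dimensionless parameters, circularity `4πS/L²` is computed
on the five-harmonic smoothed reconstruction (perimeter of the raw
traced contour is noise-dominated; the smoothed value for a noisy
1.5:1-ellipse bump lands within ~0.003 of the analytic ellipse value),
while area ratio `S/(ab)` deliberately uses the *raw* region area S —
the smoothing is attached only to the perimeter-based statistic. All
three are scale-free; tests verify drift ≤ 10⁻³ under uniform scaling.

## Cohort statistics

MH/MV substitutes 0.05 for any zero score before forming the ratio
(keeping it finite and positive; 0.05 is one chart step below the 0.2°
detection floor). Group comparisons default to Welch's t (the safer
"parametric test"; Student's pooled t is a switch), SDs use n−1, Pearson
p-values come from the exact t-transform on n−2 df, all tests are
two-sided, significance is gated at p < 0.05 exactly, and no
multiple-testing correction is applied — the tables report raw
p-values. The correlation table is computed for all ERM eyes and for the
subset with |axis| ≤ 10°, the subset in which the MH/MV contrast aligns
with the deformation axis; the subset is skipped with a warning below
n = 3.

## What the synthetic generator does and does not emulate

`bump_model()` renders a constant base layer plus an anisotropic
Gaussian foveal bump, with a multiplicative radial ripple applied to the
level-set radius and additive Gaussian surface noise. Two design choices
matter for interpretation:

- **Level-independent truth.** Ripple and anisotropy scale with the
  level-set radius, so every level set shares one shape: recovery tests
  measure ellipse-fit accuracy independently of which level the search
  selects.
- **Separated MCHART link.** MH/MV is generated from a latent log-ratio
  correlated (coefficient ρ, default −0.47) with ground-truth area
  ratio, then split into MV and MH, clipped to [0, 2] and quantized to
  the chart's 0.1° steps with scores below the 0.2° floor recorded
  as 0. The link is a statistical device for calibration studies, not a
  perceptual model.

Cohort defaults emulate the study design: 39 ERM eyes and 21 fellow-eye
controls; base thickness distributions reproduce the group ONL heights
(84.1 ± 12.9 µm vs 54.1 ± 5.3 µm at 3.87 µm/px); axis angle and axis
ratio distributions use the reported group means and SDs; ERM eyes
receive stronger boundary ripple than controls, capped (amplitude
≤ 0.09, 4–6 lobes) so that simulated eyes remain admissible — in this
phantom, shape is level-independent, so an inadmissible shape would be
excluded at *every* level, unlike clinical data where roughness varies
with depth. Two consequences follow. Simulated circularity runs higher
(≈ 0.91) than clinical ERM cohorts (≈ 0.79): sinusoidal ripple within
the admissibility bounds cannot reproduce the full irregularity of real
contracted ONL contours. And the selected ONL-B level sits a few pixels
above the reference plane rather than ~150 µm up, because the phantom's
smooth low levels are already admissible. Passing recovery tests
therefore demonstrates correctness of the geometry and statistics, not
realism of OCT speckle, segmentation error, or pseudo-hole/lamellar-hole
morphologies, none of which are modelled.

## Numerical choices and degenerate inputs

- Iso-contours: sub-pixel linear edge interpolation; loop orientation
  normalized counterclockwise; edges below floating-point arc-length
  resolution collapsed before resampling.
- Histogram ties: lower bin. Angle wrap: (−90°, 90°], with −90° mapped
  to +90° so the mirror convention has a fixed point at the vertical.
- All-zero height image: reference level 0 with a warning. Empty
  superlevel set, degenerate (collinear) contours, zero-variance
  vectors in correlations and t-tests: classed errors
  (`onlshape_*_error`), so callers can distinguish data problems from
  configuration problems; `analyze_subject()` converts selection
  failures into an `excluded` flag with the reason, mirroring clinical
  QC exclusions, and cohort tables skip excluded rows.
- Determinism: every random draw flows from explicit seeds (per-subject
  substreams derived from the master seed), the RNG state of the caller
  is restored, and repeated runs write byte-identical tables.

Test problem sizes were chosen to probe each property at the scale the
method operates (512 × 512 maps, 9-angle × 3-anisotropy recovery sweeps,
50 random convex fixtures for the moment oracle, 1000-replicate null
calibration, 100-replicate power checks at n = 39 without surface
rendering); the full suite runs in about a minute.

## Known limitations

- Single macular region: multi-component ONL-B topologies and interior
  holes are filled/ignored by construction.
- No tilt or curvature correction: the analysis trusts the input
  surfaces' geometry; a flat RPE is assumed only by the *generator*, not
  by the pipeline.
- The restorability criterion's insensitivity to area-symmetric ripple
  (above) is inherent to an area-ratio definition; a fidelity measure
  (e.g. symmetric-difference area) would discriminate more sharply but
  would not match the published definition.
- Near-circular eyes (axis ratio ≲ 1.05) have ill-conditioned axis
  angles; downstream correlations against the angle should treat such
  eyes with care (the axis-window subset does this implicitly).
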