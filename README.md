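# onlshape

Quantitative 3-D morphometry of the retinal **outer nuclear layer (ONL)**
for epiretinal membrane (ERM) research, from spectral-domain OCT
segmentation surfaces.

Tangential contraction of an epiretinal membrane deforms the retina and
causes metamorphopsia (visual distortion). The ONL — the layer of
photoreceptor cell bodies — deforms with it. `onlshape` implements a
reproducible pipeline that turns a pair of segmented boundary surfaces
(ONL/OPL boundary and RPE line) into directional shape statistics of the
macular ONL and relates them to MCHART metamorphopsia scores:

1. **Height image (HI).** Per A-scan ONL-to-RPE distance over the
   49 × 512 acquisition grid, linearly interpolated to a 512 × 512 map;
   micrometre heights are `h_px × 3.87 µm`.
2. **Reference plane.** The height level at the mode of the HI histogram
   (1-px bins, ties to the lower bin) — the base section of the layer.
3. **ONL-Base (ONL-B).** Scanning iso-height contours upward from the
   reference plane, the lowest level whose contour satisfies four
   admissibility criteria: it lies inside the HI; its concave portion
   (convex-hull deficit) is ≤ 20 000 px²; its hull/region area ratio
   A/A0 ≤ 1.2; and its elliptic-Fourier restorability A1/A0 ≥ 0.95 when
   refit from 100, 50 and 25 boundary points with five harmonics.
4. **Shape parameters.** With S and L the ONL-B area and perimeter and
   (a, b, θ) the moment-method equivalent ellipse (full axis lengths,
   `a = 4√λ₊`):
   - circularity `4πS/L²` (on the Fourier-smoothed contour),
   - area ratio `S/(ab)` (π/4 for a perfect ellipse),
   - axis ratio `a/b` (≥ 1),
   - signed axis angle θ in the left-eye fundus frame (counterclockwise
     positive; right eyes are mirrored).
5. **Cohort statistics.** Group mean ± SD tables with Welch comparisons,
   the MCHART anisotropy ratio MH/MV (a zero score is recorded as 0.05),
   and Pearson correlations of MH/MV with each shape parameter, for the
   whole ERM group and for eyes whose axis lies within ±10° of horizontal.

Because patient OCT volumes cannot be redistributed, the package ships a
fully seeded synthetic-surface generator (`bump_model()`,
`generate_cohort()`) producing anisotropic foveal bumps with known
orientation, axis ratio, boundary ripple and noise, plus MCHART scores
statistically linked to the deformation — so every stage is testable
against analytic ground truth.

## Worked example

A left eye with a 30°-oriented, 1.5:1 anisotropic foveal bump and 1 px of
surface noise:

```r
library(onlshape)
m <- bump_model(theta_true_deg = 30, sigma_major_px = 60, sigma_minor_px = 40,
                noise_sd_px = 1, seed = 42, subject_id = "demo")
sim <- generate_surfaces(m)
hi  <- build_height_image(sim$stack)
ref <- reference_level(hi)
onlb <- select_onlb(hi, ref)
print(onlb)
#> <onlb_result> level 17.0 px (65.8 um from RPE), 4110-vertex contour
#>   S = 43941 px^2, L = 3640 px, hull ratio 1.153, restore ratio 0.995
sp <- shape_params(onlb$contour, "OS")
round(c(axis_deg = sp$axis_deg, circularity = sp$circularity,
        area_ratio = sp$area_ratio, axis_ratio = sp$axis_ratio), 3)
#>    axis_deg circularity  area_ratio  axis_ratio
#>      31.058       0.939       0.782       1.472
```

The reference plane sits at 14 px (54.2 µm); the first admissible section
is three pixels above it. The fitted axis angle (31.1°) and axis ratio
(1.47) recover the generating truth (30°, 1.5) to within the noise; the
smoothed circularity 0.939 is close to the analytic value 0.941 for a
1.5:1 ellipse, and the area ratio 0.782 is near π/4 ≈ 0.785, as expected
for a nearly elliptic region.

A full cohort run mirrors the clinical workflow:

```r
spec <- cohort_spec(n_erm = 39, n_control = 21, seed = 1)
generate_cohort(spec, dir = "cohort_in")
out <- run_cohort("cohort_in", run_config(seed = 1), "cohort_out")
out$table1   # group means +/- SD and Welch comparisons
out$table2   # Pearson r of MH/MV vs each parameter, all ERM and |axis| <= 10 deg
```

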