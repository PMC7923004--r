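---
title: "Quantifying aqueductal CSF flow from cine phase-contrast MRI: models, phantom design and statistics"
author: "aqueflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aqueductal CSF flow from cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Cerebrospinal fluid (CSF) oscillates through the aqueduct of Sylvius — the
1–2 mm-radius channel connecting the third and fourth ventricles — in rhythm
with the cardiac cycle: caudal (towards the fourth ventricle) during
systole, cranial during diastole. Gated 2D cine phase-contrast (PC) MRI
measures this motion by encoding through-plane velocity into voxel phase,
linearly up to the velocity-encoding limit (VENC):

v = VENC · φ / π  (cm/s),

with caudal flow taken positive. A typical aqueduct protocol acquires one
slice perpendicular to the duct, 32 frames per cardiac cycle, VENC
20 cm/s and 0.39 × 0.39 mm² pixels so that at least four pixels span the
lumen diameter.

From a segmented aqueduct region of interest (ROI) the package computes,
per frame: the cross-sectional area CSA (pixel count × pixel area, mm²);
the spatial-mean velocity Vmean (cm/s); the signed maximal velocity Vmax
(the value at the pixel of largest magnitude, cm/s); and the flow rate
FR = Vmean · CSA, reported in mL/min (1 cm/s through 1 mm² = 0.6 mL/min).
Cycle summaries are the averages of CSA, Vmean and FR, the systolic and
diastolic peaks of Vmean, Vmax and FR, and the caudal, cranial and net
displaced volumes (µL per cycle) obtained by integrating the rectified
flow-rate curve. The cycle average of Vmax is deliberately not computed:
near flow reversal the largest-magnitude pixel is ill-defined and the
quantity is unstable.

Because real scanner data for this protocol are not redistributable, every
claim the package makes is exercised on a synthetic phantom with exact
ground truth.

## The phantom

`render_cine()` simulates one gated slice of pulsatile laminar flow in an
elliptical duct embedded in static parenchyma.

**Waveform.** The centerline velocity template is two half-sine lobes — a
caudal lobe of amplitude `systolic_amplitude` occupying `systolic_fraction`
of the cycle, then a cranial lobe of amplitude `diastolic_amplitude` —
plus a constant chosen so the cycle mean equals `net_offset`. A half-sine
(rather than, say, raised-cosine) lobe was chosen because it degenerates
exactly to a single sinusoid in the symmetric case, which gives clean
closed-form checks, and every lobe integral is analytic, so ground-truth
volumes are exact. Defaults (10 / 7 cm/s amplitudes, fraction 0.45, offset
0.4 cm/s, RR 0.9 s, 32 frames) put every summary measure inside the ranges
reported for healthy adults and people with MS in the aqueduct literature.
Frames are sampled at cycle midpoints.

**Spatial profile.** Flow is laminar: the through-plane velocity falls
parabolically from the centerline to zero at the wall,
v(r) = v_c (1 − r²) on the normalized elliptical radius. The spatial mean
over the lumen is therefore exactly v_c / 2, which is what makes fully
analytic truth possible. The laminar assumption is justified a posteriori
by `reynolds()`: at the peak velocities and areas simulated here Re stays
in the hundreds, far below the turbulence threshold. Pulsatile flattening
of the profile (Womersley flow) is deliberately out of scope.

**Partial volume.** Each pixel is rendered as the magnitude-weighted
complex (phasor) sum of `supersampling`² sub-pixel contributions: static
parenchyma contributes unit magnitude at the background phase, lumen
sub-pixels contribute `lumen_brightness` (default 1.5, CSF bright) at phase
π v / VENC. Mixing signals — not phases — is what real voxels do, and it
reproduces the two biases that drive the reproducibility findings: boundary
pixels underestimate velocity (Vmean biased down) while generous contours
inflate CSA. The center-pixel phase deficit is approximately
(dx² + dy² + w²/6) / R² for pixel width w, lumen radius R and sub-pixel
center offset (dx, dy); at the default geometry this is a few percent,
and it is the reason Vmax recovery is quoted against lumens of radius
≥ 1.3 mm in the sweep design (`phantom_sweep_design()`).

**Background phase and noise.** A first-order polynomial phase offset
field (radians over the normalized field of view) models eddy-current-like
offsets — exactly the artifact the no-flow-area (NFA) correction targets.
I.i.d. complex Gaussian noise is added to the phasor before
magnitude/phase extraction; `snr` is defined on the parenchyma magnitude.
With a fixed `seed` the output is bit-identical across runs.

**Ground truth.** `true_measures()` evaluates CSA = πab exactly, peaks on
the sampled frame grid (so truth and measurement share a sampling
convention), and volumes by dense midpoint quadrature (20 000 points) of
the closed-form template — numerically exact at the 1e-9 level. The true
mask is the set of pixels with at least 50% lumen occupancy.

What the phantom does **not** emulate: Womersley profiles, in-plane motion
and misalignment of the imaging plane, ghosting/aliasing artifacts other
than phase wrap, gating jitter, and B0/B1 inhomogeneity beyond the smooth
offset field. Passing tests therefore validate the *processing chain* under
controlled physics, not the acquisition itself.

## Processing chain

`quantify_series()` mirrors the clinical workflow:

1. **Background correction** (`background_correct()`): per frame, the mean
   velocity over a static-tissue NFA is subtracted everywhere. Per-frame
   (not cycle-pooled) subtraction is used — it reduces to the pooled form
   for static offsets and is strictly more general. After correction the
   NFA mean is zero to machine precision; the part of the offset field that
   *varies* between the NFA and the lumen survives as a near-constant shift
   of the whole Vmean curve, which the test suite quantifies explicitly.
   No phase unwrapping is attempted: at VENC 20 cm/s the simulated regime
   never wraps, and `detect_aliasing()` reports wrap-risk pixels instead of
   silently unwrapping.
2. **Reference frame** (`select_reference_frame()`): the frame maximizing
   the 99th percentile of |v| inside a search window — the automated stand-in
   for "visually select the frame of highest flow". Ties break to the
   earliest frame.
3. **Segmentation** (one reference frame, 4-connectivity throughout to
   prevent diagonal leakage through the thin partial-volume rind; the mask
   is then copied unchanged to all frames by `propagate_mask()`).
4. **Measures** (`compute_timecourses()`, `summarize_measures()`).

## The three segmentation emulations

The three strategies reproduce the *interaction contracts* of the
commercial packages used in aqueduct studies, not their proprietary
internals:

- **Border-seeded local thresholding** (`segment_border_threshold()`,
  "click a border pixel"): the threshold is |v| at the clicked pixel; the
  mask is the 4-connected super-threshold component anchored at the local
  |v| maximum within 3 px of the click. The automated click
  (`propose_seeds()`) picks the pixel whose |v| is closest to 15% of the
  peak — the visually apparent edge where signal fades into background;
  operators overdrawing the visible lumen is also the field's canonical
  explanation for CSA overestimation. A click in parenchyma floods the
  image and is rejected via a component-size cap (default 200 px).
- **Contour refinement** (`refine_contour()`, "draw, then refine"): a
  generous manual contour (emulated as the 30%-of-peak region dilated by
  2 px) defines a local search region; an Otsu threshold on |v| within the
  region separates moving CSF from background and the largest 4-connected
  component is kept. Because the laminar profile makes the within-lumen
  histogram a ramp rather than a plateau, a linear-domain Otsu split lands
  well inside the lumen (at ≈ 0.25–0.4 of the peak, geometry-dependent);
  Otsu is therefore computed on log(|v| + 0.03 max), the standard transform
  for strongly skewed intensity histograms, which stably finds the
  background/CSF separation. If the histogram is degenerate the initial
  contour is returned with a warning.
- **Seeded region growing** (`segment_region_grow()`, "click inside"):
  grows 4-connectedly from an interior click, keeping pixels with
  |v| ≥ α |v(click)|; α defaults to 0.2 and is monotone — larger α can only
  shrink the mask. α = 0 recovers the full footprint of moving pixels.

All three agree almost perfectly (pairwise Dice ≥ 0.85) on clean phantoms,
and all three place the same pixel at the lumen center — which is why the
Vmax peaks are bit-identical across strategies and immune to ±1 px click
jitter, while CSA and the Vmean-derived measures are not. That asymmetry is
the entire mechanism behind the repeatability pattern the package
reproduces: ROI-size-sensitive averages lose intraclass correlation under
operator variability; Vmax keeps it.

## Agreement and cohort statistics

**Dice** (`dice()`): 2|A∩B| / (|A|+|B|), with the published strength bands
implemented half-open exactly as quoted (almost perfect (0.8, 1],
substantial (0.6, 0.8], moderate (0.4, 0.6], fair (0.2, 0.4], slight
[0, 0.2]); two empty masks are defined identical (Dice 1), a logged
convention.

**ICC** (`icc_repeatability()`): the source protocol never names its ICC
model, so the package defaults to the two-way absolute-agreement
single-measure form ICC(A,1) = (MSR − MSE) / (MSR + (k−1)MSE +
(k/n)(MSC − MSE)) — the natural choice for one operator's repeated
measurements, since a systematic shift between sessions should count
against repeatability. The consistency form ICC(C,1) is a switch. The
p-value is the subject-effect F test. Grades: excellent > 0.90, good
(0.70, 0.90], acceptable (0.50, 0.70], insufficient (0.30, 0.50], poor
≤ 0.30 (negative ICCs map to poor). The implementation computes the sums
of squares directly; the test suite cross-checks it against an independent
`aov()` decomposition to 1e-10.

**GLM** (`fit_glm()`): ordinary least squares with treatment coding,
measure ~ age + sex + software + group. References: female sex, control
group, software C (the region-growing package). Sex coding follows the
results-section convention (female = 0 reference) where the source
protocol contradicts itself; the reference is a config switch. Reported
per coefficient: B, SE, t, the 95% CI (B ± t_crit·SE), p, and partial eta
squared as t² / (t² + df_residual) — the parameter-level equivalent of
SS_term / (SS_term + SS_error) that SPSS prints in its parameter-estimates
table.

**RM-ANOVA** (`rm_anova()`): one-way repeated measures across software with
subject blocking, realized as `aov(y ~ software + Error(subject))`; with
complete balanced data this is equivalent to the mixed-model formulation.
Post hocs are paired t-tests with Bonferroni m = 3 (the software pairs;
no cross-measure correction, matching how such tables are reported).
Degenerate decompositions are handled explicitly: zero effect and zero
residual → F = 0, p = 1; positive effect on zero residual → p = 0.
Kolmogorov–Smirnov normality screening (`describe_cohort()`) is reported
as a diagnostic only and never gates the pipeline.

## The synthetic cohort

`simulate_cohort()` renders one phantom per synthetic subject and
quantifies it with all three strategies, so software comparisons are
*within subject* exactly as in a real multi-package study. Defaults: 30
MS-like and 19 control subjects; ages N(51.8, 8.8²) and N(48.4, 12.5²)
years; sex ratios 17/30 and 14/19 female; subject-level centerline
amplitudes N(9.5, 2.5²) systolic and N(6.2, 1.8²) diastolic cm/s with
small age (−0.03 and −0.02 cm/s per year) and sex (+0.8 / +0.5 cm/s for
male) slopes; lumen radius N(1.0, 0.12²) mm truncated to [0.8, 1.6] so the
four-pixel-diameter rule holds; SNR 30. Repeat measurements re-run the
operator clicks with ±1 px jitter on the same rendered series — the
re-processing (not re-scanning) protocol.

The injected group difference raises the diastolic centerline amplitude by
2.0 cm/s in the MS-like group (with a +1.0 cm/s systolic and +0.10 mm
radius shift). The 2.0 cm/s value is a power-design choice made when the
generator was specified: with between-subject SD 1.8 cm/s and n = 30 + 19
it yields a group-term t of ≈ 4, so the qualitative headline — a
significant diastolic-Vmax group effect under every segmentation strategy,
with null software terms — is reliably detectable at the study's sample
size rather than hovering at the significance boundary. Per-software
additive bias terms (`software_bias`) exist for calibration experiments
and default to zero.

## Numerical choices and problem sizes

- Volumes integrate the flow-rate curve by the trapezoidal rule with
  periodic closure, which for uniformly gated frames equals frame-mean ×
  period; at 32 frames the half-sine test case is recovered to 0.16%,
  comfortably inside the 0.5% design tolerance.
- Conservation (net = caudal + cranial, and fr_avg·RR ↔ net volume) holds
  to 1e-9 relative by construction and is asserted on every quantified
  series.
- Phase lives in [−π, π); π wraps to −π at rendering and on file read.
- Arrays are indexed `[y, x, t]`, 1-based; the NIfTI `(x, y, 1, t)` layout
  is confined to the I/O layer and round-trip tested.
- All randomness flows from explicit integer seeds (`withr::with_seed`);
  fixed seeds give bit-identical phantoms, cohorts and files.
- Default problem sizes keep every analysis interactive on one CPU: 64×64
  matrices, 32 frames, supersampling 8 (≈ 0.1 s per phantom), a 20-phantom
  recovery sweep, a 49-subject cohort (≈ 5 s), 1000-replicate calibration
  of the RM-ANOVA F and 500-replicate CI coverage for the GLM.

## Known limitations

- Vmax recovery is partial-volume-limited: with 0.39 mm pixels a 1 mm
  lumen radius loses ≈ 2.5–5% of the centerline velocity at the center
  pixel (more if the lumen center falls on a pixel corner). The recovery
  sweep is therefore specified for radii ≥ 1.3 mm; for smaller ducts the
  bias is real and would be present in scanner data too.
- The CSF:parenchyma brightness ratio adds a small (~1%) positive bias to
  summed boundary flux; the flux-conservation test uses brightness-neutral
  rendering to isolate the geometric rendering error.
- The three strategies are functional emulations; absolute CSA offsets
  between them are systematic (the refinement strategy segments closest to
  the full lumen) and show up as strong software effects on
  ROI-size-sensitive measures in the RM-ANOVA — a deliberately conservative
  stand-in for the milder inter-package differences of real tools.
- Statistical calibration (type-I error, coverage) is verified for the
  balanced complete designs the pipeline produces; unbalanced or missing
  data are rejected, not modeled.
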