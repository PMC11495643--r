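---
title: "Estimating regional myocardial work from endocardial surface motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating regional myocardial work from endocardial surface motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In dyssynchronous heart failure (left bundle branch block, LBBB), the
early-activated septum shortens before pressure rises and is then stretched
back ("rebound stretch") by the late-activated lateral wall contracting at
high pressure. The septum therefore absorbs work (its stress--strain loop
runs clockwise) while the lateral wall performs abnormally high work.
Cardiac resynchronization therapy (CRT) reduces this redistribution, and
the size of the negative-work region -- especially in the septum -- is a
candidate predictor of reverse remodeling (the reduction in LV end-systolic
volume, dESV, at follow-up).

Regional wall stress cannot be measured in patients. `myowork` implements
the *simplified* estimation chain that replaces stress with measurable
surrogates and strain with endocardial surface-area change, so that
regional work maps, heterogeneity metrics and responder statistics can be
computed from a triangulated endocardial surface sequence and a pressure
trace alone.

## Strain: endocardial area change (RS_CT)

For a triangular endocardial patch $v$ at time $t$ in the RR interval,

$$\mathrm{RS}_{CT}(v,t) = \frac{A(v,t)}{A(v,0)} - 1,$$

with $A$ the patch area and frame 0 the end-diastolic reference
(`compute_rsct()`). Patches with zero reference area are excluded (flagged),
and degenerate triangles keep area 0 rather than being deleted so patch
indexing is stable across frames. Segmental curves are the mean of patch
strains within each of the 17 AHA segments (`segment_average_strain()`).
The average is weighted by reference patch area by default: an unweighted
mean depends on the local mesh resolution, which is an artefact of the
triangulation rather than of the physiology. An unweighted mode is kept for
sensitivity checks.

AHA segmentation (`assign_aha_segments()`) uses the apex-to-base axis:
longitudinal position measured fractionally from the base gives basal
[0, 1/3), mid [1/3, 2/3), apical [2/3, 0.95) rings and an apical cap at
0.95 and beyond (segment 17); basal/mid rings split into six 60-degree
sectors and the apical ring into four 90-degree sectors from a supplied
anterior reference direction. Septal segments are {2, 3, 8, 9, 14}.

## Stress: five surrogates

All stress and work quantities are in kPa (work density kPa = kJ/m^3);
mmHg input is converted with 1 mmHg = 0.133322 kPa.

| method | stress assigned to every segment |
|---|---|
| `P_LHC` | the measured (catheter) LV pressure, identical in all segments |
| `WS_ED` | Laplace wall stress with end-diastolic shape: $\sigma_s(t) = P(t)\, r_{\mathrm{eff},s}(0) / (2 h_s(0))$ |
| `WS_TV` | Laplace wall stress with time-varying shape: $\sigma_s(t) = P(t)\, r_{\mathrm{eff},s}(t) / (2 h_s(t))$ |
| `P_gen` | a generic normal-hemodynamics waveform (peak 16 kPa, EDP 1.07 kPa) |
| `P_gen_scaled` | the generic waveform scaled to the patient's peak pressure |

The segmental radius merges circumferential and longitudinal curvature,
$r_\mathrm{eff} = r_c r_l / (r_c + r_l)$, since total curvature is
approximately the sum of the principal curvatures and radius is inverse
curvature. Radii come from a least-squares axisymmetric ellipsoid fit to
each segment's endocardial points (`fit_segment_radii()`): the fit is
linear in $(1/a^2, 1/b^2,$ centre offset$)$, $r_c = a$, and $r_l$ is the
meridional curvature radius of the fitted ellipse at the mean latitude of
the points ($b^2/a$ at the equator). A general 9-parameter quadric is
deliberately avoided: on per-segment clouds of 50--200 points it is poorly
conditioned, while the axisymmetric fit is robust and has a closed form.
Cylinder- or ring-like degenerate clouds (no longitudinal curvature
information) fall back to an axis-centred sphere fit, flagged in the
output. How radius and thickness were sampled in time for the time-varying
method is genuinely open; the package refits per frame by default and
offers the end-diastolic fit as an option (`ws_frames = "ed"`).

The generic waveform (`generic_waveform()`) is a documented parametric
stand-in: end-diastolic baseline, raised-cosine upstroke to the peak,
raised-cosine relaxation to a diastolic minimum, slow return to EDP so the
cycle closes. A digitised waveform of unknown provenance would not be
reproducible; any sampled trace can be supplied via CSV instead
(`read_pressure_csv()`). Uniform rescaling of the pressure leaves loop
orientation, COVW and all negative-work fractions unchanged, which is why
the `P_gen` and `P_gen_scaled` rows of any metric table are identical --
the package exploits this as a consistency check in its test suite.

Pressure and strain are both referenced to the R-wave; the pressure is
linearly interpolated onto the strain frame times. No temporal smoothing is
applied anywhere.

## Work: signed loop area

Regional work density is the signed area of the stress--strain loop over
one cycle, computed by the shoelace formula with strain on the abscissa:

$$W = -\oint \sigma \, d\varepsilon,$$

counter-clockwise positive (work performed by the tissue), clockwise
negative (work done on the tissue). The loop is closed by appending the
frame-0 sample; no resampling or smoothing of the loop is done.
Self-intersecting figure-8 loops -- typical of early-activated myocardium --
yield the net signed area of their lobes, which is exactly what the
negative-work classification needs; no per-lobe decomposition is attempted.
The shoelace result is algebraically identical to the trapezoid rule for
$-\oint \sigma\, d\varepsilon$; the test suite verifies the equality to
1e-9 on 1000 random loops and against analytic ellipse areas.

Work maps carry endocardial-area weights (surface mode, giving the
$S_f$ metrics) or area-times-thickness wall-volume weights (volume mode,
$V_f$). The negative-work fraction uses a strict $W < 0$ threshold (no
tolerance band). The high-work fraction uses the weighted upper quartile of
the same patient-state map (per-patient convention, lower-interpolation on
the cumulative weight function); pooling thresholds across a cohort is
exposed as a choice for sensitivity analyses but is not the default, since
work-density scales differ across patients. COVW is the weighted population
standard deviation over the weighted mean; an unweighted mode exists for
comparison.

### Global work and efficiency

Stroke work is the signed pressure--volume loop area (kPa mL = mJ). Cavity
volume comes from signed tetrahedra against the basal boundary-loop
centroid, which implicitly closes the surface with a flat basal cap.
Total myocardial work integrates work density over the wall
(kPa mm^3 = uJ). For surface-mode maps the conversion multiplies patch
area by local thickness -- an approximation that is flagged in the result,
because the simplified estimates are intrinsically surface quantities.

Mechanical efficiency $\eta$ = stroke work / total myocardial work needs a
total-work convention that is energy-consistent. The Laplace
effective-radius stress systematically underestimates wall work on an
elongated ventricle (the harmonic radius combination is a curvature
average, not an energy equivalent), so the package defines the
energy-consistent total work (`energy_total_work()`) with the
volume-equivalent radius $r_E = 3V/A$: under uniform scaling of any
chamber shape this convention reproduces the pressure--volume work
identically (the wall thickness cancels), and the test suite confirms the
identity to 0.5% on a synchronously contracting synthetic ventricle. The
generator's energy audit (`synth_energy_audit()`) adds the work done
against a viscoelastic wall stress $\mu\, d\varepsilon/dt$ with
$\mu = 1.5$ kPa s (a physiologic myocardial viscosity); that term is
strictly dissipative, so stroke work cannot exceed total work and
$\eta \le 1$ holds by construction. On the default synthetic patients
$\eta \approx 0.74$--$0.80$.

## Cohort statistics

Echocardiographic response is a strictly greater than 10% reduction in LV
end-systolic volume; clinical response is an improvement of at least one
NYHA class. The "at least one" reading is deliberate: published patient
tables label single-class improvements as responders even where
accompanying text says "more than one", and the table is what worked
examples must reproduce; a strict mode (`strict_clinical = TRUE`) keeps
the literal reading available. A CRT (combined) responder satisfies both
rules.

Group comparisons use two-sided pooled-variance Student's t-tests (paired
for within-patient baseline-vs-CRT contrasts), with a two-factor
fixed-effects ANOVA (response group x state, with interaction) available;
degenerate zero-variance cases return p = 1 with a flag rather than an
error. Metric--outcome association uses ordinary least squares with
$R^2 = r^2$ and the p-value of Pearson's correlation at $n-2$ degrees of
freedom. No multiple-testing correction is applied, matching standard
practice for small mechanistic cohorts. All of these call the base R
implementations (`t.test`, `aov`, `lm`, `cor.test`).

The knock-out procedure (`knockout_analysis()`) replaces one parameter
group (geometry, activation, pressure, thickness) by its cohort mean for
every patient, reruns the pipeline, and reports the new metric--outcome
$R^2$ plus the normalised RMS deviation of the metric from the
fully-specific run. nRMSD is normalised by the range of the fully-specific
metric by default ("mean" is available); the normalisation is a
convention, not a derived quantity, so it is configurable and documented.
Identical metrics give exactly nRMSD = 0.

## The synthetic dyssynchronous ventricle

The generator exists so every pipeline stage can be validated without
clinical data. It emulates, at the level of surface kinematics:

* an LBBB strain pattern -- early-activated septal patches shorten early,
  lose shortening amplitude, and acquire a late-systolic rebound-stretch
  bump placed in the high-pressure window (which is what makes their loops
  run clockwise); late-activated free-wall patches pre-stretch and then
  shorten late with augmented amplitude;
* a CRT pattern -- activation dispersion and the severity-driven
  distortions compressed by a factor 0.3;
* realistic pressure waveforms (parametric, patient-varied peak/EDP,
  optional measurement noise);
* a cohort in which baseline septal negative work relates linearly (plus
  noise) to the reverse-remodeling outcome.

Segment strain curves are built from raised-cosine pulses (onset delayed
by the segment's activation time, held through systole, released in
diastole) plus raised-cosine rebound and pre-stretch bumps -- smooth,
differentiable, and with five interpretable parameters; within the septum
the distortion amplitude is graded smoothly from base to apex so the
negative-work fraction grows *continuously* with the severity parameter
(strict monotonicity is a tested invariant). Study conditions are the
generator defaults, chosen once on physiological grounds: dilated LV
(base radius 30 mm, axis length 90 mm, end-diastolic volume about 190 mL,
ejection fraction about 28%), wall thickness 8 mm, RR 800 ms, peak
pressure 16 kPa, EDP 1.07 kPa, activation delay up to 150 ms, shortening
amplitude 0.20 area strain, rebound amplitude 0.30, pre-stretch 0.10.

Prescribed per-patch areas are realized by a smooth per-vertex similarity
scaling about a mid-cavity point. This is exact for patches whose vertices
share a scale factor and approximate across segment borders, so the
generator records both the analytic prescription and the *realized*
segment strain curves (its own area bookkeeping) as ground truth; pipeline
recovery is checked against the realized curves to 1e-6, and against the
prescription exactly in the synchronous (uniform-scaling) limit where the
two coincide.

Motion noise is log-normal per-vertex scale noise (multiplicative on
areas; per-patch noise is not realizable exactly on a shared-vertex mesh),
zero at both cycle endpoints so loops close. Its default (sd 0.005) was
set by a Monte-Carlo calibration of the planted-outcome recovery: the
cohort generator plants
$\mathrm{dESV} = \beta_0 + \beta_1 V_{f,\mathrm{STNW}}(\mathrm{LBBB}) +
\varepsilon$ with residuals orthogonalised and scaled so the sample $R^2$
between the noise-free metric and the outcome equals the target (0.7 by
default) exactly; re-analysing the noisy emitted data then recovers
$R^2 \approx 0.62$--$0.71$ over 20 master seeds -- the attenuation is the
genuine errors-in-variables effect of the motion noise. $\beta_0 = -45$,
$\beta_1 = 100$ put roughly half of the default cohort above the 10%
responder threshold.

What the generator does *not* emulate: real ventricular anatomy (papillary
muscles, trabeculation, non-ellipsoidal remodeling), electrophysiology
(activation enters only as per-segment delays), infarct scar, the right
ventricle, valve events and isovolumic phase timing beyond the waveform
shape, and image-derived segmentation error beyond i.i.d. vertex noise.
Passing tests therefore demonstrate the correctness and sensitivity of the
*estimation chain*, not the clinical accuracy of the surrogates on
patients.

## Problem sizes used in the validation suite

The test and acceptance runs use a 744-triangle mesh at 41 frames per
cycle (about 0.05 s of compute per patient state), cohorts of 8--50
patients, 20 master seeds for the recovery band, and a 10-patient cohort
for the knock-out analysis; the voxel-volume oracle runs at 0.5 mm on a
12 mm star-convex mesh. These sizes were chosen to exercise every code
path at full fidelity while keeping the whole suite fast enough to run on
every change.

## Worked example

```{r example}
library(myowork)

p <- synth_patient_params(severity = 0.8, patch_noise_sd = 0)
mesh <- make_lv_mesh(p)
lbbb <- make_motion(mesh, p, "LBBB")
analysis <- analyze_patient(lbbb$surface, pressure = make_pressure(p),
                            methods = WORK_METHODS, thickness = 8,
                            state = "LBBB")
analysis$metrics

co <- make_cohort(synth_cohort_config(n_patients = 8, seed = 42))
metrics <- analyze_cohort(co, methods = "P_gen")
cohort_report(metrics, co$records)
```

## Known limitations

* The five stress surrogates share one pressure trace across segments (or
  scale it by a static/slow shape factor); regional stress heterogeneity
  beyond shape is invisible to them by design.
* Surface-mode total work in joules requires a thickness assumption and is
  an extension of the surface estimates, flagged as an approximation.
* The basal cap used for cavity volume is flat; strongly non-planar basal
  boundaries would bias volumes.
* RV metrics are out of scope: the simplified estimates cover the LV and
  septum only.
* The knock-out machinery operates on synthetic cohorts (it must be able
  to regenerate patients under substituted parameters); applying it to
  clinical data would require re-measured inputs per substitution.
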