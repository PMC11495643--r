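# myowork

Regional myocardial work estimation from endocardial surface motion, for
cardiac computational physiology: quantifying how left-ventricular (LV)
work redistributes in dyssynchronous heart failure (left bundle branch
block, LBBB) and renormalises under cardiac resynchronization therapy
(CRT), using only quantities measurable without patient-specific
finite-element modeling — a triangulated endocardial surface tracked over
one cardiac cycle plus an LV pressure trace.

## The model

Strain is the fractional endocardial patch-area change relative to
end-diastole,

    RS_CT(v, t) = A(v, t) / A(v, 0) − 1,

averaged (area-weighted) within the 17 AHA segments. Stress is one of five
surrogates: the catheter LV pressure applied to all segments (P_LHC), a
generic or peak-scaled generic pressure waveform (P_gen, P_gen,scaled), or
Laplace-law wall stress σ = P·r/(2h) with end-diastolic or time-varying
segmental shape (WS_ED, WS_TV), where r is the effective radius
r_eff = r_c·r_l / (r_c + r_l) from an axisymmetric ellipsoid fit per
segment. Regional work density (kPa ≡ kJ/m³) is the signed
stress–strain loop area W = −∮σ dε, counter-clockwise positive (work
performed by the tissue), clockwise negative (work done on it — the
signature of the early-activated septum in LBBB). Work maps feed the
heterogeneity and regional metrics: COVW (coefficient of variation of
work), negative-work fractions of the LV and septum (S_f/V_f LVNW, STNW),
the upper-quartile high-work fraction, stroke work, total myocardial work
and mechanical efficiency η.

A synthetic dyssynchronous-ventricle generator (truncated prolate
spheroid, raised-cosine segment strain patterns with activation delays,
septal rebound stretch and free-wall hyperwork, planted
metric-to-outcome structure) makes the whole chain testable end to end;
responder classification, group statistics, outcome regression and the
parameter knock-out sensitivity procedure operate on either synthetic or
real cohort tables.

## Worked example

```r
library(myowork)

p    <- synth_patient_params(severity = 0.8, patch_noise_sd = 0)
lbbb <- make_motion(make_lv_mesh(p), p, "LBBB")
analyze_patient(lbbb$surface, pressure = make_pressure(p),
                methods = WORK_METHODS, thickness = 8, state = "LBBB")$metrics
```

```
        method state weight_type covw f_lvnw f_stnw f_lvhw
1        P_LHC  LBBB        area 1.05  0.213  0.601  0.241
2        WS_ED  LBBB        area 1.05  0.213  0.601  0.241
3        WS_TV  LBBB        area 1.04  0.182  0.601  0.241
4        P_gen  LBBB        area 1.05  0.213  0.601  0.241
5 P_gen_scaled  LBBB        area 1.05  0.213  0.601  0.241
```

At severity 0.8, 60% of the septal surface performs net negative work
(`f_stnw`), about 21% of the whole LV surface is negative (`f_lvnw`), and
regional work heterogeneity is high (COVW ≈ 1.05). The generic and
peak-scaled generic pressure rows are identical because every regional
metric is invariant to uniform pressure scaling.

A full synthetic cohort with planted outcome structure:

```r
co      <- make_cohort(synth_cohort_config(n_patients = 8, seed = 42))
metrics <- analyze_cohort(co, methods = "P_gen")
cohort_report(metrics, co$records)
```

```
Cohort report: 8 patients; 4 echo / 7 clinical / 4 combined responders
Baseline metric ~ outcome regressions:
  method metric   slope    r2      p n
1  P_gen   covw    77.1 0.630 0.0186 8
2  P_gen f_lvnw   261.2 0.651 0.0155 8
3  P_gen f_stnw    96.5 0.671 0.0129 8
4  P_gen f_lvhw 14272.2 0.430 0.0774 8
```

Baseline septal negative work correlates with the reverse-remodeling
outcome (R² = 0.67 here), while the high-work fraction does not reach
significance — the planted structure the generator is designed to carry.

Real data enter through the same interfaces: `read_obj_sequence()` /
`read_mesh_with_displacements()` for the surface, `read_pressure_csv()`
for pressure, `read_cohort_csv()` for outcome tables. An eight-patient CRT
outcome table ships in `inst/extdata/crt_cohort_outcomes.csv`.

## Documentation

The methods vignette (`vignettes/myowork-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, the synthetic generator's scope and calibration, numerical
conventions (loop closure, degenerate geometry, weighted quantiles) and
known limitations.
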