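test_that("reference mesh is valid, well resolved and deterministic", {
  p <- synth_patient_params()
  mesh <- make_lv_mesh(p)
  expect_true(is.endo_surface(mesh))
  expect_gte(nrow(mesh$triangles), 200)
  expect_identical(length(unique(assign_aha_segments(mesh)$patch_segment)), 17L)
  # identical params give a byte-identical mesh
  expect_identical(mesh$vertices, make_lv_mesh(p)$vertices)
  # too-coarse resolution is rejected
  expect_error(make_lv_mesh(synth_patient_params(n_theta = 8, n_phi = 4)),
               "coarse")
})

test_that("sphere-mode geometry matches the analytic volume", {
  # a = b: truncated sphere; spherical-cap volume pi h^2 (3r - h) / 3
  r <- 30
  p <- synth_patient_params(base_radius = r, axis_length = 1.5 * r,
                            n_theta = 48, n_phi = 32)
  mesh <- make_lv_mesh(p)
  hcap <- 1.5 * r
  expect_equal(cavity_volume(mesh, 1), pi * hcap^2 * (3 * r - hcap) / 3 / 1000,
               tolerance = 0.01)
})

test_that("severity 0 collapses to a synchronous pattern", {
  qm <- quick_motion(severity = 0)
  gt <- qm$motion$ground_truth$realized_segment_strain
  # all 17 segment curves identical
  expect_lt(max(abs(sweep(gt, 2, gt[1, ]))), 1e-9)
  expect_true(all(qm$motion$activation_ms == 0))
})

test_that("dyssynchronous septum stretches during the high-pressure window and does negative work", {
  qm <- quick_motion(severity = 0.8)
  gt <- qm$motion$ground_truth$realized_segment_strain
  ft <- qm$motion$surface$frame_times
  high_p <- ft > 350 & ft < 500
  expect_gt(max(gt[14, high_p]), 0)  # apical septum stretched above reference
  # negative loop area under any positive pressure trace
  segmap <- assign_aha_segments(qm$motion$surface)
  strain <- segment_average_strain(compute_rsct(qm$motion$surface), segmap)
  for (wv in list(generic_waveform(), generic_waveform(peak_kpa = 10, edp_kpa = 0.5))) {
    sf <- build_stress_field("P_gen", wv, ft)
    wm <- compute_work_map(strain, sf, segmap)
    expect_lt(wm$work[wm$segment == 14], 0)
  }
})

test_that("CRT compresses activation dispersion by the stated factor", {
  p <- synth_patient_params(severity = 0.8, patch_noise_sd = 0)
  mesh <- make_lv_mesh(p)
  lb <- make_motion(mesh, p, "LBBB")
  cr <- make_motion(mesh, p, "CRT")
  expect_equal(stats::sd(cr$activation_ms), 0.3 * stats::sd(lb$activation_ms),
               tolerance = 1e-12)
})

test_that("severity maps monotonically onto the septal negative-work fraction", {
  sev <- seq(0.5, 0.95, by = 0.09)
  vf <- vapply(sev, function(s) {
    qm <- quick_motion(severity = s)
    synth_metric_vf_stnw(qm$motion, qm$params, "P_gen")
  }, numeric(1))
  expect_true(all(diff(vf) > 0))  # strictly monotone: Spearman rho = 1
  expect_equal(stats::cor(sev, vf, method = "spearman"), 1, tolerance = 1e-12)
})

test_that("resynchronisation never increases septal negative work (noise-free)", {
  for (s in c(0.55, 0.75, 0.95)) {
    p <- synth_patient_params(severity = s, patch_noise_sd = 0)
    mesh <- make_lv_mesh(p)
    vf_l <- synth_metric_vf_stnw(make_motion(mesh, p, "LBBB"), p, "P_gen")
    vf_c <- synth_metric_vf_stnw(make_motion(mesh, p, "CRT"), p, "P_gen")
    expect_gte(vf_l - vf_c, 0)
    expect_gt(vf_l, 0)  # baseline disease present at these severities
  }
})

test_that("synthetic pressure honours parameters and degenerates to the generic waveform", {
  p <- synth_patient_params(peak_kpa = 18.5, edp_kpa = 1.4)
  w <- make_pressure(p)
  expect_equal(w$peak, 18.5)
  expect_equal(w$edp, 1.4)
  # zero noise equals the generic waveform exactly
  g <- generic_waveform(peak_kpa = 18.5, edp_kpa = 1.4)
  expect_identical(w$pressures, g$pressures)

  # two seeds differ only through the noise realisation
  pn1 <- synth_patient_params(pressure_noise_sd = 0.2, seed = 1L)
  pn2 <- synth_patient_params(pressure_noise_sd = 0.2, seed = 2L)
  w1 <- make_pressure(pn1); w2 <- make_pressure(pn2)
  expect_false(identical(w1$pressures, w2$pressures))
  expect_equal(mean(w1$pressures - w2$pressures), 0, tolerance = 0.05)
})

test_that("cohorts are reproducible from the master seed with planted structure", {
  cfg <- synth_cohort_config(n_patients = 5, seed = 123, states = "LBBB",
                             n_frames = 25)
  co1 <- make_cohort(cfg)
  co2 <- make_cohort(cfg)
  expect_identical(co1$records, co2$records)
  expect_identical(co1$ground_truth, co2$ground_truth)
  expect_identical(co1$patients[[3]]$states$LBBB$surface$vertices,
                   co2$patients[[3]]$states$LBBB$surface$vertices)

  # the planted sample R^2 between the true metric and outcome is exact
  r <- stats::cor(co1$ground_truth$vf_stnw_lbbb, co1$records$desv_lv)^2
  expect_equal(r, cfg$r2_target, tolerance = 1e-9)
  expect_gt(stats::cor(co1$ground_truth$vf_stnw_lbbb, co1$records$desv_lv), 0)
})

test_that("a small cohort regression recovers the planted positive slope", {
  co <- make_cohort(synth_cohort_config(n_patients = 8, seed = 77, states = "LBBB"))
  vf <- vapply(seq_along(co$patients), function(i) {
    synth_metric_vf_stnw(co$patients[[i]]$states$LBBB,
                         co$patients[[i]]$params, "P_gen")
  }, numeric(1))
  reg <- regress_outcome(vf, co$records$desv_lv)
  expect_gt(reg$slope, 0)
  expect_gt(reg$r2, 0.3)
})
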