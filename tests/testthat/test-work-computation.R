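test_that("loop area matches analytic ellipses and flips with orientation", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  eps <- 0.1 * cos(th)
  sig <- 8 * sin(th)
  w <- loop_area(eps, sig)
  expect_equal(w, pi * 0.1 * 8, tolerance = 0.001)      # CCW positive
  expect_equal(loop_area(rev(eps), rev(sig)), -w, tolerance = 1e-12)

  # symmetric figure-8: equal opposite lobes cancel
  t8 <- seq(0, 2 * pi, length.out = 721)[-721]
  x8 <- 0.1 * sin(2 * t8)
  y8 <- 5 * sin(t8)
  expect_equal(loop_area(x8, y8), 0, tolerance = 1e-9)

  # constant stress, any closed strain path
  expect_equal(loop_area(eps, rep(7, length(eps))), 0, tolerance = 1e-12)

  expect_error(loop_area(c(0, 1), c(1, 0)), "3 samples")
})

test_that("shoelace equals the trapezoid -integral(sigma d eps) oracle on 1000 random loops", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(10:80, 1)
    eps <- stats::rnorm(n, 0, 0.2)
    sig <- stats::rnorm(n, 5, 4)
    worst <- max(worst, abs(loop_area(eps, sig) - trapezoid_work(eps, sig)))
  }
  expect_lt(worst, 1e-9)
})

test_that("loop area is bilinear and antisymmetric under reversal", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    eps <- stats::rnorm(n, 0, 0.2)
    sig <- stats::rnorm(n, 5, 4)
    w <- loop_area(eps, sig)
    expect_equal(loop_area(eps, 3.7 * sig), 3.7 * w, tolerance = 1e-9)
    expect_equal(loop_area(-2 * eps, sig), -2 * w, tolerance = 1e-9)
    expect_equal(loop_area(rev(eps), rev(sig)), -w, tolerance = 1e-9)
  }
})

test_that("work maps carry the loop sign convention of the physiology", {
  qm <- quick_motion(severity = 0.85)
  surf <- qm$motion$surface
  segmap <- assign_aha_segments(surf)
  strain <- segment_average_strain(compute_rsct(surf), segmap)
  stress <- build_stress_field("P_gen", generic_waveform(), surf$frame_times)
  wm <- compute_work_map(strain, stress, segmap)

  # late-activated free wall: shortening at high stress -> positive work
  expect_true(all(wm$work[wm$segment %in% c(11, 12)] > 0))
  # early-activated septum with rebound stretch at high pressure ->
  # clockwise (negative) net loop area; cross-check with the orientation
  # oracle on the raw curves
  expect_lt(wm$work[wm$segment == 14], 0)
  expect_equal(wm$work[wm$segment == 14],
               trapezoid_work(strain$values[14, ], stress$values[14, ]),
               tolerance = 1e-9)

  # scaling the stress field scales every work value by the same factor
  stress2 <- stress
  stress2$values <- stress2$values * 2.5
  wm2 <- compute_work_map(strain, stress2, segmap)
  expect_equal(wm2$work, wm$work * 2.5, tolerance = 1e-12)

  # mismatched time bases are rejected
  bad <- stress
  bad$frame_times <- bad$frame_times + 1
  expect_error(compute_work_map(strain, bad, segmap), "time base")
})

test_that("stroke work integrates the PV loop with unit conversion", {
  # rectangular loop: P 1 -> 10 kPa, V 50 -> 120 mL, CCW
  V <- c(50, 120, 120, 50)
  P <- c(1, 1, 10, 10)
  w <- pressure_waveform(c(0, 100, 200, 300, 400), c(1, 1, 10, 10, 1))
  expect_equal(stroke_work(w, V, c(0, 100, 200, 300)), 9 * 70 / 1000,
               tolerance = 1e-12)

  # constant volume: zero work
  expect_equal(stroke_work(w, rep(80, 4), c(0, 100, 200, 300)), 0)

  # ellipse loop vs trapezoid oracle
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  V <- 85 + 35 * cos(th)
  P <- 8 + 7 * sin(th)
  tms <- seq(0, 780, length.out = 199)
  wave <- pressure_waveform(tms, P)
  expect_equal(stroke_work(wave, V, tms),
               trapezoid_work(V, P) / 1000, tolerance = 1e-9)
  expect_equal(stroke_work(wave, V, tms), pi * 35 * 7 / 1000, tolerance = 0.001)

  # open loop triggers forced closure with a warning
  expect_warning(stroke_work(w, c(50, 120, 120, 90), c(0, 100, 200, 300)),
                 "forcing closure")
})

test_that("total myocardial work integrates densities over the wall", {
  # uniform 5 kJ/m^3 over 150 mL of wall -> 0.75 J
  wm <- structure(data.frame(unit_id = 1:10, segment = 1:10,
                             region = "LV free wall",
                             work = 5, weight = 15000),  # mm^3 each
                  class = c("work_map", "data.frame"))
  attr(wm, "weight_type") <- "volume"
  expect_equal(as.numeric(total_myocardial_work(wm)), 0.75, tolerance = 1e-12)

  # equal positive and negative halves cancel
  wm$work <- rep(c(5, -5), 5)
  expect_equal(as.numeric(total_myocardial_work(wm)), 0)

  # random map vs direct-summation oracle
  set.seed(8)
  wm$work <- stats::rnorm(10)
  wm$weight <- stats::runif(10, 100, 5000)
  expect_equal(as.numeric(total_myocardial_work(wm)),
               sum(wm$work * wm$weight) / 1e6, tolerance = 1e-15)

  # surface-mode map needs a thickness
  attr(wm, "weight_type") <- "area"
  expect_error(total_myocardial_work(wm), "thickness")
  expect_equal(as.numeric(total_myocardial_work(wm, thickness = 10)),
               sum(wm$work * wm$weight * 10) / 1e6, tolerance = 1e-15)
})

test_that("efficiency is the stroke/total ratio and handles degenerate input", {
  expect_equal(work_efficiency(0.63, 0.90), 0.7)
  expect_equal(work_efficiency(0.9, 0.9), 1.0)
  expect_warning(eta <- work_efficiency(1, 0), "undefined")
  expect_true(is.na(eta))
})

test_that("energy-consistent bookkeeping keeps efficiency at or below one", {
  for (sev in c(0, 0.5, 0.95)) {
    qm <- quick_motion(severity = sev)
    au <- synth_energy_audit(qm$motion, qm$params)
    expect_lte(au$efficiency, 1)
    expect_gt(au$efficiency, 0.4)
  }
  # CRT state too
  qc <- quick_motion(severity = 0.9, state = "CRT")
  expect_lte(synth_energy_audit(qc$motion, qc$params)$efficiency, 1)
})

test_that("volume-equivalent-radius total work matches PV work under uniform scaling", {
  qm <- quick_motion(severity = 0)
  wall <- generic_waveform(peak_kpa = qm$params$peak_kpa,
                           edp_kpa = qm$params$edp_kpa)
  tw <- energy_total_work(qm$motion$surface, wall)
  sw <- stroke_work(wall, cavity_volumes(qm$motion$surface),
                    qm$motion$surface$frame_times)
  expect_equal(tw, sw, tolerance = 0.005)
})
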