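test_that("patch areas match analytic values and are isometry invariant", {
  # unit right triangle
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  arr <- array(rep(t(v), 4), c(4, 3, 4))
  arr <- array(rep(as.vector(v), 4), c(4, 3, 4))
  surf <- endocardial_surface(arr, rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3)),
                              c(0, 1, 2, 3), apex_point = c(0, 0, 0),
                              base_centroid = c(1, 1, 1) / 3,
                              long_axis = c(1, 1, 1) / sqrt(3), validate = FALSE)
  expect_equal(patch_areas(surf, 1)[1], 0.5, tolerance = 1e-12)

  # icosphere total area vs 4 pi r^2
  ico <- icosphere(radius = 30, subdivisions = 4)
  expect_equal(sum(patch_areas(ico, 1)), 4 * pi * 30^2, tolerance = 0.01)

  # rigid motion leaves areas unchanged
  m <- quick_motion(severity = 0.6)$motion$surface
  moved <- rigid_transform(m)
  for (k in c(1, 10, 25)) {
    expect_equal(patch_areas(moved, k), patch_areas(m, k), tolerance = 1e-9)
  }
})

test_that("degenerate triangles get zero area with a warning, not dropped", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  arr <- array(rep(as.vector(v), 4), c(4, 3, 4))
  surf <- endocardial_surface(arr, rbind(c(1, 2, 3), c(1, 2, 4)), c(0, 1, 2, 3),
                              apex_point = c(0, 0, 0), base_centroid = c(1, 0.5, 0),
                              long_axis = c(1, 0, 0), validate = FALSE)
  expect_warning(a <- patch_areas(surf, 1), "degenerate")
  expect_identical(length(a), 2L)
  expect_identical(a[1], 0)
})

test_that("cavity volume matches analytic sphere, hemisphere and voxel oracle", {
  ico <- icosphere(radius = 30, subdivisions = 4)
  expect_equal(cavity_volume(ico, 1), 4 / 3 * pi * 27, tolerance = 0.01)

  cup <- cap_mesh(radius = 30, phi_max = pi / 2)
  expect_equal(cavity_volume(cup, 1), 2 / 3 * pi * 27, tolerance = 0.01)

  star <- star_mesh()
  expect_equal(cavity_volume(star, 1), voxel_volume(star, 1, h = 0.5),
               tolerance = 0.02)

  # rigid-motion invariance
  m <- quick_motion(severity = 0.5)$motion$surface
  expect_equal(cavity_volumes(rigid_transform(m)), cavity_volumes(m),
               tolerance = 1e-9)
})

test_that("AHA assignment follows the sector/level convention and partitions the surface", {
  p <- synth_patient_params()
  mesh <- make_lv_mesh(p)
  segmap <- assign_aha_segments(mesh)

  # partition: every triangle assigned, segment areas sum to the total
  expect_true(all(segmap$patch_segment %in% 1:17))
  a <- patch_areas(mesh, 1)
  seg_tot <- sum(vapply(1:17, function(s) sum(a[segmap$patch_segment == s]),
                        numeric(1)))
  expect_equal(seg_tot, sum(a), tolerance = 1e-12)

  # septal-labelled triangles carry only the fixed septal ids
  septal <- segmap$patch_segment %in% segmap$septal_ids
  expect_true(all(segmap$segment_region[segmap$patch_segment[septal]] == "septum"))
  expect_identical(segmap$septal_ids, c(2L, 3L, 8L, 9L, 14L))

  # a centroid at 50% of the axis in the inferoseptal direction -> segment 9
  v <- mesh$vertices[, , 1]
  tr <- mesh$triangles
  cen <- (v[tr[, 1], ] + v[tr[, 2], ] + v[tr[, 3], ]) / 3
  L <- 90
  f <- 1 - cen[, 3] / L
  theta <- atan2(cen[, 2], cen[, 1]) * 180 / pi
  mid_infsep <- which(f > 0.45 & f < 0.55 & theta > 100 & theta < 140)
  expect_true(length(mid_infsep) > 0)
  expect_true(all(segmap$patch_segment[mid_infsep] == 9L))

  # centroids at >= 95% of the axis length -> apex cap (17)
  expect_true(all(segmap$patch_segment[f >= 0.95] == 17L))

  # deterministic
  expect_identical(segmap$patch_segment,
                   assign_aha_segments(mesh)$patch_segment)
})

test_that("degenerate long axis and bad anterior reference are rejected", {
  p <- synth_patient_params()
  mesh <- make_lv_mesh(p)
  bad <- mesh
  bad$base_centroid <- bad$apex_point
  expect_error(assign_aha_segments(bad), "degenerate")
  expect_error(assign_aha_segments(mesh, anterior_ref = c(0, 0, 1)), "parallel")
})

test_that("segment radius fits recover planted sphere and spheroid geometry", {
  set.seed(42)
  # points on a sphere of radius 25
  n <- 150
  z <- runif(n, -20, 20)
  th <- runif(n, 0, 2 * pi)
  rho <- sqrt(25^2 - z^2)
  pts <- cbind(rho * cos(th), rho * sin(th), z)
  fit <- fit_segment_radii(pts, c(0, 0, 1))
  expect_equal(fit$r_circ, 25, tolerance = 0.1 / 25)
  expect_equal(fit$r_long, 25, tolerance = 0.1 / 25)

  # prolate spheroid a = 25, b = 50, equatorial band: r_circ = a and
  # r_long = b^2/a (meridional curvature radius at the equator)
  tpar <- runif(n, pi / 2 - 0.3, pi / 2 + 0.3)
  pts2 <- cbind(25 * sin(tpar) * cos(th), 25 * sin(tpar) * sin(th), 50 * cos(tpar))
  fit2 <- fit_segment_radii(pts2, c(0, 0, 1))
  expect_equal(fit2$r_circ, 25, tolerance = 0.5 / 25)
  expect_equal(fit2$r_long, 50^2 / 25, tolerance = 0.05)

  # noisy sphere: radii recovered within 1% (fixed-seed Monte Carlo)
  noisy <- pts * (1 + matrix(rnorm(3 * n, 0, 0.1 / 25), n, 3))
  fit3 <- fit_segment_radii(noisy, c(0, 0, 1))
  expect_equal(fit3$r_circ, 25, tolerance = 0.01)
  expect_equal(fit3$r_long, 25, tolerance = 0.01)

  # effective radius below both inputs on every fit
  expect_lt(effective_radius(fit2$r_circ, fit2$r_long),
            min(fit2$r_circ, fit2$r_long))
})

test_that("degenerate point sets fall back to a flagged sphere fit", {
  set.seed(1)
  th <- runif(80, 0, 2 * pi)
  # cylinder: no longitudinal curvature information at all
  pts <- cbind(25 * cos(th), 25 * sin(th), runif(80, -10, 10))
  fit <- fit_segment_radii(pts, c(0, 0, 1))
  expect_true(fit$sphere_fallback)
  expect_identical(fit$r_circ, fit$r_long)
  expect_error(fit_segment_radii(pts[1:5, ], c(0, 0, 1)), "at least 9")
})

test_that("effective radius formula and limits", {
  expect_identical(effective_radius(20, 20), 10)
  expect_identical(effective_radius(30, 60), 20)
  # monotone approach to r_circ as r_long grows
  r <- effective_radius(25, c(1e2, 1e4, 1e8))
  expect_true(all(diff(r) > 0))
  expect_equal(r[3], 25, tolerance = 1e-5)
  expect_error(effective_radius(-1, 10), "positive")
})

test_that("wall thickness tables validate and conserve wall volume in incompressible mode", {
  h <- segment_wall_thickness(10, n_frames = 5)
  expect_equal(dim(h), c(17L, 5L))
  expect_true(all(h == 10))

  areas <- matrix(100, 17, 2)
  areas[, 2] <- 80  # segment areas shrink by 0.8
  hi <- segment_wall_thickness(10, 2, segment_areas = areas, incompressible = TRUE)
  expect_equal(hi[, 2], rep(12.5, 17))  # h scales by 1.25

  expect_error(segment_wall_thickness(-1), "positive")
  expect_error(segment_wall_thickness(c(rep(8, 16), NA)), "missing")
})
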