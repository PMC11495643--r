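make_map <- function(work, weight = rep(1, length(work)),
                     region = rep("LV free wall", length(work)),
                     weight_type = "volume", method = "P_gen") {
  wm <- data.frame(unit_id = seq_along(work), segment = seq_along(work),
                   region = region, work = work, weight = weight,
                   stringsAsFactors = FALSE)
  attr(wm, "method") <- method
  attr(wm, "state") <- "LBBB"
  attr(wm, "weight_type") <- weight_type
  attr(wm, "resolution") <- "patch"
  class(wm) <- c("work_map", "data.frame")
  wm
}

test_that("COVW is dispersion over mean, scale invariant", {
  expect_equal(covw(make_map(rep(2, 6))), 0)
  expect_equal(covw(make_map(c(1, 3))), 0.5)  # population SD 1 / mean 2

  set.seed(4)
  wm <- make_map(stats::rnorm(40, 3, 1), weight = stats::runif(40, 1, 5))
  expect_equal(covw(wm), {
    m <- sum(wm$work * wm$weight) / sum(wm$weight)
    sqrt(sum(wm$weight * (wm$work - m)^2) / sum(wm$weight)) / m
  }, tolerance = 1e-12)
  wm2 <- wm; wm2$work <- wm$work * 17.3
  expect_equal(covw(wm2), covw(wm), tolerance = 1e-12)

  expect_warning(v <- covw(make_map(c(-1, 1))), "undefined")
  expect_true(is.na(v))
})

test_that("negative-work fraction is the weighted share below zero", {
  expect_equal(negative_work_fraction(make_map(c(1, 2, 3))), 0)
  expect_equal(negative_work_fraction(make_map(c(-1, -2, 1), weight = c(1, 1, 2))), 0.5)

  # brute-force enumeration oracle on a random weighted map
  set.seed(12)
  wm <- make_map(stats::rnorm(100), weight = stats::runif(100, 0.5, 4))
  expect_equal(negative_work_fraction(wm),
               sum(wm$weight[wm$work < 0]) / sum(wm$weight), tolerance = 1e-15)

  # monotone non-increasing as a positive constant is added
  f <- vapply(c(0, 0.3, 0.8, 2), function(c) {
    wm2 <- wm; wm2$work <- wm$work + c
    negative_work_fraction(wm2)
  }, numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("high-work fraction uses the per-map weighted upper quartile", {
  expect_equal(high_work_fraction(make_map(1:8)), 0.25)
  expect_equal(high_work_fraction(make_map(rep(4, 10))), 0)  # nothing above

  # sort-and-accumulate weighted-quantile oracle
  set.seed(21)
  wm <- make_map(stats::rnorm(60), weight = stats::runif(60, 0.5, 3))
  o <- order(wm$work)
  cw <- cumsum(wm$weight[o]) / sum(wm$weight)
  thr <- wm$work[o][which(cw >= 0.75)[1]]
  expect_equal(high_work_fraction(wm),
               sum(wm$weight[wm$work > thr]) / sum(wm$weight), tolerance = 1e-15)
})

test_that("septal metrics are computed over septal segments only", {
  qm <- quick_motion(severity = 0.8)
  surf <- qm$motion$surface
  segmap <- assign_aha_segments(surf)
  strain <- compute_rsct(surf)
  stress <- build_stress_field("P_gen", generic_waveform(), surf$frame_times)
  wm <- compute_work_map(strain, stress, segmap, weight = "volume", thickness = 8)
  sept <- wm[wm$segment %in% c(2, 3, 8, 9, 14), ]
  expect_equal(negative_work_fraction(wm, "septum"),
               sum(sept$weight[sept$work < 0]) / sum(sept$weight),
               tolerance = 1e-15)
  # all fractions within [0, 1]
  for (r in c("LV", "septum", "LV free wall")) {
    f <- negative_work_fraction(wm, r)
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("metric deltas are baseline minus post with antisymmetry", {
  reg3 <- c("septum", "LV free wall", "septum")
  qb <- regional_work_metrics(make_map(c(-1, 2, 3), region = reg3))
  qp <- regional_work_metrics(make_map(c(1, 2, 3), region = reg3))
  d <- delta_metric(qb, qp)
  expect_equal(unname(d["delta_f_lvnw"]),
               qb$f_lvnw - qp$f_lvnw)
  expect_equal(delta_metric(qb, qb),
               c(delta_covw = 0, delta_f_lvnw = 0, delta_f_stnw = 0,
                 delta_f_lvhw = 0))
  expect_equal(delta_metric(qp, qb), -d)

  # a septal fraction falling 0.28 -> 0.12 gives a reduction of +0.16
  a <- qb; a$f_stnw <- 0.28
  b <- qp; b$f_stnw <- 0.12
  expect_equal(unname(delta_metric(a, b)["delta_f_stnw"]), 0.16)

  qx <- regional_work_metrics(make_map(c(1, 2), region = c("septum", "LV free wall"),
                                       method = "P_LHC"))
  expect_error(delta_metric(qb, qx), "different methods")
})
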