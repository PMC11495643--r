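#' Signed stress-strain loop area
#'
#' Work density of one unit over one cardiac cycle as the signed area
#' enclosed by its stress-strain loop, `W = -contour integral of sigma
#' d(epsilon)`, computed by the shoelace formula with strain on the
#' abscissa and stress on the ordinate. Counter-clockwise loops (shortening
#' at high stress, re-lengthening at low stress) are positive: work
#' performed by the myocardium. Clockwise loops are negative: work done on
#' the myocardium. Self-intersecting figure-8 loops yield the net signed
#' area of their lobes. The loop is closed by appending the first sample.
#'
#' @param strain unitless strain samples over one cycle.
#' @param stress stress samples (kPa), same length.
#' @return Signed work density in kPa (equivalently kJ/m^3).
#' @export
loop_area <- function(strain, stress) {
  n <- length(strain)
  if (length(stress) != n) stop("strain and stress must have equal length")
  if (n < 3L) stop("need at least 3 samples to form a loop")
  x <- c(strain, strain[1])
  y <- c(stress, stress[1])
  0.5 * sum(x[-(n + 1)] * y[-1] - x[-1] * y[-(n + 1)])
}

#' Map of signed regional work densities
#'
#' Computes the stress-strain loop area for every unit of a strain field
#' (patch or AHA-segment resolution) against a per-segment stress field,
#' and attaches region labels and area or volume weights for the regional
#' metrics.
#'
#' @param strain a `strain_field` (from [compute_rsct()] or
#'   [segment_average_strain()]).
#' @param stress a `stress_field` on the same frame time base.
#' @param segmap an [assign_aha_segments()] result.
#' @param weight `"area"` (endocardial surface mode, mm^2 weights, the
#'   default for simplified estimates) or `"volume"` (wall-volume mode,
#'   weight = endocardial area x local wall thickness, mm^3).
#' @param thickness thickness specification (see
#'   [segment_wall_thickness()]); required for volume weights.
#' @param state optional state label (`"LBBB"`, `"CRT"`, ...).
#' @return Object of class `work_map`: a data frame with columns
#'   `unit_id`, `segment`, `region`, `work` (kPa), `weight`; attributes
#'   `method`, `state`, `weight_type`, `resolution`.
#' @export
compute_work_map <- function(strain, stress, segmap,
                             weight = c("area", "volume"),
                             thickness = NULL, state = NA_character_) {
  weight <- match.arg(weight)
  stopifnot(inherits(strain, "strain_field"), inherits(stress, "stress_field"))
  if (length(strain$frame_times) != length(stress$frame_times) ||
      any(abs(strain$frame_times - stress$frame_times) > 1e-9))
    stop("strain and stress fields are on different time bases")
  if (strain$resolution == "patch") {
    seg <- segmap$patch_segment[strain$unit_ids]
  } else {
    seg <- strain$unit_ids
  }
  nunit <- nrow(strain$values)
  w <- numeric(nunit)
  for (i in seq_len(nunit)) {
    w[i] <- loop_area(strain$values[i, ], stress$values[seg[i], ])
  }
  wt <- strain$ref_weight
  if (weight == "volume") {
    if (is.null(thickness)) stop("volume weights require a wall thickness")
    h <- segment_wall_thickness(thickness, 1L)[, 1]
    wt <- wt * h[seg]
  }
  if (any(wt <= 0)) stop("non-positive weights in work map")
  out <- data.frame(unit_id = strain$unit_ids,
                    segment = seg,
                    region = segmap$segment_region[seg],
                    work = w,
                    weight = wt,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- stress$method
  attr(out, "state") <- state
  attr(out, "weight_type") <- weight
  attr(out, "resolution") <- strain$resolution
  class(out) <- c("work_map", "data.frame")
  out
}

#' Global LV stroke work from the pressure-volume loop
#'
#' Signed area of the PV loop (volume abscissa, pressure ordinate,
#' counter-clockwise positive) converted to joules (kPa x mL = mJ). A loop
#' whose first and last volumes disagree beyond 1% of the volume range is
#' force-closed with a warning.
#'
#' @param pressure a [pressure_waveform()].
#' @param volumes cavity volumes in mL, one per element of `times`.
#' @param times ms; the frame times of `volumes`.
#' @return Stroke work in joules.
#' @export
stroke_work <- function(pressure, volumes, times) {
  P <- resample_waveform(pressure, times)
  n <- length(volumes)
  if (length(times) != n) stop("volumes and times must have equal length")
  gap <- abs(volumes[n] - volumes[1])
  if (gap > 0.01 * max(diff(range(volumes)), 1e-12))
    warning("PV loop is open (|dV| = ", signif(gap, 3), " mL); forcing closure")
  0.5 * sum(c(volumes, volumes[1])[-(n + 1)] * c(P, P[1])[-1] -
              c(volumes, volumes[1])[-1] * c(P, P[1])[-(n + 1)]) / 1000  # mJ -> J
}

#' Total LV myocardial work
#'
#' Integrates a work-density map over the wall: `sum(work_i * weight_i)`
#' with volume weights (kPa x mm^3 = uJ, converted to J). Surface-mode maps
#' must carry a thickness so that weight = patch area x thickness; this
#' thin-wall conversion is an approximation and is flagged in the result's
#' `mode` attribute.
#'
#' @param workmap a [compute_work_map()] result with volume weights, or
#'   area weights plus `thickness`.
#' @param thickness optional thickness specification used to convert an
#'   area-weighted map to wall volume.
#' @return Total myocardial work in joules.
#' @export
total_myocardial_work <- function(workmap, thickness = NULL) {
  stopifnot(inherits(workmap, "work_map"))
  wt <- workmap$weight
  if (attr(workmap, "weight_type") == "area") {
    if (is.null(thickness))
      stop("surface-mode work map needs a thickness to integrate to joules")
    h <- segment_wall_thickness(thickness, 1L)[, 1]
    wt <- wt * h[workmap$segment]
  }
  out <- sum(workmap$work * wt) / 1e6  # kPa*mm^3 = uJ -> J
  attr(out, "mode") <- if (attr(workmap, "weight_type") == "area")
    "surface-thickness approximation" else "volume"
  out
}

#' Volume-equivalent ventricular radius
#'
#' The radius convention `r_E = 3V/A` under which the thin-wall work
#' density integrated over the wall reproduces the pressure-volume work
#' exactly for any shape deforming by uniform scaling (for a sphere it is
#' the actual radius). Used for the energy-consistent total-work estimate.
#'
#' @param volume_ml cavity volume, mL.
#' @param area_mm2 endocardial surface area, mm^2.
#' @return Radius in mm (vectorised).
#' @export
volume_equivalent_radius <- function(volume_ml, area_mm2) {
  if (any(area_mm2 <= 0)) stop("surface area must be positive")
  3 * volume_ml * 1000 / area_mm2
}

#' Energy-consistent total myocardial work
#'
#' Total wall work over one cycle using the spatially uniform thin-wall
#' stress `sigma(t) = P(t) * r_E(t) / (2 h)` with the volume-equivalent
#' radius `r_E = 3V/A`. Under uniform scaling of the chamber this
#' integrates to the pressure-volume work exactly, which makes it the
#' appropriate denominator for mechanical efficiency; dyssynchronous
#' (non-uniform) motion perturbs the identity by a few percent.
#'
#' In this convention the wall thickness cancels between the stress
#' (`~1/h`) and the wall-volume weight (`~h`), so none is needed.
#'
#' @param surface an [endocardial_surface()].
#' @param pressure a [pressure_waveform()] of the wall (chamber) pressure.
#' @return Total myocardial work in joules.
#' @export
energy_total_work <- function(surface, pressure) {
  ft <- surface$frame_times
  strain <- compute_rsct(surface)
  V <- cavity_volumes(surface)
  A <- vapply(seq_along(ft), function(k)
    sum(suppressWarnings(patch_areas(surface, k))), numeric(1))
  P <- resample_waveform(pressure, ft)
  sig <- P * volume_equivalent_radius(V, A) / 2  # kPa * mm; h cancels
  tw <- 0
  for (i in seq_len(nrow(strain$values))) {
    tw <- tw + loop_area(strain$values[i, ], sig) * strain$ref_weight[i]
  }
  tw / 1e6  # kPa*mm^3 -> J
}

#' Mechanical efficiency of the ventricle
#'
#' `eta = stroke work / total myocardial work`, the fraction of the work
#' performed by the wall that is delivered to the circulation. Undefined
#' (NA with a warning) when total work is not positive.
#'
#' @param stroke stroke work, J.
#' @param total total myocardial work, J.
#' @return Efficiency, unitless.
#' @export
work_efficiency <- function(stroke, total) {
  if (!is.finite(total) || total <= 0) {
    warning("total myocardial work is not positive; efficiency undefined")
    return(NA_real_)
  }
  as.numeric(stroke) / as.numeric(total)
}
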