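#' @keywords internal
KPA_PER_MMHG <- 0.133322

#' Left-ventricular pressure waveform
#'
#' One cardiac cycle of LV pressure referenced to the R-wave. Pressures
#' supplied in mmHg are converted to kPa (1 mmHg = 0.133322 kPa), the
#' internal unit for all stress and work quantities.
#'
#' @param times ms from the R-wave, non-negative, strictly increasing,
#'   starting at 0.
#' @param pressures pressures at `times`, non-negative.
#' @param units `"kPa"` or `"mmHg"`.
#' @param label provenance label: `"measured"`, `"generic"` or
#'   `"generic_scaled"`.
#' @return Object of class `pressure_waveform`: `times`, `pressures` (kPa),
#'   `peak` (kPa), `edp` (end-diastolic pressure, the value at t = 0).
#' @export
pressure_waveform <- function(times, pressures,
                              units = c("kPa", "mmHg"),
                              label = "measured") {
  units <- match.arg(units)
  times <- as.numeric(times)
  pressures <- as.numeric(pressures)
  if (length(times) != length(pressures) || length(times) < 4L)
    stop("times and pressures must be equal length (>= 4 samples)")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and be strictly increasing")
  if (any(pressures < 0)) stop("pressures must be non-negative")
  if (units == "mmHg") pressures <- pressures * KPA_PER_MMHG
  structure(list(times = times, pressures = pressures,
                 label = label, peak = max(pressures), edp = pressures[1]),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("Pressure waveform (%s): %d samples over %g ms, peak %.2f kPa, EDP %.2f kPa\n",
              x$label, length(x$times), max(x$times), x$peak, x$edp))
  invisible(x)
}

#' Generic LV pressure waveform
#'
#' Smooth parametric stand-in for a normal-hemodynamics LV pressure trace:
#' end-diastolic baseline, raised-cosine isovolumic rise to the systolic
#' peak, raised-cosine relaxation to a diastolic minimum, and a slow
#' raised-cosine return to the end-diastolic pressure so the cycle closes.
#' The maximum equals `peak_kpa` exactly at `t_peak` and the value at t = 0
#' equals `edp_kpa` exactly. Defaults correspond to a normal adult LV:
#' peak 16 kPa (120 mmHg), EDP 1.07 kPa (8 mmHg), RR 800 ms.
#'
#' @param peak_kpa systolic peak pressure, kPa; must exceed `edp_kpa`.
#' @param edp_kpa end-diastolic pressure, kPa (>= 0).
#' @param t_rise ms, onset of the pressure upstroke.
#' @param t_peak ms, time of the systolic peak.
#' @param t_relax ms, end of relaxation (diastolic minimum reached).
#' @param rr_ms RR interval, ms.
#' @param diastolic_kpa diastolic minimum pressure, kPa; defaults to
#'   `min(edp_kpa, 0.67)` (about 5 mmHg).
#' @param dt sampling interval, ms.
#' @return A `pressure_waveform` labelled `"generic"`.
#' @export
generic_waveform <- function(peak_kpa = 16, edp_kpa = 1.07,
                             t_rise = 50, t_peak = 300, t_relax = 550,
                             rr_ms = 800, diastolic_kpa = min(edp_kpa, 0.67),
                             dt = 1) {
  if (peak_kpa <= edp_kpa || edp_kpa < 0)
    stop("need peak > EDP >= 0")
  if (!(0 <= t_rise && t_rise < t_peak && t_peak < t_relax && t_relax <= rr_ms))
    stop("inconsistent timings: need 0 <= t_rise < t_peak < t_relax <= rr_ms")
  tt <- seq(0, rr_ms, by = dt)
  p <- numeric(length(tt))
  p[tt < t_rise] <- edp_kpa
  i <- tt >= t_rise & tt <= t_peak
  p[i] <- edp_kpa + (peak_kpa - edp_kpa) *
    0.5 * (1 - cos(pi * (tt[i] - t_rise) / (t_peak - t_rise)))
  i <- tt > t_peak & tt <= t_relax
  p[i] <- diastolic_kpa + (peak_kpa - diastolic_kpa) *
    0.5 * (1 + cos(pi * (tt[i] - t_peak) / (t_relax - t_peak)))
  i <- tt > t_relax
  p[i] <- edp_kpa + (diastolic_kpa - edp_kpa) *
    0.5 * (1 + cos(pi * (tt[i] - t_relax) / (rr_ms - t_relax)))
  pressure_waveform(tt, p, units = "kPa", label = "generic")
}

#' Scale a waveform to a target peak pressure
#'
#' Multiplies every sample by `target_peak / peak`, used to match a generic
#' waveform to a patient-specific peak pressure from catheterization.
#'
#' @param wave a `pressure_waveform` with positive peak.
#' @param target_peak target systolic peak, kPa, > 0.
#' @return A `pressure_waveform` labelled `"generic_scaled"`.
#' @export
scale_waveform_to_peak <- function(wave, target_peak) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (target_peak <= 0) stop("target peak must be positive")
  if (wave$peak <= 0) stop("waveform peak must be positive")
  out <- pressure_waveform(wave$times, wave$pressures * target_peak / wave$peak,
                           units = "kPa", label = "generic_scaled")
  out
}

#' Resample a pressure waveform onto strain frame times
#'
#' Linear interpolation onto the requested times; both pressure and strain
#' are referenced to the R-wave, so no further alignment is applied.
#' Requesting a time outside the recorded cycle is an error.
#'
#' @param wave a `pressure_waveform`.
#' @param times ms, within `range(wave$times)`.
#' @return Numeric vector of pressures (kPa) at `times`.
#' @export
resample_waveform <- function(wave, times) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (min(times) < min(wave$times) - 1e-9 || max(times) > max(wave$times) + 1e-9)
    stop("requested times fall outside the recorded pressure cycle")
  stats::approx(wave$times, wave$pressures, xout = times, rule = 2)$y
}

#' Read a pressure trace from CSV
#'
#' Expects two columns, `time_ms` and `pressure`; units are taken from a
#' `pressure_kpa`/`pressure_mmhg` column name or from the `units` argument.
#'
#' @param path CSV file path.
#' @param units override units (`"kPa"` or `"mmHg"`); by default inferred
#'   from the pressure column name, falling back to kPa.
#' @return A `pressure_waveform` labelled `"measured"`.
#' @export
read_pressure_csv <- function(path, units = NULL) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  tcol <- grep("time", names(d), value = TRUE)[1]
  pcol <- grep("pressure", names(d), value = TRUE)[1]
  if (is.na(tcol) || is.na(pcol))
    stop("pressure CSV needs a time column and a pressure column")
  if (is.null(units))
    units <- if (grepl("mmhg", pcol)) "mmHg" else "kPa"
  pressure_waveform(d[[tcol]], d[[pcol]], units = units, label = "measured")
}
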