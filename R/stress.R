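#' Names of the five stress surrogate methods
#' @export
WORK_METHODS <- c("P_LHC", "WS_ED", "WS_TV", "P_gen", "P_gen_scaled")

#' Laplace-law wall stress
#'
#' Thin-wall estimate of myocardial wall stress from cavity pressure and
#' segmental shape: `sigma = P * r / (2 h)`. With `P` in kPa and `r`, `h`
#' both in mm the millimetres cancel and the stress is in kPa.
#'
#' @param P cavity pressure, kPa (vectorised).
#' @param r segmental (effective) radius, mm, > 0.
#' @param h segmental wall thickness, mm, > 0.
#' @return Wall stress in kPa.
#' @export
laplace_stress <- function(P, r, h) {
  if (any(r <= 0) || any(h <= 0)) stop("radius and thickness must be positive")
  P * r / (2 * h)
}

#' Per-segment stress time series for one surrogate method
#'
#' Builds the stress field used on the ordinate of the stress-strain loop
#' for one of five surrogate methods:
#' \describe{
#'   \item{P_LHC}{the measured (catheter) LV pressure applied identically
#'     to every segment;}
#'   \item{WS_ED}{Laplace wall stress with end-diastolic shape:
#'     `sigma_s(t) = P(t) * r_eff_s(ED) / (2 h_s(ED))`, i.e. a constant
#'     per-segment scaling of the pressure;}
#'   \item{WS_TV}{Laplace wall stress with time-varying shape:
#'     `sigma_s(t) = P(t) * r_eff_s(t) / (2 h_s(t))`;}
#'   \item{P_gen}{a generic normal pressure waveform applied to every
#'     segment;}
#'   \item{P_gen_scaled}{the generic waveform scaled to the patient's peak
#'     pressure.}
#' }
#' The pressure is resampled onto the strain frame times by linear
#' interpolation (both are referenced to the R-wave).
#'
#' @param method one of [WORK_METHODS].
#' @param pressure a [pressure_waveform()]; for `P_gen`/`P_gen_scaled` pass
#'   the generic (or scaled generic) waveform.
#' @param frame_times ms; the strain time base.
#' @param geometry a [segment_geometry()] object; required for `WS_ED` and
#'   `WS_TV` (`WS_TV` needs per-frame geometry).
#' @return Object of class `stress_field`: `method`, matrix `values`
#'   (17 x n_frames, kPa), `frame_times`.
#' @export
build_stress_field <- function(method, pressure, frame_times, geometry = NULL) {
  method <- match.arg(method, WORK_METHODS)
  stopifnot(inherits(pressure, "pressure_waveform"))
  P <- resample_waveform(pressure, frame_times)
  nf <- length(frame_times)
  if (method %in% c("P_LHC", "P_gen", "P_gen_scaled")) {
    vals <- matrix(P, 17L, nf, byrow = TRUE)
  } else {
    if (is.null(geometry))
      stop("method ", method, " requires segment geometry")
    if (method == "WS_ED") {
      fac <- geometry$r_eff[, 1] / (2 * geometry$h[, 1])
      vals <- outer(fac, P)
    } else {
      if (ncol(geometry$r_eff) != nf)
        stop("WS_TV requires per-frame geometry on the strain time base")
      vals <- geometry$r_eff / (2 * geometry$h) * matrix(P, 17L, nf, byrow = TRUE)
    }
  }
  structure(list(method = method, values = vals, frame_times = frame_times),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("Stress field [%s]: 17 segments x %d frames, range %.2f..%.2f kPa\n",
              x$method, ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
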