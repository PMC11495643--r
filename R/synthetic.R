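# Per-segment baseline activation fractions for a left bundle branch block
# pattern: septum and apex activate first, the LV free (lateral) wall last.
# Scaled by severity * act_max_ms to give activation times in ms.
LBBB_ACTIVATION_FRACTION <- c(
  0.55, 0.10, 0.10, 0.50, 0.90, 0.90,   # basal ring
  0.50, 0.05, 0.05, 0.45, 1.00, 0.95,   # mid ring
  0.45, 0.00, 0.40, 0.85,               # apical ring
  0.30)                                 # apex

#' Parameters of one synthetic dyssynchronous-ventricle patient
#'
#' Bundles the geometric, activation, strain-pattern, pressure and noise
#' parameters consumed by [make_lv_mesh()], [make_motion()] and
#' [make_pressure()]. `severity` in `[0, 1]` controls the electromechanical
#' dyssynchrony: 0 reproduces a synchronous contraction; increasing values
#' delay free-wall activation (up to `act_max_ms`), suppress early-septal
#' shortening, add late-systolic septal rebound stretch, and add free-wall
#' pre-stretch with augmented delayed shortening.
#'
#' @param axis_length apex-to-base length, mm.
#' @param base_radius equatorial endocardial radius, mm.
#' @param wall_thickness segmental wall thickness, mm (scalar or length 17).
#' @param severity dyssynchrony severity in `[0, 1]`.
#' @param act_max_ms free-wall activation delay at severity 1, ms.
#' @param emd_ms electromechanical delay from activation to shortening
#'   onset, ms.
#' @param shortening peak systolic area-strain shortening amplitude
#'   (unitless, positive).
#' @param rebound_amp septal rebound-stretch amplitude at severity 1.
#' @param prestretch_amp free-wall pre-stretch amplitude at severity 1.
#' @param suppression fraction of early-septal shortening lost at
#'   severity 1.
#' @param late_gain fractional augmentation of late free-wall shortening
#'   at severity 1 (the late-activated hyperwork gain).
#' @param peak_kpa,edp_kpa systolic peak and end-diastolic pressure, kPa.
#' @param rr_ms RR interval, ms.
#' @param n_frames frames per cycle (frame 1 = end-diastole).
#' @param n_theta,n_phi mesh resolution: circumferential and longitudinal
#'   vertex counts.
#' @param patch_noise_sd log-normal vertex-scale noise sd applied to the
#'   motion (multiplicative on patch areas); 0 for noise-free motion.
#' @param pressure_noise_sd additive pressure measurement noise sd, kPa.
#' @param crt_factor factor by which acute CRT compresses the activation
#'   dispersion (and with it the dyssynchrony distortions).
#' @param seed RNG seed for this patient's noise streams.
#' @return List of class `synth_patient_params`.
#' @export
synth_patient_params <- function(axis_length = 90, base_radius = 30,
                                 wall_thickness = 8,
                                 severity = 0.7, act_max_ms = 150,
                                 emd_ms = 40,
                                 shortening = 0.20, rebound_amp = 0.30,
                                 prestretch_amp = 0.10,
                                 suppression = 0.7, late_gain = 0.3,
                                 peak_kpa = 16, edp_kpa = 1.07,
                                 rr_ms = 800, n_frames = 41,
                                 n_theta = 24, n_phi = 16,
                                 patch_noise_sd = 0.005,
                                 pressure_noise_sd = 0,
                                 crt_factor = 0.3, seed = 1L) {
  stopifnot(severity >= 0, severity <= 1,
            axis_length > 0, base_radius > 0, all(wall_thickness > 0))
  structure(as.list(environment()), class = "synth_patient_params")
}

#' Reference-frame truncated prolate spheroid LV mesh
#'
#' Triangulated endocardial surface of a truncated prolate spheroid: an
#' apex pole fan plus a latitude-longitude grid, truncated at 120 degrees
#' of polar angle so the open basal ring forms the single boundary loop.
#' Apex at the origin, long axis along +z.
#'
#' @param params a [synth_patient_params()] list (only the geometric
#'   fields are used).
#' @param n_frames_dummy number of (identical) frames to replicate the
#'   reference geometry into; mainly for testing static meshes.
#' @return An [endocardial_surface()] whose frames all hold the reference
#'   (end-diastolic) geometry.
#' @export
make_lv_mesh <- function(params = synth_patient_params(),
                         n_frames_dummy = 4L) {
  a <- params$base_radius
  L <- params$axis_length
  nt <- params$n_theta
  np <- params$n_phi
  phi_max <- 2 * pi / 3
  b <- L / (1 - cos(phi_max))
  ntri <- nt + 2 * nt * (np - 1)
  if (ntri < 200L)
    stop("mesh resolution too coarse for 17 AHA segments (need >= 200 triangles)")
  phi <- seq_len(np) * phi_max / np
  theta <- (seq_len(nt) - 1) * 2 * pi / nt
  verts <- matrix(0, 1 + np * nt, 3)
  vid <- function(i, j) 1L + (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  for (i in seq_len(np)) {
    rho <- a * sin(phi[i])
    z <- b * (1 - cos(phi[i]))
    verts[vid(i, 1):vid(i, nt), ] <- cbind(rho * cos(theta), rho * sin(theta), z)
  }
  tris <- matrix(0L, ntri, 3)
  k <- 1L
  for (j in seq_len(nt)) {               # apex fan
    tris[k, ] <- c(1L, vid(1, j), vid(1, j + 1)); k <- k + 1L
  }
  for (i in seq_len(np - 1)) {
    for (j in seq_len(nt)) {
      tris[k, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)); k <- k + 1L
      tris[k, ] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)); k <- k + 1L
    }
  }
  tt <- seq(0, params$rr_ms, length.out = max(4L, n_frames_dummy))
  arr <- array(rep(verts, length(tt)), c(nrow(verts), 3, length(tt)))
  surf <- endocardial_surface(arr, tris, tt,
                              apex_point = c(0, 0, 0),
                              base_centroid = c(0, 0, L),
                              long_axis = c(0, 0, 1))
  segmap <- assign_aha_segments(surf)
  if (length(unique(segmap$patch_segment)) != 17L)
    stop("mesh resolution leaves an AHA segment empty; refine n_theta/n_phi")
  surf
}

# Raised-cosine pulse rising 0 -> 1 over [on, on + rise], holding 1 until
# rel, then falling to 0 over [rel, rel + fall]. Vectorised over t.
.hold_pulse <- function(t, on, rise, rel, fall) {
  y <- numeric(length(t))
  i <- t >= on & t < on + rise
  y[i] <- 0.5 * (1 - cos(pi * (t[i] - on) / rise))
  y[t >= on + rise & t < rel] <- 1
  i <- t >= rel & t < rel + fall
  y[i] <- 0.5 * (1 + cos(pi * (t[i] - rel) / fall))
  y
}

# Symmetric raised-cosine bump on [t0, t1].
.bump <- function(t, t0, t1) {
  y <- numeric(length(t))
  i <- t >= t0 & t <= t1
  y[i] <- 0.5 * (1 - cos(2 * pi * (t[i] - t0) / (t1 - t0)))
  y
}

#' Synthetic dyssynchronous ventricular motion
#'
#' Deforms the reference mesh over one cardiac cycle according to a
#' per-patch prescribed area-strain pattern. Each AHA segment gets a target
#' strain curve: a shortening pulse whose onset is delayed by the segment's
#' activation time, held through systole and released during diastole. With
#' increasing severity, early-activated (septal) patches lose shortening
#' amplitude and gain a late-systolic rebound-stretch bump (placed in the
#' high-pressure window, which is what makes their stress-strain loops run
#' clockwise), while late-activated free-wall patches gain pre-stretch and
#' augmented delayed shortening. Within the septum the distortion is graded
#' smoothly (base to apex) so the negative-work fraction grows continuously
#' with severity. The `"CRT"` state multiplies the activation dispersion
#' and the severity-driven distortions by `crt_factor`.
#'
#' The prescribed per-patch areas are realized by a smooth per-vertex
#' similarity scaling about a mid-cavity point (exact for patches whose
#' vertices share a scale factor, approximate across segment borders); the
#' realized segment-average strain curves are therefore returned as ground
#' truth alongside the analytic prescription.
#'
#' @param mesh reference surface from [make_lv_mesh()].
#' @param params a [synth_patient_params()].
#' @param state `"LBBB"` or `"CRT"`.
#' @return List of class `synth_motion`: `surface` (time-resolved
#'   [endocardial_surface()]), `state`, `activation_ms` (per segment),
#'   `ground_truth` (list: `prescribed_segment_strain` and
#'   `realized_segment_strain`, 17 x n_frames; `severity_effective`).
#' @export
make_motion <- function(mesh, params, state = c("LBBB", "CRT")) {
  state <- match.arg(state)
  sev <- params$severity * if (state == "CRT") params$crt_factor else 1
  nf <- params$n_frames
  tt <- seq(0, params$rr_ms, length.out = nf)
  segmap <- assign_aha_segments(mesh)
  seg <- segmap$patch_segment
  tr <- mesh$triangles
  v0 <- mesh$vertices[, , 1]
  nv <- nrow(v0)
  ntri <- nrow(tr)

  frac <- LBBB_ACTIVATION_FRACTION
  act <- sev * params$act_max_ms * frac
  early <- pmax(0, 0.5 - frac) / 0.5
  late <- pmax(0, frac - 0.5) / 0.5

  # axial fraction from base for each patch centroid -> smooth grading g_p
  cen <- (v0[tr[, 1], ] + v0[tr[, 2], ] + v0[tr[, 3], ]) / 3
  u <- mesh$long_axis
  L <- sqrt(sum((mesh$base_centroid - mesh$apex_point)^2))
  fax <- 1 - pmin(pmax(as.vector((cen - matrix(mesh$apex_point, ntri, 3,
                                               byrow = TRUE)) %*% u) / L, 0), 1)
  g <- 0.45 + 0.55 * fax

  # per-patch prescribed strain curves
  rise <- 200; release_dur <- 180
  eps <- matrix(0, ntri, nf)
  for (s in 1:17) {
    idx <- which(seg == s)
    if (!length(idx)) next
    on_s <- params$emd_ms + act[s]
    rel_s <- 560 + 0.25 * act[s]
    Cs <- .hold_pulse(tt, on_s, rise, rel_s, release_dur)
    Rb <- .bump(tt, 310, 530)
    Pr <- .bump(tt, 40, 200)
    amp_p <- params$shortening *
      (1 - params$suppression * sev * early[s] * g[idx]) *
      (1 + params$late_gain * sev * late[s])
    r_p <- params$rebound_amp * sev * early[s] * g[idx]
    s_p <- params$prestretch_amp * sev * late[s]
    eps[idx, ] <- outer(-amp_p, Cs) + outer(r_p, Rb) +
      matrix(s_p, length(idx), 1) %*% matrix(Pr, 1, nf)
  }

  # vertex target strain: reference-area-weighted mean of incident patches
  e1 <- v0[tr[, 2], ] - v0[tr[, 1], ]
  e2 <- v0[tr[, 3], ] - v0[tr[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  aref <- 0.5 * sqrt(rowSums(cr^2))
  vidx <- as.vector(t(tr))
  wrep <- rep(aref, each = 3)
  wsum <- rowsum(wrep, vidx)[, 1]
  eps_v <- rowsum(eps[rep(seq_len(ntri), each = 3), , drop = FALSE] * wrep,
                  vidx) / wsum

  lam <- sqrt(pmax(1 + eps_v, 1e-6))
  if (params$patch_noise_sd > 0) {
    # no noise at either end of the cycle: both are the same cardiac phase
    set.seed(params$seed + if (state == "CRT") 500000L else 0L)
    noise <- matrix(exp(stats::rnorm(nv * (nf - 2), 0, params$patch_noise_sd)),
                    nv, nf - 2)
    lam[, -c(1, nf)] <- lam[, -c(1, nf)] * noise
  }
  c0 <- mesh$apex_point + 0.45 * L * u
  rel0 <- v0 - matrix(c0, nv, 3, byrow = TRUE)
  verts <- array(0, c(nv, 3, nf))
  for (k in seq_len(nf)) {
    verts[, , k] <- matrix(c0, nv, 3, byrow = TRUE) + rel0 * lam[, k]
  }
  surf <- endocardial_surface(verts, tr, tt,
                              apex_point = mesh$apex_point,
                              base_centroid = mesh$base_centroid,
                              long_axis = mesh$long_axis,
                              validate = FALSE)

  # ground truth: realized areas via the generator's own bookkeeping
  realized <- matrix(0, 17, nf)
  presc <- matrix(0, 17, nf)
  A <- matrix(0, ntri, nf)
  for (k in seq_len(nf)) {
    vk <- verts[, , k]
    d1 <- vk[tr[, 2], ] - vk[tr[, 1], ]
    d2 <- vk[tr[, 3], ] - vk[tr[, 1], ]
    A[, k] <- 0.5 * sqrt(
      (d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2])^2 +
        (d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3])^2 +
        (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])^2)
  }
  for (s in 1:17) {
    idx <- which(seg == s)
    w <- A[idx, 1]
    realized[s, ] <- colSums((A[idx, , drop = FALSE] / w - 1) * w) / sum(w)
    presc[s, ] <- colSums(eps[idx, , drop = FALSE] * w) / sum(w)
  }

  structure(list(surface = surf, state = state,
                 activation_ms = act,
                 ground_truth = list(prescribed_segment_strain = presc,
                                     realized_segment_strain = realized,
                                     severity_effective = sev)),
            class = "synth_motion")
}

#' Synthetic LV pressure for one patient state
#'
#' A [generic_waveform()] with the patient's peak and end-diastolic
#' pressure, optionally corrupted by additive measurement noise (clamped
#' non-negative), playing the role of the catheter recording.
#'
#' @param params a [synth_patient_params()].
#' @param state `"LBBB"` or `"CRT"` (same hemodynamics by default).
#' @return A `pressure_waveform` labelled `"measured"`.
#' @export
make_pressure <- function(params, state = c("LBBB", "CRT")) {
  state <- match.arg(state)
  w <- generic_waveform(peak_kpa = params$peak_kpa, edp_kpa = params$edp_kpa,
                        rr_ms = params$rr_ms)
  p <- w$pressures
  if (params$pressure_noise_sd > 0) {
    set.seed(params$seed + 900000L)
    p <- pmax(0, p + stats::rnorm(length(p), 0, params$pressure_noise_sd))
  }
  pressure_waveform(w$times, p, units = "kPa", label = "measured")
}

#' Energy bookkeeping for a synthetic patient state
#'
#' Generator-level energy audit for the energy-consistent mode. Total wall
#' work is the pressure-equilibrium part under the volume-equivalent-radius
#' convention ([energy_total_work()], which reproduces pressure-volume
#' work exactly under uniform chamber scaling) plus the work done against
#' a viscoelastic wall stress `mu * d(epsilon)/dt`, which is strictly
#' dissipative (`mu * integral (d(epsilon)/dt)^2 dt >= 0` per patch).
#' Stroke work is the cavity pressure-volume loop area. Because every
#' joule of stroke work must first be performed by the wall, while the
#' viscous part never reaches the cavity, mechanical efficiency
#' `eta = SW / TW` stays at or below one.
#'
#' @param motion a [make_motion()] result.
#' @param params the matching [synth_patient_params()].
#' @param viscosity_kpa_ms myocardial viscosity `mu`, kPa ms (default
#'   1500, i.e. 1.5 kPa s).
#' @return List: `stroke_work_J`, `total_work_J` (elastic + viscous),
#'   `viscous_work_J`, `efficiency`.
#' @export
synth_energy_audit <- function(motion, params, viscosity_kpa_ms = 1500) {
  surf <- motion$surface
  wall <- generic_waveform(peak_kpa = params$peak_kpa,
                           edp_kpa = params$edp_kpa, rr_ms = params$rr_ms)
  tw_el <- energy_total_work(surf, wall)
  strain <- compute_rsct(surf)
  dt <- diff(surf$frame_times)
  deps <- t(apply(strain$values, 1, diff))
  rate2 <- rowSums((deps / matrix(dt, nrow(deps), ncol(deps), byrow = TRUE))^2 *
                     matrix(dt, nrow(deps), ncol(deps), byrow = TRUE))
  h <- mean(segment_wall_thickness(params$wall_thickness, 1L)[, 1])
  tw_visc <- viscosity_kpa_ms * sum(rate2 * strain$ref_weight * h) / 1e6
  sw <- stroke_work(wall, cavity_volumes(surf), surf$frame_times)
  tw <- tw_el + tw_visc
  list(stroke_work_J = sw, total_work_J = tw, viscous_work_J = tw_visc,
       efficiency = work_efficiency(sw, tw))
}

#' Configuration of a synthetic CRT cohort
#'
#' The cohort generator draws patient geometry, hemodynamics and
#' dyssynchrony severity, computes each patient's noise-free baseline
#' septal negative-work fraction `V_f_STNW(LBBB)` through the package's
#' own pipeline, and plants a linear outcome model
#' `dESV = beta0 + beta1 * V_f_STNW(LBBB) + eps`. When `sigma_eps` is NULL
#' it is sized from the realized between-patient variance of the metric so
#' the planted population R^2 equals `r2_target`.
#'
#' @param n_patients cohort size.
#' @param seed master seed; every random draw derives from it.
#' @param severity_range range of the uniform severity distribution.
#' @param beta0,beta1 outcome model coefficients (% dESV).
#' @param r2_target planted coefficient of determination (used when
#'   `sigma_eps` is NULL).
#' @param sigma_eps outcome noise sd (%); overrides `r2_target`.
#' @param states states to generate per patient.
#' @param metric_method stress surrogate used for the planted metric.
#' @param patch_noise_sd motion noise passed to each patient.
#' @param n_frames,n_theta,n_phi sizes passed to each patient.
#' @return List of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_patients = 8, seed = 1L,
                                severity_range = c(0.5, 0.95),
                                beta0 = -45, beta1 = 100,
                                r2_target = 0.7, sigma_eps = NULL,
                                states = c("LBBB", "CRT"),
                                metric_method = "P_gen",
                                patch_noise_sd = 0.005,
                                n_frames = 41, n_theta = 24, n_phi = 16) {
  stopifnot(n_patients >= 1, diff(severity_range) >= 0)
  structure(as.list(environment()), class = "synth_cohort_config")
}

#' Generate a synthetic CRT cohort with planted outcome structure
#'
#' @param config a [synth_cohort_config()].
#' @return List of class `synth_cohort`: `patients` (each with `params`,
#'   `pressure`, and a `synth_motion` per requested state), `records`
#'   (outcome table: `patient_id`, `desv_lv`, NYHA classes), and
#'   `ground_truth` (planted severities, noise-free `vf_stnw_lbbb`
#'   and `vf_stnw_crt`, the beta coefficients and `sigma_eps`).
#' @export
make_cohort <- function(config = synth_cohort_config()) {
  stopifnot(inherits(config, "synth_cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)
  severity <- stats::runif(n, config$severity_range[1], config$severity_range[2])
  axis_length <- stats::rnorm(n, 90, 5)
  base_radius <- stats::rnorm(n, 30, 2.5)
  thickness <- pmax(stats::rnorm(n, 8, 0.8), 4)
  peak <- pmax(stats::rnorm(n, 16, 1.5), 8)
  edp <- pmin(pmax(stats::rnorm(n, 1.2, 0.25), 0.5), 3)
  pat_seed <- sample.int(2^30, n)

  patients <- vector("list", n)
  vf_lbbb <- vf_crt <- numeric(n)
  for (i in seq_len(n)) {
    par <- synth_patient_params(
      axis_length = axis_length[i], base_radius = base_radius[i],
      wall_thickness = thickness[i], severity = severity[i],
      peak_kpa = peak[i], edp_kpa = edp[i],
      patch_noise_sd = config$patch_noise_sd,
      n_frames = config$n_frames, n_theta = config$n_theta,
      n_phi = config$n_phi, seed = pat_seed[i])
    mesh <- make_lv_mesh(par)
    # noise-free truth runs for the planted metric
    par0 <- par; par0$patch_noise_sd <- 0
    truth_lbbb <- make_motion(mesh, par0, "LBBB")
    vf_lbbb[i] <- synth_metric_vf_stnw(truth_lbbb, par, config$metric_method)
    if ("CRT" %in% config$states) {
      truth_crt <- make_motion(mesh, par0, "CRT")
      vf_crt[i] <- synth_metric_vf_stnw(truth_crt, par, config$metric_method)
    }
    states <- list()
    for (st in config$states) {
      states[[st]] <- if (config$patch_noise_sd == 0) {
        if (st == "LBBB") truth_lbbb else truth_crt
      } else make_motion(mesh, par, st)
    }
    patients[[i]] <- list(params = par, mesh = mesh, states = states,
                          pressure = make_pressure(par))
  }

  sigma <- config$sigma_eps
  if (is.null(sigma) && n >= 3) {
    # calibrated plant: draw residuals, orthogonalise them against the
    # metric and rescale so the realized sample R^2 equals r2_target
    raw <- stats::rnorm(n)
    eperp <- stats::residuals(stats::lm(raw ~ vf_lbbb))
    sigma <- abs(config$beta1) * stats::sd(vf_lbbb) *
      sqrt(1 / config$r2_target - 1) / stats::sd(eperp)
    eps <- sigma * eperp
  } else {
    if (is.null(sigma)) sigma <- 0
    eps <- stats::rnorm(n, 0, sigma)
  }
  desv <- config$beta0 + config$beta1 * vf_lbbb + eps
  nyha0 <- ifelse(severity > 0.8, 4L, 3L)
  nyha1 <- pmax(1L, nyha0 - (desv > 0) - (desv > 10) - (desv > 40))

  records <- data.frame(patient_id = sprintf("SYN%02d", seq_len(n)),
                        desv_lv = desv,
                        nyha_baseline = nyha0, nyha_followup = nyha1,
                        stringsAsFactors = FALSE)
  ground_truth <- data.frame(patient_id = records$patient_id,
                             severity = severity,
                             vf_stnw_lbbb = vf_lbbb,
                             vf_stnw_crt = vf_crt,
                             beta0 = config$beta0, beta1 = config$beta1,
                             sigma_eps = sigma)
  structure(list(patients = patients, records = records,
                 ground_truth = ground_truth, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic CRT cohort:", length(x$patients), "patients, states:",
      paste(x$config$states, collapse = "/"),
      sprintf("(master seed %d)\n", x$config$seed))
  invisible(x)
}

#' Pipeline evaluation of the planted cohort metric
#'
#' Computes the patch-resolution, volume-weighted septal negative-work
#' fraction (V_f_STNW) for one synthetic patient state through the public
#' pipeline: AHA segmentation, RS_CT strain, the requested stress
#' surrogate, signed work map, regional fraction. This is the metric the
#' cohort generator plants against the reverse-remodeling outcome.
#'
#' @param motion a [make_motion()] result.
#' @param params the matching [synth_patient_params()].
#' @param method stress surrogate: `"P_gen"`, `"P_gen_scaled"` or
#'   `"P_LHC"`.
#' @return V_f_STNW in `[0, 1]`.
#' @export
synth_metric_vf_stnw <- function(motion, params, method = "P_gen") {
  surf <- motion$surface
  segmap <- assign_aha_segments(surf)
  strain <- compute_rsct(surf)
  pres <- switch(method,
                 P_gen = generic_waveform(rr_ms = params$rr_ms),
                 P_gen_scaled = scale_waveform_to_peak(
                   generic_waveform(rr_ms = params$rr_ms), params$peak_kpa),
                 P_LHC = make_pressure(params),
                 stop("unsupported metric method: ", method))
  stress <- build_stress_field(method, pres, surf$frame_times)
  wm <- compute_work_map(strain, stress, segmap, weight = "volume",
                         thickness = mean(params$wall_thickness),
                         state = motion$state)
  negative_work_fraction(wm, "septum")
}
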