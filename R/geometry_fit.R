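#' Fit segmental radii by an axisymmetric ellipsoid
#'
#' Least-squares fit of an ellipsoid of revolution about the ventricular
#' long axis to the endocardial points of one segment. The fit is linear in
#' `(1/a^2, 1/b^2, centre offset)`: with `rho` the distance from the axis
#' and `z` the coordinate along it, `A*rho^2 + B*z^2 + C*z = 1` is solved by
#' ordinary least squares and converted back to the transverse semi-axis
#' `a` and longitudinal semi-axis `b` of the ellipsoid centred on the axis.
#'
#' The circumferential radius is `a`. The longitudinal radius is the
#' meridional radius of curvature of the fitted ellipse evaluated at the
#' mean parametric latitude of the segment's points,
#' `(a^2 cos^2 t + b^2 sin^2 t)^(3/2) / (a b)`, which reduces to `b^2/a`
#' at the equator and to the sphere radius when `a = b`.
#'
#' If the quadric fit is rank-deficient or yields non-positive curvature
#' coefficients, a sphere with centre constrained to the axis is fitted
#' instead and `r_circ = r_long` is returned with `sphere_fallback = TRUE`.
#'
#' @param points `n x 3` matrix of mm coordinates (n >= 9, non-coplanar).
#' @param long_axis unit vector of the long axis.
#' @param axis_point a point on the long axis (e.g. the apex).
#' @return List with `r_circ`, `r_long` (mm), `centre_z` (fitted centre
#'   offset along the axis from `axis_point`) and `sphere_fallback`.
#' @export
fit_segment_radii <- function(points, long_axis, axis_point = c(0, 0, 0)) {
  points <- as.matrix(points)
  if (nrow(points) < 9L) stop("need at least 9 points for the ellipsoid fit")
  u <- long_axis / sqrt(sum(long_axis^2))
  rel <- points - matrix(axis_point, nrow(points), 3, byrow = TRUE)
  z <- as.vector(rel %*% u)
  perp <- rel - outer(z, u)
  rho2 <- rowSums(perp^2)

  fit <- NULL
  X <- cbind(rho2, z^2, z)
  if (qr(X)$rank == 3L) {
    cf <- unname(qr.solve(X, rep(1, nrow(X))))
    A <- cf[1]; B <- cf[2]; C <- cf[3]
    if (is.finite(A) && is.finite(B) && A > 0 && B > 0) {
      z0 <- -C / (2 * B)
      k <- 1 + B * z0^2
      if (k > 0) {
        a <- sqrt(k / A)
        b <- sqrt(k / B)
        # near-degenerate aspect (cylinder/ring-like data): fall back
        if (b >= 0.05 * a && a >= 0.05 * b) {
          # mean parametric latitude of the points on the fitted ellipse
          t_par <- atan2(sqrt(rho2) / a, (z - z0) / b)
          tbar <- mean(t_par)
          r_long <- (a^2 * cos(tbar)^2 + b^2 * sin(tbar)^2)^1.5 / (a * b)
          fit <- list(r_circ = a, r_long = r_long, centre_z = z0,
                      sphere_fallback = FALSE)
        }
      }
    }
  }
  if (is.null(fit)) {
    # sphere with centre on the axis: rho^2 + z^2 = 2*z0*z + (r^2 - z0^2)
    Xs <- cbind(2 * z, 1)
    cs <- unname(qr.solve(Xs, rho2 + z^2))
    z0 <- cs[1]
    r2 <- cs[2] + z0^2
    if (!is.finite(r2) || r2 <= 0) stop("degenerate point set: radius fit failed")
    r <- sqrt(r2)
    fit <- list(r_circ = r, r_long = r, centre_z = z0, sphere_fallback = TRUE)
  }
  fit
}

#' Effective segmental radius
#'
#' Combines the circumferential and longitudinal radii into a single
#' curvature radius, `r_eff = r_c * r_l / (r_c + r_l)`: total surface
#' curvature is approximately the sum of the two principal curvatures, and
#' radius is inverse curvature.
#'
#' @param r_circ,r_long positive radii in mm (vectorised).
#' @return Effective radius in mm.
#' @export
effective_radius <- function(r_circ, r_long) {
  if (any(r_circ <= 0) || any(r_long <= 0))
    stop("radii must be positive")
  r_circ * r_long / (r_circ + r_long)
}

#' Segmental wall thickness table
#'
#' Validates and expands a wall thickness specification into a 17 x
#' n_frames matrix. Thickness is an input (from imaging or from a synthetic
#' ground truth); optionally an incompressibility-based time variation is
#' applied in which each segment's wall volume (endocardial area x
#' thickness) is conserved, so thickness scales inversely with segment
#' area.
#'
#' @param thickness scalar (uniform), length-17 vector, or 17 x n_frames
#'   matrix of thicknesses in mm.
#' @param n_frames number of frames to expand to.
#' @param segment_areas optional 17 x n_frames matrix of segment
#'   endocardial areas (mm^2), required when `incompressible = TRUE`.
#' @param incompressible logical; scale thickness so area x thickness is
#'   conserved relative to frame 1.
#' @return 17 x n_frames matrix of thickness in mm.
#' @export
segment_wall_thickness <- function(thickness, n_frames = 1L,
                                   segment_areas = NULL,
                                   incompressible = FALSE) {
  if (is.matrix(thickness)) {
    h <- thickness
    if (nrow(h) != 17L) stop("thickness matrix must have 17 rows")
    if (ncol(h) != n_frames) stop("thickness matrix has wrong number of frames")
  } else {
    thickness <- as.numeric(thickness)
    if (length(thickness) == 1L) thickness <- rep(thickness, 17L)
    if (length(thickness) != 17L)
      stop("thickness must be scalar, length 17, or a 17 x n_frames matrix")
    if (anyNA(thickness)) stop("missing segment thickness")
    h <- matrix(thickness, 17L, n_frames)
  }
  if (anyNA(h)) stop("missing segment thickness")
  if (any(h <= 0)) stop("wall thickness must be positive")
  if (incompressible) {
    if (is.null(segment_areas)) stop("incompressible mode needs segment_areas")
    h <- h[, 1] * segment_areas[, 1] / segment_areas
  }
  h
}

#' Segmental shape quantities over the cycle
#'
#' Per-segment circumferential, longitudinal and effective radii plus wall
#' thickness, either at every frame (for time-varying Laplace stress) or at
#' end-diastole only. Radii come from [fit_segment_radii()] applied to the
#' vertices of each segment's triangles.
#'
#' @param surface an [endocardial_surface()].
#' @param segmap an [assign_aha_segments()] result.
#' @param thickness thickness specification passed to
#'   [segment_wall_thickness()].
#' @param frames `"all"` (per-frame refit, the default) or `"ed"`
#'   (end-diastole only).
#' @param incompressible logical, passed to [segment_wall_thickness()].
#' @return Object of class `segment_geometry`: 17 x n_frames matrices
#'   `r_circ`, `r_long`, `r_eff`, `h`, logical matrix `sphere_fallback`,
#'   and the frame times used.
#' @export
segment_geometry <- function(surface, segmap, thickness = 8,
                             frames = c("all", "ed"),
                             incompressible = FALSE) {
  frames <- match.arg(frames)
  nf <- if (frames == "all") n_frames(surface) else 1L
  tr <- surface$triangles
  seg_of_patch <- segmap$patch_segment
  u <- surface$long_axis
  apex <- surface$apex_point

  r_circ <- r_long <- r_eff <- matrix(NA_real_, 17L, nf)
  fallback <- matrix(FALSE, 17L, nf)
  seg_area <- matrix(NA_real_, 17L, nf)
  vert_of_seg <- lapply(1:17, function(s) {
    unique(as.vector(tr[seg_of_patch == s, , drop = FALSE]))
  })
  for (k in seq_len(nf)) {
    v <- surface$vertices[, , k]
    ar <- suppressWarnings(patch_areas(surface, k))
    seg_area[, k] <- vapply(1:17, function(s) sum(ar[seg_of_patch == s]), numeric(1))
    for (s in 1:17) {
      idx <- vert_of_seg[[s]]
      if (length(idx) < 9L) stop("segment ", s, " has too few vertices for a radius fit")
      fit <- fit_segment_radii(v[idx, , drop = FALSE], u, apex)
      r_circ[s, k] <- fit$r_circ
      r_long[s, k] <- fit$r_long
      fallback[s, k] <- fit$sphere_fallback
    }
  }
  r_eff[] <- effective_radius(r_circ, r_long)
  h <- segment_wall_thickness(thickness, nf,
                              segment_areas = seg_area,
                              incompressible = incompressible)
  structure(list(r_circ = r_circ, r_long = r_long, r_eff = r_eff, h = h,
                 sphere_fallback = fallback,
                 frames = frames,
                 frame_times = if (frames == "all") surface$frame_times
                               else surface$frame_times[1]),
            class = "segment_geometry")
}
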