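# Shared fixtures and independent oracles, all generated in code.

# Rigid-body transform of every frame of a surface.
rigid_transform <- function(surface, axis = c(1, 2, 2), angle = 0.7,
                            translation = c(5, -3, 11)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  v <- surface$vertices
  for (k in seq_len(dim(v)[3])) {
    v[, , k] <- v[, , k] %*% t(R) +
      matrix(translation, dim(v)[1], 3, byrow = TRUE)
  }
  endocardial_surface(v, surface$triangles, surface$frame_times,
                      apex_point = as.vector(R %*% surface$apex_point) + translation,
                      base_centroid = if (is.null(surface$base_centroid)) NULL else
                        as.vector(R %*% surface$base_centroid) + translation,
                      long_axis = if (is.null(surface$long_axis)) NULL else
                        as.vector(R %*% surface$long_axis),
                      validate = FALSE)
}

# Lat-long spherical cap mesh (polar angle 0..phi_max), open at the rim.
# phi_max = pi/2 gives a hemispherical cup.
cap_mesh <- function(radius = 30, phi_max = pi / 2, n_phi = 30, n_theta = 60) {
  phi <- seq_len(n_phi) * phi_max / n_phi
  theta <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  verts <- matrix(0, 1 + n_phi * n_theta, 3)
  vid <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  for (i in seq_len(n_phi)) {
    verts[vid(i, 1):vid(i, n_theta), ] <-
      cbind(radius * sin(phi[i]) * cos(theta),
            radius * sin(phi[i]) * sin(theta),
            radius * (1 - cos(phi[i])))
  }
  ntri <- n_theta + 2 * n_theta * (n_phi - 1)
  tris <- matrix(0L, ntri, 3)
  k <- 1L
  for (j in seq_len(n_theta)) {
    tris[k, ] <- c(1L, vid(1, j), vid(1, j + 1)); k <- k + 1L
  }
  for (i in seq_len(n_phi - 1)) {
    for (j in seq_len(n_theta)) {
      tris[k, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)); k <- k + 1L
      tris[k, ] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)); k <- k + 1L
    }
  }
  arr <- array(rep(verts, 4), c(nrow(verts), 3, 4))
  endocardial_surface(arr, tris, c(0, 100, 200, 300),
                      apex_point = c(0, 0, 0),
                      base_centroid = c(0, 0, radius * (1 - cos(phi_max))),
                      long_axis = c(0, 0, 1), validate = FALSE)
}

# Smooth star-convex closed mesh: icosphere radially modulated by a fixed
# smooth function of direction.
star_mesh <- function(radius = 12, subdivisions = 3) {
  s <- icosphere(radius = 1, subdivisions = subdivisions)
  v <- s$vertices[, , 1]
  mod <- 1 + 0.18 * sin(3 * v[, 1]) + 0.12 * cos(2 * v[, 2] + 1) +
    0.1 * sin(2 * v[, 3] - 0.5)
  v <- v * radius * mod
  arr <- array(rep(v, 4), c(nrow(v), 3, 4))
  endocardial_surface(arr, s$triangles, c(0, 100, 200, 300),
                      apex_point = c(0, 0, -radius),
                      base_centroid = c(0, 0, radius),
                      long_axis = c(0, 0, 1), validate = FALSE)
}

# Independent voxel-counting volume oracle: casts z-rays through a grid of
# 0.5 mm columns, finds surface crossings per column, and counts voxel
# centres between entry/exit pairs. Independent of the signed-tetrahedron
# path used by cavity_volume().
voxel_volume <- function(surface, frame = 1, h = 0.5) {
  v <- surface$vertices[, , frame]
  tr <- surface$triangles
  p1 <- v[tr[, 1], ]; p2 <- v[tr[, 2], ]; p3 <- v[tr[, 3], ]
  xr <- range(v[, 1]); yr <- range(v[, 2]); zr <- range(v[, 3])
  xs <- seq(xr[1] - h, xr[2] + h, by = h)
  ys <- seq(yr[1] - h, yr[2] + h, by = h)
  z0 <- zr[1] - h
  total <- 0L
  for (xi in xs) {
    # vectorised over triangles for the whole y-row
    for (yi in ys) {
      # 2D point-in-triangle in the xy projection
      d1 <- (p2[, 1] - p1[, 1]) * (yi - p1[, 2]) - (p2[, 2] - p1[, 2]) * (xi - p1[, 1])
      d2 <- (p3[, 1] - p2[, 1]) * (yi - p2[, 2]) - (p3[, 2] - p2[, 2]) * (xi - p2[, 1])
      d3 <- (p1[, 1] - p3[, 1]) * (yi - p3[, 2]) - (p1[, 2] - p3[, 2]) * (xi - p3[, 1])
      hit <- which((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0))
      if (length(hit) < 2) next
      # z of the ray-plane intersection via barycentric interpolation
      den <- d1[hit] + d2[hit] + d3[hit]
      ok <- abs(den) > 1e-12
      hit <- hit[ok]; if (length(hit) < 2) next
      w1 <- d2[hit] / (d1[hit] + d2[hit] + d3[hit])
      w2 <- d3[hit] / (d1[hit] + d2[hit] + d3[hit])
      w3 <- d1[hit] / (d1[hit] + d2[hit] + d3[hit])
      zc <- sort(w1 * p1[hit, 3] + w2 * p2[hit, 3] + w3 * p3[hit, 3])
      zc <- zc[!duplicated(round(zc, 9))]
      if (length(zc) %% 2 == 1) next  # grazing hit; skip column
      for (m in seq(1, length(zc), by = 2)) {
        lo <- zc[m]; hi <- zc[m + 1]
        total <- total + max(0L, floor((hi - z0) / h) - ceiling((lo - z0) / h) + 1L)
      }
    }
  }
  total * h^3 / 1000  # mm^3 -> mL
}

# Independent trapezoid-rule oracle for W = -contour integral sigma d(eps).
trapezoid_work <- function(strain, stress) {
  x <- c(strain, strain[1])
  y <- c(stress, stress[1])
  -sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# Quick noise-free synthetic patient state.
quick_motion <- function(severity = 0.8, state = "LBBB", ...) {
  p <- synth_patient_params(severity = severity, patch_noise_sd = 0, ...)
  list(params = p, motion = make_motion(make_lv_mesh(p), p, state))
}

table1_path <- function() {
  system.file("extdata", "crt_cohort_outcomes.csv", package = "myowork")
}
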