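#' Time-resolved triangulated endocardial surface
#'
#' Container for a left-ventricular endocardial surface tracked over one
#' cardiac cycle. Vertex coordinates are in millimetres; frame 0 is
#' end-diastole (the R-wave) and frame times are milliseconds from the
#' R-wave. The triangulation is fixed across frames; only vertex positions
#' move. The surface must be an oriented, connected 2-manifold with at most
#' one boundary loop (the base); a fully closed surface is also accepted
#' (used for synthetic validation meshes).
#'
#' @param vertices numeric array `n_vertices x 3 x n_frames`, or a list of
#'   `n_vertices x 3` matrices (one per frame), coordinates in mm.
#' @param triangles integer matrix `n_triangles x 3` of 1-based vertex
#'   indices, consistently oriented.
#' @param frame_times numeric vector of ms from the R-wave, strictly
#'   increasing, starting at 0. Must cover at least 4 frames.
#' @param apex_point,base_centroid optional mm coordinates of the apex and
#'   the centroid of the basal boundary loop. If omitted they are derived
#'   from the first frame: the base centroid from the boundary loop and the
#'   apex as the vertex farthest from the base plane.
#' @param long_axis optional unit vector pointing apex to base; derived from
#'   `apex_point` and `base_centroid` when omitted.
#' @param validate logical; run manifold/orientation checks (default TRUE).
#'
#' @return An object of class `endo_surface`.
#' @export
endocardial_surface <- function(vertices, triangles, frame_times,
                                apex_point = NULL, base_centroid = NULL,
                                long_axis = NULL, validate = TRUE) {
  if (is.list(vertices)) {
    nf <- length(vertices)
    nv <- nrow(vertices[[1]])
    arr <- array(NA_real_, c(nv, 3L, nf))
    for (k in seq_len(nf)) arr[, , k] <- as.matrix(vertices[[k]])
    vertices <- arr
  }
  stopifnot(is.array(vertices), length(dim(vertices)) == 3L, dim(vertices)[2] == 3L)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  nv <- dim(vertices)[1]
  nf <- dim(vertices)[3]
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != nf)
    stop("frame_times length must match the number of frames")
  if (nf < 4L)
    stop("need at least 4 frames spanning one RR interval")
  if (frame_times[1] != 0 || any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing and start at 0")
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle indices out of range")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("triangles with repeated vertex indices")

  boundary <- NULL
  if (validate) {
    chk <- check_manifold(triangles, nv)
    boundary <- chk$boundary_loop
  } else {
    bl <- try(boundary_loop(triangles), silent = TRUE)
    if (!inherits(bl, "try-error")) boundary <- bl
  }

  v0 <- vertices[, , 1]
  if (is.null(base_centroid)) {
    base_centroid <- if (length(boundary)) colMeans(v0[boundary, , drop = FALSE]) else NULL
  }
  if (is.null(apex_point)) {
    if (is.null(base_centroid))
      stop("apex_point/base_centroid must be given for a closed surface")
    d <- sqrt(rowSums((v0 - matrix(base_centroid, nv, 3, byrow = TRUE))^2))
    apex_point <- v0[which.max(d), ]
  }
  if (is.null(long_axis) && !is.null(base_centroid)) {
    ax <- base_centroid - apex_point
    L <- sqrt(sum(ax^2))
    if (L < 1e-6) stop("degenerate long axis: apex coincides with base centroid")
    long_axis <- ax / L
  }

  structure(list(
    vertices = vertices,
    triangles = triangles,
    frame_times = frame_times,
    apex_point = as.numeric(apex_point),
    base_centroid = if (is.null(base_centroid)) NULL else as.numeric(base_centroid),
    long_axis = if (is.null(long_axis)) NULL else as.numeric(long_axis),
    boundary_loop = boundary
  ), class = "endo_surface")
}

#' @export
print.endo_surface <- function(x, ...) {
  cat("Endocardial surface:",
      dim(x$vertices)[1], "vertices,",
      nrow(x$triangles), "triangles,",
      length(x$frame_times), "frames over",
      max(x$frame_times), "ms\n")
  invisible(x)
}

n_frames <- function(surface) length(surface$frame_times)

#' @rdname endocardial_surface
#' @param x object to test.
#' @export
is.endo_surface <- function(x) inherits(x, "endo_surface")

# Boundary edges (appearing in exactly one triangle), as an ordered vertex
# loop. Errors if boundary edges form more than one loop.
boundary_loop <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (!length(bkey)) return(integer(0))
  bed <- e[key %in% bkey, , drop = FALSE]
  # walk the loop
  nxt <- structure(bed[, 2], names = as.character(bed[, 1]))
  if (anyDuplicated(names(nxt)))
    stop("surface boundary is not a simple loop")
  start <- bed[1, 1]
  loop <- integer(nrow(bed))
  cur <- start
  for (i in seq_len(nrow(bed))) {
    loop[i] <- cur
    cur <- unname(nxt[as.character(cur)])
    if (is.na(cur)) stop("surface boundary is not a closed loop")
  }
  if (cur != start) stop("surface boundary is not a single closed loop")
  if (length(loop) != nrow(bed))
    stop("surface has more than one boundary loop")
  loop
}

# Manifold, orientation and connectivity checks; returns the boundary loop.
check_manifold <- function(triangles, nv) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  ukey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ukey)
  if (any(cnt > 2L))
    stop("non-manifold surface: an edge is shared by more than 2 triangles")
  dkey <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dkey))
    stop("inconsistently oriented triangulation")
  # connectivity via union-find on edges
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a != b) parent[a] <- b
  }
  used <- unique(as.vector(triangles))
  roots <- vapply(used, find, integer(1))
  if (length(unique(roots)) > 1L)
    stop("surface is not connected")
  boundary <- boundary_loop(triangles)
  list(boundary_loop = boundary)
}

#' Per-triangle patch areas
#'
#' Area of every triangular endocardial patch at one frame, as half the
#' magnitude of the edge cross product. Degenerate triangles get area 0
#' (with a warning) rather than being dropped, so patch indexing stays
#' stable across frames.
#'
#' @param surface an [endocardial_surface()].
#' @param frame 1-based frame index.
#' @return Numeric vector of areas in mm^2, one per triangle.
#' @export
patch_areas <- function(surface, frame = 1L) {
  stopifnot(is.endo_surface(surface))
  if (frame < 1L || frame > n_frames(surface)) stop("invalid frame index")
  v <- surface$vertices[, , frame]
  tr <- surface$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  ar <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(ar == 0))
    warning(sum(ar == 0), " degenerate (zero-area) triangle(s) at frame ", frame)
  ar
}

#' Left-ventricular cavity volume
#'
#' Volume enclosed by the endocardial surface, closed at the base by a flat
#' polygon fan at the boundary-loop centroid, computed as a sum of signed
#' tetrahedra against that centroid (the basal cap then contributes
#' nothing). Closed surfaces are integrated directly.
#'
#' @inheritParams patch_areas
#' @return Cavity volume in mL.
#' @export
cavity_volume <- function(surface, frame = 1L) {
  stopifnot(is.endo_surface(surface))
  if (frame < 1L || frame > n_frames(surface)) stop("invalid frame index")
  v <- surface$vertices[, , frame]
  tr <- surface$triangles
  if (length(surface$boundary_loop)) {
    ref <- colMeans(v[surface$boundary_loop, , drop = FALSE])
  } else {
    ref <- colMeans(v)
  }
  p1 <- v[tr[, 1], , drop = FALSE] - matrix(ref, nrow(tr), 3, byrow = TRUE)
  p2 <- v[tr[, 2], , drop = FALSE] - matrix(ref, nrow(tr), 3, byrow = TRUE)
  p3 <- v[tr[, 3], , drop = FALSE] - matrix(ref, nrow(tr), 3, byrow = TRUE)
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6 / 1000  # mm^3 -> mL
}

#' Cavity volume time series
#'
#' @inheritParams patch_areas
#' @return Numeric vector of volumes (mL), one per frame.
#' @export
cavity_volumes <- function(surface) {
  vapply(seq_len(n_frames(surface)), function(k) cavity_volume(surface, k),
         numeric(1))
}
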