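#' Write one frame of a surface as Wavefront OBJ
#'
#' @param surface an [endocardial_surface()].
#' @param path output file.
#' @param frame frame index to write.
#' @export
write_obj <- function(surface, path, frame = 1L) {
  v <- surface$vertices[, , frame]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", surface$triangles[, 1],
                     surface$triangles[, 2], surface$triangles[, 3]), con)
  invisible(path)
}

read_obj_frame <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  # tolerate v/vt/vn face syntax
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  list(vertices = v, triangles = f)
}

#' Read a mesh sequence from per-frame OBJ files
#'
#' All frames must share the same triangulation and vertex count.
#'
#' @param paths OBJ file paths, one per frame, in time order.
#' @param frame_times ms from the R-wave for each frame.
#' @param ... passed to [endocardial_surface()].
#' @return An [endocardial_surface()].
#' @export
read_obj_sequence <- function(paths, frame_times, ...) {
  frames <- lapply(paths, read_obj_frame)
  tri <- frames[[1]]$triangles
  for (f in frames[-1]) {
    if (!identical(f$triangles, tri))
      stop("OBJ frames have differing triangulations")
  }
  endocardial_surface(lapply(frames, `[[`, "vertices"), tri, frame_times, ...)
}

#' Build a surface from a reference OBJ plus a displacement table
#'
#' The CSV must have columns `vertex`, `frame`, `dx`, `dy`, `dz`
#' (millimetres), with frame 1 displacements implicitly zero if absent.
#'
#' @param obj_path reference-frame OBJ file.
#' @param csv_path displacement CSV.
#' @param frame_times ms from the R-wave.
#' @param ... passed to [endocardial_surface()].
#' @return An [endocardial_surface()].
#' @export
read_mesh_with_displacements <- function(obj_path, csv_path, frame_times, ...) {
  ref <- read_obj_frame(obj_path)
  d <- utils::read.csv(csv_path)
  need <- c("vertex", "frame", "dx", "dy", "dz")
  if (!all(need %in% names(d)))
    stop("displacement CSV must contain columns: ", paste(need, collapse = ", "))
  nf <- length(frame_times)
  nv <- nrow(ref$vertices)
  arr <- array(rep(ref$vertices, nf), c(nv, 3, nf))
  for (k in seq_len(nf)) {
    dk <- d[d$frame == k, ]
    if (nrow(dk)) {
      arr[dk$vertex, 1, k] <- ref$vertices[dk$vertex, 1] + dk$dx
      arr[dk$vertex, 2, k] <- ref$vertices[dk$vertex, 2] + dk$dy
      arr[dk$vertex, 3, k] <- ref$vertices[dk$vertex, 3] + dk$dz
    }
  }
  endocardial_surface(arr, ref$triangles, frame_times, ...)
}

#' Write a work map as CSV
#'
#' Long format with the map's method/state/weighting attributes as
#' columns, suitable for joining across patients.
#'
#' @param workmap a [compute_work_map()] result.
#' @param path output CSV file.
#' @export
write_work_map_csv <- function(workmap, path) {
  d <- as.data.frame(workmap)
  d$method <- attr(workmap, "method")
  d$state <- attr(workmap, "state")
  d$weight_type <- attr(workmap, "weight_type")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a strain field as long-format CSV
#'
#' Columns `unit_id`, `frame_time_ms`, `strain`.
#'
#' @param field a `strain_field`.
#' @param path output CSV file.
#' @export
write_strain_csv <- function(field, path) {
  d <- data.frame(unit_id = rep(field$unit_ids, times = ncol(field$values)),
                  frame_time_ms = rep(field$frame_times, each = nrow(field$values)),
                  strain = as.vector(field$values))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
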