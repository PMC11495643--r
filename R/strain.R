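#' Endocardial area-change strain (RS_CT)
#'
#' Regional strain of each endocardial patch as the fractional change of
#' its area relative to end-diastole:
#' `RS_CT(v, t) = A(v, t) / A(v, 0) - 1`, where `A(v, t)` is the area of
#' patch `v` at time `t` in the RR interval and frame 0 is the
#' end-diastolic reference. Patches with zero reference area are excluded
#' from the field (recorded in `excluded`) rather than producing
#' non-finite strain.
#'
#' @param surface an [endocardial_surface()]; frame 1 must be the
#'   end-diastolic reference.
#' @return Object of class `strain_field` with patch resolution: matrix
#'   `values` (`n_units x n_frames`, unitless, exactly 0 at frame 1),
#'   `unit_ids` (triangle indices retained), `resolution = "patch"`,
#'   `frame_times`, and `ref_weight` (reference-frame patch areas, mm^2,
#'   used as averaging weights downstream).
#' @export
compute_rsct <- function(surface) {
  stopifnot(is.endo_surface(surface))
  nf <- n_frames(surface)
  A <- vapply(seq_len(nf),
              function(k) suppressWarnings(patch_areas(surface, k)),
              numeric(nrow(surface$triangles)))
  A <- matrix(A, ncol = nf)
  ref <- A[, 1]
  keep <- ref > 0
  if (!all(keep))
    warning(sum(!keep), " patch(es) with zero reference area excluded from strain field")
  values <- A[keep, , drop = FALSE] / ref[keep] - 1
  structure(list(values = values,
                 unit_ids = which(keep),
                 resolution = "patch",
                 frame_times = surface$frame_times,
                 ref_weight = ref[keep],
                 excluded = which(!keep)),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat("Strain field (", x$resolution, " resolution): ",
      nrow(x$values), " units x ", ncol(x$values), " frames\n", sep = "")
  invisible(x)
}

#' Average patch strain within AHA segments
#'
#' Reduces a patch-resolution strain field to one curve per AHA segment.
#' By default the mean is weighted by the reference-frame patch areas so
#' that the segmental curve is independent of mesh resolution; an
#' unweighted mean is available for sensitivity checks.
#'
#' @param field patch-resolution `strain_field` from [compute_rsct()].
#' @param segmap an [assign_aha_segments()] result for the same surface.
#' @param weighted logical; area-weight the average (default TRUE).
#' @return `strain_field` with `resolution = "segment"` and 17 rows;
#'   `ref_weight` holds the summed reference areas per segment.
#' @export
segment_average_strain <- function(field, segmap, weighted = TRUE) {
  stopifnot(inherits(field, "strain_field"))
  if (field$resolution != "patch")
    stop("segment_average_strain expects a patch-resolution strain field")
  seg <- segmap$patch_segment[field$unit_ids]
  w <- if (weighted) field$ref_weight else rep(1, length(seg))
  vals <- matrix(NA_real_, 17L, ncol(field$values))
  wsum <- numeric(17L)
  for (s in 1:17) {
    i <- seg == s
    if (!any(i)) stop("AHA segment ", s, " contains no patches")
    wsum[s] <- sum(w[i])
    vals[s, ] <- colSums(field$values[i, , drop = FALSE] * w[i]) / wsum[s]
  }
  structure(list(values = vals,
                 unit_ids = 1:17,
                 resolution = "segment",
                 frame_times = field$frame_times,
                 ref_weight = vapply(1:17, function(s)
                   sum(field$ref_weight[seg == s]), numeric(1)),
                 excluded = integer(0)),
            class = "strain_field")
}
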