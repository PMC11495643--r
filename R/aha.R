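#' Segment ids of the interventricular septum
#'
#' AHA segments 2 (basal anteroseptal), 3 (basal inferoseptal),
#' 8 (mid anteroseptal), 9 (mid inferoseptal) and 14 (apical septal).
#' @export
SEPTAL_SEGMENTS <- c(2L, 3L, 8L, 9L, 14L)

#' Names of the 17 AHA segments
#' @export
AHA_SEGMENT_NAMES <- c(
  "basal anterior", "basal anteroseptal", "basal inferoseptal",
  "basal inferior", "basal inferolateral", "basal anterolateral",
  "mid anterior", "mid anteroseptal", "mid inferoseptal",
  "mid inferior", "mid inferolateral", "mid anterolateral",
  "apical anterior", "apical septal", "apical inferior", "apical lateral",
  "apex")

aha_regions <- function() {
  reg <- rep("LV free wall", 17L)
  reg[SEPTAL_SEGMENTS] <- "septum"
  reg[17L] <- "apex"
  reg
}

#' Assign AHA 17-segment labels to endocardial patches
#'
#' Maps every triangle of the surface to one of the 17 standard AHA
#' segments using the long axis and an anterior reference direction.
#' Longitudinal position is measured fractionally from the base towards the
#' apex along the long axis: `[0, 1/3)` basal, `[1/3, 2/3)` mid,
#' `[2/3, 0.95)` apical and `>= 0.95` the apical cap (segment 17). Basal
#' and mid rings are divided into six 60-degree sectors and the apical ring
#' into four 90-degree sectors, starting from the anterior reference, with
#' the circumferential order anterior, (antero)septal, infero(septal),
#' inferior, (infero)lateral, (antero)lateral.
#'
#' @param surface an [endocardial_surface()] with apex, base centroid and
#'   long axis populated.
#' @param anterior_ref direction (mm vector, need not be unit or exactly
#'   orthogonal to the long axis) marking the centre of the anterior wall.
#' @param frame frame whose geometry is used for the assignment (default
#'   the end-diastolic reference frame).
#'
#' @return Object of class `aha_segment_map`: list with `patch_segment`
#'   (integer 1-17 per triangle), `segment_region` (character, length 17:
#'   `"LV free wall"`, `"septum"` or `"apex"`) and `septal_ids`.
#' @export
assign_aha_segments <- function(surface, anterior_ref = c(1, 0, 0), frame = 1L) {
  stopifnot(is.endo_surface(surface))
  apex <- surface$apex_point
  base <- surface$base_centroid
  u <- surface$long_axis
  if (is.null(base) || is.null(u))
    stop("surface lacks base centroid / long axis")
  L <- sqrt(sum((base - apex)^2))
  if (L < 1e-6) stop("degenerate long axis: apex coincides with base centroid")

  e1 <- anterior_ref - sum(anterior_ref * u) * u
  if (sqrt(sum(e1^2)) < 1e-8)
    stop("anterior reference is parallel to the long axis")
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  v <- surface$vertices[, , frame]
  tr <- surface$triangles
  cen <- (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
            v[tr[, 3], , drop = FALSE]) / 3
  rel <- cen - matrix(apex, nrow(cen), 3, byrow = TRUE)
  t_apex <- as.vector(rel %*% u) / L         # 0 at apex, 1 at base
  f <- 1 - pmin(pmax(t_apex, 0), 1)          # fraction from base towards apex
  theta <- atan2(as.vector(rel %*% e2), as.vector(rel %*% e1)) * 180 / pi

  seg <- integer(nrow(cen))
  sector6 <- (floor(((theta + 30) %% 360) / 60)) %% 6       # 0 = anterior
  sector4 <- (floor(((theta + 45) %% 360) / 90)) %% 4
  basal <- f < 1 / 3
  mid <- f >= 1 / 3 & f < 2 / 3
  apical <- f >= 2 / 3 & f < 0.95
  cap <- f >= 0.95
  seg[basal] <- 1L + sector6[basal]
  seg[mid] <- 7L + sector6[mid]
  seg[apical] <- 13L + sector4[apical]
  seg[cap] <- 17L

  structure(list(patch_segment = seg,
                 segment_region = aha_regions(),
                 septal_ids = SEPTAL_SEGMENTS),
            class = "aha_segment_map")
}

#' @export
print.aha_segment_map <- function(x, ...) {
  cat("AHA 17-segment map over", length(x$patch_segment), "patches;",
      "non-empty segments:", length(unique(x$patch_segment)), "\n")
  invisible(x)
}

# region label for each patch
patch_regions <- function(segmap) segmap$segment_region[segmap$patch_segment]
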