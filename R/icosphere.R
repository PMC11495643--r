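#' Closed icosphere test mesh
#'
#' Geodesic sphere built by recursive 4-way subdivision of an icosahedron
#' with projection onto the sphere, returned as a (closed) static
#' [endocardial_surface()]. Used for analytic area/volume validation of
#' the mesh operations.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of subdivision passes (4 gives 5120 faces).
#' @param centre centre coordinates, mm.
#' @return A closed `endo_surface` with 4 identical frames.
#' @export
icosphere <- function(radius = 30, subdivisions = 4, centre = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- midcache[[key]]
      if (!is.null(m)) return(m)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      m <- nv + length(newv)
      midcache[[key]] <- m
      m
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(c, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- v * radius + matrix(centre, nrow(v), 3, byrow = TRUE)
  tt <- c(0, 100, 200, 300)
  arr <- array(rep(v, 4), c(nrow(v), 3, 4))
  endocardial_surface(arr, f, tt,
                      apex_point = centre - c(0, 0, radius),
                      base_centroid = centre + c(0, 0, radius),
                      long_axis = c(0, 0, 1),
                      validate = FALSE)
}
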