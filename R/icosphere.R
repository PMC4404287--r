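#' Generate an icosphere mesh
#'
#' Subdivided icosahedron with vertices projected onto the sphere of the
#' given radius. As an inscribed polyhedron its surface area increases
#' with subdivision level and converges to `4 * pi * r^2` from below,
#' which makes it the analytic oracle for [mesh_surface_area()].
#'
#' @param radius Sphere radius in mm (> 0).
#' @param subdivisions Subdivision level, 0 (icosahedron, 20 triangles)
#'   to 6.
#' @return A [face_mesh()] with `20 * 4^subdivisions` triangles.
#' @export
#' @examples
#' mesh_surface_area(generate_icosphere(50, 4)) / (4 * pi * 50^2)
generate_icosphere <- function(radius, subdivisions = 3) {
  if (radius <= 0) abort("radius must be > 0.")
  if (subdivisions < 0 || subdivisions > 6) abort("subdivisions must be in 0..6.")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)  # unit circumradius
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- unit_vec(verts[i, ] + verts[j, ])
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- verts; f <- newf
  }
  face_mesh(v * radius, f)
}
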