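# Analytic solid primitives. Used for graft construction, the synthetic
# knee, and as closed-form oracles for the voxel volume kernel.

#' Axis-aligned box mesh
#'
#' @param lo,hi length-3 corners in mm, `lo < hi` componentwise.
#' @param label mesh label.
#' @return A watertight [surface_mesh()] with 8 vertices and 12 faces.
#' @export
mesh_box <- function(lo, hi, label = "box") {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # index layout from expand.grid: x fastest, then y, then z
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = lo
    c(5, 6, 7), c(6, 8, 7),      # z = hi
    c(1, 2, 5), c(2, 6, 5),      # y = lo
    c(3, 7, 4), c(4, 7, 8),      # y = hi
    c(1, 5, 3), c(3, 5, 7),      # x = lo
    c(2, 4, 6), c(4, 8, 6)       # x = hi
  )
  .finish_primitive(v, f, label)
}

# assemble, fix global orientation, then validate
.finish_primitive <- function(v, f, label) {
  m <- surface_mesh(v, f, label = label, validate = FALSE)
  m <- .orient_outward(m)
  validate_mesh(m)
  m
}

#' Capped cylinder mesh
#'
#' A closed right circular cylinder between two axis endpoints, capped flat
#' with a triangle fan around each cap centre.
#'
#' @param p0,p1 axis endpoints in mm.
#' @param radius cylinder radius in mm.
#' @param n_segments circumferential tessellation count (>= 8).
#' @param label mesh label.
#' @return A watertight [surface_mesh()].
#' @export
mesh_cylinder <- function(p0, p1, radius, n_segments = 128L, label = "cylinder") {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3L, length(p1) == 3L, radius > 0, n_segments >= 8L)
  ax <- p1 - p0
  len <- sqrt(sum(ax^2))
  if (len < 1e-9) stop("cylinder endpoints are coincident")
  u <- ax / len
  # any vector not parallel to u seeds the cross-section basis
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  n <- as.integer(n_segments)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  ring <- outer(cos(th), e1) + outer(sin(th), e2)
  v0 <- sweep(radius * ring, 2, p0, "+")
  v1 <- sweep(radius * ring, 2, p1, "+")
  v <- rbind(v0, v1, p0, p1)
  i <- seq_len(n)
  j <- c(seq_len(n)[-1], 1L)
  c0 <- 2L * n + 1L
  c1 <- 2L * n + 2L
  f <- rbind(
    cbind(i, j, n + j),          # side lower triangles
    cbind(i, n + j, n + i),      # side upper triangles
    cbind(c0, j, i),             # cap at p0
    cbind(c1, n + i, n + j)      # cap at p1
  )
  .finish_primitive(v, f, label)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the sphere; the classical smooth
#' sphere approximation used as a curvature oracle for the voxel kernel.
#'
#' @param center sphere centre in mm.
#' @param radius sphere radius in mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0-5).
#' @param label mesh label.
#' @return A watertight [surface_mesh()].
#' @export
mesh_icosphere <- function(center = c(0, 0, 0), radius = 1,
                           subdivisions = 3L, label = "sphere") {
  stopifnot(radius > 0, subdivisions >= 0L, subdivisions <= 5L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) pmin(a, b) + (nv + 1) * pmax(a, b)
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    mid_of <- function(k) {
      a <- k %% (nv + 1); b <- k %/% (nv + 1)
      (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    }
    v <- rbind(v, mid_of(keys))
    m1 <- nv + match(e1, keys)
    m2 <- nv + match(e2, keys)
    m3 <- nv + match(e3, keys)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  .finish_primitive(v, f, label)
}

#' Extrude a simple polygon into a prism
#'
#' Extrudes a convex (or star-shaped-from-vertex-1) polygon in the xy plane
#' along z. Caps are fan-triangulated from the first polygon vertex.
#'
#' @param poly_xy `n x 2` matrix of polygon vertices, counter-clockwise.
#' @param z0,z1 extrusion bounds, `z0 < z1`.
#' @param label mesh label.
#' @return A watertight [surface_mesh()].
#' @export
mesh_extrude_polygon <- function(poly_xy, z0, z1, label = "prism") {
  poly_xy <- as.matrix(poly_xy)
  n <- nrow(poly_xy)
  stopifnot(ncol(poly_xy) == 2L, n >= 3L, z1 > z0)
  v <- rbind(cbind(poly_xy, z0), cbind(poly_xy, z1))
  i <- seq_len(n)
  j <- c(i[-1], 1L)
  fan <- cbind(1L, i[-c(1L, n)] + 1L, i[-c(1L, n)])        # bottom cap, -z
  fan_top <- cbind(n + 1L, n + i[-c(1L, n)], n + i[-c(1L, n)] + 1L)
  f <- rbind(
    cbind(i, j, n + j),      # sides
    cbind(i, n + j, n + i),
    fan, fan_top
  )
  .finish_primitive(v, f, label)
}
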