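# Triangle surface meshes and rigid transforms.
#
# A surface mesh is the boundary of a solid: a watertight, consistently
# outward-oriented triangulation with coordinates in millimetres.

#' Construct a triangle surface mesh
#'
#' Builds the boundary representation of a solid bone or graft: an `n x 3`
#' vertex matrix (mm) and an `m x 3` face matrix of 1-based vertex indices.
#' By default the mesh is validated to be watertight (every edge shared by
#' exactly two faces, consistently oriented), free of degenerate triangles,
#' and outward-oriented (positive enclosed volume).
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @param label bone identifier: `"femur"`, `"tibia"` or any other string.
#' @param validate check the watertightness/orientation invariants.
#' @return An object of class `surface_mesh`.
#' @seealso [read_stl()], [enclosed_volume()], [apply_transform()]
#' @export
surface_mesh <- function(vertices, faces, label = "other", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  mesh <- structure(
    list(vertices = vertices, faces = faces, label = as.character(label)[1]),
    class = "surface_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces>\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  bb <- mesh_aabb(x)
  cat(sprintf("  bounds [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# directed edge table, one row per half-edge
.mesh_half_edges <- function(faces) {
  rbind(faces[, c(1L, 2L), drop = FALSE],
        faces[, c(2L, 3L), drop = FALSE],
        faces[, c(3L, 1L), drop = FALSE])
}

#' Check mesh watertightness
#'
#' A mesh bounds a solid iff every undirected edge is shared by exactly two
#' faces and each directed half-edge occurs exactly once (consistent
#' orientation).
#'
#' @param mesh a [surface_mesh()].
#' @return A list with `watertight` (logical), `n_boundary_edges` (edges used
#'   by a single face) and `oriented` (consistent winding).
#' @export
watertight_check <- function(mesh) {
  he <- .mesh_half_edges(mesh$faces)
  nv <- nrow(mesh$vertices)
  und <- pmin(he[, 1], he[, 2]) + as.numeric(nv + 1) * pmax(he[, 1], he[, 2])
  cnt <- table(und)
  dirk <- he[, 1] + as.numeric(nv + 1) * he[, 2]
  list(
    watertight = all(cnt == 2L) && !anyDuplicated(dirk),
    n_boundary_edges = sum(cnt == 1L),
    oriented = !anyDuplicated(dirk)
  )
}

.triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Validate surface mesh invariants
#'
#' Errors if the mesh is not watertight (reporting the open-edge count),
#' contains degenerate triangles (area below 1e-9 mm^2), or is inward
#' oriented (negative signed volume).
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh`, invisibly.
#' @export
validate_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  wt <- watertight_check(mesh)
  if (!wt$watertight) {
    stop(sprintf("mesh '%s' is not watertight: %d boundary edge(s)%s",
                 mesh$label, wt$n_boundary_edges,
                 if (!wt$oriented) ", inconsistent face orientation" else ""))
  }
  if (any(.triangle_areas(mesh) <= 1e-9)) {
    stop(sprintf("mesh '%s' contains degenerate triangles (area <= 1e-9 mm^2)",
                 mesh$label))
  }
  if (.signed_volume(mesh) <= 0) {
    stop(sprintf("mesh '%s' is inward-oriented (signed volume <= 0)", mesh$label))
  }
  invisible(mesh)
}

.signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# flip winding if the signed volume is negative (single closed component)
.orient_outward <- function(mesh) {
  if (.signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

# propagate a consistent winding over a closed, edge-manifold triangulation
# (BFS over the face adjacency graph), then fix the global sign so the
# surface is outward-oriented
.orient_consistent <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  nv <- nrow(mesh$vertices)
  he <- .mesh_half_edges(f)
  face_of <- rep(seq_len(nf), times = 3L)
  key <- pmin(he[, 1], he[, 2]) + as.numeric(nv + 1) * pmax(he[, 1], he[, 2])
  ord <- order(key)
  ks <- key[ord]
  fs <- face_of[ord]
  fwd <- (he[ord, 1] < he[ord, 2])        # half-edge runs min -> max vertex
  # pairs of rows sharing an undirected edge
  stopifnot(length(ks) %% 2L == 0L, all(ks[c(TRUE, FALSE)] == ks[c(FALSE, TRUE)]))
  f1 <- fs[c(TRUE, FALSE)]; f2 <- fs[c(FALSE, TRUE)]
  same_dir <- fwd[c(TRUE, FALSE)] == fwd[c(FALSE, TRUE)]
  adj <- vector("list", nf)
  for (e in seq_along(f1)) {
    adj[[f1[e]]] <- c(adj[[f1[e]]], list(c(f2[e], same_dir[e])))
    adj[[f2[e]]] <- c(adj[[f2[e]]], list(c(f1[e], same_dir[e])))
  }
  flip <- rep(NA, nf)
  flip[1] <- FALSE
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[cur]]) {
      g <- nb[1]
      # neighbours must traverse the shared edge oppositely; same direction
      # means exactly one of the two faces needs flipping
      want <- if (nb[2] == 1) !flip[cur] else flip[cur]
      if (is.na(flip[g])) {
        flip[g] <- want
        queue <- c(queue, g)
      } else if (flip[g] != want) {
        stop("surface is not orientable")
      }
    }
  }
  if (anyNA(flip)) stop("surface has more than one connected component")
  if (any(flip)) {
    f[flip, ] <- f[flip, c(1L, 3L, 2L), drop = FALSE]
    mesh$faces <- f
  }
  .orient_outward(mesh)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem signed-volume sum over the triangles; positive for an
#' outward-oriented surface.
#'
#' @param mesh a watertight [surface_mesh()].
#' @return Volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  wt <- watertight_check(mesh)
  if (!wt$watertight) {
    stop(sprintf("cannot compute volume: mesh not watertight (%d boundary edges)",
                 wt$n_boundary_edges))
  }
  .signed_volume(mesh)
}

#' Axis-aligned bounding box
#'
#' @param mesh a [surface_mesh()].
#' @return A `2 x 3` matrix, rows `min` and `max`.
#' @export
mesh_aabb <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

# merge vertices closer than `tol` (STL facets duplicate every vertex)
.merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  idx <- match(key, key)                # first occurrence per coordinate key
  keep <- sort(unique(idx))
  remap <- integer(nrow(vertices))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[idx[faces]], ncol = 3L)
  list(vertices = vertices[keep, , drop = FALSE], faces = faces)
}

#' Rigid-body transform
#'
#' @param rotation `3 x 3` rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 translation vector in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9) {
    stop("`rotation` is not orthonormal within 1e-9")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("`rotation` must have determinant +1 (no reflections)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("  translation [mm]:", sprintf("%.3f", x$translation), "\n")
  invisible(x)
}

#' Rotation about an arbitrary axis
#'
#' @param axis length-3 direction vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return A `3 x 3` rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param points numeric vector of length 3 or an `n x 3` matrix.
#' @param t a [rigid_transform()].
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(points, t) {
  if (is.null(dim(points))) {
    as.numeric(t$rotation %*% points) + t$translation
  } else {
    sweep(points %*% t(t$rotation), 2, t$translation, "+")
  }
}

#' Apply a rigid transform to a mesh
#'
#' Vertex-wise rigid map; the enclosed volume is preserved.
#'
#' @param mesh a [surface_mesh()].
#' @param t a [rigid_transform()].
#' @return The transformed [surface_mesh()].
#' @export
apply_transform <- function(mesh, t) {
  mesh$vertices <- transform_points(mesh$vertices, t)
  mesh
}
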