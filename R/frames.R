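# Quadrant reference frames and percentage footprint coordinates.
#
# The femoral frame is the classical quadrant grid drawn on the true-lateral
# view of the medial wall of the lateral femoral condyle: the superior border
# is the line through the highest point of the intercondylar notch along the
# notch-roof (Blumensaat) direction, and positions are expressed as fractions
# of the grid's total height (superior -> inferior) and total depth
# (posterior -> anterior). The tibial frame is the bounding rectangle of the
# plateau's cortical outline in the top view, with fractions of total depth
# (anterior -> posterior) and total width (medial -> lateral).

.norm3 <- function(v) sqrt(sum(v^2))

.unit <- function(v, what = "vector") {
  n <- .norm3(v)
  if (n < 1e-12) stop(what, " has zero length (collinear or missing landmarks?)")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.reject <- function(v, n) v - sum(v * n) * n

.get_landmark <- function(landmarks, name) {
  p <- landmarks[[name]]
  if (is.null(p)) stop("missing landmark '", name, "'")
  p <- as.numeric(p)
  if (length(p) != 3L || anyNA(p)) stop("landmark '", name, "' is not a 3D point")
  p
}

#' Femoral quadrant frame
#'
#' @param origin 3D point at the superior-posterior corner of the grid (mm).
#' @param height_axis unit vector, superior to inferior along the wall.
#' @param depth_axis unit vector, posterior to anterior along the superior
#'   border (notch-roof direction).
#' @param normal unit vector, lateral-wall outward (the true-lateral viewing
#'   axis).
#' @param total_height,total_depth grid extents in mm.
#' @return An object of class `femoral_frame`.
#' @export
femoral_frame <- function(origin, height_axis, depth_axis, normal,
                          total_height, total_depth) {
  fr <- structure(list(origin = as.numeric(origin),
                       height_axis = as.numeric(height_axis),
                       depth_axis = as.numeric(depth_axis),
                       normal = as.numeric(normal),
                       total_height = total_height,
                       total_depth = total_depth),
                  class = "femoral_frame")
  .check_frame_axes(list(fr$height_axis, fr$depth_axis, fr$normal))
  stopifnot(total_height > 0, total_depth > 0)
  fr
}

#' Tibial plateau frame
#'
#' @param origin 3D point at the anterior-medial corner of the plateau
#'   bounding rectangle (mm).
#' @param depth_axis unit vector, anterior to posterior.
#' @param width_axis unit vector, medial to lateral.
#' @param normal unit vector, plateau-view (superior) direction.
#' @param total_depth,total_width extents in mm.
#' @return An object of class `tibial_frame`.
#' @export
tibial_frame <- function(origin, depth_axis, width_axis, normal,
                         total_depth, total_width) {
  fr <- structure(list(origin = as.numeric(origin),
                       depth_axis = as.numeric(depth_axis),
                       width_axis = as.numeric(width_axis),
                       normal = as.numeric(normal),
                       total_depth = total_depth,
                       total_width = total_width),
                  class = "tibial_frame")
  .check_frame_axes(list(fr$depth_axis, fr$width_axis, fr$normal))
  stopifnot(total_depth > 0, total_width > 0)
  fr
}

.check_frame_axes <- function(axes, tol = 1e-6) {
  for (a in axes) {
    if (abs(.norm3(a) - 1) > tol) stop("frame axis is not unit length")
  }
  for (i in 1:2) for (j in (i + 1):3) {
    if (abs(sum(axes[[i]] * axes[[j]])) > tol) {
      stop("frame axes are not mutually orthogonal")
    }
  }
  invisible(TRUE)
}

#' @export
print.femoral_frame <- function(x, ...) {
  cat(sprintf("<femoral_frame: height %.1f mm, depth %.1f mm>\n",
              x$total_height, x$total_depth))
  invisible(x)
}

#' @export
print.tibial_frame <- function(x, ...) {
  cat(sprintf("<tibial_frame: depth %.1f mm, width %.1f mm>\n",
              x$total_depth, x$total_width))
  invisible(x)
}

#' Fit the femoral quadrant frame from named landmarks
#'
#' Landmarks (a named list of 3D points, plus one direction vector):
#' \describe{
#'   \item{notch_apex}{highest point of the intercondylar notch; the
#'     superior border passes through it.}
#'   \item{roof_anterior}{anterior end of the notch roof; together with the
#'     apex it fixes the superior-border (Blumensaat) direction.}
#'   \item{wall_inferior_posterior, wall_inferior_anterior}{inferior corners
#'     of the lateral-wall outline in the true-lateral view.}
#'   \item{wall_normal}{lateral-wall outward direction (viewing axis).}
#' }
#' The depth axis is the superior-border direction projected into the view
#' plane (the operational quadrant-grid convention); the height axis is the
#' in-plane perpendicular pointing inferiorly. Grid extents are the spans of
#' the outline landmarks along the two axes.
#'
#' @param femur femoral [surface_mesh()] (carried for downstream projection;
#'   the frame itself is landmark-defined, as in manual planning software).
#' @param landmarks named list, see Details.
#' @return A [femoral_frame()].
#' @export
fit_femoral_frame <- function(femur, landmarks) {
  apex <- .get_landmark(landmarks, "notch_apex")
  ant <- .get_landmark(landmarks, "roof_anterior")
  inf_p <- .get_landmark(landmarks, "wall_inferior_posterior")
  inf_a <- .get_landmark(landmarks, "wall_inferior_anterior")
  nrm <- .unit(.get_landmark(landmarks, "wall_normal"), "wall_normal")

  d <- .unit(.reject(ant - apex, nrm), "superior border direction")
  h <- .cross3(nrm, d)
  if (sum(h * (inf_p - apex)) < 0) h <- -h
  h <- .unit(h, "height axis")
  if (abs(sum(h * (inf_p - apex))) < 1e-9) {
    stop("landmarks are collinear: cannot orient the height axis")
  }
  # anterior/posterior consistency: the inferior outline must advance along
  # the depth axis in the same sense as the superior border, and the
  # resulting triad must be right-handed with respect to the wall normal
  if (sum((inf_a - inf_p) * d) <= 0) {
    stop("anterior/posterior landmarks appear swapped (depth axis inconsistent)")
  }
  if (sum(.cross3(h, d) * nrm) <= 0) {
    stop("anterior/posterior landmarks appear swapped (left-handed frame)")
  }
  corners <- rbind(apex, ant, inf_p, inf_a)
  rel <- sweep(corners, 2, apex)
  sd_ <- as.numeric(rel %*% d)
  sh_ <- as.numeric(rel %*% h)
  td <- diff(range(sd_))
  th <- diff(range(sh_))
  if (td < 1e-6 || th < 1e-6) stop("degenerate lateral-wall outline")
  origin <- apex + min(sd_) * d + min(sh_) * h
  femoral_frame(origin, h, d, nrm, total_height = th, total_depth = td)
}

#' Fit the tibial plateau frame from named landmarks
#'
#' Landmarks: `plateau_anterior`, `plateau_posterior`, `plateau_medial`,
#' `plateau_lateral` (extreme cortical-outline points of the plateau in top
#' view) and `plateau_normal` (superior direction of the joint surface).
#' The frame is the bounding rectangle of those points: depth axis anterior
#' to posterior, width axis medial to lateral, origin at the anterior-medial
#' corner.
#'
#' @param tibia tibial [surface_mesh()].
#' @param landmarks named list, see Details.
#' @return A [tibial_frame()].
#' @export
fit_tibial_frame <- function(tibia, landmarks) {
  ant <- .get_landmark(landmarks, "plateau_anterior")
  post <- .get_landmark(landmarks, "plateau_posterior")
  med <- .get_landmark(landmarks, "plateau_medial")
  lat <- .get_landmark(landmarks, "plateau_lateral")
  nrm <- .unit(.get_landmark(landmarks, "plateau_normal"), "plateau_normal")

  d <- .unit(.reject(post - ant, nrm), "depth axis")
  w <- .cross3(nrm, d)
  if (sum(w * (lat - med)) < 0) w <- -w
  w <- .unit(w, "width axis")
  if (abs(sum(w * (lat - med))) < 1e-9) {
    stop("degenerate plateau outline: medial-lateral landmarks collinear with depth axis")
  }
  corners <- rbind(ant, post, med, lat)
  rel <- sweep(corners, 2, ant)
  sd_ <- as.numeric(rel %*% d)
  sw_ <- as.numeric(rel %*% w)
  td <- diff(range(sd_))
  tw <- diff(range(sw_))
  if (td < 1e-6 || tw < 1e-6) stop("degenerate (flat) plateau outline")
  origin <- ant + min(sd_) * d + min(sw_) * w
  tibial_frame(origin, d, w, nrm, total_depth = td, total_width = tw)
}

#' Map grid fractions to a point on the bone surface
#'
#' Places the in-plane grid point `origin + frac_1 * extent_1 * axis_1 +
#' frac_2 * extent_2 * axis_2` and projects it onto the bone surface along
#' the frame normal (nearest ray-mesh hit in either direction). For the
#' femoral frame `frac_1` is the height fraction (from the superior border)
#' and `frac_2` the depth fraction (from the posterior border); for the
#' tibial frame `frac_1` is the depth fraction (from the anterior border)
#' and `frac_2` the width fraction (from the medial border).
#'
#' @param frame a [femoral_frame()] or [tibial_frame()].
#' @param frac_1,frac_2 fractions in `[0, 1]`.
#' @param mesh the bone [surface_mesh()] to project onto.
#' @return A length-3 point on the surface, with attributes `face` (hit
#'   triangle index) and `face_normal` (outward unit normal of that
#'   triangle).
#' @export
grid_to_point <- function(frame, frac_1, frac_2, mesh) {
  stopifnot(frac_1 >= 0, frac_1 <= 1, frac_2 >= 0, frac_2 <= 1)
  if (inherits(frame, "femoral_frame")) {
    g <- frame$origin + frac_1 * frame$total_height * frame$height_axis +
      frac_2 * frame$total_depth * frame$depth_axis
  } else if (inherits(frame, "tibial_frame")) {
    g <- frame$origin + frac_1 * frame$total_depth * frame$depth_axis +
      frac_2 * frame$total_width * frame$width_axis
  } else {
    stop("`frame` must be a femoral_frame or tibial_frame")
  }
  .project_to_surface(g, frame$normal, mesh)
}

.project_to_surface <- function(point, direction, mesh) {
  hits <- cpp_ray_hits(mesh$vertices, mesh$faces, as.numeric(point),
                       as.numeric(direction))
  if (length(hits$t) == 0L) {
    stop("projection ray misses the mesh: frame and bone appear inconsistent")
  }
  k <- which.min(abs(hits$t))
  p <- as.numeric(point) + hits$t[k] * as.numeric(direction)
  f <- hits$face[k]
  tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
  n <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  n <- .unit(n, "face normal")
  structure(p, face = f, face_normal = n)
}

#' Footprint percentage coordinates of the AM and PL bundles
#'
#' The shipped fraction table (also available as a YAML config in
#' `inst/extdata/footprint_fractions.yaml`): femoral AM at 25% of total
#' height and 33% of total depth, femoral PL at 45.1% and 50%; tibial AM at
#' 35% of total depth and 50.5% of total width, tibial PL at 46.4% and
#' 52.4%. Femoral depth fractions follow the quadrant-grid convention of
#' measuring from the posterior border; `depth_from = "anterior"` converts
#' femoral depth fractions to the opposite reading of the prose convention.
#'
#' @param side `"femur"` or `"tibia"`.
#' @param bundle `"AM"` or `"PL"` (the central point is derived, see
#'   [footprint_center()]).
#' @param depth_from femoral depth convention, `"posterior"` (default) or
#'   `"anterior"`.
#' @param table optional fraction table (as returned by
#'   [load_footprint_fractions()]).
#' @return Named numeric vector `c(frac_1, frac_2)`.
#' @export
footprint_fractions <- function(side = c("femur", "tibia"),
                                bundle = c("AM", "PL"),
                                depth_from = c("posterior", "anterior"),
                                table = NULL) {
  side <- match.arg(side)
  bundle <- match.arg(bundle)
  depth_from <- match.arg(depth_from)
  if (is.null(table)) table <- load_footprint_fractions()
  fr <- table[[side]][[bundle]]
  if (is.null(fr)) stop("no fractions for ", side, " ", bundle)
  fr <- as.numeric(fr)
  if (side == "femur" && depth_from == "anterior") fr[2] <- 1 - fr[2]
  names(fr) <- if (side == "femur") c("height", "depth") else c("depth", "width")
  fr
}

#' Load the footprint fraction table
#'
#' @param path YAML file with `femur`/`tibia` blocks of `AM`/`PL` fraction
#'   pairs; defaults to the table shipped with the package.
#' @return Nested list of fraction pairs.
#' @export
load_footprint_fractions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "footprint_fractions.yaml",
                        package = "aclimpinge")
  }
  yaml::read_yaml(path)
}

#' Compute a bundle footprint centre on the bone surface
#'
#' AM and PL centres come from the percentage table via [grid_to_point()];
#' the central point is the 3D midpoint of the AM and PL surface points,
#' re-projected onto the surface along the frame normal.
#'
#' @param side `"femur"` or `"tibia"`.
#' @param bundle `"AM"`, `"central"` or `"PL"`.
#' @param frame the fitted frame for that side.
#' @param mesh the bone [surface_mesh()].
#' @param depth_from femoral depth convention (see [footprint_fractions()]).
#' @param table optional fraction table.
#' @return A surface point as in [grid_to_point()].
#' @export
footprint_center <- function(side, bundle, frame, mesh,
                             depth_from = c("posterior", "anterior"),
                             table = NULL) {
  depth_from <- match.arg(depth_from)
  if (bundle %in% c("AM", "PL")) {
    fr <- footprint_fractions(side, bundle, depth_from = depth_from,
                              table = table)
    return(grid_to_point(frame, fr[1], fr[2], mesh))
  }
  if (bundle != "central") stop("unknown bundle '", bundle, "'")
  am <- footprint_center(side, "AM", frame, mesh, depth_from, table)
  pl <- footprint_center(side, "PL", frame, mesh, depth_from, table)
  mid <- (as.numeric(am) + as.numeric(pl)) / 2
  .project_to_surface(mid, frame$normal, mesh)
}
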