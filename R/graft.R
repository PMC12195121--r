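# The virtual graft: a rigid cylinder spanning the femoral and tibial
# footprint centres. No bending or wrapping at the notch margin is modelled.

#' Build a virtual cylindrical graft
#'
#' Creates a watertight capped cylinder whose axis runs from the femoral to
#' the tibial footprint centre.
#'
#' @param femoral_point,tibial_point 3D footprint centres in mm.
#' @param diameter graft diameter in mm (7 and 9 in the reference design;
#'   any positive value is accepted).
#' @param n_segments circumferential tessellation (default 128, which keeps
#'   the enclosed volume within 0.1% of the analytic cylinder volume).
#' @return A [surface_mesh()] labelled `"graft"`, with attributes
#'   `femoral_point`, `tibial_point`, `diameter` and `axis`.
#' @export
build_graft <- function(femoral_point, tibial_point, diameter,
                        n_segments = 128L) {
  femoral_point <- as.numeric(femoral_point)
  tibial_point <- as.numeric(tibial_point)
  if (diameter <= 0) stop("`diameter` must be positive")
  len <- .norm3(tibial_point - femoral_point)
  if (len < 1e-9) stop("footprint endpoints are coincident")
  if (len <= diameter / 2) {
    stop(sprintf(
      "endpoint separation (%.2f mm) must exceed the graft radius (%.2f mm)",
      len, diameter / 2))
  }
  m <- mesh_cylinder(femoral_point, tibial_point, radius = diameter / 2,
                     n_segments = n_segments, label = "graft")
  attr(m, "femoral_point") <- femoral_point
  attr(m, "tibial_point") <- tibial_point
  attr(m, "diameter") <- diameter
  attr(m, "axis") <- (tibial_point - femoral_point) / len
  m
}

#' Truncate a graft away from its attachment sites
#'
#' Returns the impingement probe: the graft shortened by `cap_depth` at each
#' end (a coaxial cylinder), so that overlap immediately at the insertion
#' sites can be excluded from the impingement measurement. `cap_depth = 0`
#' returns the full graft unchanged.
#'
#' @param graft a graft mesh from [build_graft()].
#' @param femoral_point,tibial_point the graft endpoints (default: taken
#'   from the graft attributes).
#' @param cap_depth length removed at each end, mm (>= 0).
#' @param n_segments tessellation of the rebuilt probe.
#' @return A [surface_mesh()] probe.
#' @export
attachment_exclusion_mask <- function(graft,
                                      femoral_point = attr(graft, "femoral_point"),
                                      tibial_point = attr(graft, "tibial_point"),
                                      cap_depth = 0,
                                      n_segments = 128L) {
  if (cap_depth < 0) stop("`cap_depth` must be >= 0")
  if (cap_depth == 0) return(graft)
  femoral_point <- as.numeric(femoral_point)
  tibial_point <- as.numeric(tibial_point)
  len <- .norm3(tibial_point - femoral_point)
  if (2 * cap_depth >= len) {
    stop(sprintf("2 * cap_depth (%.2f mm) must be below the axis length (%.2f mm)",
                 2 * cap_depth, len))
  }
  u <- (tibial_point - femoral_point) / len
  build_graft(femoral_point + cap_depth * u, tibial_point - cap_depth * u,
              diameter = attr(graft, "diameter"), n_segments = n_segments)
}
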