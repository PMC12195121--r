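# Impingement measurement: graft-femur Boolean overlap volume and the
# anterior-view notch width.

#' Graft-notch impingement volume
#'
#' Overlap volume between the femoral solid and the graft probe, measured
#' with the voxel Boolean kernel. Impingement is measured against the
#' entire femoral solid -- the intercondylar notch is where overlap
#' physically occurs -- rather than against a pre-segmented notch region.
#' Optional clip planes (see [intersection_volume()]) let the caller
#' exclude the attachment side of the femoral wall.
#'
#' @param femur femoral [surface_mesh()].
#' @param graft_probe graft (or truncated graft) [surface_mesh()].
#' @param spacing voxel edge length in mm (default 0.5).
#' @param clip_planes optional half-space constraints.
#' @return Overlap volume in mm^3 (0 when the solids are disjoint).
#' @export
impingement_volume <- function(femur, graft_probe, spacing = 0.5,
                               clip_planes = NULL) {
  intersection_volume(femur, graft_probe, spacing = spacing,
                      clip_planes = clip_planes)
}

#' Notch width from the anterior view
#'
#' Measures the intercondylar notch at its widest part as seen from the
#' anterior view: the femoral silhouette is rasterized in the
#' mediolateral/proximodistal plane, and horizontal chords are swept over
#' notch height in `step`-mm increments; the width is the largest
#' mediolateral gap between the condylar inner walls.
#'
#' @param femur femoral [surface_mesh()].
#' @param pose optional [rigid_transform()] applied to the femur first
#'   (e.g. a 90-degree flexion pose for scanned knees; the measurement
#'   itself is pose-invariant for the synthetic femur).
#' @param step chord sweep step in mm (default 0.25).
#' @return Notch width in mm.
#' @export
notch_width <- function(femur, pose = NULL, step = 0.25) {
  if (!is.null(pose)) femur <- apply_transform(femur, pose)
  validate_mesh(femur)
  # silhouette along the anteroposterior (y) axis: permute to (x, z, y)
  # so the parity kernel casts along the viewing direction
  perm <- femur
  perm$vertices <- femur$vertices[, c(1L, 3L, 2L), drop = FALSE]
  grid <- .grid_for_aabb(mesh_aabb(perm), step)
  occ <- cpp_voxelize(perm$vertices, perm$faces, grid$origin, step,
                      as.integer(grid$dims))
  dim(occ) <- grid$dims
  sil <- apply(occ, c(1L, 2L), any)     # x (ML) by z (height)
  widest <- 0
  for (j in seq_len(ncol(sil))) {
    row <- sil[, j]
    occ_idx <- which(row)
    if (length(occ_idx) < 2L) next
    inner <- row[occ_idx[1]:occ_idx[length(occ_idx)]]
    r <- rle(inner)
    gaps <- r$lengths[!r$values]
    if (length(gaps)) widest <- max(widest, max(gaps) * step)
  }
  if (widest <= 0) {
    stop("no intercondylar notch found (no concavity in the anterior silhouette)")
  }
  widest
}
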