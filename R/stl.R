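# STL input/output. STL stores three duplicated vertices per facet, so
# reading merges coincident vertices before the watertightness check.

#' Read an STL file
#'
#' Reads a binary or ASCII STL surface, merges duplicated facet vertices
#' (tolerance `merge_tol`), and validates the watertightness and outward
#' orientation invariants. A mesh whose facets are consistently wound but
#' globally inverted is re-oriented rather than rejected.
#'
#' @param path path to an `.stl` file.
#' @param label bone identifier stored on the mesh.
#' @param merge_tol vertex merge tolerance in mm.
#' @param validate if `TRUE` (default) enforce the solid invariants; a
#'   non-watertight surface raises an error naming the open-edge count.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, label = "other", merge_tol = 1e-6, validate = TRUE) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  tris <- NULL
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    invisible(readBin(con, "raw", n = 80L))
    nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(nt) && nt >= 0 && size == 84 + 50 * as.numeric(nt)) {
      raw <- readBin(con, "raw", n = 50L * nt)
      block <- matrix(raw, nrow = 50L)            # one column per facet
      fl <- readBin(as.vector(block[1:48, , drop = FALSE]), "numeric",
                    n = 12L * nt, size = 4L, endian = "little")
      m <- matrix(fl, nrow = 12L)                 # normal + 3 vertices
      # columns of m[4:12, ] are per-facet; unravel to (3*nt) x 3 points
      tris <- t(matrix(m[4:12, , drop = FALSE], nrow = 3L))
    }
  }
  if (is.null(tris)) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("cannot parse STL file (neither valid binary nor ASCII): ", path)
    }
    nums <- lapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]))
    tris <- do.call(rbind, nums)
    if (anyNA(tris)) stop("malformed vertex line in ASCII STL: ", path)
  }
  nt <- nrow(tris) / 3L
  faces <- matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE)
  md <- .merge_vertices(tris, faces, tol = merge_tol)
  mesh <- surface_mesh(md$vertices, md$faces, label = label, validate = FALSE)
  if (validate) {
    wt <- watertight_check(mesh)
    if (!wt$watertight) {
      stop(sprintf("STL surface '%s' is not watertight: %d boundary edge(s)",
                   basename(path), wt$n_boundary_edges))
    }
    mesh <- .orient_outward(mesh)
    validate_mesh(mesh)
  }
  mesh
}

#' Write a mesh as ASCII STL
#'
#' Deterministic formatting: identical meshes produce byte-identical files.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  out <- c(
    sprintf("solid %s", mesh$label),
    as.vector(rbind(
      sprintf("  facet normal %s", fmt(n)),
      "    outer loop",
      sprintf("      vertex %s", fmt(a)),
      sprintf("      vertex %s", fmt(b)),
      sprintf("      vertex %s", fmt(c_)),
      "    endloop",
      "  endfacet"
    )),
    sprintf("endsolid %s", mesh$label)
  )
  writeLines(out, path)
  invisible(path)
}

#' Write a mesh in OFF format
#'
#' Plain-text OFF export for debugging in external mesh viewers.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- c(
    "OFF",
    sprintf("%d %d 0", nrow(v), nrow(f)),
    sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  )
  writeLines(out, path)
  invisible(path)
}
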