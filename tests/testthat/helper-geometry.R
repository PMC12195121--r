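# shared fixtures: analytic solids and a small default knee, all built in
# code at test time

unit_cube <- function() mesh_box(c(0, 0, 0), c(1, 1, 1))

default_knee <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_knee()
    cache
  }
})

# records data frame shaped like run_knee() output, for the stats tests
make_records <- function(volume, diameter = 9, femoral = "AM", tibial = "AM",
                         knee_id = "k1", angle = 0) {
  data.frame(knee_id = knee_id, flexion_angle = angle,
             femoral_position = femoral, tibial_position = tibial,
             diameter = diameter, volume = volume, spacing = 0.5,
             status = "ok", error = NA_character_,
             stringsAsFactors = FALSE)
}

# write a binary STL for the given mesh (little-endian), used to exercise
# the binary reader against the ASCII path
write_binary_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- c(0, 0, 0)
    writeBin(as.numeric(c(n, t(tri))), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}
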