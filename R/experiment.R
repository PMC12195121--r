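# Factorial experiment runner: footprint positions x graft diameters x
# flexion angles, one impingement record per cell.

#' Factorial simulation design
#'
#' The default design is the full reference battery: 3 femoral x 3 tibial
#' footprint positions x 2 graft diameters (7, 9 mm) x 4 flexion angles
#' (0, 45, 90, 120 degrees) = 72 cells per knee.
#'
#' @param femoral_positions,tibial_positions subsets of
#'   `c("AM", "central", "PL")`.
#' @param diameters graft diameters in mm.
#' @param flexion_angles flexion angles in degrees.
#' @param spacing voxel spacing of the volume kernel in mm.
#' @param n_segments graft tessellation.
#' @param attachment_exclusion how the graft-attachment region is kept out
#'   of the impingement volume: `"wall_plane"` (default) clips the count at
#'   the femoral-wall tangent plane through the footprint, `"cap"`
#'   truncates the graft by `cap_depth` at both ends, `"none"` counts all
#'   overlap.
#' @param cap_depth truncation length in mm for
#'   `attachment_exclusion = "cap"`.
#' @param depth_from femoral depth-fraction convention (see
#'   [footprint_fractions()]).
#' @return An object of class `factorial_design`.
#' @export
factorial_design <- function(femoral_positions = c("AM", "central", "PL"),
                             tibial_positions = c("AM", "central", "PL"),
                             diameters = c(7, 9),
                             flexion_angles = c(0, 45, 90, 120),
                             spacing = 0.5,
                             n_segments = 128L,
                             attachment_exclusion = c("wall_plane", "cap", "none"),
                             cap_depth = 0,
                             depth_from = c("posterior", "anterior")) {
  positions <- c("AM", "central", "PL")
  femoral_positions <- match.arg(femoral_positions, positions,
                                 several.ok = TRUE)
  tibial_positions <- match.arg(tibial_positions, positions,
                                several.ok = TRUE)
  attachment_exclusion <- match.arg(attachment_exclusion)
  depth_from <- match.arg(depth_from)
  stopifnot(length(diameters) >= 1L, all(diameters > 0),
            length(flexion_angles) >= 1L, spacing > 0, cap_depth >= 0)
  structure(list(femoral_positions = femoral_positions,
                 tibial_positions = tibial_positions,
                 diameters = as.numeric(diameters),
                 flexion_angles = as.numeric(flexion_angles),
                 spacing = spacing, n_segments = as.integer(n_segments),
                 attachment_exclusion = attachment_exclusion,
                 cap_depth = cap_depth, depth_from = depth_from),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf(paste0("<factorial_design: %d femoral x %d tibial x %d diameter",
                     " x %d angle = %d cells per knee; spacing %.2g mm;",
                     " attachment exclusion '%s'>\n"),
              length(x$femoral_positions), length(x$tibial_positions),
              length(x$diameters), length(x$flexion_angles),
              length(x$femoral_positions) * length(x$tibial_positions) *
                length(x$diameters) * length(x$flexion_angles),
              x$spacing, x$attachment_exclusion))
  invisible(x)
}

#' Enumerate footprint combinations of a design
#'
#' @param design a [factorial_design()].
#' @return A data frame with columns `femoral_position` and
#'   `tibial_position`, one row per configuration (9 in the default
#'   design).
#' @export
footprint_combinations <- function(design = factorial_design()) {
  expand.grid(femoral_position = design$femoral_positions,
              tibial_position = design$tibial_positions,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run the factorial design on one knee
#'
#' Fits the quadrant frames, places the footprint centres, builds the
#' graft for every design cell and measures its impingement volume against
#' the femur. A failure in one cell is recorded as a structured error row
#' (`status = "error"`) and the run continues.
#'
#' @param knee a `synthetic_knee` (or compatible list with `femur`,
#'   `tibia`, `landmarks`, and for posing, `truth$flexion_axis`).
#' @param design a [factorial_design()].
#' @param knee_id identifier written into the records.
#' @param verbose log per-cell progress to `stderr`.
#' @return A data frame of impingement records, one row per cell:
#'   `knee_id`, `flexion_angle`, `femoral_position`, `tibial_position`,
#'   `diameter`, `volume` (mm^3), `spacing`, `status`, `error`.
#' @export
run_knee <- function(knee, design = factorial_design(),
                     knee_id = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "factorial_design"))
  knee_id <- knee_id %||% knee$id %||% "knee1"
  cells <- expand.grid(flexion_angle = design$flexion_angles,
                       femoral_position = design$femoral_positions,
                       tibial_position = design$tibial_positions,
                       diameter = design$diameters,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$flexion_angle, cells$femoral_position,
                       cells$tibial_position, cells$diameter), ,
                 drop = FALSE]

  fem_frame <- NULL
  fem_pts <- list()
  frame_err <- NULL
  tryCatch({
    fem_frame <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
    for (pos in design$femoral_positions) {
      fem_pts[[pos]] <- footprint_center("femur", pos, fem_frame, knee$femur,
                                         depth_from = design$depth_from)
    }
  }, error = function(e) frame_err <<- conditionMessage(e))

  tib_pts_by_angle <- list()
  tib_err_by_angle <- list()
  for (ang in unique(cells$flexion_angle)) {
    key <- as.character(ang)
    tryCatch({
      posed <- if (ang == 0) knee else pose_at_flexion(knee, ang)
      tf <- fit_tibial_frame(posed$tibia, posed$landmarks$tibia)
      pts <- list()
      for (pos in design$tibial_positions) {
        pts[[pos]] <- footprint_center("tibia", pos, tf, posed$tibia)
      }
      tib_pts_by_angle[[key]] <- pts
    }, error = function(e) tib_err_by_angle[[key]] <<- conditionMessage(e))
  }

  n <- nrow(cells)
  volume <- rep(NA_real_, n)
  status <- rep("ok", n)
  errmsg <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ang <- cells$flexion_angle[i]
    fpos <- cells$femoral_position[i]
    tpos <- cells$tibial_position[i]
    d <- cells$diameter[i]
    res <- tryCatch({
      if (!is.null(frame_err)) stop("femoral frame: ", frame_err)
      terr <- tib_err_by_angle[[as.character(ang)]]
      if (!is.null(terr)) stop("tibial frame at ", ang, " deg: ", terr)
      fp <- fem_pts[[fpos]]
      tp <- tib_pts_by_angle[[as.character(ang)]][[tpos]]
      graft <- build_graft(fp, tp, diameter = d,
                           n_segments = design$n_segments)
      probe <- graft
      clip <- NULL
      if (design$attachment_exclusion == "cap") {
        probe <- attachment_exclusion_mask(graft, cap_depth = design$cap_depth,
                                           n_segments = design$n_segments)
      } else if (design$attachment_exclusion == "wall_plane") {
        clip <- list(list(point = as.numeric(fp),
                          normal = attr(fp, "face_normal")))
      }
      impingement_volume(knee$femur, probe, spacing = design$spacing,
                         clip_planes = clip)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "error"
      errmsg[i] <- conditionMessage(res)
    } else {
      volume[i] <- res
    }
    if (verbose) {
      message(sprintf("[%s] %3g deg fem=%s tib=%s d=%g mm -> %s", knee_id,
                      ang, fpos, tpos, d,
                      if (status[i] == "ok") sprintf("%.1f mm^3", volume[i])
                      else paste("ERROR:", errmsg[i])))
    }
  }
  out <- data.frame(knee_id = knee_id, flexion_angle = cells$flexion_angle,
                    femoral_position = cells$femoral_position,
                    tibial_position = cells$tibial_position,
                    diameter = cells$diameter, volume = volume,
                    spacing = design$spacing, status = status,
                    error = errmsg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the factorial design on a knee population
#'
#' @param knees list of knees (see [generate_population()]).
#' @param design a [factorial_design()].
#' @param verbose log per-cell progress.
#' @return Row-bound impingement records of all knees.
#' @export
run_population <- function(knees, design = factorial_design(),
                           verbose = FALSE) {
  recs <- lapply(seq_along(knees), function(i) {
    run_knee(knees[[i]], design,
             knee_id = knees[[i]]$id %||% sprintf("knee%02d", i),
             verbose = verbose)
  })
  do.call(rbind, recs)
}

#' Aggregate impingement records into a mean +/- SD table
#'
#' @param records impingement records from [run_knee()].
#' @param group_by character vector of grouping columns (default femoral by
#'   tibial position).
#' @return A data frame with one row per factor combination and columns
#'   `n`, `mean`, `sd` (n-1 denominator). Empty groups are omitted with a
#'   warning.
#' @export
aggregate_impingement <- function(records,
                                  group_by = c("femoral_position",
                                               "tibial_position")) {
  stopifnot(nrow(records) > 0, all(group_by %in% names(records)))
  ok <- records$status == "ok" & !is.na(records$volume)
  if (!all(ok)) {
    warning(sprintf("%d failed record(s) omitted from aggregation",
                    sum(!ok)))
  }
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0) stop("no successful records to aggregate")
  full <- do.call(expand.grid, c(lapply(rec[group_by], unique),
                                 list(stringsAsFactors = FALSE)))
  g <- rec[group_by]
  agg_n <- aggregate(rec$volume, by = g, FUN = length)
  agg_m <- aggregate(rec$volume, by = g, FUN = mean)
  agg_s <- aggregate(rec$volume, by = g, FUN = sd)
  out <- agg_n
  names(out)[ncol(out)] <- "n"
  out$mean <- agg_m$x
  out$sd <- agg_s$x
  if (nrow(out) < nrow(full)) {
    warning("empty factor combination(s) omitted from the table")
  }
  out[do.call(order, out[group_by]), , drop = FALSE]
}

#' Write impingement records as CSV
#'
#' Stable column order; re-running an identical configuration yields
#' byte-identical files unless a timestamp header is requested.
#'
#' @param records impingement records.
#' @param path output path.
#' @param timestamp prepend a `# generated <time>` comment line.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, timestamp = FALSE) {
  cols <- c("knee_id", "flexion_angle", "femoral_position",
            "tibial_position", "diameter", "volume", "spacing", "status",
            "error")
  con <- file(path, "w")
  on.exit(close(con))
  if (timestamp) writeLines(sprintf("# generated %s", Sys.time()), con)
  write.csv(records[cols], con, row.names = FALSE)
  invisible(path)
}

#' Read impingement records from CSV
#'
#' @param path CSV written by [write_records()].
#' @return Impingement records data frame.
#' @export
read_records <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an experiment configuration file
#'
#' YAML with any of the [factorial_design()] fields plus optional `seed`
#' and `n_knees` for population generation.
#'
#' @param path YAML file.
#' @return A list with elements `design` (a [factorial_design()]), `seed`
#'   and `n_knees`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design_args <- cfg[intersect(names(cfg),
                               names(formals(factorial_design)))]
  list(design = do.call(factorial_design, design_args),
       seed = cfg$seed %||% 1L,
       n_knees = cfg$n_knees %||% 9L)
}
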