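# Parametric synthetic knee generator.
#
# Stands in for CT-reconstructed subjects: a stylized distal femur (two
# condylar blocks flanking an intercondylar notch whose roof slopes
# anteriorly-inferiorly, i.e. a planar Blumensaat surface) and a proximal
# tibia (elliptic plateau slab), both watertight, with analytic ground
# truth for every quantity the measurement pipeline recovers: quadrant
# frames, landmarks, footprint centres, notch width and the flexion axis.
# The geometry is deliberately simple rather than anatomically faithful --
# its purpose is controllable, closed-form validation geometry.

#' Parameters of the synthetic knee generator
#'
#' All lengths in mm, angles in degrees. The defaults describe an
#' average-sized adult knee: notch width 19.0 mm (population SD 3.4 mm in
#' [generate_population()]), notch height 25 mm, 24 mm-wide condylar
#' blocks and a 28 mm anteroposterior condylar depth. The notch roof
#' slopes 40 degrees anteriorly and the plateau sits 14 mm anterior to
#' the femoral centre, the extension pose in which near-extension grafts
#' run almost parallel to the roof and impinge beneath its anterior
#' margin, as in roof impingement after anterior tunnel placement.
#'
#' @param notch_width gap between the condylar inner walls at the notch
#'   base -- the widest part of the notch seen in the anterior view.
#' @param notch_height distance from the distal (notch base) plane to the
#'   highest point of the notch.
#' @param condyle_radius half-width of each condylar block; also sets the
#'   bone stock above the notch apex.
#' @param condyle_spacing centre-to-centre mediolateral distance between
#'   the condylar blocks. Defaults to `notch_width + 2 * condyle_radius`,
#'   the value consistent with the wall positions; a conflicting explicit
#'   value is an error.
#' @param roof_angle inclination of the notch roof relative to the
#'   anteroposterior axis; larger values bring the anterior roof margin
#'   closer to the joint line and increase extension impingement.
#' @param femur_depth anteroposterior extent of the condylar mass.
#' @param plateau_semi_axes mediolateral and anteroposterior semi-axes of
#'   the elliptic tibial plateau.
#' @param plateau_thickness thickness of the plateau slab.
#' @param tibia_offset anterior offset of the plateau centre relative to
#'   the femoral anteroposterior centre.
#' @param joint_gap distance between the femoral distal plane and the
#'   plateau surface.
#' @param flexion_axis_height,flexion_axis_depth position of the
#'   transepicondylar (flexion) axis above the notch base plane and from
#'   the posterior femoral border, as fractions of `notch_height` and
#'   `femur_depth`.
#' @param mesh_resolution target boundary edge length for tessellated
#'   curved outlines (the plateau ellipse).
#' @param seed integer seed recorded with the knee; the geometry is fully
#'   deterministic given the parameters.
#' @return An object of class `synthetic_knee_params`.
#' @export
synthetic_knee_params <- function(notch_width = 19,
                                  notch_height = 25,
                                  condyle_radius = 12,
                                  condyle_spacing = NULL,
                                  roof_angle = 40,
                                  femur_depth = 28,
                                  plateau_semi_axes = c(25, 25),
                                  plateau_thickness = 12,
                                  tibia_offset = 14,
                                  joint_gap = 2,
                                  flexion_axis_height = 0.3,
                                  flexion_axis_depth = 0.3,
                                  mesh_resolution = 2,
                                  seed = 1L) {
  p <- list(notch_width = notch_width, notch_height = notch_height,
            condyle_radius = condyle_radius,
            condyle_spacing = condyle_spacing %||%
              (notch_width + 2 * condyle_radius),
            roof_angle = roof_angle, femur_depth = femur_depth,
            plateau_semi_axes = as.numeric(plateau_semi_axes),
            plateau_thickness = plateau_thickness,
            tibia_offset = tibia_offset, joint_gap = joint_gap,
            flexion_axis_height = flexion_axis_height,
            flexion_axis_depth = flexion_axis_depth,
            mesh_resolution = mesh_resolution, seed = as.integer(seed))
  dims <- c(notch_width = p$notch_width, notch_height = p$notch_height,
            condyle_radius = p$condyle_radius, femur_depth = p$femur_depth,
            plateau_ml = p$plateau_semi_axes[1],
            plateau_ap = p$plateau_semi_axes[2],
            plateau_thickness = p$plateau_thickness,
            joint_gap = p$joint_gap, mesh_resolution = p$mesh_resolution)
  if (any(dims <= 0)) {
    stop("infeasible parameters: non-positive dimension(s): ",
         paste(names(dims)[dims <= 0], collapse = ", "))
  }
  if (abs(p$condyle_spacing - (p$notch_width + 2 * p$condyle_radius)) > 1e-9) {
    stop("infeasible parameters: condyle_spacing must equal ",
         "notch_width + 2 * condyle_radius (wall positions would conflict)")
  }
  if (p$roof_angle <= 0 || p$roof_angle >= 60) {
    stop("infeasible parameters: roof_angle must be in (0, 60) degrees")
  }
  outlet <- p$notch_height - p$femur_depth * tan(p$roof_angle * pi / 180)
  if (outlet < 1) {
    stop(sprintf(paste0(
      "infeasible parameters: the notch roof reaches the distal plane before",
      " the anterior border (anterior outlet height %.2f mm < 1 mm);",
      " reduce roof_angle or femur_depth"), outlet))
  }
  structure(p, class = "synthetic_knee_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_knee_params <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_knee_params: notch %.1f x %.1f mm, roof %.0f deg,",
                     " condyles %.0f mm, plateau %.0f x %.0f mm, seed %d>\n"),
              x$notch_width, x$notch_height, x$roof_angle,
              2 * x$condyle_radius, 2 * x$plateau_semi_axes[1],
              2 * x$plateau_semi_axes[2], x$seed))
  invisible(x)
}

# femur solid: block minus an open-bottomed notch channel with vertical
# walls and a planar roof sloping from the apex (posterior, z = notch
# height) down to the anterior outlet. 24 lattice vertices, all faces
# conforming (no T-junctions).
.femur_mesh <- function(p) {
  w2 <- p$notch_width / 2
  cw <- 2 * p$condyle_radius
  xs <- c(-(w2 + cw), -w2, w2, w2 + cw)      # x0 outer-medial .. x3 outer-lateral
  y0 <- -p$femur_depth / 2
  y1 <- p$femur_depth / 2
  zb <- 0
  zr0 <- p$notch_height
  zr1 <- p$notch_height - p$femur_depth * tan(p$roof_angle * pi / 180)
  zt <- p$notch_height + p$condyle_radius

  v <- rbind(
    # 1-8: top lattice (y0 row then y1 row)
    cbind(xs, y0, zt), cbind(xs, y1, zt),
    # 9-16: bottom lattice
    cbind(xs, y0, zb), cbind(xs, y1, zb),
    # 17-20: roof corners at the walls
    c(-w2, y0, zr0), c(w2, y0, zr0), c(-w2, y1, zr1), c(w2, y1, zr1),
    # 21-24: roof-level points on the outer borders (split the outer faces)
    c(xs[1], y0, zr0), c(xs[4], y0, zr0), c(xs[1], y1, zr1), c(xs[4], y1, zr1)
  )
  T0 <- 1:4; T1 <- 5:8; B0 <- 9:12; B1 <- 13:16
  RPL <- 17L; RPR <- 18L; RAL <- 19L; RAR <- 20L    # roof post/ant, left/right
  SPL <- 21L; SPR <- 22L; SAL <- 23L; SAR <- 24L    # outer-border splits

  quad <- function(a, b, c_, d) rbind(c(a, b, c_), c(a, c_, d))
  f <- rbind(
    # top (3 strips)
    quad(T0[1], T0[2], T1[2], T1[1]),
    quad(T0[2], T0[3], T1[3], T1[2]),
    quad(T0[3], T0[4], T1[4], T1[3]),
    # bottom (condyle undersides)
    quad(B0[1], B0[2], B1[2], B1[1]),
    quad(B0[3], B0[4], B1[4], B1[3]),
    # notch roof
    quad(RPL, RPR, RAR, RAL),
    # notch walls (medial wall of the lateral condyle is the +x one)
    quad(B0[2], B1[2], RAL, RPL),
    quad(B0[3], B1[3], RAR, RPR),
    # posterior face (5 conforming panels)
    quad(B0[1], B0[2], RPL, SPL),
    quad(SPL, RPL, T0[2], T0[1]),
    quad(RPL, RPR, T0[3], T0[2]),
    quad(B0[3], B0[4], SPR, RPR),
    quad(RPR, SPR, T0[4], T0[3]),
    # anterior face (5 conforming panels)
    quad(B1[1], B1[2], RAL, SAL),
    quad(SAL, RAL, T1[2], T1[1]),
    quad(RAL, RAR, T1[3], T1[2]),
    quad(B1[3], B1[4], SAR, RAR),
    quad(RAR, SAR, T1[4], T1[3]),
    # outer borders: hexagons fanned from the posterior roof-level split
    c(SPL, B0[1], B1[1]), c(SPL, B1[1], SAL),
    c(SPL, SAL, T1[1]), c(SPL, T1[1], T0[1]),
    c(SPR, B0[4], B1[4]), c(SPR, B1[4], SAR),
    c(SPR, SAR, T1[4]), c(SPR, T1[4], T0[4])
  )
  m <- surface_mesh(v, f, label = "femur", validate = FALSE)
  m <- .orient_consistent(m)
  validate_mesh(m)
  m
}

# elliptic plateau slab; segment count is a multiple of 4 so the extreme
# medial/lateral/anterior/posterior outline points are exact polygon
# vertices
.tibia_mesh <- function(p) {
  a <- p$plateau_semi_axes[1]
  b <- p$plateau_semi_axes[2]
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  n <- max(32L, 4L * as.integer(ceiling(per / (4 * p$mesh_resolution))))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  poly <- cbind(a * cos(th), p$tibia_offset + b * sin(th))
  z_top <- -p$joint_gap
  m <- mesh_extrude_polygon(poly, z_top - p$plateau_thickness, z_top,
                            label = "tibia")
  m
}

# analytic femoral quadrant frame (closed form, independent of the
# landmark-fitting code path)
.femoral_truth_frame <- function(p) {
  w2 <- p$notch_width / 2
  y0 <- -p$femur_depth / 2
  y1 <- p$femur_depth / 2
  zr0 <- p$notch_height
  rho <- p$roof_angle * pi / 180
  zr1 <- zr0 - p$femur_depth * tan(rho)
  d <- c(0, cos(rho), -sin(rho))
  h <- c(0, -sin(rho), -cos(rho))
  apex <- c(w2, y0, zr0)
  corners <- rbind(apex,
                   c(w2, y1, zr1),      # anterior roof end
                   c(w2, y0, 0),        # inferior posterior
                   c(w2, y1, 0))        # inferior anterior
  rel <- sweep(corners, 2, apex)
  sd_ <- as.numeric(rel %*% d)
  sh_ <- as.numeric(rel %*% h)
  femoral_frame(apex + min(sd_) * d + min(sh_) * h, h, d, c(1, 0, 0),
                total_height = diff(range(sh_)),
                total_depth = diff(range(sd_)))
}

.tibial_truth_frame <- function(p) {
  a <- p$plateau_semi_axes[1]
  b <- p$plateau_semi_axes[2]
  z_top <- -p$joint_gap
  tibial_frame(origin = c(-a, p$tibia_offset + b, z_top),
               depth_axis = c(0, -1, 0), width_axis = c(1, 0, 0),
               normal = c(0, 0, 1),
               total_depth = 2 * b, total_width = 2 * a)
}

# in-plane quadrant point; the synthetic wall/plateau are planar, so the
# analytic footprint is the grid point itself
.truth_point <- function(frame, f1, f2) {
  if (inherits(frame, "femoral_frame")) {
    frame$origin + f1 * frame$total_height * frame$height_axis +
      f2 * frame$total_depth * frame$depth_axis
  } else {
    frame$origin + f1 * frame$total_depth * frame$depth_axis +
      f2 * frame$total_width * frame$width_axis
  }
}

#' Generate a synthetic knee
#'
#' Builds the watertight femur and tibia meshes in the full-extension
#' reference pose together with the ground-truth bundle: named landmarks
#' for both frames, the analytic frames themselves, the six bundle
#' footprint centres, the notch width, and the flexion axis. Identical
#' parameters give bit-identical output.
#'
#' @param params a [synthetic_knee_params()] object (default parameters if
#'   omitted).
#' @return An object of class `synthetic_knee` with elements `femur`,
#'   `tibia`, `landmarks` (`$femur`, `$tibia`), `truth` (frames, footprint
#'   points, `notch_width`, `flexion_axis`), `params` and `flexion_angle`
#'   (0 in the reference pose).
#' @export
generate_knee <- function(params = synthetic_knee_params()) {
  stopifnot(inherits(params, "synthetic_knee_params"))
  p <- params
  femur <- .femur_mesh(p)
  tibia <- .tibia_mesh(p)
  w2 <- p$notch_width / 2
  y0 <- -p$femur_depth / 2
  y1 <- p$femur_depth / 2
  zr0 <- p$notch_height
  zr1 <- zr0 - p$femur_depth * tan(p$roof_angle * pi / 180)
  a <- p$plateau_semi_axes[1]
  b <- p$plateau_semi_axes[2]
  z_top <- -p$joint_gap

  landmarks <- list(
    femur = list(
      notch_apex = c(w2, y0, zr0),
      roof_anterior = c(w2, y1, zr1),
      wall_inferior_posterior = c(w2, y0, 0),
      wall_inferior_anterior = c(w2, y1, 0),
      wall_normal = c(1, 0, 0)
    ),
    tibia = list(
      plateau_anterior = c(0, p$tibia_offset + b, z_top),
      plateau_posterior = c(0, p$tibia_offset - b, z_top),
      plateau_medial = c(-a, p$tibia_offset, z_top),
      plateau_lateral = c(a, p$tibia_offset, z_top),
      plateau_normal = c(0, 0, 1)
    )
  )

  ff <- .femoral_truth_frame(p)
  tf <- .tibial_truth_frame(p)
  tab <- list(femur = list(AM = c(0.250, 0.330), PL = c(0.451, 0.500)),
              tibia = list(AM = c(0.350, 0.505), PL = c(0.464, 0.524)))
  fp <- list(femur = list(), tibia = list())
  for (side in c("femur", "tibia")) {
    fr <- if (side == "femur") ff else tf
    am <- .truth_point(fr, tab[[side]]$AM[1], tab[[side]]$AM[2])
    pl <- .truth_point(fr, tab[[side]]$PL[1], tab[[side]]$PL[2])
    fp[[side]] <- list(AM = am, central = (am + pl) / 2, PL = pl)
  }
  # footprints must land on the condylar wall, inside the notch
  for (bdl in names(fp$femur)) {
    pt <- fp$femur[[bdl]]
    roof_z <- zr0 - (pt[2] - y0) * tan(p$roof_angle * pi / 180)
    if (pt[3] <= 0 || pt[3] >= roof_z || pt[2] <= y0 || pt[2] >= y1) {
      stop(sprintf(paste0("infeasible parameters: femoral %s footprint ",
                          "(y=%.1f, z=%.1f) falls off the condylar wall"),
                   bdl, pt[2], pt[3]))
    }
  }

  structure(list(
    femur = femur, tibia = tibia, landmarks = landmarks,
    truth = list(
      femoral_frame = ff, tibial_frame = tf, footprints = fp,
      notch_width = p$notch_width,
      flexion_axis = list(
        point = c(0, y0 + p$flexion_axis_depth * p$femur_depth,
                  p$flexion_axis_height * p$notch_height),
        direction = c(1, 0, 0))
    ),
    params = p, flexion_angle = 0
  ), class = "synthetic_knee")
}

#' @export
print.synthetic_knee <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_knee at %g deg flexion: femur %d faces, ",
                     "tibia %d faces, notch %.1f mm>\n"),
              x$flexion_angle, nrow(x$femur$faces), nrow(x$tibia$faces),
              x$truth$notch_width))
  invisible(x)
}

#' Flexion transform about the transepicondylar axis
#'
#' @param angle flexion angle in degrees (positive = flexion, the tibia
#'   swings posteriorly).
#' @param axis_point a point on the flexion axis (the axis runs
#'   mediolaterally).
#' @return A [rigid_transform()].
#' @export
flexion_transform <- function(angle, axis_point) {
  R <- rotation_about_axis(c(1, 0, 0), -angle)
  c0 <- as.numeric(axis_point)
  rigid_transform(R, c0 - as.numeric(R %*% c0))
}

#' Pose a synthetic knee at a flexion angle
#'
#' Rotates the tibia (mesh, landmarks, ground-truth footprints and frame)
#' about the generator's transepicondylar axis by `angle` relative to the
#' current pose; the femur stays fixed. `0` degrees is the full-extension
#' reference pose. The four study angles are 0, 45, 90 and 120 degrees;
#' other values are accepted with a warning.
#'
#' @param knee a [generate_knee()] object.
#' @param angle incremental flexion angle in degrees.
#' @return The posed `synthetic_knee`, with the applied [rigid_transform()]
#'   in `$pose`.
#' @export
pose_at_flexion <- function(knee, angle) {
  stopifnot(inherits(knee, "synthetic_knee"))
  if (!angle %in% c(0, 45, 90, 120)) {
    warning(sprintf("flexion angle %g deg is outside the study set {0, 45, 90, 120}",
                    angle))
  }
  t <- flexion_transform(angle, knee$truth$flexion_axis$point)
  knee$tibia <- apply_transform(knee$tibia, t)
  lm <- knee$landmarks$tibia
  for (nm in names(lm)) {
    lm[[nm]] <- if (nm == "plateau_normal") {
      as.numeric(t$rotation %*% lm[[nm]])
    } else {
      transform_points(lm[[nm]], t)
    }
  }
  knee$landmarks$tibia <- lm
  knee$truth$footprints$tibia <- lapply(knee$truth$footprints$tibia,
                                        transform_points, t = t)
  tf <- knee$truth$tibial_frame
  tf$origin <- transform_points(tf$origin, t)
  tf$depth_axis <- as.numeric(t$rotation %*% tf$depth_axis)
  tf$width_axis <- as.numeric(t$rotation %*% tf$width_axis)
  tf$normal <- as.numeric(t$rotation %*% tf$normal)
  knee$truth$tibial_frame <- tf
  knee$flexion_angle <- knee$flexion_angle + angle
  knee$pose <- if (is.null(knee$pose)) t else compose_transform(t, knee$pose)
  knee
}

# evaluate `code` under a temporary RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic knee population
#'
#' Draws `n` knees with independent Gaussian variation of the continuous
#' generator parameters, truncated to feasibility by rejection (at most 100
#' attempts per knee). The default standard deviations emulate
#' between-subject anatomical variability, with the notch width varying by
#' 3.4 mm around its 19.0 mm mean.
#'
#' @param n number of knees (>= 1).
#' @param param_means named list overriding mean parameters (defaults:
#'   [synthetic_knee_params()] defaults).
#' @param param_sds named list of standard deviations; parameters not
#'   listed are held fixed. Default:
#'   `list(notch_width = 3.4, notch_height = 1.5, condyle_radius = 1,
#'   roof_angle = 1.5, femur_depth = 1.5, plateau_semi_axes = c(1.5, 1.5))`.
#' @param seed integer seed; the population is reproducible per seed.
#' @return A list of `synthetic_knee` objects with `$id` set to
#'   `knee01 ...`.
#' @export
generate_population <- function(n = 9,
                                param_means = list(),
                                param_sds = list(notch_width = 3.4,
                                                 notch_height = 1.5,
                                                 condyle_radius = 1,
                                                 roof_angle = 1.5,
                                                 femur_depth = 1.5,
                                                 plateau_semi_axes = c(1.5, 1.5)),
                                seed = 1L) {
  stopifnot(n >= 1)
  if (any(unlist(param_sds) < 0)) stop("standard deviations must be >= 0")
  base <- do.call(synthetic_knee_params, param_means)
  .with_seed(seed, {
    knees <- vector("list", n)
    for (i in seq_len(n)) {
      knee <- NULL
      for (attempt in seq_len(100L)) {
        draw <- unclass(base)
        for (nm in names(param_sds)) {
          sds <- param_sds[[nm]]
          draw[[nm]] <- rnorm(length(draw[[nm]]), mean = draw[[nm]], sd = sds)
        }
        draw$seed <- base$seed + i
        knee <- tryCatch({
          prm <- do.call(synthetic_knee_params,
                         draw[setdiff(names(draw), "condyle_spacing")])
          generate_knee(prm)
        }, error = function(e) NULL)
        if (!is.null(knee)) break
      }
      if (is.null(knee)) {
        stop("could not draw a feasible knee in 100 attempts; ",
             "check param_means/param_sds")
      }
      knee$id <- sprintf("knee%02d", i)
      knees[[i]] <- knee
    }
    knees
  })
}

#' Write a synthetic knee fixture to disk
#'
#' The fixture trio is `femur.stl`, `tibia.stl` (ASCII STL) and
#' `truth.json` (parameters, landmarks and ground truth). This is the
#' pipeline's on-disk exchange format.
#'
#' @param knee a `synthetic_knee`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_knee <- function(knee, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stl(knee$femur, file.path(dir, "femur.stl"))
  write_stl(knee$tibia, file.path(dir, "tibia.stl"))
  truth <- knee$truth
  payload <- list(
    id = knee$id %||% "knee",
    flexion_angle = knee$flexion_angle,
    params = unclass(knee$params),
    landmarks = knee$landmarks,
    notch_width = truth$notch_width,
    flexion_axis = truth$flexion_axis,
    footprints = truth$footprints
  )
  jsonlite::write_json(payload, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic knee fixture
#'
#' @param dir directory holding `femur.stl`, `tibia.stl`, `truth.json`.
#' @return A `synthetic_knee` object.
#' @export
read_knee <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  params <- do.call(synthetic_knee_params,
                    js$params[setdiff(names(js$params), "condyle_spacing")])
  knee <- generate_knee(params)
  knee$femur <- read_stl(file.path(dir, "femur.stl"), label = "femur")
  knee$tibia <- read_stl(file.path(dir, "tibia.stl"), label = "tibia")
  knee$id <- js$id
  knee
}
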