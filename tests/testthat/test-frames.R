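angle_between <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b)))) * 180 / pi
}

test_that("fitted femoral frame recovers the generator ground truth", {
  knee <- default_knee()
  ff <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
  truth <- knee$truth$femoral_frame
  expect_lt(angle_between(ff$height_axis, truth$height_axis), 1)
  expect_lt(angle_between(ff$depth_axis, truth$depth_axis), 1)
  expect_lt(angle_between(ff$normal, truth$normal), 1)
  expect_lt(abs(ff$total_height - truth$total_height) / truth$total_height,
            0.02)
  expect_lt(abs(ff$total_depth - truth$total_depth) / truth$total_depth,
            0.02)
  expect_lt(max(abs(ff$origin - truth$origin)), 0.1)
})

test_that("frames are rigidly equivariant", {
  knee <- default_knee()
  t1 <- rigid_transform(rotation_about_axis(c(0.2, 1, 0.4), 24), c(7, -4, 2))
  lm <- knee$landmarks$femur
  lm_t <- lapply(names(lm), function(nm) {
    if (nm == "wall_normal") as.numeric(t1$rotation %*% lm[[nm]])
    else transform_points(lm[[nm]], t1)
  })
  names(lm_t) <- names(lm)
  f0 <- fit_femoral_frame(knee$femur, lm)
  f1 <- fit_femoral_frame(apply_transform(knee$femur, t1), lm_t)
  expect_equal(f1$origin, transform_points(f0$origin, t1), tolerance = 1e-9)
  expect_equal(f1$height_axis, as.numeric(t1$rotation %*% f0$height_axis),
               tolerance = 1e-9)
  expect_equal(f1$depth_axis, as.numeric(t1$rotation %*% f0$depth_axis),
               tolerance = 1e-9)
  expect_equal(f1$total_height, f0$total_height, tolerance = 1e-12)
  expect_equal(f1$total_depth, f0$total_depth, tolerance = 1e-12)
})

test_that("swapped anterior/posterior landmarks are detected", {
  knee <- default_knee()
  lm <- knee$landmarks$femur
  swapped <- lm
  swapped$notch_apex <- lm$roof_anterior
  swapped$roof_anterior <- lm$notch_apex
  swapped$wall_inferior_posterior <- lm$wall_inferior_anterior
  swapped$wall_inferior_anterior <- lm$wall_inferior_posterior
  expect_error(fit_femoral_frame(knee$femur, swapped), "swapped")
  expect_error(fit_femoral_frame(knee$femur, lm[-1]), "notch_apex")
})

test_that("tibial frame recovers the plateau bounding rectangle", {
  prm <- synthetic_knee_params(plateau_semi_axes = c(25, 18))
  knee <- generate_knee(prm)
  tf <- fit_tibial_frame(knee$tibia, knee$landmarks$tibia)
  expect_lt(abs(tf$total_width - 50), 0.5)
  expect_lt(abs(tf$total_depth - 36), 0.5)

  degen <- knee$landmarks$tibia
  degen$plateau_medial <- degen$plateau_anterior
  degen$plateau_lateral <- degen$plateau_posterior
  expect_error(fit_tibial_frame(knee$tibia, degen), "degenerate")
})

test_that("grid fractions map onto ground-truth footprint points", {
  knee <- default_knee()
  ff <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
  tf <- fit_tibial_frame(knee$tibia, knee$landmarks$tibia)

  corner <- grid_to_point(ff, 0, 0, knee$femur)
  expect_lt(max(abs(as.numeric(corner) - ff$origin)), 1e-6)

  for (bdl in c("AM", "central", "PL")) {
    pf <- footprint_center("femur", bdl, ff, knee$femur)
    expect_lt(max(abs(as.numeric(pf) - knee$truth$footprints$femur[[bdl]])),
              1)
    pt <- footprint_center("tibia", bdl, tf, knee$tibia)
    expect_lt(max(abs(as.numeric(pt) - knee$truth$footprints$tibia[[bdl]])),
              1)
  }

  # central is the re-projected midpoint of AM and PL
  am <- footprint_center("femur", "AM", ff, knee$femur)
  pl <- footprint_center("femur", "PL", ff, knee$femur)
  ce <- footprint_center("femur", "central", ff, knee$femur)
  expect_lt(max(abs(as.numeric(ce) - (as.numeric(am) + as.numeric(pl)) / 2)),
            1)
})

test_that("the opposite femoral depth convention mirrors the fraction", {
  fr_post <- footprint_fractions("femur", "AM")
  fr_ant <- footprint_fractions("femur", "AM", depth_from = "anterior")
  expect_equal(unname(fr_ant[2]), 1 - unname(fr_post[2]))
  expect_identical(unname(fr_post), c(0.25, 0.33))
  expect_identical(unname(footprint_fractions("tibia", "PL")),
                   c(0.464, 0.524))
})

test_that("increasing the height fraction moves the point monotonically", {
  knee <- default_knee()
  ff <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
  hs <- seq(0.05, 0.6, by = 0.05)
  proj <- vapply(hs, function(fh) {
    p <- grid_to_point(ff, fh, 0.4, knee$femur)
    sum((as.numeric(p) - ff$origin) * ff$height_axis)
  }, numeric(1))
  expect_true(all(diff(proj) > 0))
})

test_that("re-fitting a frame from its own corner points is idempotent", {
  knee <- default_knee()
  f0 <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
  lm <- list(
    notch_apex = f0$origin,
    roof_anterior = f0$origin + f0$total_depth * f0$depth_axis,
    wall_inferior_posterior = f0$origin + f0$total_height * f0$height_axis,
    wall_inferior_anterior = f0$origin + f0$total_depth * f0$depth_axis +
      f0$total_height * f0$height_axis,
    wall_normal = f0$normal
  )
  f1 <- fit_femoral_frame(knee$femur, lm)
  expect_equal(f1$origin, f0$origin, tolerance = 1e-6)
  expect_equal(f1$height_axis, f0$height_axis, tolerance = 1e-6)
  expect_equal(f1$depth_axis, f0$depth_axis, tolerance = 1e-6)
  expect_equal(f1$total_height, f0$total_height, tolerance = 1e-6)
  expect_equal(f1$total_depth, f0$total_depth, tolerance = 1e-6)
})

test_that("a ray that misses the mesh is reported", {
  knee <- default_knee()
  ff <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
  ff$origin <- ff$origin + c(0, 0, 500)      # grid far above the bone
  expect_error(grid_to_point(ff, 0.2, 0.4, knee$femur), "misses")
})

test_that("full-chain footprint recovery holds across 20 random knees", {
  knees <- generate_population(20, seed = 77)
  for (knee in knees) {
    ff <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
    tf <- fit_tibial_frame(knee$tibia, knee$landmarks$tibia)
    for (bdl in c("AM", "central", "PL")) {
      expect_lt(max(abs(as.numeric(footprint_center("femur", bdl, ff,
                                                    knee$femur)) -
                          knee$truth$footprints$femur[[bdl]])), 1)
      expect_lt(max(abs(as.numeric(footprint_center("tibia", bdl, tf,
                                                    knee$tibia)) -
                          knee$truth$footprints$tibia[[bdl]])), 1)
    }
  }
})
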