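# closed-form oracles for the voxel volume kernel

test_that("voxelization volume matches closed forms", {
  vg <- voxelize(unit_cube(), spacing = 0.1)
  expect_lt(abs(voxel_volume(vg) - 1.0), 0.03)

  sph <- mesh_icosphere(c(0, 0, 0), radius = 5, subdivisions = 4)
  vs <- voxelize(sph, spacing = 0.2)
  expect_lt(abs(voxel_volume(vs) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.01)
})

test_that("an off-solid grid query is all-false with a warning", {
  far <- list(origin = c(100, 100, 100), dims = c(4L, 4L, 4L))
  expect_warning(vg <- voxelize(unit_cube(), spacing = 0.5, grid = far),
                 "empty grid")
  expect_false(any(vg$occupancy))
})

test_that("parity and winding-number inside tests agree", {
  sph <- mesh_icosphere(c(0, 0, 0), radius = 5, subdivisions = 3)
  grid <- list(origin = c(-6, -6, -6), dims = c(13L, 13L, 13L))
  vp <- voxelize(sph, spacing = 1, grid = grid, method = "parity")
  vw <- voxelize(sph, spacing = 1, grid = grid, method = "winding")
  expect_identical(vp$occupancy, vw$occupancy)
})

test_that("intersection volume matches closed forms and special cases", {
  a <- unit_cube()
  expect_identical(intersection_volume(a, mesh_box(c(5, 5, 5), c(6, 6, 6)),
                                       spacing = 0.1), 0)
  expect_lt(abs(intersection_volume(a, a, spacing = 0.1) - 1.0), 0.03)

  # half of a cylinder: axis pierces a half-space realized as a large box
  cyl <- mesh_cylinder(c(0, 0, -15), c(0, 0, 15), radius = 3.5,
                       n_segments = 256)
  half <- mesh_box(c(-20, -20, -40), c(20, 20, 0))
  v_half <- intersection_volume(cyl, half, spacing = 0.25)
  expect_lt(abs(v_half - pi * 3.5^2 * 15) / (pi * 3.5^2 * 15), 0.01)

  # cylinder crossing a 10 mm slab perpendicular to its axis
  cyl2 <- mesh_cylinder(c(0, 0, -30), c(0, 0, 30), radius = 4.5,
                        n_segments = 256)
  slab <- mesh_box(c(-30, -30, -5), c(30, 30, 5))
  v_slab <- intersection_volume(cyl2, slab, spacing = 0.25)
  expect_lt(abs(v_slab - pi * 4.5^2 * 10) / (pi * 4.5^2 * 10), 0.01)
})

test_that("intersection volume is exactly symmetric", {
  a <- mesh_box(c(0, 0, 0), c(3.1, 2.7, 4.3))
  b <- mesh_cylinder(c(1.1, 1.3, -2), c(1.7, 0.9, 6), radius = 1.4,
                     n_segments = 64)
  expect_identical(intersection_volume(a, b, spacing = 0.37),
                   intersection_volume(b, a, spacing = 0.37))
})

test_that("intersection volume is monotone under solid inclusion", {
  slab <- mesh_box(c(-30, -30, 2), c(30, 30, 9))
  vols <- vapply(c(2, 3, 4.5, 6), function(r) {
    cyl <- mesh_cylinder(c(0.2, -0.1, -10), c(0.3, 0.4, 20), radius = r,
                         n_segments = 128)
    intersection_volume(cyl, slab, spacing = 0.5)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("voxel estimates refine monotonically toward the closed form", {
  pairs <- list(
    list(a = unit_cube(), b = mesh_box(c(0.3, 0.3, 0.3), c(1.3, 1.3, 1.3)),
         truth = 0.7^3),
    list(a = mesh_cylinder(c(0, 0, -30), c(0, 0, 30), 4.5, 128),
         b = mesh_box(c(-30, -30, -5), c(30, 30, 5)),
         truth = pi * 4.5^2 * 10),
    list(a = mesh_icosphere(c(0, 0, 0), 5, 4),
         b = mesh_box(c(0, 0, 0), c(10, 10, 10)),
         truth = (4 / 3 * pi * 125) / 8)
  )
  for (p in pairs) {
    errs <- vapply(c(1.0, 0.5, 0.25), function(h) {
      abs(intersection_volume(p$a, p$b, spacing = h) - p$truth)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-9),
                info = paste("errors:", paste(signif(errs, 4), collapse = " ")))
  }
})

test_that("rigid motion of both solids barely changes the intersection", {
  a <- mesh_cylinder(c(0, 0, -20), c(0, 0, 20), radius = 4.5,
                     n_segments = 128)
  b <- mesh_box(c(-20, -20, -4), c(20, 20, 4))
  t1 <- rigid_transform(rotation_about_axis(c(1, 1, 0), 33), c(5, -3, 2))
  v0 <- intersection_volume(a, b, spacing = 0.25)
  v1 <- intersection_volume(apply_transform(a, t1), apply_transform(b, t1),
                            spacing = 0.25)
  expect_lt(abs(v1 - v0) / v0, 0.02)
})

test_that("clip planes restrict the counted region to a half-space", {
  a <- unit_cube()
  full <- intersection_volume(a, a, spacing = 0.05)
  halved <- intersection_volume(a, a, spacing = 0.05,
                                clip_planes = list(list(point = c(0.5, 0, 0),
                                                        normal = c(1, 0, 0))))
  expect_lt(abs(halved - full / 2), 0.02)
})
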