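test_that("the default design enumerates 9 configurations and 72 cells", {
  des <- factorial_design()
  combos <- footprint_combinations(des)
  expect_identical(nrow(combos), 9L)
  expect_identical(nrow(unique(combos)), 9L)

  rec <- run_knee(default_knee(), des, knee_id = "k1")
  expect_identical(nrow(rec), 72L)
  expect_true(all(rec$status == "ok"))
  # natural primary key is unique
  key <- with(rec, paste(knee_id, flexion_angle, femoral_position,
                         tibial_position, diameter))
  expect_false(anyDuplicated(key) > 0)
})

test_that("a singleton design yields one record", {
  des <- factorial_design(femoral_positions = "AM",
                          tibial_positions = "PL", diameters = 8,
                          flexion_angles = 0)
  rec <- run_knee(default_knee(), des)
  expect_identical(nrow(rec), 1L)
})

test_that("deep-flexion cells are all zero on the default knee", {
  rec <- run_knee(default_knee(), factorial_design(), knee_id = "k1")
  deep <- rec$volume[rec$flexion_angle %in% c(90, 120)]
  expect_identical(length(deep), 36L)
  expect_true(all(deep == 0))
})

test_that("re-running a configuration writes byte-identical CSV", {
  des <- factorial_design(flexion_angles = c(0, 90))
  r1 <- run_knee(default_knee(), des, knee_id = "k1")
  r2 <- run_knee(default_knee(), des, knee_id = "k1")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(r1, f1)
  write_records(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_records(f1)
  expect_equal(back$volume, r1$volume, tolerance = 1e-9)
})

test_that("cell failures are isolated as structured error records", {
  knee <- default_knee()
  knee$landmarks$femur$notch_apex <- NULL
  des <- factorial_design(flexion_angles = 0)
  rec <- run_knee(knee, des, knee_id = "bad")
  expect_identical(nrow(rec), 18L)
  expect_true(all(rec$status == "error"))
  expect_true(all(grepl("notch_apex", rec$error)))
  expect_true(all(is.na(rec$volume)))
})

test_that("aggregation reports mean, n-1 SD and group sizes", {
  # three identical knees: zero SD everywhere
  knees <- generate_population(3, param_sds = list(), seed = 3)
  des <- factorial_design(flexion_angles = 0, diameters = c(7, 9))
  rec <- run_population(knees, des)
  agg <- aggregate_impingement(rec[rec$diameter == 9, ])
  expect_identical(nrow(agg), 9L)
  expect_true(all(agg$n == 3))
  expect_true(all(agg$sd == 0))

  by_d <- aggregate_impingement(rec, group_by = "diameter")
  expect_gt(by_d$mean[by_d$diameter == 9], by_d$mean[by_d$diameter == 7])

  failed <- rec[rec$diameter == 9, ]
  failed$status[1] <- "error"
  expect_warning(aggregate_impingement(failed), "omitted")
})

test_that("experiment configs round-trip through YAML", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("femoral_positions: [AM, PL]",
               "diameters: [8]",
               "flexion_angles: [0, 45]",
               "spacing: 0.4",
               "attachment_exclusion: cap",
               "cap_depth: 3",
               "seed: 7",
               "n_knees: 4"), cfg)
  got <- read_experiment_config(cfg)
  expect_identical(got$design$femoral_positions, c("AM", "PL"))
  expect_identical(got$design$tibial_positions, c("AM", "central", "PL"))
  expect_identical(got$design$diameters, 8)
  expect_identical(got$design$spacing, 0.4)
  expect_identical(got$design$attachment_exclusion, "cap")
  expect_identical(got$design$cap_depth, 3L)
  expect_identical(got$seed, 7L)
  expect_identical(got$n_knees, 4L)
})
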