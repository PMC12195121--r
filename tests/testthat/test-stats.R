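# oracles: hand-computed t and F statistics, and null-simulation
# calibration of every test's type-I error

two_sided_p_t <- function(t, df) 2 * pt(-abs(t), df)

test_that("diameter t-test matches the pooled-variance formula", {
  g1 <- c(12.1, 15.3, 9.8, 14.2, 11.0)      # "7 mm"
  g2 <- c(18.4, 16.9, 21.2, 19.8, 17.5)     # "9 mm"
  rec <- rbind(make_records(g1, diameter = 7), make_records(g2, diameter = 9))
  got <- ttest_diameter(rec)

  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t_manual <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(unname(got$statistic), t_manual, tolerance = 1e-12)
  expect_equal(got$df, n1 + n2 - 2)
  expect_equal(got$p_value, two_sided_p_t(t_manual, n1 + n2 - 2),
               tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- rbind(make_records(c(1, 2, 3), diameter = 7),
                make_records(c(1, 2, 3), diameter = 9))
  got0 <- ttest_diameter(same)
  expect_equal(unname(got0$statistic), 0, tolerance = 1e-12)
  expect_equal(got0$p_value, 1, tolerance = 1e-12)

  expect_error(ttest_diameter(make_records(c(1, 2), diameter = 9)),
               "two graft diameters")
  expect_error(ttest_diameter(rbind(make_records(1, diameter = 7),
                                    make_records(c(1, 2), diameter = 9))),
               "n >= 2")
})

test_that("paired flexion t-test handles matching and degeneracy", {
  base <- expand.grid(f = c("AM", "PL"), t = c("AM", "PL"),
                      stringsAsFactors = FALSE)
  v0 <- c(10, 8, 6, 4)
  mk <- function(v, ang) make_records(v, femoral = base$f, tibial = base$t,
                                      angle = ang)
  rec <- rbind(mk(v0, 0), mk(v0 - c(3, 2, 2, 1), 45))
  got <- ttest_flexion_paired(rec, 0, 45)
  d <- c(3, 2, 2, 1)
  t_manual <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(unname(got$statistic), t_manual, tolerance = 1e-12)
  expect_equal(got$p_value, two_sided_p_t(t_manual, 3), tolerance = 1e-12)

  ident <- rbind(mk(v0, 0), mk(v0, 45))
  same <- ttest_flexion_paired(ident, 0, 45)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p_value, 1)

  shift <- rbind(mk(v0, 0), mk(v0 - 2, 45))
  degen <- ttest_flexion_paired(shift, 0, 45)
  expect_equal(degen$p_value, 0)
  expect_match(degen$note, "zero variance")

  broken <- rbind(mk(v0, 0), mk(v0, 45)[-1, ])
  expect_error(ttest_flexion_paired(broken, 0, 45), "unmatched")
})

test_that("one-way ANOVA matches a hand-computed table", {
  groups <- list(AM = c(5, 7, 6, 8), central = c(3, 4, 5, 4),
                 PL = c(1, 2, 1, 2))
  rec <- do.call(rbind, lapply(names(groups), function(g) {
    make_records(groups[[g]], tibial = g)
  }))
  got <- anova_oneway(rec, "tibial")

  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_manual <- (ss_b / 2) / (ss_w / 9)
  expect_equal(unname(got$statistic), f_manual, tolerance = 1e-9)
  expect_equal(got$df, c(2, 9))
  expect_equal(got$p_value, pf(f_manual, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got$effect_size, ss_b / (ss_b + ss_w), tolerance = 1e-12)

  # partial eta squared equals the one-factor model R^2
  fit <- lm(volume ~ tibial_position, data = rec)
  expect_equal(got$effect_size, summary(fit)$r.squared, tolerance = 1e-12)
})

test_that("one-way ANOVA limits: identical groups and separated groups", {
  rec0 <- do.call(rbind, lapply(c("AM", "central", "PL"), function(g) {
    make_records(c(2, 2, 2), tibial = g)
  }))
  got0 <- anova_oneway(rec0, "tibial")
  expect_equal(unname(got0$statistic), 0)
  expect_equal(got0$p_value, 1)
  expect_equal(got0$effect_size, 0)

  # between-variance >> within-variance pushes partial eta^2 toward 1
  rec1 <- rbind(make_records(c(0, 1e-4), tibial = "AM"),
                make_records(c(100, 100.0001), tibial = "central"),
                make_records(c(200, 199.9999), tibial = "PL"))
  expect_gt(anova_oneway(rec1, "tibial")$effect_size, 0.999999)
})

test_that("two-level one-way ANOVA is exactly the squared pooled t", {
  set.seed(42)
  rec <- rbind(make_records(rnorm(8, 10, 2), femoral = "AM"),
               make_records(rnorm(8, 12, 2), femoral = "PL"))
  a <- anova_oneway(rec, "femoral")
  t <- ttest_diameter(within(rec, diameter <- ifelse(femoral_position ==
                                                       "AM", 7, 9)))
  expect_equal(unname(a$statistic), unname(t$statistic)^2,
               tolerance = 1e-9)
  expect_equal(a$p_value, t$p_value, tolerance = 1e-9)
})

test_that("two-way ANOVA matches hand-computed balanced sums of squares", {
  # balanced 2 x 2 with 2 replicates
  cells <- expand.grid(f = c("AM", "PL"), t = c("AM", "PL"), r = 1:2,
                       stringsAsFactors = FALSE)
  v <- c(10, 6, 7, 2,   12, 7, 8, 4)
  rec <- make_records(v, femoral = cells$f, tibial = cells$t)
  got <- anova_twoway(rec)

  y <- array(v, dim = c(2, 2, 2))          # f, t, replicate
  grand <- mean(v)
  m_f <- apply(y, 1, mean)
  m_t <- apply(y, 2, mean)
  m_ft <- apply(y, c(1, 2), mean)
  ss_f <- 4 * sum((m_f - grand)^2)
  ss_t <- 4 * sum((m_t - grand)^2)
  ss_i <- 2 * sum((sweep(sweep(m_ft, 1, m_f), 2, m_t) + grand)^2)
  ss_e <- sum((y - rep(m_ft, 2))^2)
  expect_equal(unname(got$femoral$statistic), (ss_f / 1) / (ss_e / 4),
               tolerance = 1e-9)
  expect_equal(unname(got$tibial$statistic), (ss_t / 1) / (ss_e / 4),
               tolerance = 1e-9)
  expect_equal(unname(got$interaction$statistic), (ss_i / 1) / (ss_e / 4),
               tolerance = 1e-9)
  expect_equal(got$femoral$effect_size, ss_f / (ss_f + ss_e),
               tolerance = 1e-9)

  # identical observations in all cells: F = 0 throughout
  flat <- make_records(rep(5, 8), femoral = cells$f, tibial = cells$t)
  got0 <- anova_twoway(flat)
  expect_equal(unname(got0$femoral$statistic), 0)
  expect_equal(unname(got0$interaction$statistic), 0)
  expect_equal(got0$tibial$p_value, 1)

  missing_cell <- rec[!(rec$femoral_position == "AM" &
                          rec$tibial_position == "PL"), ]
  expect_error(anova_twoway(missing_cell), "non-empty")
})

test_that("every test keeps its type-I error at the nominal level", {
  n_rep <- 1000
  z2 <- 2 * sqrt(0.05 * 0.95 / n_rep)

  set.seed(101)
  rej <- mean(replicate(n_rep, {
    rec <- rbind(make_records(rnorm(9), diameter = 7),
                 make_records(rnorm(9), diameter = 9))
    ttest_diameter(rec)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), z2)

  set.seed(102)
  keys <- expand.grid(f = c("AM", "central", "PL"),
                      t = c("AM", "central", "PL"),
                      stringsAsFactors = FALSE)
  rej <- mean(replicate(n_rep, {
    rec <- rbind(make_records(rnorm(9), femoral = keys$f, tibial = keys$t,
                              angle = 0),
                 make_records(rnorm(9), femoral = keys$f, tibial = keys$t,
                              angle = 45))
    ttest_flexion_paired(rec, 0, 45)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), z2)

  set.seed(103)
  rej <- mean(replicate(n_rep, {
    rec <- make_records(rnorm(27), tibial = rep(c("AM", "central", "PL"),
                                                each = 9))
    anova_oneway(rec, "tibial")$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), z2)

  # interaction test under an additive (no-interaction) model
  set.seed(104)
  f_eff <- c(AM = 2, central = 0, PL = -2)
  t_eff <- c(AM = 3, central = 0, PL = -3)
  rej <- mean(replicate(n_rep, {
    k <- keys[rep(seq_len(9), each = 3), ]
    v <- f_eff[k$f] + t_eff[k$t] + rnorm(27)
    rec <- make_records(v, femoral = k$f, tibial = k$t)
    anova_twoway(rec)$interaction$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), z2)
})
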