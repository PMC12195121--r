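# Statistical battery over impingement records: independent t-test by
# graft diameter, paired t-test across flexion angles, one-way ANOVA over
# footprint positions, and two-way ANOVA with the femoral x tibial
# interaction. Partial eta squared (SS_effect / (SS_effect + SS_error))
# accompanies every ANOVA effect.
#
# Tests default to two-sided with pooled variances and no multiplicity
# correction; Welch variances are available via a flag. The unit of
# analysis is the record, so callers select the stratum (typically one
# flexion angle and one diameter) before testing.

#' Impingement test result
#'
#' Container for a single hypothesis test: statistic, degrees of freedom,
#' p-value, effect size (partial eta squared where applicable) and group
#' sizes.
#'
#' @param test test label.
#' @param statistic named test statistic (t or F).
#' @param df degrees of freedom (length 1 or 2).
#' @param p_value p-value in `[0, 1]`.
#' @param effect_size partial eta squared, or `NA` for t-tests.
#' @param groups named integer vector of per-group sizes.
#' @param note optional annotation (e.g. degeneracy flags).
#' @return An object of class `impingement_test`.
#' @export
impingement_test <- function(test, statistic, df, p_value,
                             effect_size = NA_real_, groups = NULL,
                             note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  if (!is.na(effect_size)) stopifnot(effect_size >= 0, effect_size <= 1)
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 groups = groups, note = note),
            class = "impingement_test")
}

#' @export
print.impingement_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g", x$test,
              names(x$statistic)[1] %||% "stat", x$statistic[1], dfs,
              x$p_value))
  if (!is.na(x$effect_size)) {
    cat(sprintf(", partial eta^2 = %.4g", x$effect_size))
  }
  cat("\n")
  if (!is.null(x$groups)) {
    cat("  n per group:",
        paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
        "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

.ok_records <- function(records) {
  stopifnot(is.data.frame(records), "volume" %in% names(records))
  if ("status" %in% names(records)) {
    records <- records[records$status == "ok", , drop = FALSE]
  }
  records[!is.na(records$volume), , drop = FALSE]
}

#' Independent t-test of impingement volume by graft diameter
#'
#' Two-sided two-sample t-test comparing impingement volumes between the
#' two graft diameters present in the records; pooled variance by default,
#' Welch via `var_equal = FALSE`.
#'
#' @param records impingement records (pre-filtered to the stratum of
#'   interest, e.g. one flexion angle).
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @return An [impingement_test()].
#' @export
ttest_diameter <- function(records, var_equal = TRUE) {
  rec <- .ok_records(records)
  ds <- sort(unique(rec$diameter))
  if (length(ds) != 2L) {
    stop("records must contain exactly two graft diameters (found ",
         length(ds), ")")
  }
  g1 <- rec$volume[rec$diameter == ds[1]]
  g2 <- rec$volume[rec$diameter == ds[2]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each diameter group needs n >= 2")
  }
  if (sd(g1) == 0 && sd(g2) == 0) {
    # degenerate: t-test undefined; equal constants accept, unequal reject
    eq <- isTRUE(all.equal(mean(g1), mean(g2)))
    return(impingement_test(
      "independent t-test (diameter)", c(t = if (eq) 0 else Inf),
      df = length(g1) + length(g2) - 2, p_value = if (eq) 1 else 0,
      groups = stats::setNames(c(length(g1), length(g2)),
                               paste0(ds, " mm")),
      note = "zero within-group variance"))
  }
  ht <- t.test(g1, g2, var.equal = var_equal)
  impingement_test("independent t-test (diameter)",
                   c(t = unname(ht$statistic)), df = unname(ht$parameter),
                   p_value = ht$p.value,
                   groups = stats::setNames(c(length(g1), length(g2)),
                                            paste0(ds, " mm")))
}

#' Paired t-test of impingement volume between two flexion angles
#'
#' Records are matched on (knee, femoral position, tibial position,
#' diameter); every key must be present at both angles.
#'
#' @param records impingement records containing both angles.
#' @param angle_a,angle_b the two flexion angles to compare (degrees).
#' @return An [impingement_test()].
#' @export
ttest_flexion_paired <- function(records, angle_a, angle_b) {
  rec <- .ok_records(records)
  key_cols <- c("knee_id", "femoral_position", "tibial_position", "diameter")
  a <- rec[rec$flexion_angle == angle_a, , drop = FALSE]
  b <- rec[rec$flexion_angle == angle_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("no records at one of the requested flexion angles")
  }
  ka <- do.call(paste, c(a[key_cols], sep = "|"))
  kb <- do.call(paste, c(b[key_cols], sep = "|"))
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("duplicate configuration keys within an angle stratum")
  }
  missing <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(missing)) {
    stop("unmatched configuration keys across angles: ",
         paste(utils::head(missing, 5L), collapse = "; "),
         if (length(missing) > 5L) " ..." else "")
  }
  d <- a$volume[order(ka)] - b$volume[order(kb)]
  n <- length(d)
  if (n < 2L) stop("paired t-test needs at least 2 matched pairs")
  if (sd(d) == 0) {
    # zero variance of differences: identical vectors accept, constant
    # nonzero shift is an infinite t (reported as p = 0 with a flag)
    zero <- isTRUE(all.equal(mean(d), 0))
    return(impingement_test(
      sprintf("paired t-test (%g vs %g deg)", angle_a, angle_b),
      c(t = if (zero) 0 else sign(mean(d)) * Inf), df = n - 1,
      p_value = if (zero) 1 else 0,
      groups = c(pairs = n),
      note = "zero variance of paired differences"))
  }
  ht <- t.test(d)
  impingement_test(sprintf("paired t-test (%g vs %g deg)", angle_a, angle_b),
                   c(t = unname(ht$statistic)), df = unname(ht$parameter),
                   p_value = ht$p.value, groups = c(pairs = n))
}

#' One-way ANOVA of impingement volume over footprint positions
#'
#' Between-groups F-test comparing the three footprint positions (AM,
#' central, PL) on one side, with partial eta squared
#' `SS_between / (SS_between + SS_within)`.
#'
#' @param records impingement records (pre-filtered to the stratum of
#'   interest).
#' @param factor `"femoral"` or `"tibial"`.
#' @return An [impingement_test()].
#' @export
anova_oneway <- function(records, factor = c("femoral", "tibial")) {
  factor <- match.arg(factor)
  col <- paste0(factor, "_position")
  rec <- .ok_records(records)
  rec$g <- base::factor(rec[[col]])
  sizes <- table(rec$g)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("one-way ANOVA needs >= 2 levels with n >= 2 each")
  }
  fit <- aov(volume ~ g, data = rec)
  tab <- summary(fit)[[1]]
  ss_b <- tab[1, "Sum Sq"]
  ss_w <- tab[2, "Sum Sq"]
  f <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  if (ss_b + ss_w <= 1e-12 * max(1, sum(rec$volume^2))) {
    # all observations identical up to rounding noise
    ss_b <- 0
    ss_w <- 0
    f <- 0
    p <- 1
  }
  impingement_test(sprintf("one-way ANOVA (%s position)", factor),
                   c(F = unname(f)),
                   df = c(tab[1, "Df"], tab[2, "Df"]), p_value = unname(p),
                   effect_size = if (ss_b + ss_w > 0) ss_b / (ss_b + ss_w) else 0,
                   groups = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Two-way ANOVA: femoral and tibial main effects plus interaction
#'
#' Fits `volume ~ femoral * tibial`. The reference design is balanced, in
#' which case the sequential decomposition equals the type-II one;
#' unbalanced input triggers a warning and type-II sums of squares
#' (computed by model comparison). Partial eta squared is reported per
#' effect.
#'
#' @param records impingement records with a full femoral x tibial
#'   crossing.
#' @return A named list of [impingement_test()] objects: `femoral`,
#'   `tibial`, `interaction`.
#' @export
anova_twoway <- function(records) {
  rec <- .ok_records(records)
  rec$fg <- base::factor(rec$femoral_position)
  rec$tg <- base::factor(rec$tibial_position)
  cells <- table(rec$fg, rec$tg)
  if (any(cells == 0L)) {
    stop("two-way ANOVA requires every femoral x tibial cell to be non-empty")
  }
  balanced <- length(unique(as.vector(cells))) == 1L
  if (!balanced) {
    warning("unbalanced design: using type-II sums of squares")
  }
  # type-II sums of squares by model comparison (equals sequential SS on
  # balanced data)
  rss <- function(formula) sum(stats::residuals(lm(formula, data = rec))^2)
  noise <- 1e-12 * max(1, sum(rec$volume^2))
  rss_full <- rss(volume ~ fg * tg)
  rss_add <- rss(volume ~ fg + tg)
  ss_f <- max(rss(volume ~ tg) - rss_add, 0)
  ss_t <- max(rss(volume ~ fg) - rss_add, 0)
  ss_i <- max(rss_add - rss_full, 0)
  if (sum((rec$volume - mean(rec$volume))^2) <= noise) {
    ss_f <- ss_t <- ss_i <- rss_full <- 0
  }
  df_f <- nlevels(rec$fg) - 1L
  df_t <- nlevels(rec$tg) - 1L
  df_i <- df_f * df_t
  df_e <- nrow(rec) - nlevels(rec$fg) * nlevels(rec$tg)
  if (df_e < 1L) stop("no residual degrees of freedom (need replicate cells)")
  ms_e <- rss_full / df_e
  mk <- function(label, ss, df) {
    if (ms_e <= noise) {
      f <- if (ss > noise) Inf else 0
      p <- if (ss > noise) 0 else 1
    } else {
      f <- (ss / df) / ms_e
      p <- pf(f, df, df_e, lower.tail = FALSE)
    }
    eta <- if (ss + rss_full > 0) ss / (ss + rss_full) else 0
    impingement_test(sprintf("two-way ANOVA (%s)", label), c(F = f),
                     df = c(df, df_e), p_value = p, effect_size = eta,
                     groups = stats::setNames(as.integer(cells),
                                              paste(rep(rownames(cells),
                                                        ncol(cells)),
                                                    rep(colnames(cells),
                                                        each = nrow(cells)),
                                                    sep = ":")))
  }
  list(femoral = mk("femoral main effect", ss_f, df_f),
       tibial = mk("tibial main effect", ss_t, df_t),
       interaction = mk("femoral x tibial interaction", ss_i, df_i))
}

#' Full statistical report over impingement records
#'
#' Runs the reference battery on one stratum: the diameter t-test, all
#' pairwise paired flexion t-tests, one-way ANOVAs for femoral and tibial
#' positions (at the reference angle and per diameter), and the two-way
#' ANOVA.
#'
#' @param records impingement records of a full factorial run.
#' @param at_angle stratum angle for the position tests (default 0).
#' @return A named list of [impingement_test()] objects / lists.
#' @export
stats_report <- function(records, at_angle = 0) {
  rec <- .ok_records(records)
  at0 <- rec[rec$flexion_angle == at_angle, , drop = FALSE]
  angles <- sort(unique(rec$flexion_angle))
  flexion <- list()
  if (length(angles) > 1L) {
    for (i in seq_len(length(angles) - 1L)) {
      for (j in seq((i + 1L), length(angles))) {
        nm <- sprintf("%gv%g", angles[i], angles[j])
        flexion[[nm]] <- tryCatch(
          ttest_flexion_paired(rec, angles[i], angles[j]),
          error = function(e) NULL)
      }
    }
  }
  out <- list(diameter = tryCatch(ttest_diameter(at0), error = function(e) NULL),
              flexion = flexion)
  for (d in sort(unique(at0$diameter))) {
    sub <- at0[at0$diameter == d, , drop = FALSE]
    out[[sprintf("oneway_femoral_%gmm", d)]] <-
      tryCatch(anova_oneway(sub, "femoral"), error = function(e) NULL)
    out[[sprintf("oneway_tibial_%gmm", d)]] <-
      tryCatch(anova_oneway(sub, "tibial"), error = function(e) NULL)
    out[[sprintf("twoway_%gmm", d)]] <-
      tryCatch(anova_twoway(sub), error = function(e) NULL)
  }
  out
}
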