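# Minimal result graphics: an unstyled grouped bar chart of mean
# impingement volume with SD whiskers.

#' Bar chart of mean impingement volumes
#'
#' Plots mean +/- SD impingement volume per tibial position, grouped by
#' femoral position, for one flexion angle and one diameter stratum.
#'
#' @param records impingement records.
#' @param at_angle flexion angle stratum (default 0).
#' @param diameter diameter stratum in mm (default: the largest present).
#' @param ... passed to [graphics::barplot()].
#' @return The aggregated table, invisibly.
#' @export
plot_impingement <- function(records, at_angle = 0, diameter = NULL, ...) {
  rec <- .ok_records(records)
  rec <- rec[rec$flexion_angle == at_angle, , drop = FALSE]
  if (is.null(diameter)) diameter <- max(rec$diameter)
  rec <- rec[rec$diameter == diameter, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records in the requested stratum")
  agg <- aggregate_impingement(rec)
  lv_f <- unique(agg$femoral_position)
  lv_t <- unique(agg$tibial_position)
  m <- matrix(NA_real_, nrow = length(lv_f), ncol = length(lv_t),
              dimnames = list(lv_f, lv_t))
  s <- m
  for (i in seq_len(nrow(agg))) {
    m[agg$femoral_position[i], agg$tibial_position[i]] <- agg$mean[i]
    s[agg$femoral_position[i], agg$tibial_position[i]] <- agg$sd[i]
  }
  ylim <- c(0, max(m + ifelse(is.na(s), 0, s), na.rm = TRUE) * 1.1)
  bp <- barplot(m, beside = TRUE, ylim = ylim,
                xlab = "tibial position",
                ylab = expression(paste("impingement volume [", mm^3, "]")),
                legend.text = paste("femoral", lv_f), ...)
  ok <- !is.na(s) & s > 0
  if (any(ok)) {
    arrows(bp[ok], m[ok] - pmin(s[ok], m[ok]), bp[ok], m[ok] + s[ok],
           angle = 90, code = 3, length = 0.03)
  }
  mtext(sprintf("%g mm graft at %g deg flexion", diameter, at_angle))
  invisible(agg)
}
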