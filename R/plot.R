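# Simple base-graphics views of a report: per-level parameter curves and
# backside profiles.

#' Plot per-level asymmetry curves of a report
#'
#' Three stacked panels over the vertebral levels C7..L5: full-side
#' R-squared, backside area asymmetry, left-right area asymmetry. Useful to
#' eyeball where along the spine the torso is most asymmetric.
#'
#' @param x an `assessment_report`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.assessment_report <- function(x, ...) {
  df <- x$per_level
  ix <- level_index(df$level)
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  panel <- function(yv, ylab, main) {
    graphics::plot(ix, yv, type = "b", pch = 19, xaxt = "n",
                   xlab = "", ylab = ylab, main = main, cex.main = 0.9)
    graphics::axis(1, at = seq_along(LEVEL_LABELS), labels = LEVEL_LABELS,
                   cex.axis = 0.6, las = 2)
  }
  panel(df$r_squared_full, expression(R^2), "Left-right fit")
  panel(df$backside_area_asym, "asymmetry", "Backside area asymmetry")
  panel(df$lr_area_asym, "asymmetry", "Left-right area asymmetry")
  invisible(x)
}

#' Plot the backside profiles of one slice
#'
#' Mirrors the per-slice backside view: relative radius and vertical
#' distance from the vertebral-body line on both sides of the SP, indexed by
#' angular offset from the SP (the local minimum at offset 0).
#'
#' @param slice a `slice_asymmetry`.
#' @param ... ignored.
#' @return `slice`, invisibly.
#' @export
plot_backside <- function(slice, ...) {
  k <- length(slice$rad_back_right) - 1
  offs <- 0:k
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(offs, cbind(slice$rad_back_right, slice$rad_back_left),
                    type = "l", lty = 1, col = c("firebrick", "navy"),
                    xlab = "offset from SP (deg)", ylab = "relative radius",
                    main = paste("Backside radii, level", slice$level),
                    cex.main = 0.9)
  graphics::legend("bottomright", c("right", "left"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n")
  graphics::matplot(offs, cbind(slice$dist_vb_right, slice$dist_vb_left),
                    type = "l", lty = 1, col = c("firebrick", "navy"),
                    xlab = "offset from SP (deg)", ylab = "Dist_VB (mm)",
                    main = "Distance from vertebral-body line", cex.main = 0.9)
  invisible(slice)
}
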