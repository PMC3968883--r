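#' Overlay plot of a shape-model mode
#'
#' Draws the mean contour with the mode evaluated at `+/- c` standard
#' deviations, the conventional rendering for inspecting what a mode
#' does. Combined models are drawn as two open polylines.
#'
#' @param model a `shape_model`.
#' @param mode_index retained-mode index.
#' @param c displacement in SD units (default 2.5).
#' @param ... passed to [graphics::plot()].
#' @export
plot_mode <- function(model, mode_index, c = 2.5, ...) {
  mean_m <- vec_to_shape(model$mean_shape)
  plus <- mode_shape(model, mode_index, c)
  minus <- mode_shape(model, mode_index, -c)
  rng <- apply(rbind(mean_m, plus, minus), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2], asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("Mode %d at +/- %.1f SD", mode_index, c), ...)
  draw_contour(minus, col = "steelblue")
  draw_contour(plus, col = "firebrick")
  draw_contour(mean_m, col = "black", lwd = 2)
  graphics::legend("topright", bty = "n", lwd = c(2, 1, 1),
                   col = c("black", "firebrick", "steelblue"),
                   legend = c("mean", sprintf("+%.1f SD", c), sprintf("-%.1f SD", c)))
  invisible(NULL)
}

#' Overlay two contours (e.g. left vs aligned right, or before vs after)
#'
#' @param a,b contours or point matrices of equal size.
#' @param labels legend labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot_contour_overlay <- function(a, b, labels = c("a", "b"), ...) {
  pa <- contour_points(a); pb <- contour_points(b)
  rng <- apply(rbind(pa, pb), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2], asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  draw_contour(pa, col = "black", lwd = 2)
  draw_contour(pb, col = "firebrick")
  graphics::legend("topright", bty = "n", lwd = c(2, 1),
                   col = c("black", "firebrick"), legend = labels)
  invisible(NULL)
}

draw_contour <- function(pts, ...) {
  n <- nrow(pts)
  if (n %% 130 == 0 || (n %% 2 == 0 && n > 65)) {
    h <- n %/% 2
    graphics::lines(pts[seq_len(h), ], ...)
    graphics::lines(pts[h + seq_len(h), ], ...)
  } else {
    graphics::lines(pts, ...)
  }
  graphics::points(pts, pch = 20, cex = 0.3, ...)
}
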