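#' Plot the arena with optional points or paths
#'
#' Diagnostic base-graphics view: arena boundary, inner circle, quadrant
#' axes, landmark (filled dot), object locations (crosses), and any
#' overlaid points.
#'
#' @param x An [arena_config()].
#' @param points Optional two-column matrix / data frame of points to
#'   overlay (e.g. pooled path samples or recall responses).
#' @param ... Passed to [graphics::points()] for the overlay.
#' @export
plot.arena_config <- function(x, points = NULL, ...) {
  r <- x$radius
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::plot(x$center[1] + r * cos(th), x$center[2] + r * sin(th),
                 type = "l", asp = 1, xlab = "x (vm)", ylab = "y (vm)",
                 main = "Arena")
  graphics::lines(x$center[1] + x$inner_radius * cos(th),
                  x$center[2] + x$inner_radius * sin(th), lty = 2)
  graphics::abline(h = x$center[2], v = x$center[1], lty = 3,
                   col = "grey60")
  if (!is.null(points)) {
    m <- as_point_matrix(point_coords(points))
    graphics::points(m[, 1], m[, 2], ...)
  }
  graphics::points(x$landmark[1], x$landmark[2], pch = 16, cex = 1.3)
  for (id in names(x$objects)) {
    o <- x$objects[[id]]
    graphics::points(o[1], o[2], pch = 4, lwd = 2)
    graphics::text(o[1], o[2], id, pos = 3, cex = 0.8)
  }
  invisible(x)
}

#' @export
plot.ol_session <- function(x, arena = arena_config(), ...) {
  plot(arena)
  if (!is.null(x$path))
    graphics::lines(x$path$samples$x_vm, x$path$samples$y_vm,
                    col = "grey40")
  graphics::points(x$trials$response_x_vm, x$trials$response_y_vm,
                   pch = ifelse(x$trials$cue == "ego", 1, 2), ...)
  graphics::title(sub = paste("session", x$id, "-", x$group))
  invisible(x)
}
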