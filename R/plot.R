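#' @export
plot.pf_field <- function(x, main = NULL, ...) {
  graphics::image(field_x(x), field_y(x), x$values, asp = 1,
                  xlab = "x (um)", ylab = "y (um)", main = main, ...)
  invisible(x)
}

#' @export
plot.pf_drift_field <- function(x, ...) {
  graphics::image(x$x_centers, x$v_centers, x$F,
                  xlab = "x (um)", ylab = "v (um/min)",
                  main = "F(x, v) = <dv/dt | x, v>", ...)
  invisible(x)
}

#' @export
plot.pf_portrait <- function(x, ...) {
  xr <- range(x$field$x_edges); vr <- range(x$field$v_edges)
  plot(NA, xlim = xr, ylim = vr, xlab = "x (um)", ylab = "v (um/min)",
       main = paste("phase portrait:", x$label), ...)
  cols <- c("-1" = "grey70", "0" = "orange")
  gpal <- c("red3", "blue3", "darkgreen", "purple", "brown")
  for (i in seq_along(x$paths)) {
    g <- if (!is.null(x$groups)) x$groups[i] else 0L
    col <- if (g > 0) gpal[(g - 1) %% length(gpal) + 1]
           else if (!is.null(x$cycling) && x$cycling[i]) "orange" else "grey70"
    graphics::lines(x$paths[[i]][, 1], x$paths[[i]][, 2], col = col, lwd = 0.6)
  }
  if (!is.null(x$terminals))
    graphics::points(x$terminals$x, x$terminals$v, pch = 4, cex = 2, lwd = 2)
  if (!is.null(x$separatrix) && nrow(x$separatrix))
    graphics::points(x$separatrix[, 1], x$separatrix[, 2], pch = 16, cex = 0.4)
  invisible(x)
}

#' @export
plot.pf_trajectory <- function(x, ...) {
  plot(x$t_min / 60, x$x_um, type = "l", xlab = "t (h)", ylab = "x (um)", ...)
  invisible(x)
}

#' @export
plot.pf_friction_cut <- function(x, ...) {
  plot(x$v, x$F, type = "b", pch = 16, xlab = "v (um/min)",
       ylab = "F(x->0, v) (um/min^2)", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}
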