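#' Extract the cell boundary as an ordered contour
#'
#' Traces the phi = 1/2 level set (marching squares via
#' \code{grDevices::contourLines}), returns the largest closed component
#' ordered counterclockwise with outward unit normals, cumulative arc length
#' and total perimeter.  If more than one sizeable component is present the
#' cell is flagged as ruptured and the largest is returned.
#'
#' @param phi a \code{pf_field} with at least one region above the level.
#' @param level contour level (default 1/2).
#' @param min_frac components with polygon area below \code{min_frac} times
#'   the largest component's area are ignored when deciding rupture.
#' @return an object of class \code{pf_contour}: list with \code{points}
#'   (n x 2, not repeating the first point), \code{normals} (n x 2, unit),
#'   \code{arclength} (cumulative, starting at 0), \code{perimeter} (um,
#'   including the closing segment) and \code{ruptured} (logical).
#' @export
extract_contour <- function(phi, level = 0.5, min_frac = 0.01) {
  cl <- grDevices::contourLines(field_x(phi), field_y(phi), phi$values,
                                levels = level)
  if (length(cl) == 0)
    stop("no phi = ", level, " level set found (empty cell)")
  areas <- vapply(cl, function(p) abs(shoelace_area(cbind(p$x, p$y))), 0)
  main <- which.max(areas)
  ruptured <- sum(areas > min_frac * areas[main]) > 1
  pts <- cbind(cl[[main]]$x, cl[[main]]$y)
  # contourLines may or may not repeat the first vertex on closed loops
  if (nrow(pts) > 1 &&
      sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (shoelace_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]

  g <- cpp_gradient(phi$values, phi$dx)
  gxf <- scalar_field(g$gx, phi$dx, phi$origin)
  gyf <- scalar_field(g$gy, phi$dx, phi$origin)
  gx <- interp_field(gxf, pts[, 1], pts[, 2])
  gy <- interp_field(gyf, pts[, 1], pts[, 2])
  gn <- sqrt(gx^2 + gy^2)
  gn[gn < 1e-12] <- NA
  normals <- cbind(-gx / gn, -gy / gn)
  # fall back to the geometric outward direction where the gradient vanished
  bad <- !is.finite(normals[, 1])
  if (any(bad)) {
    cen <- colMeans(pts)
    d <- sqrt((pts[bad, 1] - cen[1])^2 + (pts[bad, 2] - cen[2])^2)
    normals[bad, ] <- cbind((pts[bad, 1] - cen[1]) / d, (pts[bad, 2] - cen[2]) / d)
  }

  seg <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  structure(list(points = pts, normals = normals,
                 arclength = c(0, cumsum(seg))[seq_len(nrow(pts))],
                 perimeter = sum(seg), ruptured = ruptured),
            class = "pf_contour")
}

#' @export
print.pf_contour <- function(x, ...) {
  cat(sprintf("pf_contour: %d points, perimeter %.2f um%s\n",
              nrow(x$points), x$perimeter,
              if (x$ruptured) " [RUPTURED]" else ""))
  invisible(x)
}

# signed polygon area (shoelace); positive for counterclockwise orientation
shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon given as a vertex list
#'
#' Used for the area weights of micropattern basins.
#'
#' @param pts n x 2 matrix of vertices (first vertex not repeated).
#' @return absolute enclosed area (um^2).
#' @export
polygon_area <- function(pts) abs(shoelace_area(as.matrix(pts)))
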