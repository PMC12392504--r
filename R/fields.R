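#' Scalar field on a uniform rectangular grid
#'
#' Container for the phase field phi, polarity P and micropattern chi.
#' \code{values} is an nx-by-ny matrix whose rows index x and columns index
#' y; element (i, j) sits at \code{origin + (i-1, j-1) * dx} (um).
#'
#' @param values numeric matrix of field values.
#' @param dx grid spacing (um).
#' @param origin physical coordinates of the (1,1) grid node (um).
#' @return an object of class \code{pf_field}.
#' @export
scalar_field <- function(values, dx, origin = c(0, 0)) {
  stopifnot(is.matrix(values), is.numeric(values), dx > 0, length(origin) == 2)
  if (!all(is.finite(values))) stop("field values must all be finite")
  structure(list(values = values, dx = dx, origin = as.numeric(origin)),
            class = "pf_field")
}

#' @export
print.pf_field <- function(x, ...) {
  cat(sprintf("pf_field: %d x %d grid, dx = %g um, origin (%g, %g), range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$dx, x$origin[1], x$origin[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname scalar_field
#' @param f a \code{pf_field}.
#' @export
field_x <- function(f) f$origin[1] + (seq_len(nrow(f$values)) - 1) * f$dx

#' @rdname scalar_field
#' @export
field_y <- function(f) f$origin[2] + (seq_len(ncol(f$values)) - 1) * f$dx

#' Bilinear interpolation of a field at arbitrary points
#'
#' @param f a \code{pf_field}.
#' @param x,y point coordinates (um), recycled to common length.
#' @param fill value returned for points outside the grid.
#' @return numeric vector of interpolated values.
#' @export
interp_field <- function(f, x, y, fill = 0) {
  nx <- nrow(f$values); ny <- ncol(f$values)
  fx <- (x - f$origin[1]) / f$dx
  fy <- (y - f$origin[2]) / f$dx
  out <- rep(fill, length(fx))
  ok <- fx >= 0 & fy >= 0 & fx <= nx - 1 & fy <= ny - 1 & is.finite(fx) & is.finite(fy)
  if (any(ok)) {
    i <- pmin(floor(fx[ok]), nx - 2); j <- pmin(floor(fy[ok]), ny - 2)
    tx <- fx[ok] - i; ty <- fy[ok] - j
    v <- f$values
    k00 <- cbind(i + 1, j + 1); k10 <- cbind(i + 2, j + 1)
    k01 <- cbind(i + 1, j + 2); k11 <- cbind(i + 2, j + 2)
    out[ok] <- (1 - tx) * (1 - ty) * v[k00] + tx * (1 - ty) * v[k10] +
      (1 - tx) * ty * v[k01] + tx * ty * v[k11]
  }
  out
}

check_same_grid <- function(...) {
  fs <- list(...)
  ref <- fs[[1]]
  for (f in fs[-1]) {
    if (!identical(dim(f$values), dim(ref$values)) ||
        !isTRUE(all.equal(f$dx, ref$dx)) ||
        !isTRUE(all.equal(f$origin, ref$origin)))
      stop("fields are not on the same grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Check the phase-field overshoot invariant
#'
#' phi should stay within \code{[-eps, 1 + eps]}; values are deliberately not
#' clipped (clipping would silently break the gradient-flow property), so a
#' violation raises a warning with the observed range.
#'
#' @param phi a \code{pf_field}.
#' @param eps overshoot tolerance (default 0.02).
#' @return \code{TRUE} invisibly if within tolerance, otherwise \code{FALSE}.
#' @export
check_phi_range <- function(phi, eps = 0.02) {
  r <- range(phi$values)
  if (r[1] < -eps || r[2] > 1 + eps) {
    warning(sprintf("phase field overshoots tolerance: range [%.4f, %.4f], eps = %g",
                    r[1], r[2], eps), call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Cell area
#'
#' The area entering the incompressibility constraint,
#' \code{A = integral(phi^2) dr}, by grid quadrature.
#'
#' @param phi a \code{pf_field}.
#' @return area in um^2.
#' @export
cell_area <- function(phi) cpp_area(phi$values, phi$dx)

#' Centre of mass of the cell
#'
#' phi-weighted centroid \code{integral(r phi) / integral(phi)}.
#'
#' @param phi a \code{pf_field}.
#' @return numeric length-2 vector (x, y) in um.
#' @export
center_of_mass <- function(phi) {
  w <- sum(phi$values)
  if (w <= 0) stop("cannot compute centre of mass of an empty field")
  xs <- field_x(phi); ys <- field_y(phi)
  c(sum(rowSums(phi$values) * xs), sum(colSums(phi$values) * ys)) / w
}

#' Functional derivative of the interfacial (Cahn-Hilliard) free energy
#'
#' Returns \code{dF_CH/dphi = gamma[(c0/lambda) * 2 phi(1-phi)(1-2phi) -
#' lambda * laplacian(phi)]}, which vanishes on uniform phi = 0 or 1 and on
#' the equilibrium logistic front.
#'
#' @param phi a \code{pf_field}.
#' @param params a \code{pf_params} object.
#' @return a \code{pf_field} of the same shape.
#' @export
fd_cahn_hilliard <- function(phi, params) {
  scalar_field(cpp_fd_ch(phi$values, phi$dx, params$gamma, params$lambda, params$c0),
               phi$dx, phi$origin)
}

#' Functional derivative of the area-constraint energy
#'
#' \code{dF_area/dphi = -(4 kappa / (pi R0^2)) (1 - A / (pi R0^2)) phi} with
#' \code{A = integral(phi^2)}; identically zero when the area is on target.
#'
#' @inheritParams fd_cahn_hilliard
#' @return a \code{pf_field}.
#' @export
fd_area <- function(phi, params) {
  scalar_field(cpp_fd_area(phi$values, phi$dx, params$kappa, params$R0),
               phi$dx, phi$origin)
}

#' Total free energy of a configuration
#'
#' \code{F = F_CH + F_area}; with motility off the dynamics is a gradient
#' flow and this quantity is non-increasing step to step.
#'
#' @inheritParams fd_cahn_hilliard
#' @return scalar energy (gamma0 um units).
#' @export
free_energy <- function(phi, params) {
  g <- cpp_gradient(phi$values, phi$dx)
  p <- phi$values
  well <- (params$c0 / params$lambda) * (p * (1 - p))^2
  grad <- (params$lambda / 2) * (g$gx^2 + g$gy^2)
  fch <- params$gamma * sum(well + grad) * phi$dx^2
  A0 <- pi * params$R0^2
  fch + params$kappa * (1 - cell_area(phi) / A0)^2
}

#' Velocity field of the force balance
#'
#' \code{v = (1/eta) [ (dF/dphi) grad(phi) + f_motility ]} with
#' \code{f_motility = alpha P phi^2 (1-phi)^2 (1-chi) nhat} and
#' \code{nhat = -grad(phi)/|grad(phi)|} (zero where the gradient magnitude is
#' below \code{1e-6/dx}).
#'
#' @param phi,P,chi \code{pf_field}s on a common grid.
#' @param params a \code{pf_params} object.
#' @return list with \code{pf_field}s \code{vx} and \code{vy} (um/min).
#' @export
velocity_field <- function(phi, P, chi, params) {
  check_same_grid(phi, P, chi)
  delta <- fd_cahn_hilliard(phi, params)$values + fd_area(phi, params)$values
  v <- cpp_velocity(phi$values, P$values, chi$values, delta, phi$dx,
                    params$alpha, params$eta)
  list(vx = scalar_field(v$vx, phi$dx, phi$origin),
       vy = scalar_field(v$vy, phi$dx, phi$origin))
}

#' Advance the phase field and polarity by one explicit Euler step
#'
#' One step of \code{dphi/dt = -v . grad(phi) - M dF/dphi} together with the
#' deterministic polarity terms (off-pattern inhibition, perimeter
#' inhibition, basal decay).  Patch impulses are applied separately between
#' steps.
#'
#' @param state a cell state as returned by \code{\link{initialize_cell}}.
#' @param chi micropattern field on the same grid.
#' @param dt time step (min); validated against \code{\link{stability_dt}}.
#' @param params a \code{pf_params} object.
#' @param freeze_shape if \code{TRUE}, phi is held fixed and only the
#'   polarity is advanced.
#' @return the updated cell state.
#' @export
step_phase_field <- function(state, chi, dt, params, freeze_shape = FALSE) {
  if (dt > stability_dt(params))
    stop("dt = ", dt, " exceeds the stability bound ", signif(stability_dt(params), 3))
  check_same_grid(state$phi, state$P, chi)
  out <- cpp_step(state$phi$values, state$P$values, chi$values,
                  state$phi$dx, dt, params, freeze_shape)
  if (!all(is.finite(out$phi)))
    stop("numerical failure: non-finite phase field after step at t = ",
         state$t, " min (area ", signif(out$area, 4), ")")
  state$phi$values <- out$phi
  state$P$values <- out$P
  state$t <- state$t + dt
  state
}
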