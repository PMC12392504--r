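#' Synthetic SDE specification with analytically known drift
#'
#' Second-order Langevin fixtures \code{dv/dt = F*(x, v) + noise * eta(t)},
#' \code{dx/dt = v}, used to validate the drift-inference pipeline against
#' a known ground truth:
#' \describe{
#'   \item{ou}{Ornstein-Uhlenbeck velocity, \code{F* = -xi v} (stationary
#'     persistence decay; the canonical free-migration model).}
#'   \item{van_der_pol}{\code{F* = mu (1 - x^2) v - x}, the classical limit
#'     cycle.}
#'   \item{double_well}{\code{F* = -4 k x (x^2 - x0^2) - xi v}, damped
#'     motion in the quartic well \code{U = k (x^2 - x0^2)^2} (bistable).}
#' }
#'
#' @param name model name.
#' @param xi friction coefficient (ou, double_well), min^-1.
#' @param mu van der Pol gain.
#' @param x0 well position (double_well).
#' @param k well stiffness (double_well).
#' @param noise additive acceleration-noise amplitude sigma_n (units of
#'   drift per sqrt(min)).
#' @return an object of class \code{pf_sde_spec}.
#' @export
sde_spec <- function(name = c("ou", "van_der_pol", "double_well"),
                     xi = 0.2, mu = 1, x0 = 1, k = 1, noise = 0.5) {
  name <- match.arg(name)
  structure(list(name = name, xi = xi, mu = mu, x0 = x0, k = k, noise = noise),
            class = "pf_sde_spec")
}

#' Analytic drift of a synthetic SDE
#'
#' @param spec a \code{pf_sde_spec}.
#' @return vectorised function F*(x, v).
#' @export
analytic_drift <- function(spec) {
  switch(spec$name,
    ou = function(x, v) -spec$xi * v,
    van_der_pol = function(x, v) spec$mu * (1 - x^2) * v - x,
    double_well = function(x, v) -4 * spec$k * x * (x^2 - spec$x0^2) - spec$xi * v,
    stop("unknown SDE model '", spec$name, "'"))
}

# largest |dF/dv| over the working box, for the explicit-Euler stability check
sde_stiffness <- function(spec, x_scale) {
  switch(spec$name,
    ou = spec$xi,
    van_der_pol = spec$mu * max(1, x_scale^2 - 1),
    double_well = spec$xi)
}

#' Simulate trajectories of a synthetic SDE
#'
#' Euler-Maruyama integration of \code{v <- v + F*(x, v) dt + noise
#' sqrt(dt) N(0,1)}, \code{x <- x + v dt}, vectorised over trajectories and
#' seeded for bit-reproducibility.  Positions are recorded every
#' \code{sample_every} steps in the same trajectory layout as the cell
#' simulator, so the entire inference stack runs unchanged on these
#' fixtures.  The conditional mean of the one-step velocity increment of
#' this generator is exactly \code{F*(x, v) dt}, which is the quantity the
#' binned drift estimator targets (see the methods vignette for the
#' coarse-graining bias that appears when observations are coarser than
#' the generative step).
#'
#' @param spec a \code{pf_sde_spec}.
#' @param n_traj number of trajectories.
#' @param T duration (min).
#' @param dt integration step (min).  An error with a suggested bound is
#'   raised when the deterministic update would be unstable
#'   (\code{dt * max|dF/dv| > 2}).
#' @param seed RNG seed.
#' @param sample_every record every this many steps (default 1).
#' @param x_init,v_init initial conditions, recycled over trajectories;
#'   defaults scatter starts over the working range of each model.
#' @return a \code{pf_trajectory_set}.
#' @export
simulate_sde <- function(spec, n_traj, T, dt, seed = 1, sample_every = 1,
                         x_init = NULL, v_init = NULL) {
  stopifnot(n_traj >= 1, T > 0, dt > 0)
  x_scale <- switch(spec$name, ou = 40, van_der_pol = 2.5, double_well = 1.5 * spec$x0)
  stiff <- sde_stiffness(spec, x_scale)
  if (dt * stiff > 2)
    stop("dt = ", dt, " is unstable for '", spec$name,
         "'; need dt <= ", signif(2 / stiff, 3))
  F_star <- analytic_drift(spec)
  set.seed(seed)
  if (is.null(x_init)) x_init <- stats::runif(n_traj, -x_scale / 2, x_scale / 2)
  if (is.null(v_init)) v_init <- stats::rnorm(n_traj, 0, max(spec$noise, 0.1))
  x <- rep_len(x_init, n_traj); v <- rep_len(v_init, n_traj)
  nsteps <- round(T / dt)
  nrec <- floor(nsteps / sample_every) + 1
  X <- matrix(NA_real_, nrec, n_traj)
  tt <- numeric(nrec)
  X[1, ] <- x; tt[1] <- 0
  r <- 1L
  sqdt <- sqrt(dt)
  for (s in seq_len(nsteps)) {
    a <- F_star(x, v)
    v <- v + a * dt + spec$noise * sqdt * stats::rnorm(n_traj)
    x <- x + v * dt
    if (s %% sample_every == 0) {
      r <- r + 1L
      X[r, ] <- x; tt[r] <- s * dt
    }
  }
  runs <- lapply(seq_len(n_traj), function(j) {
    tr <- data.frame(t_min = tt, x_um = X[, j], y_um = 0,
                     area_um2 = NA_real_, perim_um = NA_real_)
    attr(tr, "seed") <- seed
    attr(tr, "flags") <- list(ruptured = FALSE, escaped = FALSE, failed = FALSE)
    class(tr) <- c("pf_trajectory", "data.frame")
    tr
  })
  trajectory_set(runs, params = NULL, pattern = NULL)
}
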