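#' Model parameters for the phase-field cell
#'
#' Builds the full parameter set of the model with defaults calibrated to the
#' default simulated cell.  Physical quantities are in micrometres and
#' minutes; the line tension scale \code{gamma0} is arbitrary and all
#' force-like parameters are expressed in units of it.  The two fast polarity
#' timescales \code{tau_f} (interval between stochastic activity patches) and
#' \code{tau_chi} (off-pattern polarity inhibition) are given in seconds, as
#' conventional for this model, and converted to minutes internally.
#'
#' Defaults: gamma = 0.8 gamma0, lambda = 4.8 um, kappa = 6000 gamma0 um,
#' R0 = 18 um, eta = 0.67 gamma0 min um^-3, M = 0.75 um / (gamma0 min),
#' mu_beta = 7.5, sigma_beta = 37.5, sigma_patch = 6.7 um,
#' s0 = 2 pi (1.5 R0) um, tau_f = 2.2 s, tau_chi = 9.6 s, tau_s = 8 min,
#' tau = 4 min, ell = 6 um, alpha = 1.4 gamma0 um^-2.
#'
#' @param gamma line tension, units of \code{gamma0}.
#' @param lambda interface width (um).
#' @param kappa area-constraint strength (gamma0 um).
#' @param R0 target radius (um); the target area is pi R0^2.
#' @param eta friction coefficient (gamma0 min um^-3).
#' @param M transport coefficient of the relaxational dynamics.
#' @param alpha motility-force magnitude (gamma0 um^-2).
#' @param mu_beta,sigma_beta mean and s.d. of the Gaussian patch amplitude.
#' @param sigma_patch spatial extent of an activity patch (um).
#' @param s0 perimeter threshold for global polarity inhibition (um);
#'   defaults to \code{2*pi*1.5*R0}.  \code{Inf} disables the term.
#' @param tau_f patch period (seconds); \code{Inf} disables patches.
#' @param tau_chi off-pattern inhibition timescale (seconds); \code{Inf}
#'   disables the coupling (the "no chi coupling" knockout).
#' @param tau_s perimeter-inhibition timescale (min).
#' @param tau basal polarity decay timescale (min).
#' @param ell filopodial probe distance (um).
#' @param gamma0 arbitrary tension scale; results depend only on ratios.
#' @param c0 dimensionless coefficient of the double-well potential in the
#'   interfacial free energy (the equilibrium 1D front is logistic with rate
#'   \code{4*sqrt(2*c0/32)/lambda}; the default \code{c0 = 16} gives rate
#'   \code{4*sqrt(2)/lambda}).
#' @param no_filopodia logical; if \code{TRUE}, patch placement weights are
#'   proportional to polarity only (the filopodial-sensing knockout).
#' @param dx grid spacing (um).
#' @param dt time step (min); must not exceed \code{stability_dt()}.
#' @param pad domain padding beyond the micropattern bounding box (um).
#' @param record_every trajectory recording interval (min).
#' @return an object of class \code{pf_params} (a validated list).
#' @export
model_params <- function(gamma = 0.8, lambda = 4.8, kappa = 6000, R0 = 18,
                         eta = 0.67, M = 0.75, alpha = 1.4,
                         mu_beta = 7.5, sigma_beta = 37.5, sigma_patch = 6.7,
                         s0 = NULL, tau_f = 2.2, tau_chi = 9.6,
                         tau_s = 8, tau = 4, ell = 6,
                         gamma0 = 1, c0 = 16, no_filopodia = FALSE,
                         dx = 1, dt = 0.005, pad = 12, record_every = 1) {
  if (is.null(s0)) s0 <- 2 * pi * 1.5 * R0
  p <- list(gamma = gamma, lambda = lambda, kappa = kappa, R0 = R0,
            eta = eta, M = M, alpha = alpha,
            mu_beta = mu_beta, sigma_beta = sigma_beta,
            sigma_patch = sigma_patch, s0 = s0,
            tau_f = tau_f, tau_chi = tau_chi, tau_s = tau_s, tau = tau,
            ell = ell, gamma0 = gamma0, c0 = c0,
            no_filopodia = isTRUE(no_filopodia),
            tau_f_min = tau_f / 60, tau_chi_min = tau_chi / 60,
            dx = dx, dt = dt, pad = pad, record_every = record_every)
  class(p) <- "pf_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  pos <- c("gamma", "lambda", "kappa", "R0", "eta", "M", "sigma_patch",
           "s0", "tau_f", "tau_chi", "tau_s", "tau", "gamma0", "c0",
           "dx", "dt", "record_every")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number", call. = FALSE)
  }
  for (nm in c("alpha", "mu_beta", "sigma_beta", "ell", "pad")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number", call. = FALSE)
  }
  if (p$dt > stability_dt(p))
    stop("time step dt = ", p$dt, " exceeds the explicit-Euler stability bound ",
         signif(stability_dt(p), 3),
         " min (diffusive limit of the interfacial term / area-constraint mode)",
         call. = FALSE)
  invisible(p)
}

#' Explicit-Euler stability bound for the time step
#'
#' The binding constraints are the diffusive limit of the
#' \code{M*gamma*lambda} Laplacian term, \code{dx^2 / (4 M gamma lambda)},
#' and the relaxation rate of the global area-constraint mode,
#' \code{pi R0^2 / (8 M kappa)}.  The reaction term of the double-well
#' potential is slower at the default parameters.
#'
#' @param params a \code{pf_params} object.
#' @return maximum stable \code{dt} in minutes.
#' @export
stability_dt <- function(params) {
  diff_lim <- params$dx^2 / (4 * params$M * params$gamma * params$lambda)
  area_lim <- (pi * params$R0^2) / (8 * params$M * params$kappa)
  react_lim <- params$lambda / (2 * params$M * params$gamma * params$c0)
  min(diff_lim, area_lim, react_lim)
}

#' Radius of the phi = 1/2 level set whose integrated phi^2 area is pi R0^2
#'
#' A diffuse logistic disk with half-level at radius R has
#' \code{integral(phi^2) ~ pi R^2 - 2 pi R / k} with front rate
#' \code{k = 4 sqrt(2) c(c0) / lambda}; this returns the R that makes the
#' integral equal the target area, used when seeding new cells.
#'
#' @param params a \code{pf_params} object.
#' @return radius in um.
#' @export
half_level_radius <- function(params) {
  k <- front_rate(params)
  1 / k + sqrt(1 / k^2 + params$R0^2)
}

# logistic front rate implied by the interfacial energy coefficients:
# phi' = sqrt(2 * (c0/lambda) / lambda) * ... = (sqrt(2*c0)/lambda) phi(1-phi)
front_rate <- function(params) sqrt(2 * params$c0) / params$lambda

#' @export
print.pf_params <- function(x, ...) {
  cat("phase-field cell parameters\n")
  cat(sprintf("  gamma = %g gamma0, lambda = %g um, kappa = %g, R0 = %g um\n",
              x$gamma, x$lambda, x$kappa, x$R0))
  cat(sprintf("  eta = %g, M = %g, alpha = %g\n", x$eta, x$M, x$alpha))
  cat(sprintf("  patches: mu_beta = %g, sigma_beta = %g, sigma = %g um, tau_f = %g s\n",
              x$mu_beta, x$sigma_beta, x$sigma_patch, x$tau_f))
  cat(sprintf("  polarity: tau_chi = %g s, tau_s = %g min, tau = %g min, s0 = %g um, ell = %g um\n",
              x$tau_chi, x$tau_s, x$tau, x$s0, x$ell))
  cat(sprintf("  numerics: dx = %g um, dt = %g min (stable <= %.3g), pad = %g um\n",
              x$dx, x$dt, stability_dt(x), x$pad))
  if (x$no_filopodia) cat("  knockout: filopodial sensing OFF\n")
  invisible(x)
}
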