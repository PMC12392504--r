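#' Filopodial placement weights for polarity patches
#'
#' Probability weights over contour points for placing the next activity
#' patch: \code{w_i = (1 - chi(theta_i + ell * nhat_i)) * max(P(theta_i), 0)},
#' normalised to sum to one.  A contour point whose probe lands fully off
#' the pattern gets zero weight; if every weight vanishes (e.g. a fully
#' depolarised cell) the uniform distribution is returned so the scheduler
#' never deadlocks.  Polarity is clamped at zero because the weights must
#' form a probability distribution while P itself may be negative.
#'
#' @param contour a \code{pf_contour}.
#' @param P polarity \code{pf_field}.
#' @param chi micropattern \code{pf_field}; points outside the grid count as
#'   fully off-pattern (chi = 1).
#' @param ell probe distance along the outward normal (um).
#' @param no_filopodia if \code{TRUE}, the probe factor is dropped and
#'   weights are proportional to \code{max(P, 0)} only.
#' @return numeric vector of probabilities over contour points.
#' @export
filopodial_weights <- function(contour, P, chi, ell, no_filopodia = FALSE) {
  pts <- contour$points
  w <- pmax(interp_field(P, pts[, 1], pts[, 2], fill = 0), 0)
  if (!no_filopodia) {
    probe <- pts + ell * contour$normals
    chi_probe <- interp_field(chi, probe[, 1], probe[, 2], fill = 1)
    w <- w * pmax(1 - chi_probe, 0)
  }
  tot <- sum(w)
  if (tot <= 0) rep(1 / nrow(pts), nrow(pts)) else w / tot
}

#' Add one radially symmetric activity patch to the polarity field
#'
#' \code{P <- P + beta * exp(-|r - theta|^2 / (2 sigma^2)) * phi}: an
#' instantaneous impulse confined to the cell interior by the phi factor.
#'
#' @param P polarity \code{pf_field}.
#' @param theta patch centre (x, y) in um, normally a contour point.
#' @param beta patch amplitude (may be negative).
#' @param sigma patch spatial extent (um).
#' @param phi phase \code{pf_field} on the same grid.
#' @return the updated polarity \code{pf_field}.
#' @export
apply_activity_patch <- function(P, theta, beta, sigma, phi) {
  check_same_grid(P, phi)
  P$values <- cpp_apply_patch(P$values, phi$values, P$dx,
                              P$origin[1], P$origin[2],
                              theta[1], theta[2], beta, sigma)
  P
}

#' Advance the deterministic polarity terms by one Euler step
#'
#' \code{dP/dt = -(chi phi)/tau_chi - (s/s0)^2 H(s - s0) phi / tau_s -
#' P/tau}.  The off-pattern and perimeter inhibitions are localised to the
#' cell by the phi factor; with both knocked out (\code{tau_chi = Inf},
#' \code{s0 = Inf}) the field decays exponentially with timescale
#' \code{tau}.
#'
#' @param P,phi,chi \code{pf_field}s on a common grid.
#' @param s current cell perimeter (um).
#' @param dt time step (min).
#' @param params a \code{pf_params} object.
#' @return the updated polarity \code{pf_field}.
#' @export
step_polarity <- function(P, phi, chi, s, dt, params) {
  check_same_grid(P, phi, chi)
  stopifnot(s >= 0)
  inh_chi <- if (is.finite(params$tau_chi_min)) chi$values * phi$values / params$tau_chi_min else 0
  inh_s <- if (is.finite(params$s0) && s > params$s0)
    (s / params$s0)^2 * phi$values / params$tau_s else 0
  P$values <- P$values + dt * (-inh_chi - inh_s - P$values / params$tau)
  P
}

#' Patch firing times of the polarity event scheduler
#'
#' Patches fire once per \code{tau_f} of simulated time, at the first step
#' whose clock crosses each multiple of \code{tau_f}; over a duration T
#' exactly \code{floor(T / tau_f)} patches fire.
#'
#' @param duration simulated duration (min).
#' @param tau_f_min patch period in minutes.
#' @return numeric vector of firing times (min).
#' @export
patch_times <- function(duration, tau_f_min) {
  if (!is.finite(tau_f_min)) return(numeric(0))
  n <- floor(duration / tau_f_min + 1e-9)
  seq_len(n) * tau_f_min
}

#' Draw one activity-patch event
#'
#' Samples the patch location from \code{\link{filopodial_weights}} and the
#' amplitude from Normal(mu_beta, sigma_beta) using R's RNG.
#'
#' @param contour a \code{pf_contour}.
#' @param P,chi \code{pf_field}s.
#' @param params a \code{pf_params} object.
#' @return list with \code{theta} (x, y), \code{beta} and the sampled index.
#' @export
draw_patch <- function(contour, P, chi, params) {
  w <- filopodial_weights(contour, P, chi, params$ell, params$no_filopodia)
  i <- sample.int(length(w), 1, prob = w)
  list(theta = contour$points[i, ], beta = stats::rnorm(1, params$mu_beta, params$sigma_beta),
       index = i)
}

#' Summarise the polarisation state along the cell boundary
#'
#' Samples P along the ordered contour and measures how much of the total
#' positive polarity sits in the single largest contiguous positive arc
#' (treating the contour as circular).  A cell whose dominant arc carries at
#' least half the positive mass is called singly polarised.
#'
#' @param P polarity \code{pf_field}.
#' @param contour a \code{pf_contour}.
#' @return list with \code{frac_dominant} (share of positive polarity in the
#'   largest arc), \code{n_arcs} and \code{singly_polarized}.
#' @export
polarization_summary <- function(P, contour) {
  v <- interp_field(P, contour$points[, 1], contour$points[, 2], fill = 0)
  pos <- pmax(v, 0)
  tot <- sum(pos)
  if (tot <= 0)
    return(list(frac_dominant = 0, n_arcs = 0L, singly_polarized = FALSE))
  r <- rle(v > 0)
  # merge wrap-around arc
  masses <- numeric(0)
  starts <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    idx <- seq(starts[k], length.out = r$lengths[k])
    masses <- c(masses, sum(pos[idx]))
  }
  if (length(r$values) >= 2 && r$values[1] && r$values[length(r$values)]) {
    masses <- c(masses[1] + masses[length(masses)],
                masses[-c(1, length(masses))])
  }
  list(frac_dominant = max(masses) / tot, n_arcs = length(masses),
       singly_polarized = max(masses) / tot >= 0.5)
}
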