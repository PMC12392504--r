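#' Initialise a cell on a micropattern
#'
#' Seeds a logistic disk for phi (half-level radius corrected so the
#' integrated phi^2 area starts at ~ pi R0^2, see
#' \code{\link{half_level_radius}}) and a zero polarity field.  Placement
#' modes: \code{basin_random} picks one of the two basins of the two-state
#' pattern at random and jitters the centre uniformly while keeping the disk
#' inside the basin; \code{uniform_x} draws the centre x uniformly over the
#' positions that keep the disk inside the rectangle (y = 0); \code{center}
#' places the cell at the origin (used for free 2D and freeze-shape runs).
#'
#' @param pattern a \code{pf_pattern}.
#' @param params a \code{pf_params} object.
#' @param mode placement mode; defaults to \code{basin_random} for the
#'   two-state pattern, \code{uniform_x} for the rectangle, \code{center}
#'   otherwise.
#' @param seed optional integer seed for the placement draw.
#' @return a cell state: list with \code{pf_field}s \code{phi} and \code{P},
#'   clock \code{t = 0} and the grid description.
#' @export
initialize_cell <- function(pattern, params = model_params(),
                            mode = NULL, seed = NULL) {
  if (is.null(mode))
    mode <- switch(pattern$kind, two_state = "basin_random",
                   rectangle = "uniform_x", "center")
  mode <- match.arg(mode, c("basin_random", "uniform_x", "center"))
  if (!is.null(seed)) set.seed(seed)
  grid <- pattern_grid(pattern, params)
  Rh <- half_level_radius(params)

  if (mode == "basin_random") {
    if (pattern$kind != "two_state")
      stop("basin_random placement requires a two-state pattern")
    hy <- pattern$basin[2] / 2
    margin <- c(pattern$basin[1] / 2, hy) - Rh
    if (any(margin < -0.5))
      stop("cell of target radius R0 = ", params$R0,
           " um does not fit inside a ", pattern$basin[1], " x ",
           pattern$basin[2], " um basin")
    margin <- pmax(margin, 0)
    side <- if (stats::runif(1) < 0.5) -1 else 1
    cx0 <- pattern$bridge[2] / 2 + pattern$basin[1] / 2
    center <- c(side * cx0 + stats::runif(1, -margin[1], margin[1]),
                stats::runif(1, -margin[2], margin[2]))
  } else if (mode == "uniform_x") {
    if (pattern$kind != "rectangle")
      stop("uniform_x placement requires a rectangular pattern")
    mx <- pattern$rect[1] / 2 - Rh
    if (mx < -0.5) stop("cell does not fit inside the rectangle")
    center <- c(stats::runif(1, -max(mx, 0), max(mx, 0)), 0)
  } else {
    center <- c(0, 0)
  }

  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dx
  r <- sqrt(outer((xs - center[1])^2, (ys - center[2])^2, "+"))
  k <- front_rate(params)
  # refine the analytic half-level radius so the discrete integral(phi^2)
  # area starts exactly on target
  A0 <- pi * params$R0^2
  disk_area <- function(R) cpp_area(1 / (1 + exp(k * (r - R))), grid$dx)
  lo <- Rh - 2; hi <- Rh + 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (disk_area(mid) < A0) lo <- mid else hi <- mid
  }
  Rh <- (lo + hi) / 2
  phi <- 1 / (1 + exp(k * (r - Rh)))
  list(phi = scalar_field(phi, grid$dx, grid$origin),
       P = scalar_field(matrix(0, grid$nx, grid$ny), grid$dx, grid$origin),
       t = 0, center = center, grid = grid)
}

#' Run one cell simulation
#'
#' Evolves the coupled phase-field / polarity dynamics with stochastic
#' activity patches on a micropattern and records the centre-of-mass
#' trajectory every \code{params$record_every} minutes.  Identical
#' (params, pattern, duration, seed) give bit-identical output.
#'
#' @param params a \code{pf_params} object.
#' @param pattern a \code{pf_pattern} (or a chi \code{pf_field}; then
#'   \code{state} must be supplied).
#' @param duration simulated duration (min).
#' @param seed integer seed for the run's RNG (placement + patch noise).
#' @param init_mode placement mode passed to \code{\link{initialize_cell}}.
#' @param state optional pre-built cell state (overrides placement).
#' @param freeze_shape if \code{TRUE}, phi is held fixed and only the
#'   polarity evolves (static-shape polarity solve).
#' @param record_fields if \code{> 0}, phi and P snapshots are stored every
#'   \code{record_fields} minutes in the \code{snapshots} attribute.
#' @param log_patches if \code{TRUE} (default), every patch event
#'   (t, x, y, beta) is logged.
#' @return a \code{pf_trajectory}: data frame with columns \code{t_min},
#'   \code{x_um}, \code{y_um}, \code{area_um2}, \code{perim_um} and
#'   attributes \code{seed}, \code{flags} (ruptured / escaped / failed),
#'   \code{patches}, \code{final} (final fields), \code{params},
#'   \code{pattern}.
#' @export
run_simulation <- function(params, pattern, duration, seed = 1,
                           init_mode = NULL, state = NULL,
                           freeze_shape = FALSE, record_fields = 0,
                           log_patches = TRUE) {
  stopifnot(duration > 0)
  validate_params(params)
  set.seed(seed)
  if (inherits(pattern, "pf_field")) {
    chi <- pattern
    if (is.null(state)) stop("supply 'state' when passing a raw chi field")
    bbox <- c(diff(range(field_x(chi))), diff(range(field_y(chi))))
    pattern_meta <- NULL
  } else {
    if (is.null(state)) state <- initialize_cell(pattern, params, mode = init_mode)
    chi <- build_pattern(pattern, grid = state$grid, params = params)
    bbox <- pattern_bbox(pattern)
    if (!all(is.finite(bbox)))
      bbox <- c(diff(range(field_x(chi))), diff(range(field_y(chi))))
    pattern_meta <- pattern
  }
  check_same_grid(state$phi, state$P, chi)

  control <- list(dt = params$dt, duration = duration,
                  record_every = params$record_every,
                  freeze_shape = freeze_shape, log_patches = log_patches,
                  fields_every = record_fields,
                  rupture_frac = 0.05,
                  bbox_hx = bbox[1] / 2, bbox_hy = bbox[2] / 2,
                  escape_margin = params$R0 / 2)
  out <- cpp_run(state$phi$values, state$P$values, chi$values,
                 state$phi$dx, state$phi$origin[1], state$phi$origin[2],
                 params, control)
  if (out$failed)
    warning("simulation seed ", seed, " failed numerically; run flagged", call. = FALSE)
  if (out$phi_min < -0.02 || out$phi_max > 1.02)
    warning(sprintf("phase field overshoot beyond tolerance during run (range [%.3f, %.3f])",
                    out$phi_min, out$phi_max), call. = FALSE)

  traj <- data.frame(t_min = out$t, x_um = out$x, y_um = out$y,
                     area_um2 = out$area, perim_um = out$perimeter)
  patches <- out$patches
  colnames(patches) <- c("t_min", "x_um", "y_um", "beta", "fallback")
  attr(traj, "seed") <- seed
  attr(traj, "flags") <- list(ruptured = out$ruptured, escaped = out$escaped,
                              failed = out$failed)
  attr(traj, "patches") <- patches
  # a numerically failed run may hold non-finite fields; keep them raw
  mkfield <- function(v) {
    if (all(is.finite(v))) scalar_field(v, state$phi$dx, state$phi$origin)
    else structure(list(values = v, dx = state$phi$dx, origin = state$phi$origin),
                   class = "pf_field")
  }
  attr(traj, "final") <- list(phi = mkfield(out$phi), P = mkfield(out$P))
  attr(traj, "phi_range") <- c(out$phi_min, out$phi_max)
  attr(traj, "params") <- params
  attr(traj, "pattern") <- pattern_meta
  if (record_fields > 0)
    attr(traj, "snapshots") <- list(
      t = out$snap_t,
      phi = lapply(out$snap_phi, scalar_field, dx = state$phi$dx, origin = state$phi$origin),
      P = lapply(out$snap_P, scalar_field, dx = state$phi$dx, origin = state$phi$origin))
  class(traj) <- c("pf_trajectory", "data.frame")
  traj
}

#' Run a seeded ensemble of simulations
#'
#' N independent runs with seeds \code{base_seed .. base_seed + n - 1}.
#' Ruptured and numerically failed runs are kept in the set but marked not
#' OK and excluded from downstream inference, with a logged count.
#'
#' @param params,pattern,duration as in \code{\link{run_simulation}}.
#' @param n number of runs.
#' @param base_seed first seed.
#' @param ... passed to \code{\link{run_simulation}}.
#' @return a \code{pf_trajectory_set}: list of trajectories with metadata
#'   (\code{seeds}, \code{ok}, \code{n_excluded}, \code{params_hash}).
#' @export
run_ensemble <- function(params, pattern, n, duration, base_seed = 1, ...) {
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n) - 1L
  runs <- lapply(seeds, function(s)
    run_simulation(params, pattern, duration, seed = s, ...))
  trajectory_set(runs, params = params, pattern = pattern)
}

#' Assemble trajectories into a set
#'
#' @param runs list of \code{pf_trajectory} objects.
#' @param params,pattern shared metadata (optional).
#' @return a \code{pf_trajectory_set}.
#' @export
trajectory_set <- function(runs, params = NULL, pattern = NULL) {
  ok <- vapply(runs, function(tr) {
    fl <- attr(tr, "flags")
    is.null(fl) || !(isTRUE(fl$ruptured) || isTRUE(fl$failed))
  }, TRUE)
  structure(list(runs = runs,
                 seeds = vapply(runs, function(tr) {
                   s <- attr(tr, "seed"); if (is.null(s)) NA_integer_ else as.integer(s)
                 }, 1L),
                 ok = ok, n_excluded = sum(!ok),
                 params = params, pattern = pattern,
                 params_hash = if (!is.null(params)) params_hash(params) else NA_character_),
            class = "pf_trajectory_set")
}

#' @export
print.pf_trajectory_set <- function(x, ...) {
  cat(sprintf("pf_trajectory_set: %d runs (%d excluded: ruptured/failed)\n",
              length(x$runs), x$n_excluded))
  invisible(x)
}

#' @export
print.pf_trajectory <- function(x, ...) {
  fl <- attr(x, "flags")
  cat(sprintf("pf_trajectory: %d samples over %.1f min, seed %s%s\n",
              nrow(x), max(x$t_min), format(attr(x, "seed")),
              if (!is.null(fl) && (fl$ruptured || fl$escaped || fl$failed))
                paste0(" [", paste(names(fl)[unlist(fl)], collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Relax a cell with motility disabled
#'
#' Gradient-flow relaxation of the free energy on an unconfined domain
#' (alpha = 0 has no effect because P stays 0 and patches are disabled via
#' \code{tau_f = Inf}); used to verify the equilibrium disk shape.
#'
#' @param params a \code{pf_params} object.
#' @param duration relaxation time (min).
#' @param seed RNG seed (unused by the dynamics; placement is centred).
#' @return a \code{pf_trajectory}.
#' @export
relax_cell <- function(params = model_params(), duration = 40, seed = 1) {
  q <- params
  q$tau_f <- Inf; q$tau_f_min <- Inf
  pat <- pattern_spec("free2d")
  run_simulation(q, pat, duration, seed = seed, init_mode = "center")
}
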