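#' Friction cut F(x -> 0, v) through the drift field
#'
#' Averages the drift over x-bins whose centres lie within
#' \code{x_window} of the pattern symmetry axis (count-weighted) and
#' reports the small-velocity slope of the resulting curve.  A positive
#' slope at small |v| is "negative friction": slow cells tend to
#' accelerate, the signature of constricted two-state migration; ordinary
#' persistence decay gives a negative slope (F(0, v) = -xi v).
#'
#' @param field a \code{pf_drift_field}.
#' @param x_window half-width of the averaging window around x = 0 (um);
#'   default 1.5 x-bin widths.
#' @param v_max fit the slope over |v| <= v_max; default the median |v-bin
#'   centre|.
#' @return an object of class \code{pf_friction_cut}: data frame with
#'   columns \code{v}, \code{F}, \code{n}, plus attributes \code{slope}
#'   (weighted least squares through the small-|v| points) and
#'   \code{x_window}.
#' @export
friction_cut <- function(field, x_window = NULL, v_max = NULL) {
  if (is.null(x_window)) x_window <- 1.5 * mean(diff(field$x_centers))
  sel <- abs(field$x_centers) <= x_window
  if (!any(sel)) stop("no x-bins inside the window |x| <= ", x_window)
  Fm <- field$F[sel, , drop = FALSE]
  Cm <- pmin(field$count[sel, , drop = FALSE], 1e12)  # analytic fields use Inf
  Cm[!is.finite(Fm)] <- 0
  wsum <- colSums(Cm)
  Fv <- ifelse(wsum > 0, colSums(ifelse(is.finite(Fm), Fm, 0) * Cm) / pmax(wsum, 1),
               NA_real_)
  ok <- is.finite(Fv)
  if (!any(ok)) stop("no populated bins inside the window |x| <= ", x_window)
  out <- data.frame(v = field$v_centers[ok], F = Fv[ok], n = wsum[ok])
  if (is.null(v_max)) v_max <- stats::median(abs(field$v_centers))
  fit_sel <- abs(out$v) <= v_max
  slope <- NA_real_
  if (sum(fit_sel) >= 2) {
    fit <- stats::lm(F ~ v, data = out[fit_sel, ], weights = out$n[fit_sel])
    slope <- unname(stats::coef(fit)["v"])
  }
  attr(out, "slope") <- slope
  attr(out, "x_window") <- x_window
  attr(out, "v_max") <- v_max
  class(out) <- c("pf_friction_cut", "data.frame")
  out
}

#' @export
print.pf_friction_cut <- function(x, ...) {
  s <- attr(x, "slope")
  cat(sprintf("friction cut F(x->0, v): %d v-bins, small-|v| slope %.4g min^-1 (%s friction)\n",
              nrow(x), s, if (is.finite(s) && s > 0) "negative" else "normal"))
  invisible(x)
}

#' Basin dwell times on a two-state pattern
#'
#' A hysteretic two-threshold state machine over x(t): the cell enters the
#' right basin when x exceeds \code{x_threshold + hysteresis/2}, the left
#' basin when x drops below the negative of that, and keeps its state in
#' between (so noise smaller than the hysteresis band never creates
#' spurious hops).  A hop is a left-right transition; each dwell is the
#' time between successive basin entries.  The leading time before the
#' first entry and the trailing incomplete dwell are discarded.
#'
#' @param traj a \code{pf_trajectory} (or any data frame with \code{t_min}
#'   and \code{x_um}).
#' @param x_threshold basin entry threshold (um); default for the default
#'   two-state geometry is the bridge half-length minus R0/2 (8.5 um).
#' @param hysteresis width of the guard band (um).
#' @return an object of class \code{pf_hopping}: list with \code{dwells}
#'   (min), \code{n_hops}, \code{entries} (data frame of entry times and
#'   sides) and the thresholds used.
#' @export
hopping_times <- function(traj, x_threshold = 8.5, hysteresis = 4) {
  x <- traj$x_um; t <- traj$t_min
  hi <- x_threshold + hysteresis / 2
  state <- 0L  # 0 unknown, -1 left, +1 right
  entry_t <- numeric(0); entry_s <- integer(0)
  for (k in seq_along(x)) {
    s_new <- if (x[k] > hi) 1L else if (x[k] < -hi) -1L else state
    if (s_new != state) {
      entry_t <- c(entry_t, t[k]); entry_s <- c(entry_s, s_new)
      state <- s_new
    }
  }
  dwells <- if (length(entry_t) >= 2) diff(entry_t) else numeric(0)
  structure(list(dwells = dwells, n_hops = max(0L, length(entry_t) - 1L),
                 entries = data.frame(t_min = entry_t, side = entry_s),
                 x_threshold = x_threshold, hysteresis = hysteresis),
            class = "pf_hopping")
}

#' @export
print.pf_hopping <- function(x, ...) {
  cat(sprintf("pf_hopping: %d hops, mean dwell %.1f min (threshold +/-%g um, hysteresis %g um)\n",
              x$n_hops, if (length(x$dwells)) mean(x$dwells) else NA,
              x$x_threshold, x$hysteresis))
  invisible(x)
}

#' Pooled hopping-time histogram over an ensemble
#'
#' @param set a \code{pf_trajectory_set}.
#' @param breaks histogram bin width in minutes (default 30).
#' @param ... passed to \code{\link{hopping_times}}.
#' @return list with the pooled \code{dwells}, per-run hop counts and a
#'   histogram (counts per 30-min bin).
#' @export
pooled_hopping_times <- function(set, breaks = 30, ...) {
  hs <- lapply(set$runs[set$ok], hopping_times, ...)
  dwells <- unlist(lapply(hs, `[[`, "dwells"))
  n_hops <- vapply(hs, `[[`, 0L, "n_hops")
  brk <- seq(0, max(c(dwells, breaks)) + breaks, by = breaks)
  list(dwells = dwells, n_hops = n_hops,
       hist = if (length(dwells)) hist(dwells, breaks = brk, plot = FALSE) else NULL)
}

#' Area-weighted basin occupancy
#'
#' \code{P_left = (T_left / A_left) / (T_left / A_left + T_right / A_right)}:
#' the fraction of time spent in the left basin, weighted by basin area so
#' that a cell exploring uniformly scores 0.5 even on basins of unequal
#' size.  Basin membership is decided from x; time on the bridge
#' (|x| <= x_split) is excluded.
#'
#' @param trajs a \code{pf_trajectory}, a \code{pf_trajectory_set}, or a
#'   list with precomputed times \code{T_left}, \code{T_right} (min).
#' @param A_left,A_right basin areas (um^2); see \code{\link{basin_areas}}.
#' @param x_split boundary between basin and bridge (um); default 17.5
#'   (the default bridge half-length).
#' @return an object of class \code{pf_occupancy}: list with \code{P_left},
#'   \code{T_left}, \code{T_right} (min) and the areas.
#' @export
occupancy_fractions <- function(trajs, A_left, A_right, x_split = 17.5) {
  stopifnot(A_left > 0, A_right > 0)
  if (is.list(trajs) && !is.data.frame(trajs) &&
      !inherits(trajs, "pf_trajectory_set") &&
      all(c("T_left", "T_right") %in% names(trajs))) {
    T_left <- trajs$T_left; T_right <- trajs$T_right
  } else {
    runs <- if (inherits(trajs, "pf_trajectory_set")) trajs$runs[trajs$ok] else list(trajs)
    T_left <- 0; T_right <- 0
    for (tr in runs) {
      rec <- stats::median(diff(tr$t_min))
      T_left <- T_left + rec * sum(tr$x_um < -x_split)
      T_right <- T_right + rec * sum(tr$x_um > x_split)
    }
  }
  if (T_left + T_right <= 0) stop("no time spent in either basin")
  rl <- T_left / A_left; rr <- T_right / A_right
  structure(list(P_left = rl / (rl + rr), T_left = T_left, T_right = T_right,
                 A_left = A_left, A_right = A_right, x_split = x_split),
            class = "pf_occupancy")
}

#' @export
print.pf_occupancy <- function(x, ...) {
  cat(sprintf("occupancy: P_left = %.3f (T_left %.0f min / %g um^2, T_right %.0f min / %g um^2)\n",
              x$P_left, x$T_left, x$A_left, x$T_right, x$A_right))
  invisible(x)
}
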