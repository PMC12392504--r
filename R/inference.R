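#' Positions, velocities and accelerations from a trajectory
#'
#' Downsamples the recorded x(t) to the inference cadence
#' \code{dt_sample}, then forms finite differences
#' \code{v_k = (x_{k+1} - x_k)/dt} and \code{a_k = (v_{k+1} - v_k)/dt}.
#' Each acceleration is conditioned on the leading pair \code{(x_k, v_k)}
#' (the plain Euler reading of the underdamped equation of motion); the
#' convention is centralised here so it can be switched.
#'
#' @param traj a \code{pf_trajectory} or a \code{pf_trajectory_set} (flagged
#'   runs are skipped).
#' @param dt_sample sampling interval in minutes; must be a multiple of the
#'   recording interval.
#' @return data frame with columns \code{run}, \code{x}, \code{v}, \code{a}
#'   and attribute \code{dt_sample}.
#' @export
finite_difference_kinematics <- function(traj, dt_sample = 10) {
  if (inherits(traj, "pf_trajectory_set")) {
    keep <- which(traj$ok)
    if (!length(keep)) stop("no usable (non-flagged) runs in the set")
    out <- do.call(rbind, lapply(keep, function(i) {
      k <- finite_difference_kinematics(traj$runs[[i]], dt_sample)
      k$run <- i
      k
    }))
    attr(out, "dt_sample") <- dt_sample
    return(out)
  }
  t <- traj$t_min
  rec <- stats::median(diff(t))
  stride <- dt_sample / rec
  if (abs(stride - round(stride)) > 1e-8)
    stop("dt_sample (", dt_sample, ") must be a multiple of the recording interval (",
         rec, ")")
  stride <- as.integer(round(stride))
  x <- traj$x_um[seq(1, length(t), by = stride)]
  if (length(x) < 3) stop("need at least 3 samples at dt_sample = ", dt_sample)
  v <- diff(x) / dt_sample
  a <- diff(v) / dt_sample
  n <- length(a)
  out <- data.frame(run = 1L, x = x[seq_len(n)], v = v[seq_len(n)], a = a)
  attr(out, "dt_sample") <- dt_sample
  out
}

#' Binned conditional-mean drift field F(x, v)
#'
#' Estimates the deterministic part of the equation of motion
#' \code{dv/dt = F(x, v) + sigma(x, v) eta(t)} as the average acceleration
#' conditional on position and velocity: F per bin is the mean of \code{a}
#' over samples in the bin.  Bins with fewer than \code{min_count} samples
#' are masked (NA).  The per-bin standard deviation is also returned as a
#' crude noise-amplitude estimate, but is not used downstream.
#'
#' @param samples data frame from \code{\link{finite_difference_kinematics}}
#'   (columns x, v, a).
#' @param x_edges,v_edges bin edges; by default 36 x-bins over the x range
#'   and 30 v-bins over the central 98\% of the v distribution.
#' @param n_x,n_v number of bins used when edges are not supplied.
#' @param min_count minimum samples per usable bin.
#' @return an object of class \code{pf_drift_field}: list with matrices
#'   \code{F}, \code{sd}, \code{count} (x-bins by v-bins) and the bin edges
#'   and centres.
#' @export
estimate_drift_field <- function(samples, x_edges = NULL, v_edges = NULL,
                                 n_x = 36, n_v = 30, min_count = 20) {
  stopifnot(nrow(samples) > 0)
  if (is.null(x_edges))
    x_edges <- seq(min(samples$x), max(samples$x), length.out = n_x + 1)
  if (is.null(v_edges)) {
    q <- stats::quantile(samples$v, c(0.01, 0.99), names = FALSE)
    if (q[1] == q[2]) q <- q + c(-1, 1) * max(1e-8, abs(q[1]) * 0.1 + 1e-8)
    v_edges <- seq(q[1], q[2], length.out = n_v + 1)
  }
  stopifnot(all(diff(x_edges) > 0), all(diff(v_edges) > 0))
  nx <- length(x_edges) - 1L; nv <- length(v_edges) - 1L
  ix <- findInterval(samples$x, x_edges, rightmost.closed = TRUE)
  iv <- findInterval(samples$v, v_edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nx & iv >= 1 & iv <= nv
  ix <- ix[ok]; iv <- iv[ok]; a <- samples$a[ok]
  bin <- (iv - 1L) * nx + ix
  cnt <- tabulate(bin, nbins = nx * nv)
  s1 <- rowsum_safe(a, bin, nx * nv)
  s2 <- rowsum_safe(a^2, bin, nx * nv)
  Fv <- ifelse(cnt > 0, s1 / pmax(cnt, 1), NA_real_)
  varv <- ifelse(cnt > 1, (s2 - s1^2 / pmax(cnt, 1)) / pmax(cnt - 1, 1), NA_real_)
  mask <- cnt < min_count
  Fv[mask] <- NA_real_
  if (all(is.na(Fv)))
    stop("no bin reaches min_count = ", min_count,
         " samples; supply more data or coarser bins")
  structure(list(F = matrix(Fv, nx, nv),
                 sd = matrix(sqrt(pmax(varv, 0)), nx, nv),
                 count = matrix(cnt, nx, nv),
                 x_edges = x_edges, v_edges = v_edges,
                 x_centers = (x_edges[-1] + x_edges[-(nx + 1)]) / 2,
                 v_centers = (v_edges[-1] + v_edges[-(nv + 1)]) / 2,
                 min_count = min_count),
            class = "pf_drift_field")
}

rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.pf_drift_field <- function(x, ...) {
  cat(sprintf("pf_drift_field: %d x-bins x %d v-bins, %d populated (min_count %d)\n",
              length(x$x_centers), length(x$v_centers),
              sum(is.finite(x$F)), x$min_count))
  invisible(x)
}

#' Drift field evaluated from an analytic function
#'
#' Builds a fully populated \code{pf_drift_field} from a known drift
#' F*(x, v), for validating streamline tracing and classification against
#' closed-form dynamics.
#'
#' @param f function of (x, v) returning the drift (vectorised).
#' @param x_edges,v_edges bin edges.
#' @return a \code{pf_drift_field} with infinite counts.
#' @export
drift_field_from_function <- function(f, x_edges, v_edges) {
  nx <- length(x_edges) - 1L; nv <- length(v_edges) - 1L
  xc <- (x_edges[-1] + x_edges[-(nx + 1)]) / 2
  vc <- (v_edges[-1] + v_edges[-(nv + 1)]) / 2
  Fm <- outer(xc, vc, f)
  structure(list(F = Fm, sd = matrix(0, nx, nv),
                 count = matrix(Inf, nx, nv),
                 x_edges = x_edges, v_edges = v_edges,
                 x_centers = xc, v_centers = vc, min_count = 0),
            class = "pf_drift_field")
}

#' Trace streamlines of a drift field
#'
#' From each seed, iterates \code{x <- x + v dt}, \code{v <- v + F(x,v) dt}
#' with bilinear interpolation of F between populated bin centres.  A
#' streamline terminates at a point where both speed and acceleration are
#' below tolerance (a terminal point), stops when it leaves the populated
#' region (masked bins are never read), or runs to \code{max_steps} and
#' becomes a cycling candidate.
#'
#' @param field a \code{pf_drift_field}.
#' @param seeds m x 2 matrix of (x, v) seeds; by default a coarse grid over
#'   the populated bin centres.
#' @param dt_s integration step (min); by default 5\% of the field's own
#'   timescale \code{rms(v)/rms(F)} (capped at 0.1), which keeps the
#'   explicit update stable for stiff drift fields.
#' @param eps_v,eps_F termination tolerances; default 5\% of the RMS of the
#'   v-bin centres and of the populated |F| values.
#' @param max_steps iteration cap.
#' @param n_seed_x,n_seed_v seed-grid size when \code{seeds} is NULL.
#' @return an object of class \code{pf_portrait} (unlabelled): streamline
#'   paths, per-seed status (terminated / escaped / cycling candidate), end
#'   points, tolerances and the field.
#' @export
integrate_streamlines <- function(field, seeds = NULL, dt_s = NULL,
                                  eps_v = NULL, eps_F = NULL,
                                  max_steps = 1e5,
                                  n_seed_x = 12, n_seed_v = 10) {
  if (!any(is.finite(field$F))) stop("drift field has no populated bins")
  v_rms <- sqrt(mean(field$v_centers^2))
  F_rms <- sqrt(mean(field$F[is.finite(field$F)]^2))
  if (is.null(dt_s)) dt_s <- min(0.1, 0.05 * v_rms / max(F_rms, 1e-12))
  if (is.null(eps_v)) eps_v <- 0.05 * v_rms
  if (is.null(eps_F)) eps_F <- 0.05 * F_rms
  if (is.null(seeds)) {
    sx <- field$x_centers[unique(pmax(1, round(seq(1, length(field$x_centers),
                                                   length.out = n_seed_x))))]
    sv <- field$v_centers[unique(pmax(1, round(seq(1, length(field$v_centers),
                                                   length.out = n_seed_v))))]
    seeds <- as.matrix(expand.grid(x = sx, v = sv))
    # keep only seeds inside the populated region
    keep <- vapply(seq_len(nrow(seeds)), function(i) {
      ix <- findInterval(seeds[i, 1], field$x_centers)
      iv <- findInterval(seeds[i, 2], field$v_centers)
      ix >= 1 && iv >= 1 && ix < length(field$x_centers) &&
        iv < length(field$v_centers) &&
        all(is.finite(field$F[ix + 0:1, iv + 0:1]))
    }, TRUE)
    seeds <- seeds[keep, , drop = FALSE]
  }
  if (!nrow(seeds)) stop("no seeds fall in the populated region of the field")
  res <- cpp_streamlines(field$F, field$x_centers, field$v_centers,
                         seeds, dt_s, eps_v, eps_F, as.integer(max_steps),
                         500L)
  bin_diag <- sqrt(mean(diff(field$x_centers))^2 + mean(diff(field$v_centers))^2)
  structure(list(seeds = seeds, status = res$status, steps = res$steps,
                 x_end = res$x_end, v_end = res$v_end, paths = res$paths,
                 eps_v = eps_v, eps_F = eps_F, r_c = bin_diag,
                 dt_s = dt_s, max_steps = max_steps, field = field,
                 label = NA_character_),
            class = "pf_portrait")
}

# recurrence test for a non-terminating orbit: late-time points must wind
# about a common interior point and revisit an earlier late-time point
is_cycling_orbit <- function(path, field, r_c) {
  n <- nrow(path)
  if (n < 20) return(FALSE)
  tail_idx <- seq(floor(n / 2), n)
  tl <- path[tail_idx, , drop = FALSE]
  # bounded: stays within the field extent
  if (any(tl[, 1] < min(field$x_edges) - 1e-9) ||
      any(tl[, 1] > max(field$x_edges) + 1e-9)) return(FALSE)
  # scale v to x units so angles and distances are not dominated by one axis
  sc <- diff(range(field$x_centers)) / max(diff(range(field$v_centers)), 1e-12)
  tx <- tl[, 1]; tv <- tl[, 2] * sc
  cx <- mean(tx); cv <- mean(tv)
  ang <- atan2(tv - cv, tx - cx)
  dang <- diff(ang)
  dang <- ifelse(dang > pi, dang - 2 * pi, ifelse(dang < -pi, dang + 2 * pi, dang))
  winding <- abs(sum(dang))
  if (winding < 2 * pi) return(FALSE)
  # revisit: final point comes back near an earlier tail point
  m <- length(tx)
  prev <- seq_len(max(1, floor(0.75 * m)))
  d <- sqrt((tx[prev] - tx[m])^2 + (tv[prev] - tv[m])^2)
  spacing <- stats::median(sqrt(diff(tx)^2 + diff(tv)^2))
  min(d) < max(r_c * sqrt(1 + sc^2) / sqrt(2), 3 * spacing)
}

#' Classify the phase portrait of a drift field
#'
#' Clusters streamline terminal points (single linkage, radius one bin
#' diagonal) and assigns one of the canonical motility labels:
#' \describe{
#'   \item{limit_cycle}{at least \code{f_cyc} of streamlines neither
#'     terminate nor escape and their late-time orbits are recurrent
#'     (closed loops).}
#'   \item{bistable}{exactly two dominant terminal clusters at near-zero
#'     velocity whose x separation exceeds \code{x_sep}.}
#'   \item{stationary}{terminal points lie along v ~ 0 spread over a wide
#'     x range without two dominant clusters.}
#'   \item{other}{anything else (e.g. a single point attractor).}
#' }
#' Separatrix points are the midpoints between adjacent seeds attracted to
#' different terminal groups.
#'
#' @param portrait a \code{pf_portrait} from
#'   \code{\link{integrate_streamlines}}.
#' @param x_sep minimum x separation of the two clusters for bistability;
#'   defaults to a quarter of the field's x extent (for the two-state
#'   pattern pass the bridge half-length).
#' @param f_cyc minimum cycling fraction for the limit-cycle label.
#' @param dominant_frac share of terminated streamlines a cluster needs to
#'   count as dominant.
#' @return the portrait with \code{label}, \code{groups} (per-seed terminal
#'   group, 0 = cycling, -1 = escaped), \code{terminals} (cluster centres),
#'   \code{separatrix} (matrix of boundary points) and \code{diagnostics}.
#' @export
classify_phase_portrait <- function(portrait, x_sep = NULL, f_cyc = 0.25,
                                    dominant_frac = 0.2) {
  field <- portrait$field
  # extent of the populated region (the full bin range can be much wider
  # when the data concentrate in the middle bins)
  pop <- which(rowSums(is.finite(field$F)) > 0)
  xr <- diff(range(field$x_centers[pop]))
  if (xr == 0) xr <- diff(range(field$x_centers))
  if (is.null(x_sep)) x_sep <- 0.25 * xr
  ns <- length(portrait$status)
  if (!ns) stop("empty portrait")

  cycling <- portrait$status == 3L &
    vapply(seq_len(ns), function(i)
      is_cycling_orbit(portrait$paths[[i]], field, portrait$r_c), TRUE)
  term <- portrait$status == 1L

  groups <- integer(ns)
  groups[portrait$status == 2L & !cycling] <- -1L
  terminals <- NULL
  if (any(term)) {
    pts <- cbind(portrait$x_end[term], portrait$v_end[term])
    # cluster in bin units so x and v are commensurate
    sc <- cbind(pts[, 1] / mean(diff(field$x_centers)),
                pts[, 2] / mean(diff(field$v_centers)))
    if (nrow(pts) == 1) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::dist(sc), method = "single")
      cl <- stats::cutree(hc, h = sqrt(2))
    }
    groups[term] <- cl
    terminals <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
      data.frame(group = g, x = mean(pts[cl == g, 1]), v = mean(pts[cl == g, 2]),
                 n = sum(cl == g))
    }))
  }

  n_term <- sum(term)
  cyc_frac <- mean(cycling)
  label <- "other"
  if (cyc_frac >= f_cyc) {
    label <- "limit_cycle"
  } else if (n_term > 0) {
    dom <- terminals[terminals$n >= dominant_frac * n_term, , drop = FALSE]
    v_small <- 3 * portrait$eps_v
    if (nrow(dom) == 2 && all(abs(dom$v) < v_small) &&
        abs(diff(dom$x)) > x_sep) {
      label <- "bistable"
    } else {
      spread <- diff(range(portrait$x_end[term]))
      if (all(abs(portrait$v_end[term]) < v_small) && spread > 0.3 * xr &&
          nrow(dom) != 2)
        label <- "stationary"
    }
  }

  sep <- separatrix_points(portrait$seeds, groups)
  portrait$label <- label
  portrait$groups <- groups
  portrait$cycling <- cycling
  portrait$terminals <- terminals
  portrait$separatrix <- sep
  portrait$diagnostics <- list(cycling_fraction = cyc_frac,
                               n_terminated = n_term,
                               n_escaped = sum(portrait$status == 2L & !cycling),
                               x_sep = x_sep, f_cyc = f_cyc)
  portrait
}

# midpoints between adjacent seeds whose streamlines end in different groups
separatrix_points <- function(seeds, groups) {
  if (nrow(seeds) < 2) return(matrix(numeric(0), 0, 2))
  xs <- sort(unique(seeds[, 1])); vs <- sort(unique(seeds[, 2]))
  key <- paste(match(seeds[, 1], xs), match(seeds[, 2], vs))
  g <- function(i, j) {
    k <- match(paste(i, j), key)
    if (is.na(k)) NA_integer_ else groups[k]
  }
  out <- NULL
  for (i in seq_along(xs)) {
    for (j in seq_along(vs)) {
      g0 <- g(i, j)
      if (is.na(g0)) next
      if (i < length(xs)) {
        g1 <- g(i + 1, j)
        if (!is.na(g1) && g1 != g0)
          out <- rbind(out, c((xs[i] + xs[i + 1]) / 2, vs[j]))
      }
      if (j < length(vs)) {
        g1 <- g(i, j + 1)
        if (!is.na(g1) && g1 != g0)
          out <- rbind(out, c(xs[i], (vs[j] + vs[j + 1]) / 2))
      }
    }
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

#' @export
print.pf_portrait <- function(x, ...) {
  cat(sprintf("pf_portrait: %d streamlines, label = %s\n",
              length(x$status), x$label))
  if (!is.null(x$diagnostics))
    cat(sprintf("  cycling %.0f%%, %d terminated, %d escaped\n",
                100 * x$diagnostics$cycling_fraction,
                x$diagnostics$n_terminated, x$diagnostics$n_escaped))
  invisible(x)
}

#' Bootstrap variability of the inferred dynamics
#'
#' Resamples whole trajectories with replacement, re-runs the
#' estimate -> integrate -> classify pipeline on each resample (with bin
#' edges fixed to the full-data estimate so portraits are comparable) and
#' summarises label frequencies and terminal-point scatter.
#'
#' @param set a \code{pf_trajectory_set} (>= 2 usable runs).
#' @param B number of bootstrap resamples; \code{B = 0} returns an empty
#'   summary alongside the base estimate.
#' @param base_seed RNG seed for the resampling.
#' @param dt_sample inference cadence (min).
#' @param min_count,n_x,n_v passed to \code{\link{estimate_drift_field}}.
#' @param ... passed to \code{\link{classify_phase_portrait}}.
#' @return list with \code{base} (full-data labelled portrait),
#'   \code{label_freq}, \code{terminals} (data frame over resamples),
#'   \code{separatrix} (list of matrices) and \code{labels}.
#' @export
bootstrap_inference <- function(set, B = 50, base_seed = 1, dt_sample = 10,
                                min_count = 20, n_x = 36, n_v = 30, ...) {
  samples <- finite_difference_kinematics(set, dt_sample)
  base_field <- estimate_drift_field(samples, n_x = n_x, n_v = n_v,
                                     min_count = min_count)
  base <- classify_phase_portrait(integrate_streamlines(base_field), ...)
  if (B == 0)
    return(list(base = base, label_freq = table(character(0)),
                labels = character(0), terminals = NULL, separatrix = list()))
  runs <- unique(samples$run)
  if (length(runs) < 2) stop("bootstrap needs at least 2 usable trajectories")
  set.seed(base_seed)
  labels <- character(B)
  terms <- vector("list", B)
  seps <- vector("list", B)
  for (b in seq_len(B)) {
    pick <- sample(runs, length(runs), replace = TRUE)
    res <- do.call(rbind, lapply(pick, function(r) samples[samples$run == r, ]))
    fld <- tryCatch(
      estimate_drift_field(res, x_edges = base_field$x_edges,
                           v_edges = base_field$v_edges, min_count = min_count),
      error = function(e) NULL)
    if (is.null(fld)) { labels[b] <- NA_character_; next }
    po <- tryCatch(classify_phase_portrait(integrate_streamlines(fld), ...),
                   error = function(e) NULL)
    if (is.null(po)) { labels[b] <- NA_character_; next }
    labels[b] <- po$label
    if (!is.null(po$terminals)) {
      tb <- po$terminals; tb$rep <- b
      terms[[b]] <- tb
    }
    seps[[b]] <- po$separatrix
  }
  list(base = base,
       label_freq = table(labels[!is.na(labels)]) / sum(!is.na(labels)),
       labels = labels,
       terminals = if (length(tt <- do.call(rbind, terms))) tt else NULL,
       separatrix = seps)
}
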