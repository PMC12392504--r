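fake_traj <- function(t, x) {
  tr <- data.frame(t_min = t, x_um = x, y_um = 0, area_um2 = NA, perim_um = NA)
  class(tr) <- c("pf_trajectory", "data.frame")
  tr
}

test_that("finite differences are exact on polynomial motion", {
  t <- seq(0, 200, by = 1)

  k <- finite_difference_kinematics(fake_traj(t, rep(7, length(t))), 10)
  expect_true(all(k$v == 0) && all(k$a == 0))

  k <- finite_difference_kinematics(fake_traj(t, 3 * t), 10)
  expect_equal(unique(k$v), 3)
  expect_true(all(k$a == 0))

  # second difference of a quadratic is exact
  g <- 0.04
  k <- finite_difference_kinematics(fake_traj(t, g * t^2 / 2), 10)
  expect_equal(k$a, rep(g, nrow(k)), tolerance = 1e-12)

  expect_error(finite_difference_kinematics(fake_traj(t, t), 2.5), "multiple")
  expect_error(finite_difference_kinematics(fake_traj(0:10, 0:10), 10), "at least 3")
})

test_that("binned conditional moments recover means, sds and masks", {
  sm <- data.frame(run = 1L,
                   x = c(rep(0.5, 40), rep(1.5, 5)),
                   v = rep(0.5, 45),
                   a = c(rep(c(1, -1), 20), rep(2, 5)))
  f <- estimate_drift_field(sm, x_edges = 0:2, v_edges = 0:1, min_count = 10)
  expect_equal(f$F[1, 1], 0)            # mean of interleaved +/-1
  expect_equal(f$sd[1, 1], sd(rep(c(1, -1), 20)))
  expect_true(is.na(f$F[2, 1]))         # 5 samples < min_count
  expect_equal(f$count[2, 1], 5)

  sm0 <- data.frame(run = 1, x = runif(100), v = runif(100), a = 0)
  f0 <- estimate_drift_field(sm0, x_edges = c(0, 1), v_edges = c(0, 1), min_count = 10)
  expect_equal(f0$F[1, 1], 0)

  expect_error(estimate_drift_field(sm[1:3, ], x_edges = 0:1, v_edges = 0:1,
                                    min_count = 50), "min_count")
})

test_that("OU fixtures recover the friction coefficient from F(0, v)", {
  spec <- sde_spec("ou", xi = 0.2, noise = 0.6)
  s <- simulate_sde(spec, 100, T = 48 * 60, dt = 10, seed = 3, x_init = 0)
  k <- finite_difference_kinematics(s, dt_sample = 10)
  f <- estimate_drift_field(k, min_count = 20)
  cut <- friction_cut(f, x_window = Inf)
  expect_equal(attr(cut, "slope"), -0.2, tolerance = 0.1)
})

test_that("streamlines terminate, escape or cycle as the analytic dynamics dictate", {
  xe <- seq(-4, 4, length.out = 41); ve <- seq(-4, 4, length.out = 41)

  # damped oscillator: globally attracting spiral to the origin (field on a
  # wide box so the spiral's transient swings stay in the populated region)
  xw <- seq(-10, 10, length.out = 81)
  damp <- drift_field_from_function(function(x, v) -x - 0.5 * v, xw, xw)
  sd_grid <- as.matrix(expand.grid(x = seq(-3, 3, by = 1.5), v = seq(-3, 3, by = 1.5)))
  po <- integrate_streamlines(damp, seeds = sd_grid, dt_s = 0.05,
                              eps_v = 0.05, eps_F = 0.05, max_steps = 2e4)
  expect_true(all(po$status == 1))
  expect_lt(max(abs(po$x_end)), 0.3)
  expect_lt(max(abs(po$v_end)), 0.3)

  # pure growth: leaves the domain, records no terminal point
  grow <- drift_field_from_function(function(x, v) v, xe, ve)
  po <- integrate_streamlines(grow, seeds = cbind(0, c(1, 2)), dt_s = 0.05)
  expect_true(all(po$status == 2))

  # van der Pol: bounded non-terminating orbits
  vdp <- drift_field_from_function(function(x, v) (1 - x^2) * v - x, xe, ve)
  po <- integrate_streamlines(vdp, dt_s = 0.02, max_steps = 2e4)
  expect_true(any(po$status == 3))
  cl <- classify_phase_portrait(po)
  expect_equal(cl$label, "limit_cycle")
})

test_that("the classifier separates the three canonical portraits", {
  xe <- seq(-4, 4, length.out = 41); ve <- seq(-4, 4, length.out = 41)

  dw <- drift_field_from_function(function(x, v) -4 * x * (x^2 - 4) - 2 * v,
                                  xe, ve)
  cl <- classify_phase_portrait(integrate_streamlines(dw, dt_s = 0.02,
                                                      max_steps = 2e4),
                                x_sep = 1)
  expect_equal(cl$label, "bistable")
  expect_equal(sort(cl$terminals$x[cl$terminals$n > 5]), c(-2, 2), tolerance = 0.1)
  expect_gt(nrow(cl$separatrix), 0)

  lin <- drift_field_from_function(function(x, v) -0.5 * v, xe, ve)
  cl <- classify_phase_portrait(integrate_streamlines(lin, dt_s = 0.05,
                                                      max_steps = 2e4))
  expect_equal(cl$label, "stationary")

  vdp <- drift_field_from_function(function(x, v) (1 - x^2) * v - x, xe, ve)
  cl <- classify_phase_portrait(integrate_streamlines(vdp, dt_s = 0.02,
                                                      max_steps = 2e4))
  expect_equal(cl$label, "limit_cycle")
})

test_that("streamline interpolation never reads masked bins", {
  xe <- seq(-4, 4, length.out = 21); ve <- seq(-4, 4, length.out = 21)
  f <- drift_field_from_function(function(x, v) v * 0 - 1, xe, ve)
  f$F[f$x_centers > 0, ] <- NA   # mask the right half
  po <- integrate_streamlines(f, seeds = cbind(-1, 1), dt_s = 0.05, max_steps = 1e4)
  # the streamline moves right and must stop at the mask edge, not read NA
  expect_equal(po$status, 2L)
  expect_true(all(is.finite(po$paths[[1]])))
  expect_lt(po$x_end[1], 0.5)
})

test_that("bootstrap of identical trajectories is degenerate; B = 0 is a no-op", {
  t <- seq(0, 2000, by = 10)
  set.seed(1)
  x <- cumsum(rnorm(length(t)))
  one <- fake_traj(t, x)
  set <- trajectory_set(list(one, one, one, one))
  bs <- bootstrap_inference(set, B = 8, base_seed = 2, dt_sample = 10,
                            min_count = 5, n_x = 8, n_v = 8)
  expect_true(all(bs$labels == bs$labels[1]))
  term <- bs$terminals
  if (!is.null(term)) {
    for (g in unique(term$group))
      expect_lt(max(abs(diff(term$x[term$group == g]))), 1e-9)
  }
  bs0 <- bootstrap_inference(set, B = 0, dt_sample = 10, min_count = 5,
                             n_x = 8, n_v = 8)
  expect_length(bs0$labels, 0)
  expect_s3_class(bs0$base, "pf_portrait")
})

test_that("bootstrap labels an OU ensemble stationary in nearly all resamples", {
  spec <- sde_spec("ou", xi = 0.2, noise = 0.6)
  s <- simulate_sde(spec, 60, T = 24 * 60, dt = 10, seed = 9, x_init = NULL)
  bs <- bootstrap_inference(s, B = 20, base_seed = 4, dt_sample = 10,
                            min_count = 10, n_x = 12, n_v = 12)
  freq <- bs$label_freq
  expect_gte(freq[["stationary"]], 0.9)
})
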