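test_that("friction cut reports the analytic small-velocity slope", {
  xe <- seq(-4, 4, length.out = 21); ve <- seq(-3, 3, length.out = 21)

  ou <- drift_field_from_function(function(x, v) -0.2 * v, xe, ve)
  cut <- friction_cut(ou)
  expect_equal(attr(cut, "slope"), -0.2, tolerance = 1e-9)

  # van der Pol at x ~ 0: F(0, v) ~ +mu v, i.e. negative friction
  vdp <- drift_field_from_function(function(x, v) (1 - x^2) * v - x, xe, ve)
  cut <- friction_cut(vdp, x_window = 0.3)
  expect_gt(attr(cut, "slope"), 0.5)

  expect_error(friction_cut(ou, x_window = -1), "no x-bins")
})

test_that("hysteretic dwell detection matches constructed crossing times", {
  thr <- 8.5; hyst <- 4; hi <- thr + hyst / 2  # entries at +/-10.5
  t <- 0:600
  x <- numeric(length(t))
  x[t >= 100] <- 12; x[t >= 250] <- -12; x[t >= 500] <- 12
  h <- hopping_times(fake_traj2(t, x), thr, hyst)
  expect_equal(h$entries$t_min, c(100, 250, 500))
  expect_equal(h$dwells, c(150, 250))
  expect_equal(h$n_hops, 2L)

  # noise below the hysteresis band changes nothing
  set.seed(8)
  h2 <- hopping_times(fake_traj2(t, x + runif(length(t), -1.8, 1.8)), thr, hyst)
  expect_equal(h2$dwells, h$dwells)

  # never leaving one basin: no hops
  h3 <- hopping_times(fake_traj2(t, rep(12, length(t))), thr, hyst)
  expect_equal(h3$n_hops, 0L)
  expect_length(h3$dwells, 0)

  # clean oscillation: dwells approximately the half period
  tt <- seq(0, 2000, by = 1)
  h4 <- hopping_times(fake_traj2(tt, 15 * sin(2 * pi * tt / 400)), thr, hyst)
  expect_equal(mean(h4$dwells), 200, tolerance = 0.05)
})

test_that("area-weighted occupancy reproduces hand arithmetic and its symmetries", {
  eq <- occupancy_fractions(list(T_left = 600, T_right = 600),
                            A_left = 1444, A_right = 1444)
  expect_equal(eq$P_left, 0.5)

  oc <- occupancy_fractions(list(T_left = 30 * 60, T_right = 10 * 60),
                            A_left = 1444, A_right = 722)
  expect_equal(oc$P_left, (30 / 1444) / ((30 / 1444) + (10 / 722)), tolerance = 1e-12)
  expect_equal(oc$P_left, 0.6, tolerance = 0.001)

  one <- occupancy_fractions(list(T_left = 100, T_right = 0),
                             A_left = 1000, A_right = 1000)
  expect_equal(one$P_left, 1)

  # label swap maps P_left -> 1 - P_left
  sw <- occupancy_fractions(list(T_left = 10 * 60, T_right = 30 * 60),
                            A_left = 722, A_right = 1444)
  expect_equal(sw$P_left, 1 - oc$P_left, tolerance = 1e-12)

  # time rescaling leaves the fraction unchanged
  sc <- occupancy_fractions(list(T_left = 3 * 60, T_right = 1 * 60),
                            A_left = 1444, A_right = 722)
  expect_equal(sc$P_left, oc$P_left, tolerance = 1e-12)

  expect_error(occupancy_fractions(list(T_left = 0, T_right = 0), 1, 1), "no time")
})

test_that("occupancy counts basin time from trajectories and excludes the bridge", {
  t <- 0:99
  x <- c(rep(-30, 40), rep(0, 20), rep(30, 40))  # 40 min left, 20 bridge, 40 right
  oc <- occupancy_fractions(fake_traj2(t, x), A_left = 1444, A_right = 1444,
                            x_split = 17.5)
  expect_equal(oc$T_left, oc$T_right)
  expect_equal(oc$T_left + oc$T_right, 80, tolerance = 2)
  expect_equal(oc$P_left, 0.5)
})
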