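test_that("analytic drifts match their definitions", {
  expect_equal(analytic_drift(sde_spec("ou", xi = 0.2))(3, 2), -0.4)
  expect_equal(analytic_drift(sde_spec("van_der_pol", mu = 1))(2, 1), 1 * (1 - 4) * 1 - 2)
  expect_equal(analytic_drift(sde_spec("double_well", x0 = 1, k = 1, xi = 0.5))(0.5, 1),
               -4 * 0.5 * (0.25 - 1) - 0.5)
  expect_error(sde_spec("brownian"))
})

test_that("noiseless OU integrates to the exponential-relaxation closed form", {
  spec <- sde_spec("ou", xi = 0.2, noise = 0)
  s <- simulate_sde(spec, n_traj = 1, T = 30, dt = 0.01, seed = 1,
                    x_init = 0, v_init = 2)
  x <- s$runs[[1]]$x_um
  t <- s$runs[[1]]$t_min
  # x(t) = v0 (1 - exp(-xi t)) / xi
  expect_equal(x[length(x)], 2 * (1 - exp(-0.2 * 30)) / 0.2, tolerance = 0.005)
  expect_equal(x[t == 10], 2 * (1 - exp(-2)) / 0.2, tolerance = 0.005)
})

test_that("OU stationary velocity variance matches sigma^2 / (2 xi)", {
  spec <- sde_spec("ou", xi = 0.2, noise = 0.6)
  s <- simulate_sde(spec, n_traj = 20, T = 2000, dt = 0.1, seed = 7,
                    x_init = 0, v_init = 0)
  v <- unlist(lapply(s$runs, function(tr) diff(tr$x_um) / 0.1))
  burn <- rep(seq_len(length(v) / 20) > 200, 20)  # drop transients per run
  expect_equal(stats::var(v[burn]), 0.6^2 / (2 * 0.2), tolerance = 0.1)
})

test_that("SDE fixtures are seeded and validate dt stability", {
  spec <- sde_spec("ou", xi = 0.2)
  a <- simulate_sde(spec, 3, T = 50, dt = 0.5, seed = 4)
  b <- simulate_sde(spec, 3, T = 50, dt = 0.5, seed = 4)
  expect_identical(a$runs[[2]]$x_um, b$runs[[2]]$x_um)
  c <- simulate_sde(spec, 3, T = 50, dt = 0.5, seed = 5)
  expect_false(identical(a$runs[[2]]$x_um, c$runs[[2]]$x_um))
  expect_error(simulate_sde(spec, 1, T = 10, dt = 11, seed = 1), "unstable")
})

test_that("drift recovery improves as the ensemble grows", {
  spec <- sde_spec("ou", xi = 0.2, noise = 0.6)
  F_true <- analytic_drift(spec)
  rms <- sapply(c(50, 200), function(n) {
    s <- simulate_sde(spec, n, T = 48 * 60, dt = 10, seed = 21, x_init = 0)
    k <- finite_difference_kinematics(s, dt_sample = 10)
    f <- estimate_drift_field(k, min_count = 20)
    ok <- is.finite(f$F)
    tru <- outer(f$x_centers, f$v_centers, F_true)
    sqrt(weighted.mean((f$F[ok] - tru[ok])^2, f$count[ok]))
  })
  expect_lt(rms[2], rms[1])
})

test_that("coarse observation of a finely-integrated OU path shows the known drift bias", {
  # velocities from positions sampled every Dt underestimate the friction:
  # the regression slope of a on v is (rho - 1)/Dt with
  # rho = (1 - e^-xi*Dt)^2 / (2*(xi*Dt - 1 + e^-xi*Dt)); the estimator
  # targets the coarse-grained transition drift, not the instantaneous one
  xi <- 0.2; Dt <- 10
  spec <- sde_spec("ou", xi = xi, noise = 0.6)
  s <- simulate_sde(spec, 100, T = 48 * 60, dt = 0.5, seed = 13,
                    sample_every = 20, x_init = 0)
  k <- finite_difference_kinematics(s, dt_sample = Dt)
  f <- estimate_drift_field(k, min_count = 20)
  slope <- attr(friction_cut(f, x_window = Inf), "slope")
  rho <- (1 - exp(-xi * Dt))^2 / (2 * (xi * Dt - 1 + exp(-xi * Dt)))
  expect_equal(slope, (rho - 1) / Dt, tolerance = 0.1)
  # i.e. nowhere near the instantaneous -xi
  expect_gt(slope, -0.1)
})
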