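test_that("polarity decays exponentially with all sources and inhibitions off", {
  p <- model_params()
  phi <- make_disk(10, p)
  P <- const_field(5, phi)
  chi <- const_field(0, phi)
  s <- 100  # below s0
  dt <- 0.01
  n <- 400  # 4 minutes = one decay time
  for (i in seq_len(n)) P <- step_polarity(P, phi, chi, s, dt, p)
  expect_equal(max(abs(P$values)), 5 * exp(-n * dt / p$tau), tolerance = 0.005)
})

test_that("knockouts disable exactly their term", {
  p <- model_params()
  phi <- make_disk(10, p)
  chi <- const_field(1, phi)     # fully off-pattern
  P <- const_field(1, phi)

  # s0 -> Inf: perimeter term contributes nothing even for huge s
  p_s0 <- model_params(s0 = Inf)
  a <- step_polarity(P, phi, const_field(0, phi), s = 1e6, dt = 0.01, p_s0)
  b <- step_polarity(P, phi, const_field(0, phi), s = 10, dt = 0.01, p_s0)
  expect_equal(a$values, b$values, tolerance = 1e-14)

  # tau_chi -> Inf: chi coupling contributes nothing
  p_chi <- model_params(tau_chi = Inf)
  a <- step_polarity(P, phi, chi, s = 10, dt = 0.01, p_chi)
  b <- step_polarity(P, phi, const_field(0, phi), s = 10, dt = 0.01, p_chi)
  expect_equal(a$values, b$values, tolerance = 1e-14)

  # with the coupling on, off-pattern polarity is driven down at rate chi*phi/tau_chi
  a <- step_polarity(P, phi, chi, s = 10, dt = 0.01, p)
  expect_lt(max(a$values - (P$values - 0.01 * (chi$values * phi$values / p$tau_chi_min +
                                               P$values / p$tau))), 1e-12)
})

test_that("activity patches have the closed-form Gaussian increment confined to the cell", {
  p <- model_params()
  phi <- make_disk(12, p)
  P0 <- const_field(0, phi)

  unchanged <- apply_activity_patch(P0, c(12, 0), beta = 0, sigma = p$sigma_patch, phi)
  expect_equal(unchanged$values, P0$values)

  ct <- extract_contour(phi)
  theta <- ct$points[which.min(abs(ct$points[, 2]) + (ct$points[, 1] < 0) * 100), ]
  P1 <- apply_activity_patch(P0, theta, beta = 1, sigma = p$sigma_patch, phi)
  # at the contour point itself phi = 1/2: increment = beta/2
  expect_equal(interp_field(P1, theta[1], theta[2]), 0.5, tolerance = 0.02)
  # one patch width inward (phi ~ 1): increment = beta * exp(-1/2)
  inner <- theta - p$sigma_patch * c(theta[1], theta[2]) / sqrt(sum(theta^2))
  expect_equal(interp_field(P1, inner[1], inner[2]), exp(-0.5), tolerance = 0.02)
  # far outside the cell the patch deposits (almost) nothing
  expect_lt(max(P1$values[phi$values < 1e-3]), 1e-3)
})

test_that("filopodial weights follow (1 - chi(probe)) * max(P, 0)", {
  p <- model_params()
  phi <- make_disk(12, p)
  ct <- extract_contour(phi)
  chi0 <- const_field(0, phi)

  # uniform positive polarity, fully adhesive: uniform weights
  w <- filopodial_weights(ct, const_field(2, phi), chi0, p$ell)
  expect_equal(w, rep(1 / nrow(ct$points), nrow(ct$points)), tolerance = 1e-9)

  # non-adhesive half plane x > 12: probes from the +x arc land off-pattern
  xs <- field_x(phi)
  chiv <- matrix(stats::plogis((outer(xs, rep(1, length(field_y(phi)))) - 12) / 0.5),
                 length(xs), length(field_y(phi)))
  chi_half <- scalar_field(chiv, phi$dx, phi$origin)
  w <- filopodial_weights(ct, const_field(2, phi), chi_half, p$ell)
  probe_x <- ct$points[, 1] + p$ell * ct$normals[, 1]
  expect_lt(max(w[probe_x > 16]), 1e-3)
  expect_gt(min(w[probe_x < 8]), 1e-3)

  # no_filopodia: weights proportional to max(P, 0) only
  Pv <- const_field(0, phi)
  Pv$values[, seq_len(ncol(Pv$values) / 2)] <- 3  # positive on the lower half
  w <- filopodial_weights(ct, Pv, chi_half, p$ell, no_filopodia = TRUE)
  pv <- pmax(interp_field(Pv, ct$points[, 1], ct$points[, 2]), 0)
  expect_equal(w, pv / sum(pv), tolerance = 1e-9)

  # fully depolarised cell: uniform fallback
  w <- filopodial_weights(ct, const_field(-1, phi), chi0, p$ell)
  expect_equal(w, rep(1 / nrow(ct$points), nrow(ct$points)))
})

test_that("the patch scheduler fires once per tau_f with Gaussian amplitudes", {
  expect_length(patch_times(60, 2.2 / 60), floor(60 / (2.2 / 60)))
  expect_length(patch_times(10, Inf), 0)

  # a short run fires exactly floor(T / tau_f) patches
  p <- model_params()
  tr <- suppressWarnings(run_simulation(p, pattern_spec("two_state"), duration = 5, seed = 11))
  expect_equal(nrow(attr(tr, "patches")), floor(5 / p$tau_f_min))

  # sigma_beta = 0: every amplitude equals mu_beta
  p0 <- model_params(sigma_beta = 0)
  tr <- suppressWarnings(run_simulation(p0, pattern_spec("two_state"), duration = 3, seed = 2))
  expect_true(all(attr(tr, "patches")[, "beta"] == p0$mu_beta))

  # seeded amplitude draws agree with the Gaussian law within 3 s.e.
  set.seed(42)
  betas <- rnorm(1e4, 7.5, 37.5)
  expect_lt(abs(mean(betas) - 7.5), 3 * 37.5 / sqrt(1e4))
})

test_that("identical seeds give bit-identical patch sequences and trajectories", {
  p <- model_params()
  pat <- pattern_spec("two_state")
  a <- suppressWarnings(run_simulation(p, pat, duration = 10, seed = 5))
  b <- suppressWarnings(run_simulation(p, pat, duration = 10, seed = 5))
  expect_identical(attr(a, "patches"), attr(b, "patches"))
  expect_identical(a$x_um, b$x_um)
  expect_identical(attr(a, "final")$P$values, attr(b, "final")$P$values)
  c <- suppressWarnings(run_simulation(p, pat, duration = 10, seed = 6))
  expect_false(identical(a$x_um, c$x_um))
})

test_that("static-shape polarity dynamics tends to a singly polarised state", {
  # polarity model alone, shape frozen, on the rectangle: the positive
  # feedback should select a single dominant front in most replicates
  p <- model_params()
  pat <- pattern_spec("rectangle")
  wins <- 0L
  n_rep <- 12
  for (s in seq_len(n_rep)) {
    st <- initialize_cell(pat, p, mode = "center")
    tr <- suppressWarnings(run_simulation(p, pat, duration = 45, seed = 100 + s,
                         state = st, freeze_shape = TRUE))
    ct <- extract_contour(attr(tr, "final")$phi)
    ps <- polarization_summary(attr(tr, "final")$P, ct)
    wins <- wins + ps$singly_polarized
  }
  expect_gt(wins, n_rep / 2)
})
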