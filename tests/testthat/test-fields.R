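test_that("interfacial functional derivative vanishes on uniform phases", {
  p <- model_params()
  for (val in c(0, 1)) {
    f <- scalar_field(matrix(val, 20, 20), 1)
    d <- fd_cahn_hilliard(f, p)
    expect_lt(max(abs(d$values)), 1e-12)
  }
})

test_that("relaxed 1D front matches the logistic first integral and improves under refinement", {
  p <- model_params()
  k <- sqrt(2 * p$c0) / p$lambda
  err <- sapply(c(1, 0.5), function(dx) {
    x <- seq(-20, 20, by = dx)
    prof <- 1 / (1 + exp(-k * x))
    f <- scalar_field(matrix(prof, length(x), 5), dx)
    d <- fd_cahn_hilliard(f, p)
    max(abs(d$values[, 3]))
  })
  # scale: the bulk term alone is O(gamma*c0/lambda) ~ 2.7, so these are
  # few-percent relative residuals that halve (at least) under refinement
  expect_lt(err[1], 0.1)
  expect_lt(err[2], err[1] / 2)
})

test_that("area functional derivative follows the closed form", {
  p <- model_params()
  # on-target area: build any phi and scale so integral(phi^2) = pi R0^2
  f <- make_disk(p$R0, p)
  f$values <- f$values * sqrt(pi * p$R0^2 / cell_area(f))
  expect_lt(max(abs(fd_area(f, p)$values)), 1e-8)

  zero <- scalar_field(matrix(0, 15, 15), 1)
  expect_equal(fd_area(zero, p)$values, zero$values)

  # sharp disk of radius R0/2: A = A0/4, so dF/dphi = -(4 kappa/A0)(3/4) phi
  sharp <- make_sharp_disk(p$R0 / 2, dx = 0.25)
  A0 <- pi * p$R0^2
  expect_equal(cell_area(sharp) / A0, 1 / 4, tolerance = 0.01)
  fac <- -(4 * p$kappa / A0) * (1 - cell_area(sharp) / A0)
  expect_equal(fd_area(sharp, p)$values, fac * sharp$values, tolerance = 1e-12)
})

test_that("cell area quadrature is exact on indicator blocks", {
  v <- matrix(0, 30, 30)
  v[5:14, 8:19] <- 1   # 10 x 12 block
  f <- scalar_field(v, 0.5)
  expect_equal(cell_area(f), 10 * 12 * 0.25)
  expect_equal(cell_area(scalar_field(matrix(0, 5, 5), 1)), 0)
})

test_that("center of mass is symmetric, translation-equivariant and matches brute force", {
  p <- model_params()
  d0 <- make_disk(10, p)
  expect_equal(center_of_mass(d0), c(0, 0), tolerance = 1e-8)
  d5 <- make_disk(10, p, center = c(5, 0), L = 30)
  expect_equal(center_of_mass(d5), c(5, 0), tolerance = 1e-6)

  # crescent: disk minus shifted disk, against direct weighted summation
  cres <- d0
  cres$values <- pmax(d0$values - make_disk(8, p, center = c(4, 1), L = 30)$values, 0)
  xs <- field_x(cres); ys <- field_y(cres)
  w <- cres$values
  brute <- c(sum(outer(xs, rep(1, length(ys))) * w), sum(outer(rep(1, length(xs)), ys) * w)) / sum(w)
  expect_equal(center_of_mass(cres), brute, tolerance = 1e-12)

  expect_error(center_of_mass(scalar_field(matrix(0, 5, 5), 1)), "empty")
})

test_that("motility force is zero off-pattern and has the closed-form midpoint magnitude", {
  p <- model_params()
  phi <- make_disk(p$R0, p)
  P0 <- const_field(3, phi)
  chi0 <- const_field(0, phi)
  chi1 <- const_field(1, phi)

  # chi = 1 everywhere: velocity identical to the P = 0 case
  vP <- velocity_field(phi, P0, chi1, p)
  v0 <- velocity_field(phi, const_field(0, phi), chi1, p)
  expect_equal(vP$vx$values, v0$vx$values, tolerance = 1e-12)
  expect_equal(vP$vy$values, v0$vy$values, tolerance = 1e-12)

  # motility contribution = alpha * P * phi^2(1-phi)^2 / eta at the interface,
  # outward along the normal; at phi = 1/2 the magnitude is alpha * P / (16 eta)
  von <- velocity_field(phi, P0, chi0, p)
  dvx <- scalar_field(von$vx$values - v0$vx$values, phi$dx, phi$origin)
  dvy <- scalar_field(von$vy$values - v0$vy$values, phi$dx, phi$origin)
  # sample at the grid node closest to phi = 1/2 on the +x axis
  iy <- which.min(abs(field_y(phi)))
  ix <- which.min(abs(phi$values[, iy] - 0.5) + 10 * (field_x(phi) < 0))
  mag <- sqrt(dvx$values[ix, iy]^2 + dvy$values[ix, iy]^2)
  ph <- phi$values[ix, iy]
  expect_equal(mag, p$alpha * 3 * ph^2 * (1 - ph)^2 / p$eta, tolerance = 1e-6)
  # direction: outward (+x here)
  expect_gt(dvx$values[ix, iy], 0)

  # no force anywhere when the shape is at its energy minimum and P = 0:
  # velocities are bounded by the residual discretisation error
  expect_lt(max(abs(v0$vx$values)), 0.5)
})

test_that("explicit step preserves an equilibrium disk and respects the stability bound", {
  p <- model_params()
  st <- initialize_cell(pattern_spec("free2d"), p, seed = 1)
  chi <- const_field(0, st$phi)
  # relax first so the analytic profile settles onto the discrete equilibrium
  for (i in 1:2000) st <- step_phase_field(st, chi, p$dt, p)
  ref <- st$phi$values
  for (i in 1:200) st <- step_phase_field(st, chi, p$dt, p)
  expect_lt(max(abs(st$phi$values - ref)), 2e-3)
  expect_error(step_phase_field(st, chi, 10 * stability_dt(p), p), "stability")
})

test_that("relaxation is a gradient flow: free energy non-increasing, area toward target", {
  p <- model_params()
  st0 <- initialize_cell(pattern_spec("free2d"), p, seed = 1)
  st0$phi <- make_disk(12, p, L = 3 * p$R0)   # sub-target disk on the same grid size
  st0$P <- const_field(0, st0$phi)
  chi <- const_field(0, st0$phi)
  st <- st0
  E <- free_energy(st$phi, p)
  A <- cell_area(st$phi)
  A0 <- pi * p$R0^2
  for (rep in 1:20) {
    for (i in 1:50) st <- step_phase_field(st, chi, p$dt, p)
    E2 <- free_energy(st$phi, p)
    A2 <- cell_area(st$phi)
    expect_lte(E2, E + 2e-3)   # explicit-Euler tolerance near equilibrium
    expect_gte(A2, A - 1e-6)   # grows monotonically toward pi R0^2
    E <- E2; A <- A2
  }
  expect_gt(A, 0.8 * A0)
})

test_that("shifting phi, P and chi together shifts the dynamics identically", {
  p <- model_params()
  n <- 64
  org <- c(-32, -32)
  xs <- org[1] + 0:(n - 1)
  k <- sqrt(2 * p$c0) / p$lambda
  mk <- function(cx) {
    r <- sqrt(outer((xs - cx)^2, xs^2, "+"))
    scalar_field(1 / (1 + exp(k * (r - 10))), 1, org)
  }
  phiA <- mk(-5); phiB <- mk(0)   # shifted by 5 grid cells
  P <- const_field(2, phiA); chi <- const_field(0, phiA)
  outA <- cpp_step(phiA$values, P$values, chi$values, 1, p$dt, p, FALSE)
  outB <- cpp_step(phiB$values, P$values, chi$values, 1, p$dt, p, FALSE)
  # interior columns of A equal B shifted by 5 (avoid the domain boundary)
  expect_equal(outA$phi[11:50, ], outB$phi[16:55, ], tolerance = 1e-12)
})
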