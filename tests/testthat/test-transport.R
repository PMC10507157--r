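gauss_profile <- function(x, mu, sigma2) {
  exp(-(x - mu)^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)
}

test_that("uniform closed-domain profile is a fixed point", {
  cfg <- diffusion_config(da = 1e-3, length = 1, n_grid = 51, t_end = 2,
                          initial_profile = rep(2, 51), boundary = "closed")
  prof <- solve_fick_1d(cfg)
  expect_lt(max(abs(prof$concentration - 2)), 1e-12)
})

test_that("closed boundaries conserve mass to 1e-8", {
  x <- seq(0, 1, length.out = 201)
  init <- gauss_profile(x, 0.5, 0.05^2)
  cfg <- diffusion_config(da = 1e-3, length = 1, n_grid = 201, t_end = 10,
                          initial_profile = init, boundary = "closed",
                          save_times = c(0, 1, 2, 5, 10))
  prof <- solve_fick_1d(cfg)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  m0 <- trapz(x, init)
  for (t in unique(prof$time)) {
    snap <- prof[prof$time == t, ]
    expect_lt(abs(trapz(snap$x, snap$concentration) - m0) / m0, 1e-8)
  }
})

test_that("Gaussian pulse matches the heat-kernel closed form", {
  n <- 401
  x <- seq(0, 1, length.out = n)
  s0 <- 0.05^2
  da <- 1e-3
  t_end <- 5
  cfg <- diffusion_config(da = da, length = 1, n_grid = n, t_end = t_end,
                          initial_profile = gauss_profile(x, 0.5, s0),
                          boundary = "closed", save_times = t_end)
  prof <- solve_fick_1d(cfg)
  snap <- prof[abs(prof$time - t_end) < cfg$dt, ]
  analytic <- gauss_profile(x, 0.5, s0 + 2 * da * t_end)
  rel_l2 <- sqrt(sum((snap$concentration - analytic)^2) / sum(analytic^2))
  expect_lt(rel_l2, 1e-3)
})

test_that("spatial scheme is second order (error drops ~4x when halving dx)", {
  err_at <- function(n, dt) {
    x <- seq(0, 1, length.out = n)
    s0 <- 0.05^2
    cfg <- diffusion_config(da = 1e-3, length = 1, n_grid = n, t_end = 5,
                            dt = dt,
                            initial_profile = gauss_profile(x, 0.5, s0),
                            boundary = "closed", save_times = 5)
    prof <- solve_fick_1d(cfg)
    snap <- prof[abs(prof$time - 5) < 1e-2, ]
    analytic <- gauss_profile(x, 0.5, s0 + 2 * 1e-3 * 5)
    sqrt(sum((snap$concentration - analytic)^2) / sum(analytic^2))
  }
  # dt rescaled by 4 with dx halved, as for a second-order-in-space,
  # first-order-in-time explicit scheme
  ratio <- err_at(101, 1e-3) / err_at(201, 2.5e-4)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.5)
})

test_that("unstable time steps are rejected with the admissible bound", {
  expect_error(diffusion_config(da = 1e-3, length = 1, n_grid = 101,
                                dt = 1, t_end = 10),
               "maximum admissible dt")
  expect_error(diffusion_config(da = 0, length = 1), "> 0")
  expect_error(diffusion_config(da = 1, n_grid = 2), ">= 3")
})

test_that("retained fraction: limits, quadrature oracle, snapshot lookup", {
  x <- seq(0, 1, length.out = 201)
  init <- gauss_profile(x, 0.5, 0.03^2)
  cfg <- diffusion_config(da = 1e-4, length = 1, n_grid = 201, t_end = 5,
                          initial_profile = init, boundary = "closed",
                          save_times = c(0, 5))
  prof <- solve_fick_1d(cfg)

  expect_equal(retained_fraction(prof, c(0, 1), 5), 1, tolerance = 1e-9)
  expect_equal(retained_fraction(prof, c(0.9, 0.901), 5), 0)

  # independent trapezoidal integration of the same snapshot
  snap <- prof[prof$time == max(prof$time), ]
  keep <- snap$x >= 0.25 & snap$x <= 0.75
  xr <- snap$x[keep]; vr <- snap$concentration[keep]
  oracle <- sum(diff(xr) * (head(vr, -1) + tail(vr, -1)) / 2) /
    attr(prof, "injected_mass")
  expect_equal(retained_fraction(prof, c(0.25, 0.75), 5), oracle,
               tolerance = 1e-10)

  expect_error(retained_fraction(prof, c(0, 1), 3.123), "snapshots")
})

test_that("slower diffusivity retains more analyte at 120 s", {
  run_with <- function(da) {
    cfg <- diffusion_config(da = da, length = 0.01, n_grid = 101,
                            t_end = 120, boundary = "inlet",
                            inlet_concentration = 1, inlet_duration = 60,
                            save_times = 120)
    solve_fick_1d(cfg)
  }
  slow <- run_with(1e-8)   # MOF-confined transport
  fast <- run_with(1e-6)   # open-pore transport
  region <- c(0, 0.002)    # capture layer near the inlet
  f_slow <- retained_fraction(slow, region, 120)
  f_fast <- retained_fraction(fast, region, 120)
  expect_gt(f_slow, f_fast)
  expect_true(f_slow >= 0 && f_slow <= 1)
  expect_true(f_fast >= 0 && f_fast <= 1)
})

test_that("penetration depth: algebraic identity, plug-in value, monotonicity", {
  # radicand engineered to 1: Z equals lambda / (2 pi)
  expect_equal(penetration_depth(2 * pi, 2, -2), 1, tolerance = 1e-12)

  # independent plug-in arithmetic at 633 nm
  expect_equal(penetration_depth(633, 1.34, -18),
               633 / (2 * pi) * sqrt((1.34 + 18) / 324), tolerance = 1e-12)

  # the MOF coating extends the field relative to air for any plasmonic
  # silver permittivity
  for (eps_ag in c(-2.5, -5, -10, -18, -30)) {
    expect_gt(penetration_depth(633, 1.34, eps_ag),
              penetration_depth(633, 1.0003, eps_ag))
  }

  # strictly increasing in the medium permittivity
  zs <- vapply(seq(1, 3, by = 0.25),
               function(e) penetration_depth(633, e, -18), numeric(1))
  expect_true(all(diff(zs) > 0))

  expect_error(penetration_depth(633, 1.34, 5), "negative")
  expect_error(penetration_depth(-1, 1.34, -18), "> 0")
  expect_error(penetration_depth(633, -1, -18), "> 0")
})
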