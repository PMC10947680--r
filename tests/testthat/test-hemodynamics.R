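test_that("vorticity is exact on linear fields and second-order on Taylor-Green", {
  s <- fix_solid(n = 48, omega = 7, radius = 0.015)
  om <- vorticity(s, 1)
  expect_equal(unname(range(om$values[om$valid & s$mask[, , 1]])), c(14, 14))

  # uniform shear v = (gamma * y, 0): omega = -gamma exactly
  g <- grid_spec(32, 32, 1e-3, 1e-3)
  xy <- grid_xy(g)
  vel <- array(0, c(32, 32, 2, 1))
  vel[, , 1, 1] <- 3 * xy$y
  sh <- planar_velocity_series(g, 0, vel, array(TRUE, c(32, 32, 1)))
  omsh <- vorticity(sh, 1)
  expect_equal(unname(range(omsh$values[omsh$valid])), c(-3, -3),
               tolerance = 1e-12)

  # Taylor-Green: pointwise error O(dx^2), ratio ~4 under dx halving
  err_at <- function(n) {
    g <- grid_spec(n, n, 0.1 / n, 0.1 / n)
    tg <- gen_taylor_green(g, nu = 4e-6, times = c(0, 0.1, 0.2), U0 = 0.5)
    om <- vorticity(tg$series, 1)
    an <- tg_analytic(g, 0.5, 4e-6, 0)
    sqrt(mean((om$values[om$valid] - an$omega[om$valid])^2))
  }
  e1 <- err_at(48); e2 <- err_at(96)
  expect_gt(e1 / e2, 3.5); expect_lt(e1 / e2, 4.5)
})

test_that("vortex strength adds magnitudes and recovers Lamb-Oseen circulation", {
  # omega = 2 over a disc: VS = 2 * (discrete area)
  s <- fix_solid(n = 48, omega = 1, radius = 0.015)
  om <- vorticity(s, 1)
  area <- sum(om$valid & s$mask[, , 1]) * grid_dS(s$grid)
  expect_equal(vortex_strength(om, s$mask[, , 1]), 2 * area, tolerance = 1e-12)

  # counter-rotating patches do not cancel
  g <- grid_spec(96, 64, 6e-4, 6e-4)
  pair <- gen_lamb_oseen_pair(g, gamma = 0.02, core_radius = 0.004,
                              separation = 0.03)
  vs_pair <- vortex_strength(vorticity(pair, 1))
  expect_equal(vs_pair, 2 * 0.02, tolerance = 0.02)

  # single vortex on a domain >= 8 core radii: VS -> |Gamma|, vs the
  # radial-quadrature oracle of the Oseen profile
  rc <- 0.006; gam <- 0.03
  gd <- grid_spec(128, 128, 10 * rc / 128, 10 * rc / 128)
  lone <- gen_lamb_oseen_pair(gd, gamma = gam, core_radius = rc,
                              separation = 0, gamma_b = 0)
  vs <- vortex_strength(vorticity(lone, 1))
  oracle <- stats::integrate(function(r) 2 * pi * r * gam / (pi * rc^2) *
                               exp(-r^2 / rc^2), 0, 5 * rc)$value
  expect_equal(vs, oracle, tolerance = 0.02)
  expect_equal(vs, gam, tolerance = 0.02)

  # empty mask warns and returns 0
  expect_warning(v0 <- vortex_strength(vorticity(s, 1),
                                       matrix(FALSE, 48, 48)), "empty mask")
  expect_equal(v0, 0)
})

test_that("viscous energy loss: zero for rigid rotation, mu*gamma^2*A for shear, analytic on Taylor-Green", {
  props <- fluid_properties()
  s <- fix_solid(n = 64, omega = 10, radius = 0.02)
  ket <- kinetic_energy(s, 1, props)
  expect_lt(abs(viscous_energy_loss(s, 1, props)), 1e-10 * ket)

  # uniform shear: integrand is exactly mu * gamma^2
  g <- grid_spec(32, 32, 1e-3, 1e-3)
  xy <- grid_xy(g)
  vel <- array(0, c(32, 32, 2, 1))
  gam <- 4
  vel[, , 1, 1] <- gam * xy$y
  sh <- planar_velocity_series(g, 0, vel, array(TRUE, c(32, 32, 1)))
  area <- 32 * 32 * grid_dS(g)
  expect_equal(viscous_energy_loss(sh, 1, props), props$mu * gam^2 * area,
               tolerance = 1e-12)

  # Taylor-Green vs the analytic dissipation integral mu U^2 k^2 L^2 e^2
  gtg <- grid_spec(96, 96, 0.1 / 96, 0.1 / 96)
  tg <- gen_taylor_green(gtg, nu = props$mu / props$rho,
                         times = c(0, 0.1, 0.2), U0 = 0.5)
  k <- 2 * pi / 0.1
  vel_an <- props$mu * 0.5^2 * k^2 * 0.1^2 * exp(-4 * (props$mu / props$rho) * k^2 * 0.1)
  expect_equal(viscous_energy_loss(tg$series, 2, props), vel_an,
               tolerance = 0.01)

  # a non-solenoidal field triggers the divergence warning
  bad <- array(0, c(32, 32, 2, 1))
  bad[, , 1, 1] <- 5 * xy$x
  bs <- planar_velocity_series(g, 0, bad, array(TRUE, c(32, 32, 1)))
  expect_warning(viscous_energy_loss(bs, 1, props), "divergence")
})

test_that("kinetic energy matches closed forms", {
  props <- fluid_properties()
  # uniform |v| = U over the mask: KET = 1/2 rho U^2 A (mask-discretized)
  g <- grid_spec(64, 64, 1e-3, 1e-3)
  xy <- grid_xy(g)
  R <- 0.025
  disc <- (xy$x - 0.0315)^2 + (xy$y - 0.0315)^2 <= R^2
  u <- gen_uniform(g, c(0.6, 0.8), mask = disc, n_frames = 1L)
  expect_equal(kinetic_energy(u, 1, props),
               0.5 * props$rho * 1^2 * sum(disc) * grid_dS(g),
               tolerance = 1e-12)
  # solid rotation over a disc: exact polar integral 1/4 pi rho Omega^2 R^4
  s <- fix_solid(n = 128, omega = 10, radius = 0.04, dx = 1e-3)
  expect_equal(kinetic_energy(s, 1, props), 0.25 * pi * props$rho * 100 * 0.04^4,
               tolerance = 0.005)
  expect_equal(kinetic_energy(fix_solid(n = 32, omega = 0, radius = 0.01), 1),
               0)
})

test_that("inflow velocity follows the 97.5% quantile rule over the valve band", {
  g <- grid_spec(32, 32, 1e-3, 1e-3)
  lm <- landmarks(valve_a = c(0.005, 0.005), valve_b = c(0.025, 0.005),
                  apex = c(0.015, 0.028), inflow_depth = 0.005)
  # uniform speed in the band -> that speed
  u <- gen_uniform(g, c(0, 0.5), n_frames = 1L)
  u$landmarks <- lm
  expect_equal(inflow_velocity(u, 1, lm), 0.5)
  # zero field -> 0
  z <- gen_uniform(g, c(0, 0), n_frames = 1L)
  expect_equal(inflow_velocity(z, 1, lm), 0)

  # order-statistic oracle: 39 nodes at 1 m/s, one at 10 m/s in a 40-node
  # band -> type-7 quantile 1 + 0.025 * 9 = 1.225
  band <- icflow:::inflow_band(g, matrix(TRUE, 32, 32), lm)
  idx <- which(band)
  u2 <- gen_uniform(g, c(0, 0), n_frames = 1L)
  u2$velocity[, , 1, 1][idx[1:40]] <- 1
  u2$velocity[, , 1, 1][idx[1]] <- 10
  m <- matrix(FALSE, 32, 32); m[idx[1:40]] <- TRUE
  u2$mask <- array(m, c(32, 32, 1))
  expect_equal(inflow_velocity(u2, 1, lm), 1.225)
  expect_equal(unname(quantile(c(rep(1, 39), 10), 0.975, type = 7)), 1.225)

  # band entirely outside the mask -> NA with a message
  off <- gen_uniform(g, c(1, 0),
                     mask = {mm <- matrix(FALSE, 32, 32); mm[30:32, ] <- TRUE; mm},
                     n_frames = 1L)
  expect_message(res <- inflow_velocity(off, 1, lm), "empty inflow band")
  expect_true(is.na(res))
})

test_that("NSE pressure gradient is exact for rigid rotation and analytic on Taylor-Green", {
  props <- fluid_properties()
  # steady rotation: grad p = rho Omega^2 (x - xc, y - yc), exact
  s <- fix_solid(n = 48, omega = 10, radius = 0.015)
  gr <- pressure_gradient_nse(s, 2, props)
  g <- s$grid; xy <- grid_xy(g)
  xc <- mean(range(grid_x(g))); yc <- mean(range(grid_y(g)))
  ex <- props$rho * 100 * (xy$x - xc)
  ey <- props$rho * 100 * (xy$y - yc)
  expect_lt(max(abs(gr$gx[gr$valid] - ex[gr$valid])), 1e-8)
  expect_lt(max(abs(gr$gy[gr$valid] - ey[gr$valid])), 1e-8)

  # zero field -> zero gradient
  z <- gen_uniform(grid_spec(16, 16, 1e-3, 1e-3), c(0, 0), n_frames = 4L)
  gz <- pressure_gradient_nse(z, 2, props)
  expect_equal(max(abs(gz$gx[gz$valid])), 0)

  # Taylor-Green: all three terms active, matches the analytic gradient
  gtg <- grid_spec(96, 96, 0.1 / 96, 0.1 / 96)
  nu <- props$mu / props$rho
  tg <- gen_taylor_green(gtg, nu = nu, times = seq(0, 0.5, length.out = 12),
                         U0 = 0.5, rho = props$rho)
  gr2 <- pressure_gradient_nse(tg$series, 6, props)
  an <- tg_analytic(gtg, 0.5, nu, tg$series$times[6])
  rel <- sqrt(mean((gr2$gx[gr2$valid] - an$px[gr2$valid])^2)) /
    sqrt(mean(an$px[gr2$valid]^2))
  expect_lt(rel, 0.01)

  # too few frames for the time derivative
  s1 <- fix_solid(n = 32, omega = 1, radius = 0.01, n_frames = 2L)
  expect_error(pressure_gradient_nse(s1, 1), "temporal derivative")
})

test_that("WLS pressure integration: constant gradients, gauge, weighting rationale", {
  g <- grid_spec(32, 24, 1e-3, 1e-3)
  mask <- matrix(TRUE, 24, 32)
  xy <- grid_xy(g)
  # gradient (a, 0) over a rectangle -> p = a x minus mean, exact
  a <- 250
  grad <- list(gx = matrix(a, 24, 32), gy = matrix(0, 24, 32), valid = mask)
  pw <- integrate_pressure_wls(grad, g, mask)
  truth <- a * xy$x; truth <- truth - mean(truth)
  expect_lt(max(abs(pw$pressure$values - truth)), 1e-9)
  expect_equal(mean(pw$pressure$values[pw$pressure$valid]), 0,
               tolerance = 1e-12)
  # zero gradient -> zero pressure
  g0 <- list(gx = matrix(0, 24, 32), gy = matrix(0, 24, 32), valid = mask)
  expect_lt(max(abs(integrate_pressure_wls(g0, g, mask)$pressure$values)),
            1e-12)

  # identity weighting on an exact (curl-free) gradient reproduces the
  # potential to round-off
  gq <- list(gx = 2 * xy$x * 1e4, gy = matrix(0, 24, 32) + 3e2, valid = mask)
  pq <- integrate_pressure_wls(gq, g, mask, weighting = "identity")
  tq <- 1e4 * xy$x^2 + 3e2 * xy$y; tq <- tq - mean(tq)
  expect_lt(max(abs(pq$pressure$values - tq)), 1e-8)

  # localized gradient corruption: curl weighting beats identity weighting
  set.seed(5)
  gc_ <- gq
  bad <- cbind(sample(3:22, 25, TRUE), sample(3:30, 25, TRUE))
  gc_$gx[bad] <- gc_$gx[bad] + 5e4
  gc_$gy[bad] <- gc_$gy[bad] - 5e4
  pw_w <- integrate_pressure_wls(gc_, g, mask, weighting = "curl")
  pw_i <- integrate_pressure_wls(gc_, g, mask, weighting = "identity")
  rmse <- function(p) pressure_rmse(p$pressure, tq)
  expect_lt(rmse(pw_w), rmse(pw_i))
})

test_that("solid-rotation pressure is recovered against the closed form", {
  s <- fix_solid(n = 96, omega = 10, radius = 0.03)
  grad <- pressure_gradient_nse(s, 2)
  pw <- integrate_pressure_wls(grad, s$grid, s$mask[, , 1])
  truth <- solid_pressure_truth(s$grid, 10, pw$pressure$valid)
  pp <- diff(range(truth[pw$pressure$valid]))
  expect_lt(pressure_rmse(pw$pressure, truth) / pp, 1e-6)
})

test_that("IVPD reads linear fields exactly and is gauge-free", {
  g <- grid_spec(40, 40, 1e-3, 1e-3)
  xy <- grid_xy(g)
  a <- 2000  # Pa/m
  p <- scalar_field_frame(g, a * xy$x, matrix(TRUE, 40, 40), 0, "pressure")
  lm <- landmarks(valve_a = c(0.005, 0.01), valve_b = c(0.005, 0.02),
                  apex = c(0.035, 0.015))
  # valve midpoint at x = 0.005, apex at x = 0.035: dP = -a * 0.03 Pa
  expect_equal(ivpd(p, lm), -a * 0.03 / 133.322, tolerance = 1e-12)
  # uniform pressure -> 0
  pu <- scalar_field_frame(g, matrix(7, 40, 40), matrix(TRUE, 40, 40), 0,
                           "pressure")
  expect_equal(ivpd(pu, lm), 0)
  # gauge shift leaves the difference unchanged
  p2 <- scalar_field_frame(g, a * xy$x + 12345, matrix(TRUE, 40, 40), 0,
                           "pressure")
  expect_equal(ivpd(p2, lm), ivpd(p, lm), tolerance = 1e-10)
  # landmark outside the valid region is rejected by name
  pv <- scalar_field_frame(g, a * xy$x,
                           {m <- matrix(TRUE, 40, 40); m[, 30:40] <- FALSE; m},
                           0, "pressure")
  expect_error(ivpd(pv, lm), "apex")
})

test_that("timeseries chain: steady flow is constant, zero flow is zero, peaks align", {
  props <- fluid_properties()
  # steady solid rotation: every parameter constant over phase
  s <- fix_solid(n = 48, omega = 8, radius = 0.015, n_frames = 6L)
  s$landmarks <- landmarks(valve_a = c(0.017, 0.012), valve_b = c(0.025, 0.012),
                           apex = c(0.024, 0.033), inflow_depth = 0.004)
  ts <- compute_timeseries(s, props = props)
  for (col in c("inflow_v_mps", "ivpd_mmhg", "vs_indexed_per_s",
                "ket_indexed_J_per_m3", "vel_indexed_W_per_m3")) {
    expect_lt(diff(range(ts[[col]])), 1e-9 + 1e-9 * max(abs(ts[[col]])))
  }
  # zero flow: all parameters zero
  z <- gen_uniform(grid_spec(16, 16, 1e-3, 1e-3), c(0, 0), n_frames = 4L)
  z$landmarks <- landmarks(c(0.004, 0.004), c(0.012, 0.004), c(0.008, 0.012),
                           inflow_depth = 0.003)
  tz <- compute_timeseries(z)
  expect_equal(max(abs(tz$inflow_v_mps)), 0)
  expect_equal(max(abs(tz$ivpd_mmhg)), 0)
  expect_equal(max(abs(tz$vs_indexed_per_s)), 0)

  # rv_filling: VS, KET, VEL peak at the frame of peak circulation
  g <- grid_spec(48, 40, 0.003, 0.003)
  spec <- synthetic_spec(seed = 2, frames_per_cycle = 20)
  gen <- gen_rv_filling(g, spec)
  tr <- compute_timeseries(gen$series, gen$landmarks, props)
  gam <- icflow:::rv_gamma_waveform(gen$series$times, spec$period, 1)
  pk <- which.max(gam)
  expect_equal(which.max(tr$vs_indexed_per_s), pk)
  expect_equal(which.max(tr$ket_indexed_J_per_m3), pk)
  expect_equal(which.max(tr$vel_indexed_W_per_m3), pk)
})

test_that("parameters scale correctly under velocity scaling", {
  props <- fluid_properties()
  g <- grid_spec(48, 40, 0.003, 0.003)
  spec <- synthetic_spec(seed = 3, frames_per_cycle = 16)
  gen <- gen_rv_filling(g, spec)
  s <- gen$series
  i <- which.max(vapply(seq_along(s$times), function(k) kinetic_energy(s, k),
                        numeric(1)))
  lam <- 2.5
  s2 <- s; s2$velocity <- lam * s$velocity
  expect_equal(vortex_strength(vorticity(s2, i)),
               lam * vortex_strength(vorticity(s, i)), tolerance = 1e-12)
  expect_equal(kinetic_energy(s2, i, props), lam^2 * kinetic_energy(s, i, props),
               tolerance = 1e-12)
  expect_equal(viscous_energy_loss(s2, i, props),
               lam^2 * viscous_energy_loss(s, i, props), tolerance = 1e-12)
  expect_equal(inflow_velocity(s2, i, gen$landmarks),
               lam * inflow_velocity(s, i, gen$landmarks), tolerance = 1e-12)
  # VEL >= 0, KET >= 0, VS >= 0 across all frames
  for (k in seq_along(s$times)) {
    expect_gte(suppressWarnings(viscous_energy_loss(s, k, props)), 0)
    expect_gte(kinetic_energy(s, k, props), 0)
    expect_gte(vortex_strength(vorticity(s, k)), 0)
  }
})

test_that("derivative operators converge at second order on Taylor-Green", {
  props <- fluid_properties()
  errs <- lapply(c(48, 96), function(n) {
    g <- grid_spec(n, n, 0.1 / n, 0.1 / n)
    nu <- props$mu / props$rho
    tg <- gen_taylor_green(g, nu = nu, times = seq(0, 0.4, length.out = 8),
                           U0 = 0.5)
    an <- tg_analytic(g, 0.5, nu, tg$series$times[4])
    gr <- pressure_gradient_nse(tg$series, 4, props)
    om <- vorticity(tg$series, 4)
    dd <- icflow:::dissipation_density(tg$series$velocity[, , , 4],
                                       tg$series$mask[, , 4], g, props$mu)
    phi_an <- an$phi(props$mu)
    c(grad = sqrt(mean((gr$gx[gr$valid] - an$px[gr$valid])^2)),
      om = sqrt(mean((om$values[om$valid] - an$omega[om$valid])^2)),
      phi = sqrt(mean((dd$values[dd$valid] - phi_an[dd$valid])^2)))
  })
  ratio <- errs[[1]] / errs[[2]]
  expect_true(all(ratio > 3.5 & ratio < 4.5))
})
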