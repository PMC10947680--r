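test_that("UOD flags nothing on uniform fields and exactly one planted spike", {
  g <- grid_spec(16, 16, 1e-3, 1e-3)
  u <- gen_uniform(g, c(1, 0), n_frames = 1L)
  expect_equal(sum(detect_outliers_uod(u, 3, 2, 0.1)), 0)

  u$velocity[9, 7, 1, 1] <- 10
  sp <- detect_outliers_uod(u, 3, 2, 0.1)
  expect_equal(sum(sp), 1)
  expect_true(sp[9, 7, 1])

  # translation invariance of the residual: adding a constant changes nothing
  u2 <- u
  u2$velocity[, , 1, 1] <- u2$velocity[, , 1, 1] + 5
  u2$velocity[, , 2, 1] <- u2$velocity[, , 2, 1] - 3
  expect_identical(detect_outliers_uod(u2, 3, 2, 0.1), sp)

  # empty mask: nothing flagged, no error
  u3 <- gen_uniform(g, c(1, 0),
                    mask = matrix(FALSE, 16, 16), n_frames = 1L)
  expect_equal(sum(detect_outliers_uod(u3, 3, 2, 0.1)), 0)
})

test_that("UOD detects planted spikes on a rotating flow with high sensitivity", {
  # brute-force oracle of the normalized median residual at every node
  uod_oracle <- function(v, mask, thr, eps) {
    ny <- nrow(mask); nx <- ncol(mask)
    flag <- matrix(FALSE, ny, nx)
    for (k in 1:2) {
      comp <- v[, , k]
      for (i in 1:ny) for (j in 1:nx) {
        if (!mask[i, j]) next
        nb <- c()
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
          if (mask[ii, jj]) nb <- c(nb, comp[ii, jj])
        }
        if (length(nb) < 3) next
        med <- median(nb)
        rm <- median(abs(nb - med))
        if (abs(comp[i, j] - med) / (rm + eps) > thr) flag[i, j] <- TRUE
      }
    }
    flag
  }

  g <- grid_spec(48, 48, 1e-3, 1e-3)
  s <- gen_solid_rotation(g, omega = 10, mask_radius = 0.02, n_frames = 1L)
  pk <- icflow:::peak_speed(s)
  set.seed(31)
  s$velocity[, , 1, 1] <- s$velocity[, , 1, 1] + rnorm(48 * 48, sd = 0.01 * pk)
  s$velocity[, , 2, 1] <- s$velocity[, , 2, 1] + rnorm(48 * 48, sd = 0.01 * pk)
  idx <- which(s$mask[, , 1])
  spikes <- sample(idx, max(3, round(0.01 * length(idx))))
  for (p in spikes) {
    s$velocity[, , 1, 1][p] <- 10 * s$velocity[, , 1, 1][p]
    s$velocity[, , 2, 1][p] <- 10 * s$velocity[, , 2, 1][p]
  }
  sp <- detect_outliers_uod(s, 3, 2, 0.1)
  truth <- matrix(FALSE, 48, 48); truth[spikes] <- TRUE
  expect_gte(sum(sp[, , 1] & truth) / sum(truth), 0.95)
  expect_lte(sum(sp[, , 1] & !truth & s$mask[, , 1]) /
               sum(s$mask[, , 1] & !truth), 0.01)
  # implementation agrees with the brute-force residual formula node by node
  expect_identical(sp[, , 1],
                   uod_oracle(s$velocity[, , , 1], s$mask[, , 1], 2, 0.1))
})

test_that("replacement restores spikes, never touches clean nodes, zeroes isolated nodes", {
  g <- grid_spec(16, 16, 1e-3, 1e-3)
  u <- gen_uniform(g, c(0.3, -0.2), n_frames = 1L)
  u$velocity[8, 8, , 1] <- c(7, -7)
  sp <- detect_outliers_uod(u, 3, 2, 0.1)
  ur <- replace_outliers(u, sp)
  expect_equal(ur$velocity[8, 8, , 1], c(0.3, -0.2))
  # untouched elsewhere, bitwise
  keep <- u$velocity; keep[8, 8, , 1] <- ur$velocity[8, 8, , 1]
  expect_identical(ur$velocity, keep)

  # no flags: identity
  u2 <- gen_uniform(g, c(0.3, -0.2), n_frames = 1L)
  expect_identical(replace_outliers(u2, array(FALSE, dim(u2$mask)))$velocity,
                   u2$velocity)

  # isolated flagged node with no valid neighbor is zeroed and reported
  m <- matrix(FALSE, 16, 16); m[8, 8] <- TRUE
  u3 <- gen_uniform(g, c(1, 1), mask = m, n_frames = 1L)
  sp3 <- array(FALSE, dim(u3$mask)); sp3[8, 8, 1] <- TRUE
  expect_message(u4 <- replace_outliers(u3, sp3), "no valid neighbor")
  expect_equal(u4$velocity[8, 8, , 1], c(0, 0))
})

test_that("low-rank denoising: full energy is identity, exact low-rank recovery, noise suppression", {
  g <- grid_spec(16, 16, 1e-3, 1e-3)
  ny <- 16; nx <- 16; nt <- 12
  xy <- grid_xy(g)
  pattern <- sin(2 * pi * xy$x / 0.016) * cos(2 * pi * xy$y / 0.016)
  amp <- sin(2 * pi * (0:(nt - 1)) / nt) + 2
  vel <- array(0, c(ny, nx, 2, nt))
  for (i in 1:nt) {
    vel[, , 1, i] <- pattern * amp[i]
    vel[, , 2, i] <- -0.5 * pattern * amp[i]
  }
  mask <- array(TRUE, c(ny, nx, nt))
  s <- planar_velocity_series(g, (0:(nt - 1)) / nt, vel, mask, period = 1,
                              periodic = TRUE)
  # energy_fraction = 1: output equals input to round-off
  s_full <- lowrank_denoise(s, 1)
  expect_equal(s_full$velocity, s$velocity, tolerance = 1e-12)
  # rank-1 input is recovered exactly with one mode
  s_r1 <- lowrank_denoise(s, 0.9)
  expect_equal(attr(s_r1, "rank"), 1L)
  expect_equal(s_r1$velocity, s$velocity, tolerance = 1e-12)

  # rank-2 signal + noise: truncation at the oracle rank beats no truncation
  pattern2 <- cos(2 * pi * xy$x / 0.016)
  amp2 <- cos(2 * pi * (0:(nt - 1)) / nt)
  vel2 <- vel
  for (i in 1:nt) vel2[, , 2, i] <- vel2[, , 2, i] + pattern2 * amp2[i]
  set.seed(7)
  noisy <- vel2 + array(rnorm(length(vel2), sd = 0.3), dim(vel2))
  sn <- planar_velocity_series(g, (0:(nt - 1)) / nt, noisy, mask, period = 1,
                               periodic = TRUE)
  for (rule in c("energy", "noise_floor")) {
    sd_ <- lowrank_denoise(sn, 0.8, rule)
    err_trunc <- sqrt(mean((sd_$velocity - vel2)^2))
    err_raw <- sqrt(mean((noisy - vel2)^2))
    expect_lt(err_trunc, err_raw)
  }
  expect_error(lowrank_denoise(s, 0), "energy_fraction")
})

test_that("phase averaging reproduces identical beats and averages noise as 1/sqrt(N)", {
  g <- grid_spec(12, 12, 1e-3, 1e-3)
  nt_beat <- 12; Tc <- 1
  xy <- grid_xy(g)
  base <- sin(2 * pi * xy$x / 0.012)
  frame_v <- function(ph) base * sin(2 * pi * ph)
  make_series <- function(n_beats, sigma = 0) {
    times <- (0:(n_beats * nt_beat - 1)) * (Tc / nt_beat)
    vel <- array(0, c(12, 12, 2, length(times)))
    for (i in seq_along(times)) {
      ph <- (times[i] %% Tc) / Tc
      vel[, , 1, i] <- frame_v(ph)
      vel[, , 2, i] <- 0.5 * frame_v(ph)
    }
    if (sigma > 0) vel <- vel + array(rnorm(length(vel), sd = sigma), dim(vel))
    planar_velocity_series(g, times, vel, array(TRUE, c(12, 12, length(times))))
  }
  beats4 <- beat_definition(0:4 * Tc, n_phases = nt_beat)
  clean <- make_series(4)
  avg <- phase_average(clean, beats4)
  # mean of identical beats equals one beat at the common phases
  one <- make_series(1)
  expect_equal(avg$velocity[, , , 3], one$velocity[, , , 3], tolerance = 1e-10)
  # a single beat passes through (resampled onto its own phases)
  avg1 <- phase_average(make_series(1), beat_definition(0:1 * Tc, nt_beat))
  expect_equal(avg1$velocity, one$velocity, tolerance = 1e-10)

  # noise shrinks as 1/sqrt(N) (Monte-Carlo, 100 reps)
  set.seed(123)
  sigma <- 0.2
  rms_for <- function(N) {
    mean(replicate(100, {
      s <- make_series(N, sigma)
      a <- phase_average(s, beat_definition(0:N * Tc, nt_beat))
      sqrt(mean((a$velocity - clean$velocity[, , , 1:nt_beat])^2))
    }))
  }
  r1 <- rms_for(1); r4 <- rms_for(4); r16 <- rms_for(16)
  expect_equal(r1 / r4, 2, tolerance = 0.2)
  expect_equal(r1 / r16, 4, tolerance = 0.2)

  # short beats are excluded; all-short is an error
  few <- make_series(1)
  expect_error(suppressMessages(
    phase_average(few, beat_definition(c(0, 0.25, 0.5) * Tc, nt_beat))),
    "no beat")
})

test_that("resample_time is identity at original stamps and bounds sinusoid error", {
  g <- grid_spec(12, 12, 1e-3, 1e-3)
  nt <- 30; Tc <- 1
  xy <- grid_xy(g)
  vel <- array(0, c(12, 12, 2, nt))
  for (i in 1:nt) {
    ph <- (i - 1) / nt
    vel[, , 1, i] <- sin(2 * pi * ph) * (1 + xy$x)
    vel[, , 2, i] <- cos(2 * pi * ph)
  }
  s <- planar_velocity_series(g, (0:(nt - 1)) / nt * Tc, vel,
                              array(TRUE, c(12, 12, nt)),
                              period = Tc, periodic = TRUE)
  # constant series stays constant
  cst <- gen_uniform(g, c(0.2, 0.1), n_frames = 8L)
  rc <- resample_time(cst, 5L)
  expect_equal(max(abs(rc$velocity[, , 1, ] - 0.2)), 0, tolerance = 1e-14)
  # resampling to the original stamps is the identity
  r30 <- resample_time(s, 30L)
  expect_equal(r30$velocity, s$velocity, tolerance = 1e-12)
  # 30 -> 20 phases: max error within the linear-interpolation bound
  r20 <- resample_time(s, 20L)
  truth20 <- array(0, c(12, 12, 2, 20))
  for (i in 1:20) {
    ph <- (i - 1) / 20
    truth20[, , 1, i] <- sin(2 * pi * ph) * (1 + xy$x)
    truth20[, , 2, i] <- cos(2 * pi * ph)
  }
  # |f''|max h^2 / 8 with f = sin(2 pi t / T), h = T/30
  bound <- (2 * pi)^2 * (1 / 30)^2 / 8 * max(1 + xy$x)
  expect_lt(max(abs(r20$velocity - truth20)), bound * 1.000001)
})

test_that("estimate_period recovers the cycle length of a periodic recording", {
  g <- grid_spec(24, 24, 2e-3, 2e-3)
  spec <- synthetic_spec(seed = 9, period = 0.8, noise = 0)
  gen <- gen_rv_filling(g, spec)
  pair <- degrade_to_modalities(gen$series,
                                synthetic_spec(seed = 9, period = 0.8,
                                               noise = 0.02, echo_beats = 4,
                                               echo_rate_hz = 25))
  expect_equal(estimate_period(pair$echo), 0.8, tolerance = 0.08)
})
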