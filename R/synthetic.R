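# Synthetic, divergence-free velocity fields with analytic ground truth.
#
# Closed-form families (solid rotation, Taylor-Green, Hill's vortex) are
# evaluated from their analytic velocity expressions. Streamfunction families
# (Lamb-Oseen pair, RV filling) obtain velocity by differencing the analytic
# streamfunction with the package's standard second-order stencil, so the
# discrete central-difference divergence vanishes identically at interior
# nodes (the discrete mixed derivatives of the streamfunction commute).

#' Parameterization of a synthetic flow fixture
#'
#' Captures everything needed to regenerate a synthetic dataset and its
#' degraded two-modality pair bit-for-bit: flow family, cardiac-cycle period,
#' frame counts, physical family parameters, modality noise and
#' misregistration, and the master random seed.
#'
#' @param family Flow family.
#' @param period Cardiac cycle period T in seconds.
#' @param frames_per_cycle Frames per cycle for the generated truth (>= 10,
#'   the usual clinical adequacy minimum for echo).
#' @param jet_peak_speed Peak tricuspid inflow jet speed (m/s) for
#'   `rv_filling`.
#' @param core_radius Gaussian vortex core radius (m).
#' @param omega Solid-body rotation rate (1/s).
#' @param gamma Vortex circulation (m^2/s) for `lamb_oseen_pair`.
#' @param nu Kinematic viscosity (m^2/s) for `taylor_green`.
#' @param noise Modality noise std as a fraction of the truth's peak speed.
#' @param echo_rate_hz Echo-like modality frame rate (Hz).
#' @param echo_beats Number of beats recorded by the echo-like modality.
#' @param mri_phases MRI-like modality phases per cycle.
#' @param plane_offset In-plane misregistration offset `c(dx, dy)` (m)
#'   applied to the MRI-like modality.
#' @param plane_rotation In-plane misregistration rotation (radians).
#' @param seed Master integer seed; per-modality noise streams are derived
#'   from it by fixed offsets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(family = c("rv_filling", "solid_rotation",
                                      "taylor_green", "lamb_oseen_pair",
                                      "hill_vortex_3d", "uniform"),
                           period = 0.8, frames_per_cycle = 40L,
                           jet_peak_speed = 0.8, core_radius = 0.008,
                           omega = 10, gamma = 0.04, nu = 4e-6,
                           noise = 0.05, echo_rate_hz = 20, echo_beats = 3L,
                           mri_phases = 25L, plane_offset = c(0, 0),
                           plane_rotation = 0, seed = 1L) {
  family <- match.arg(family)
  stopifnot(period > 0, frames_per_cycle >= 10, noise >= 0,
            core_radius > 0, echo_rate_hz > 0, echo_beats >= 1,
            mri_phases >= 2, length(plane_offset) == 2)
  structure(list(family = family, period = period,
                 frames_per_cycle = as.integer(frames_per_cycle),
                 jet_peak_speed = jet_peak_speed, core_radius = core_radius,
                 omega = omega, gamma = gamma, nu = nu, noise = noise,
                 echo_rate_hz = echo_rate_hz, echo_beats = as.integer(echo_beats),
                 mri_phases = as.integer(mri_phases),
                 plane_offset = as.numeric(plane_offset),
                 plane_rotation = plane_rotation, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Steady solid-body rotation on a disc
#'
#' `v = (-omega * (y - yc), omega * (x - xc))` inside a disc mask centered on
#' the grid. Pointwise vorticity is exactly `2 * omega`; the strain-rate
#' tensor (hence viscous dissipation) is exactly zero; the relative pressure
#' field is `rho * omega^2 * r^2 / 2` up to gauge.
#'
#' @param grid A 2D [grid_spec()].
#' @param omega Rotation rate (1/s).
#' @param mask_radius Disc radius (m); must fit inside the grid.
#' @param n_frames Number of (identical) frames.
#' @param period Nominal cycle period (s).
#' @return A [planar_velocity_series()] (steady, periodic).
#' @export
gen_solid_rotation <- function(grid, omega, mask_radius, n_frames = 4L,
                               period = 1) {
  xy <- grid_xy(grid)
  xc <- mean(range(grid_x(grid))); yc <- mean(range(grid_y(grid)))
  half_x <- diff(range(grid_x(grid))) / 2
  half_y <- diff(range(grid_y(grid))) / 2
  if (mask_radius > min(half_x, half_y))
    stop(sprintf(paste0("mask_radius %g m exceeds the half-extent of the grid",
                        " (%g m in x, %g m in y)"),
                 mask_radius, half_x, half_y))
  mask <- (xy$x - xc)^2 + (xy$y - yc)^2 <= mask_radius^2
  vx <- -omega * (xy$y - yc)
  vy <- omega * (xy$x - xc)
  v1 <- array(c(vx, vy), c(grid$ny, grid$nx, 2))
  nt <- as.integer(n_frames)
  vel <- array(v1, c(grid$ny, grid$nx, 2, nt))
  times <- (seq_len(nt) - 1) / nt * period
  planar_velocity_series(grid, times, vel, array(mask, c(dim(mask), nt)),
                         period = period, periodic = TRUE)
}

#' Uniform steady flow
#'
#' @param grid A 2D [grid_spec()].
#' @param u Velocity vector `c(ux, uy)` (m/s).
#' @param mask Optional logical matrix; defaults to all nodes.
#' @param n_frames Number of identical frames.
#' @param period Nominal period (s).
#' @return A [planar_velocity_series()].
#' @export
gen_uniform <- function(grid, u = c(1, 0), mask = NULL, n_frames = 4L,
                        period = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, grid$ny, grid$nx)
  nt <- as.integer(n_frames)
  v1 <- array(0, c(grid$ny, grid$nx, 2))
  v1[, , 1] <- u[1]; v1[, , 2] <- u[2]
  vel <- array(v1, c(grid$ny, grid$nx, 2, nt))
  planar_velocity_series(grid, (seq_len(nt) - 1) / nt * period, vel,
                         array(mask, c(dim(mask), nt)),
                         period = period, periodic = TRUE)
}

#' Decaying Taylor-Green vortex lattice with closed-form pressure
#'
#' `v = (U0 sin(kx) cos(ky), -U0 cos(kx) sin(ky)) * exp(-2 nu k^2 t)` on one
#' periodic cell, with `k = 2 pi / (nx * dx)`. The pressure consistent with
#' this velocity (the momentum balance reduces to `grad p = -rho u . grad u`,
#' the unsteady and viscous terms cancelling since `mu = rho nu`) is
#' `p = (rho U0^2 / 4)(cos 2kx + cos 2ky) exp(-4 nu k^2 t)`, returned as
#' per-frame ground-truth scalar fields for validating the pressure
#' reconstruction chain. The grid must be square-celled (`dx == dy`) and span
#' exactly one periodic cell, which also makes the discrete central
#' divergence of the sampled field vanish identically.
#'
#' @param grid A 2D [grid_spec()] with `dx == dy` and `nx * dx == ny * dy`.
#' @param nu Kinematic viscosity (m^2/s).
#' @param times Frame times (s).
#' @param U0 Velocity amplitude (m/s).
#' @param rho Fluid density (kg/m^3) used for the pressure truth.
#' @return List with `series` (mask = all nodes) and `pressure_truth`, a list
#'   of [scalar_field_frame()]s (gauge: zero spatial mean).
#' @export
gen_taylor_green <- function(grid, nu = 4e-6, times = seq(0, 0.5, length.out = 12),
                             U0 = 0.5, rho = 1060) {
  if (abs(grid$dx - grid$dy) > 1e-12 * grid$dx ||
      abs(grid$nx * grid$dx - grid$ny * grid$dy) > 1e-9)
    stop("taylor_green requires a square-celled grid spanning one periodic cell")
  L <- grid$nx * grid$dx
  k <- 2 * pi / L
  xy <- grid_xy(grid)
  sx <- sin(k * xy$x); cx <- cos(k * xy$x)
  sy <- sin(k * xy$y); cy <- cos(k * xy$y)
  nt <- length(times)
  vel <- array(0, c(grid$ny, grid$nx, 2, nt))
  truth <- vector("list", nt)
  p0 <- (rho * U0^2 / 4) * (cos(2 * k * xy$x) + cos(2 * k * xy$y))
  mask <- matrix(TRUE, grid$ny, grid$nx)
  for (i in seq_len(nt)) {
    ev <- exp(-2 * nu * k^2 * times[i])
    vel[, , 1, i] <- U0 * sx * cy * ev
    vel[, , 2, i] <- -U0 * cx * sy * ev
    p <- p0 * ev^2
    p <- p - mean(p)
    truth[[i]] <- scalar_field_frame(grid, p, mask, times[i], "pressure")
  }
  series <- planar_velocity_series(grid, times, vel,
                                   array(mask, c(dim(mask), nt)),
                                   period = NULL, periodic = FALSE)
  list(series = series, pressure_truth = truth)
}

# Lamb-Oseen streamfunction for unit circulation at squared radius r2:
# psi = -(1/2pi) (ln r + E1(r^2/rc^2)/2); regular at r = 0, evaluated by
# series for small arguments to avoid the ln-cancellation.
oseen_psi_unit <- function(r2, rc) {
  z <- r2 / rc^2
  out <- numeric(length(z))
  small <- z < 1e-3
  euler <- 0.57721566490153286
  if (any(small)) {
    zs <- z[small]
    out[small] <- log(rc) - euler / 2 + 0.5 * (zs - zs^2 / 4 + zs^3 / 18)
  }
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- 0.5 * log(r2[!small]) + 0.5 * pracma::expint(zb)
  }
  out <- -out / (2 * pi)
  dim(out) <- dim(r2)
  out
}

# velocity from a streamfunction matrix by the package stencil:
# u = d(psi)/dy, v = -d(psi)/dx (full-grid differencing)
velocity_from_psi <- function(psi, grid) {
  allm <- matrix(TRUE, nrow(psi), ncol(psi))
  u <- masked_deriv(psi, allm, grid$dy, "y")$d
  v <- -masked_deriv(psi, allm, grid$dx, "x")$d
  array(c(u, v), c(nrow(psi), ncol(psi), 2))
}

#' Lamb-Oseen vortex pair (streamfunction construction)
#'
#' Two Gaussian-core vortices of circulation `gamma` and `gamma_b` placed
#' `separation` apart along x at the grid center. Velocity is the discrete
#' curl of the analytic streamfunction. Set `gamma_b = 0` for a single
#' vortex. Steady (frames identical); mask covers the full grid.
#'
#' @param grid A 2D [grid_spec()].
#' @param gamma Circulation of the left vortex (m^2/s).
#' @param core_radius Core radius (m).
#' @param separation Center-to-center distance (m).
#' @param gamma_b Circulation of the right vortex; default `-gamma`.
#' @param n_frames Number of identical frames.
#' @param period Nominal period (s).
#' @return A [planar_velocity_series()].
#' @export
gen_lamb_oseen_pair <- function(grid, gamma, core_radius, separation,
                                gamma_b = -gamma, n_frames = 3L, period = 1) {
  xy <- grid_xy(grid)
  xc <- mean(range(grid_x(grid))); yc <- mean(range(grid_y(grid)))
  psi <- gamma * oseen_psi_unit((xy$x - (xc - separation / 2))^2 +
                                (xy$y - yc)^2, core_radius)
  if (gamma_b != 0)
    psi <- psi + gamma_b * oseen_psi_unit((xy$x - (xc + separation / 2))^2 +
                                          (xy$y - yc)^2, core_radius)
  v1 <- velocity_from_psi(psi, grid)
  nt <- as.integer(n_frames)
  vel <- array(v1, c(grid$ny, grid$nx, 2, nt))
  mask <- matrix(TRUE, grid$ny, grid$nx)
  planar_velocity_series(grid, (seq_len(nt) - 1) / nt * period, vel,
                         array(mask, c(dim(mask), nt)),
                         period = period, periodic = TRUE)
}

# raised-cosine window on [t0, t0 + tau), zero elsewhere
raised_cosine <- function(t, t0, tau) {
  inside <- t >= t0 & t < t0 + tau
  out <- numeric(length(t))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / tau))
  out
}

# circulation waveform of the filling fixture: E-wave peaking at 0.5 T plus
# a smaller A-wave in late diastole
rv_gamma_waveform <- function(t, period, gamma0) {
  gamma0 * (raised_cosine(t, 0.25 * period, 0.5 * period) +
            0.35 * raised_cosine(t, 0.78 * period, 0.20 * period))
}

#' Diastolic RV-filling fixture: inflow jet rolling up into a vortex ring
#'
#' Emulates early-diastolic right-ventricular filling on an apical
#' four-chamber-like plane: a counter-rotating Lamb-Oseen vortex pair (the 2D
#' trace of the vortex ring) straddles the tricuspid-valve line and drives a
#' jet into a half-elliptic chamber mask; the pair's circulation follows a
#' raised-cosine E-wave (peaking at 0.5 T) plus a smaller late-diastolic
#' A-wave, and the cores advect toward the apex with the accumulated inflow.
#' Velocity is the discrete curl of the analytic streamfunction, so the
#' field is exactly divergence-free under the package's stencil. The cycle is
#' periodic with period `spec$period`.
#'
#' @param grid A 2D [grid_spec()].
#' @param spec A [synthetic_spec()] with `family = "rv_filling"`; uses
#'   `period`, `frames_per_cycle`, `jet_peak_speed`, `core_radius`.
#' @return List with `series` (a periodic single-cycle
#'   [planar_velocity_series()] carrying its [landmarks()]) and `landmarks`.
#' @export
gen_rv_filling <- function(grid, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$family != "rv_filling")
    stop("spec$family must be 'rv_filling'")
  Tc <- spec$period
  nt <- spec$frames_per_cycle
  times <- (seq_len(nt) - 1) / nt * Tc

  xr <- range(grid_x(grid)); yr <- range(grid_y(grid))
  Lx <- diff(xr); Ly <- diff(yr)
  xc <- mean(xr)
  y_base <- yr[1] + 0.12 * Ly
  a_semi <- 0.32 * Lx
  b_semi <- 0.72 * Ly
  xy <- grid_xy(grid)
  mask <- (((xy$x - xc) / a_semi)^2 + ((xy$y - y_base) / b_semi)^2 <= 1) &
    (xy$y >= y_base - 1e-12)

  valve_w <- 0.5 * a_semi
  xv <- xc - 0.30 * a_semi            # valve sits septal of the chamber center
  lm <- landmarks(valve_a = c(xv - valve_w / 2, y_base),
                  valve_b = c(xv + valve_w / 2, y_base),
                  apex = c(xc, y_base + 0.88 * b_semi))

  d_half <- 0.30 * valve_w            # half-separation of the vortex cores
  rc <- spec$core_radius
  gamma0 <- spec$jet_peak_speed * pi * d_half /
    (1 - exp(-d_half^2 / rc^2))
  gam <- rv_gamma_waveform(times, Tc, gamma0)
  adv <- cumsum(gam); adv <- if (max(adv) > 0) adv / max(adv) else adv

  vel <- array(0, c(grid$ny, grid$nx, 2, nt))
  y_max <- y_base + 0.80 * b_semi     # clamp: cores stay inside the chamber
  for (i in seq_len(nt)) {
    if (gam[i] == 0) next
    yc_core <- min(y_base + (0.18 + 0.42 * adv[i]) * b_semi, y_max)
    psi <- gam[i] * (oseen_psi_unit((xy$x - (xv - d_half))^2 +
                                    (xy$y - yc_core)^2, rc) -
                     oseen_psi_unit((xy$x - (xv + d_half))^2 +
                                    (xy$y - yc_core)^2, rc))
    vel[, , , i] <- velocity_from_psi(psi, grid)
  }
  series <- planar_velocity_series(grid, times, vel,
                                   array(mask, c(dim(mask), nt)),
                                   landmarks = lm, period = Tc,
                                   periodic = TRUE)
  list(series = series, landmarks = lm)
}

#' Hill's spherical vortex (3D, vortex at rest, uniform far-field -U)
#'
#' Axisymmetric about z through the grid center. In the frame where the
#' vortex is at rest the axial velocity on the axis at the sphere center is
#' `3U/2` and the far field tends to the uniform stream `(0, 0, -U)`.
#'
#' @param grid3d A 3D [grid_spec()].
#' @param U Far-field stream speed (m/s).
#' @param a Sphere radius (m); must fit inside the grid.
#' @param n_frames Number of identical frames.
#' @return A [volume_velocity_series()] with an all-TRUE mask.
#' @export
gen_hill_vortex_3d <- function(grid3d, U, a, n_frames = 1L) {
  stopifnot(!is.null(grid3d$nz))
  xs <- grid_x(grid3d); ys <- grid_y(grid3d); zs <- grid_z(grid3d)
  cx <- mean(range(xs)); cy <- mean(range(ys)); cz <- mean(range(zs))
  if (a > min(diff(range(xs)), diff(range(ys)), diff(range(zs))) / 2)
    stop(sprintf("sphere radius %g m exceeds the grid half-extent", a))
  ny <- grid3d$ny; nx <- grid3d$nx; nz <- grid3d$nz
  X <- array(rep(xs, each = ny), c(ny, nx, nz)) - cx
  Y <- array(ys, c(ny, nx, nz)) - cy
  Z <- array(rep(zs, each = ny * nx), c(ny, nx, nz)) - cz
  hv <- hill_velocity(X, Y, Z, U, a)
  nt <- as.integer(n_frames)
  vel <- array(0, c(ny, nx, nz, 3, nt))
  for (i in seq_len(nt)) {
    vel[, , , 1, i] <- hv$vx
    vel[, , , 2, i] <- hv$vy
    vel[, , , 3, i] <- hv$vz
  }
  mask <- array(TRUE, c(ny, nx, nz, nt))
  volume_velocity_series(grid3d, (seq_len(nt) - 1), vel, mask)
}

# closed-form Hill's vortex velocity at centered coordinates; also the
# analytic oracle for the plane-projection tests
hill_velocity <- function(X, Y, Z, U, a) {
  s2 <- X^2 + Y^2
  R2 <- s2 + Z^2
  inside <- R2 <= a^2
  vz <- array(0, dim(X)); vs_over_s <- array(0, dim(X))
  # interior: u_z = 3U/2 (1 - (2 s^2 + z^2)/a^2), u_s = 3U/2 s z / a^2
  vz[inside] <- 1.5 * U * (1 - (2 * s2[inside] + Z[inside]^2) / a^2)
  vs_over_s[inside] <- 1.5 * U * Z[inside] / a^2
  # exterior: dipole + uniform stream -U
  out <- !inside
  R3 <- R2[out]^1.5; R5 <- R2[out]^2.5
  vz[out] <- -U + U * a^3 / 2 * (2 / R3 - 3 * s2[out] / R5)
  vs_over_s[out] <- 1.5 * U * a^3 * Z[out] / R5
  list(vx = vs_over_s * X, vy = vs_over_s * Y, vz = vz)
}

# periodic linear interpolation of a series at arbitrary times (mod period);
# returns velocity array and nearest-frame mask
sample_series_periodic <- function(series, t_query) {
  Tc <- series$period
  if (is.null(Tc)) stop("series has no period; cannot sample periodically")
  tq <- t_query %% Tc
  tt <- series$times
  nt <- length(tt)
  ny <- series$grid$ny; nx <- series$grid$nx
  vel <- array(0, c(ny, nx, 2, length(tq)))
  mask <- array(FALSE, c(ny, nx, length(tq)))
  # bracketing frames with wrap between last and first
  t_ext <- c(tt, tt[1] + Tc)
  for (q in seq_along(tq)) {
    j <- findInterval(tq[q], t_ext, rightmost.closed = FALSE)
    j <- max(1L, min(j, nt))
    j2 <- if (j == nt) 1L else j + 1L
    t1 <- tt[j]; t2 <- if (j == nt) tt[1] + Tc else tt[j + 1]
    w <- if (t2 > t1) (tq[q] - t1) / (t2 - t1) else 0
    vel[, , , q] <- (1 - w) * series$velocity[, , , j] +
      w * series$velocity[, , , j2]
    mask[, , q] <- if (w < 0.5) series$mask[, , j] else series$mask[, , j2]
  }
  list(velocity = vel, mask = mask)
}

# rigid in-plane misregistration: resample each frame at back-transformed
# coordinates (rotation about the union-mask centroid plus offset) and rotate
# the vector components accordingly; mask by bilinear weight >= 0.5
apply_misregistration <- function(velocity, mask, grid, offset, rotation) {
  if (all(offset == 0) && rotation == 0)
    return(list(velocity = velocity, mask = mask))
  ny <- grid$ny; nx <- grid$nx
  nt <- dim(velocity)[4]
  xy <- grid_xy(grid)
  um <- apply(mask, c(1, 2), any)
  cx <- mean(xy$x[um]); cy <- mean(xy$y[um])
  cr <- cos(rotation); sr <- sin(rotation)
  # source position: inverse transform of node position
  qx <- cr * (xy$x - cx) + sr * (xy$y - cy) + cx - offset[1]
  qy <- -sr * (xy$x - cx) + cr * (xy$y - cy) + cy - offset[2]
  out_v <- array(0, dim(velocity))
  out_m <- array(FALSE, dim(mask))
  for (i in seq_len(nt)) {
    u <- bilinear_sample(velocity[, , 1, i], grid, qx, qy)
    v <- bilinear_sample(velocity[, , 2, i], grid, qx, qy)
    mw <- bilinear_sample(mask[, , i] * 1, grid, qx, qy)
    out_v[, , 1, i] <- cr * u - sr * v
    out_v[, , 2, i] <- sr * u + cr * v
    out_m[, , i] <- !is.na(mw) & mw >= 0.5
  }
  out_v[is.na(out_v)] <- 0
  list(velocity = out_v, mask = out_m)
}

# bilinear interpolation of matrix F (grid-aligned) at points (px, py); NA
# outside the grid
bilinear_sample <- function(F, grid, px, py) {
  gx <- (px - grid$origin[1]) / grid$dx + 1
  gy <- (py - grid$origin[2]) / grid$dy + 1
  # nudge points sitting exactly on the far boundary into the last cell
  gx[abs(gx - grid$nx) < 1e-9] <- grid$nx - 1e-9
  gy[abs(gy - grid$ny) < 1e-9] <- grid$ny - 1e-9
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  ok <- j0 >= 1 & j0 <= grid$nx - 1 & i0 >= 1 & i0 <= grid$ny - 1
  out <- array(NA_real_, dim(px))
  idx <- which(ok)
  if (length(idx)) {
    i0i <- i0[idx]; j0i <- j0[idx]
    f11 <- F[cbind(i0i, j0i)];     f12 <- F[cbind(i0i, j0i + 1)]
    f21 <- F[cbind(i0i + 1, j0i)]; f22 <- F[cbind(i0i + 1, j0i + 1)]
    fxi <- fx[idx]; fyi <- fy[idx]
    out[idx] <- (1 - fyi) * ((1 - fxi) * f11 + fxi * f12) +
      fyi * ((1 - fxi) * f21 + fxi * f22)
  }
  out
}

#' Degrade a truth field into an echo-like / MRI-like modality pair
#'
#' Emulates the two-modality acquisition setting: the echo-like modality
#' samples `echo_beats` consecutive cycles at `echo_rate_hz` (clinical echo
#' runs around 20 Hz) and the MRI-like modality reconstructs one cycle into
#' `mri_phases` phases (clinically 20-30), optionally through a rigid
#' in-plane misregistration. Independent Gaussian noise with std
#' `spec$noise * peak speed` is added per velocity component, with
#' per-modality RNG streams derived from `spec$seed` by fixed offsets so the
#' pair is independently noisy yet bit-reproducible.
#'
#' @param truth A periodic single-cycle [planar_velocity_series()] with a
#'   known `period`.
#' @param spec A [synthetic_spec()].
#' @return List with `echo` (multi-beat series carrying a `beats` attribute,
#'   a [beat_definition()]) and `mri` (single-cycle periodic series).
#' @export
degrade_to_modalities <- function(truth, spec) {
  stopifnot(inherits(truth, "planar_velocity_series"),
            inherits(spec, "synthetic_spec"), !is.null(truth$period))
  Tc <- truth$period
  if (spec$echo_rate_hz * Tc < 10)
    stop(sprintf(paste0("echo frame rate %g Hz over a %g s cycle gives %.1f",
                        " frames/beat; at least 10 frames per beat required"),
                 spec$echo_rate_hz, Tc, spec$echo_rate_hz * Tc))
  pk <- peak_speed(truth)
  sd_noise <- spec$noise * pk

  # echo-like: multi-beat resampling at the echo frame rate
  t_echo <- seq(0, spec$echo_beats * Tc - 1e-9, by = 1 / spec$echo_rate_hz)
  se <- sample_series_periodic(truth, t_echo)
  if (sd_noise > 0) {
    se$velocity <- se$velocity +
      with_seed(spec$seed + 1000003L,
                array(rnorm(length(se$velocity), sd = sd_noise),
                      dim(se$velocity)))
  }
  echo <- planar_velocity_series(truth$grid, t_echo, se$velocity, se$mask,
                                 landmarks = truth$landmarks, period = Tc,
                                 periodic = FALSE)
  attr(echo, "beats") <- beat_definition((0:spec$echo_beats) * Tc,
                                         n_phases = spec$mri_phases)

  # MRI-like: single cycle at the phase count, optional misregistration
  t_mri <- (seq_len(spec$mri_phases) - 1) / spec$mri_phases * Tc
  sm <- sample_series_periodic(truth, t_mri)
  mis <- apply_misregistration(sm$velocity, sm$mask, truth$grid,
                               spec$plane_offset, spec$plane_rotation)
  if (sd_noise > 0) {
    mis$velocity <- mis$velocity +
      with_seed(spec$seed + 2000003L,
                array(rnorm(length(mis$velocity), sd = sd_noise),
                      dim(mis$velocity)))
  }
  mri <- planar_velocity_series(truth$grid, t_mri, mis$velocity, mis$mask,
                                landmarks = truth$landmarks, period = Tc,
                                periodic = TRUE)
  list(echo = echo, mri = mri)
}
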