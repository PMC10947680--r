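# Shared fixtures and small oracles used across the test files. Everything is
# generated in code; no stored data.

RHO_BLOOD <- 1060
MU_BLOOD <- 0.004

# small solid-rotation fixture
fix_solid <- function(n = 64, omega = 10, radius = NULL, dx = 1e-3,
                      n_frames = 4L) {
  g <- grid_spec(n, n, dx, dx)
  if (is.null(radius)) radius <- 0.35 * n * dx
  gen_solid_rotation(g, omega, radius, n_frames = n_frames)
}

# analytic solid-rotation relative pressure (zero-mean over `mask`)
solid_pressure_truth <- function(grid, omega, mask, rho = RHO_BLOOD) {
  xy <- grid_xy(grid)
  xc <- mean(range(grid_x(grid))); yc <- mean(range(grid_y(grid)))
  p <- 0.5 * rho * omega^2 * ((xy$x - xc)^2 + (xy$y - yc)^2)
  p - mean(p[mask])
}

# Taylor-Green analytic fields at time t on a grid (k from the grid extent)
tg_analytic <- function(grid, U0, nu, t) {
  L <- grid$nx * grid$dx
  k <- 2 * pi / L
  xy <- grid_xy(grid)
  ev <- exp(-2 * nu * k^2 * t)
  list(k = k,
       u = U0 * sin(k * xy$x) * cos(k * xy$y) * ev,
       v = -U0 * cos(k * xy$x) * sin(k * xy$y) * ev,
       omega = 2 * U0 * k * sin(k * xy$x) * sin(k * xy$y) * ev,
       # dissipation density: strain tensor has only diagonal terms here
       phi = function(mu) 4 * mu * U0^2 * k^2 *
         (cos(k * xy$x) * cos(k * xy$y))^2 * ev^2,
       px = -(RHO_BLOOD * U0^2 * k / 2) * sin(2 * k * xy$x) * ev^2,
       py = -(RHO_BLOOD * U0^2 * k / 2) * sin(2 * k * xy$y) * ev^2)
}

# gauge-matched RMSE between a reconstructed pressure frame and a truth matrix
pressure_rmse <- function(pressure, truth) {
  m <- pressure$valid
  p <- pressure$values[m] - mean(pressure$values[m])
  pt <- truth[m] - mean(truth[m])
  sqrt(mean((p - pt)^2))
}

# nodes at least `k` nodes away from the grid edge
interior_nodes <- function(grid, k = 2L) {
  m <- matrix(FALSE, grid$ny, grid$nx)
  m[(k + 1):(grid$ny - k), (k + 1):(grid$nx - k)] <- TRUE
  m
}

# reference pipeline cleanup used in the end-to-end agreement experiments
cleanup_series <- function(s, rule = "noise_floor") {
  spur <- detect_outliers_uod(s, 3L, 2, 0.1)
  s <- replace_outliers(s, spur, 3L)
  lowrank_denoise(s, 0.95, rule)
}
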