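#' Time-resolved planar velocity field
#'
#' The central container: a 2-component velocity field on a regular grid over
#' a set of frames, with a per-frame boolean chamber mask and optional
#' anatomical landmarks. Velocity is stored as a 4D array
#' `velocity[iy, ix, component, frame]` in m/s (component 1 = vx, 2 = vy).
#' Values outside the mask may be non-zero but are excluded from every
#' integral the package computes.
#'
#' @param grid A [grid_spec()] (2D).
#' @param times Strictly increasing frame times in seconds.
#' @param velocity Numeric array `c(ny, nx, 2, n_frames)`, finite inside the
#'   mask.
#' @param mask Logical array `c(ny, nx, n_frames)` (a single `c(ny, nx)`
#'   matrix is recycled over frames).
#' @param landmarks Optional [landmarks()].
#' @param period Cycle period T in seconds, if known.
#' @param periodic Logical; `TRUE` for a phase-averaged single beat, where
#'   temporal derivatives and resampling wrap around the cycle.
#' @return An object of class `planar_velocity_series`.
#' @export
planar_velocity_series <- function(grid, times, velocity, mask,
                                   landmarks = NULL, period = NULL,
                                   periodic = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), is.null(grid$nz))
  times <- as.numeric(times)
  nt <- length(times)
  stopifnot(nt >= 1, !is.unsorted(times, strictly = TRUE))
  if (length(dim(mask)) == 2) mask <- array(mask, c(dim(mask), nt))
  stopifnot(identical(dim(velocity), c(grid$ny, grid$nx, 2L, as.integer(nt))) ||
            identical(dim(velocity), as.integer(c(grid$ny, grid$nx, 2, nt))))
  stopifnot(identical(dim(mask)[1:2], dim(velocity)[1:2]), dim(mask)[3] == nt)
  for (k in 1:2) {
    comp <- array(velocity[, , k, ], c(grid$ny, grid$nx, nt))
    if (any(!is.finite(comp[mask])))
      stop("velocity must be finite inside the mask")
  }
  structure(list(grid = grid, times = times, velocity = velocity,
                 mask = array(as.logical(mask), dim(mask)),
                 landmarks = landmarks, period = period,
                 periodic = isTRUE(periodic)),
            class = "planar_velocity_series")
}

#' @export
print.planar_velocity_series <- function(x, ...) {
  cat(sprintf("<planar_velocity_series> %d frames, %d x %d grid, t = [%g, %g] s%s\n",
              length(x$times), x$grid$nx, x$grid$ny,
              min(x$times), max(x$times),
              if (x$periodic) sprintf(", periodic (T = %g s)", x$period) else ""))
  invisible(x)
}

n_frames <- function(series) length(series$times)

#' Time-resolved volumetric velocity field
#'
#' Three-component counterpart of [planar_velocity_series()] for 4D-flow-like
#' data: `velocity[iy, ix, iz, component, frame]` (components vx, vy, vz) and
#' `mask[iy, ix, iz, frame]`.
#'
#' @inheritParams planar_velocity_series
#' @param velocity Numeric array `c(ny, nx, nz, 3, n_frames)` in m/s.
#' @param mask Logical array `c(ny, nx, nz, n_frames)` (3D array recycled).
#' @return An object of class `volume_velocity_series`.
#' @export
volume_velocity_series <- function(grid, times, velocity, mask,
                                   period = NULL, periodic = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), !is.null(grid$nz))
  times <- as.numeric(times)
  nt <- length(times)
  stopifnot(nt >= 1, !is.unsorted(times, strictly = TRUE))
  if (length(dim(mask)) == 3) mask <- array(mask, c(dim(mask), nt))
  stopifnot(all(dim(velocity) == c(grid$ny, grid$nx, grid$nz, 3, nt)),
            all(dim(mask) == c(grid$ny, grid$nx, grid$nz, nt)))
  structure(list(grid = grid, times = times, velocity = velocity,
                 mask = array(as.logical(mask), dim(mask)),
                 period = period, periodic = isTRUE(periodic)),
            class = "volume_velocity_series")
}

#' @export
print.volume_velocity_series <- function(x, ...) {
  cat(sprintf("<volume_velocity_series> %d frames, %d x %d x %d grid\n",
              length(x$times), x$grid$nx, x$grid$ny, x$grid$nz))
  invisible(x)
}

#' Scalar field on a grid at one time point
#'
#' Holds derived per-node scalars: vorticity (1/s), relative pressure (Pa),
#' kinetic-energy density (J/m^3) or viscous-dissipation density (W/m^3),
#' together with a validity mask marking nodes where the quantity could be
#' evaluated.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `c(ny, nx)`.
#' @param valid Logical matrix `c(ny, nx)`; values must be finite where TRUE.
#' @param time Time stamp in seconds.
#' @param quantity One of `"vorticity"`, `"pressure"`, `"ke_density"`,
#'   `"vel_density"`.
#' @return An object of class `scalar_field_frame`.
#' @export
scalar_field_frame <- function(grid, values, valid, time = NA_real_,
                               quantity = c("vorticity", "pressure",
                                            "ke_density", "vel_density")) {
  quantity <- match.arg(quantity)
  stopifnot(all(dim(values) == c(grid$ny, grid$nx)),
            all(dim(valid) == c(grid$ny, grid$nx)))
  if (any(!is.finite(values[valid])))
    stop("scalar field has non-finite values inside its valid mask")
  structure(list(grid = grid, values = values, valid = valid,
                 time = time, quantity = quantity),
            class = "scalar_field_frame")
}

#' @export
print.scalar_field_frame <- function(x, ...) {
  cat(sprintf("<scalar_field_frame> %s, %d valid nodes, range [%g, %g]\n",
              x$quantity, sum(x$valid),
              suppressWarnings(min(x$values[x$valid])),
              suppressWarnings(max(x$values[x$valid]))))
  invisible(x)
}

#' Anatomical landmarks for a planar chamber field
#'
#' The tricuspid-valve line (two endpoints) and the apex point, used to place
#' the inflow-velocity sampling band (valve line extended `inflow_depth` into
#' the chamber, default 1 cm) and the pressure-difference sampling sites.
#'
#' @param valve_a,valve_b Numeric length-2, valve-line endpoints (m).
#' @param apex Numeric length-2, apex point (m).
#' @param inflow_depth Band depth in meters (default 0.01 = 1 cm).
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(valve_a, valve_b, apex, inflow_depth = 0.01) {
  stopifnot(length(valve_a) == 2, length(valve_b) == 2, length(apex) == 2,
            inflow_depth > 0)
  if (sqrt(sum((valve_a - valve_b)^2)) <= 0)
    stop("valve endpoints must be distinct")
  structure(list(valve_a = as.numeric(valve_a), valve_b = as.numeric(valve_b),
                 apex = as.numeric(apex),
                 inflow_depth = as.numeric(inflow_depth)),
            class = "landmarks")
}

#' Beat boundaries for multi-beat recordings
#'
#' @param boundaries Strictly increasing beat boundary times (s); beat k
#'   spans `[boundaries[k], boundaries[k+1])`.
#' @param n_phases Target phase count for phase-averaged resampling.
#' @return An object of class `beat_definition` with the mean cycle period
#'   `T` (s).
#' @export
beat_definition <- function(boundaries, n_phases = 30L) {
  boundaries <- as.numeric(boundaries)
  stopifnot(length(boundaries) >= 2, !is.unsorted(boundaries, strictly = TRUE),
            n_phases >= 2)
  structure(list(boundaries = boundaries,
                 period = mean(diff(boundaries)),
                 n_phases = as.integer(n_phases)),
            class = "beat_definition")
}

# velocity array of one frame, c(ny, nx, 2)
frame_velocity <- function(series, i) series$velocity[, , , i, drop = FALSE][, , , 1]

frame_mask <- function(series, i) series$mask[, , i]

# peak masked speed across all frames
peak_speed <- function(series) {
  pk <- 0
  for (i in seq_len(n_frames(series))) {
    m <- frame_mask(series, i)
    if (!any(m)) next
    v <- frame_velocity(series, i)
    sp <- sqrt(v[, , 1]^2 + v[, , 2]^2)
    pk <- max(pk, max(sp[m]))
  }
  pk
}
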