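#' Analysis plane definition
#'
#' A 2D sampling plane inside a 3D volume: an origin point, two orthonormal
#' in-plane direction vectors, and the in-plane grid. The plane node with
#' in-plane coordinates `(x, y)` (taken from `grid`'s node coordinates) sits
#' at `origin + x * e1 + y * e2` in volume coordinates.
#'
#' @param origin Numeric length-3 point (m).
#' @param e1,e2 Numeric length-3 in-plane direction vectors; must be
#'   orthonormal to 1e-12.
#' @param grid A 2D [grid_spec()] for the plane.
#' @return An object of class `plane_def`.
#' @export
plane_def <- function(origin, e1, e2, grid) {
  stopifnot(length(origin) == 3, length(e1) == 3, length(e2) == 3,
            inherits(grid, "grid_spec"), is.null(grid$nz))
  if (abs(sqrt(sum(e1^2)) - 1) > 1e-12 || abs(sqrt(sum(e2^2)) - 1) > 1e-12 ||
      abs(sum(e1 * e2)) > 1e-12)
    stop("e1 and e2 must be orthonormal (unit length, perpendicular)")
  structure(list(origin = as.numeric(origin), e1 = as.numeric(e1),
                 e2 = as.numeric(e2), grid = grid),
            class = "plane_def")
}

# trilinear interpolation of 3D array A at points (px, py, pz); returns
# values (NA outside) and whether any of the 8 stencil corners satisfies
# `corner_any` (a logical array, e.g. the voxel mask)
trilinear_sample <- function(A, grid3, px, py, pz, corner_any = NULL) {
  gx <- (px - grid3$origin[1]) / grid3$dx + 1
  gy <- (py - grid3$origin[2]) / grid3$dy + 1
  gz <- (pz - grid3$origin[3]) / grid3$dz + 1
  gx[abs(gx - grid3$nx) < 1e-9] <- grid3$nx - 1e-9
  gy[abs(gy - grid3$ny) < 1e-9] <- grid3$ny - 1e-9
  gz[abs(gz - grid3$nz) < 1e-9] <- grid3$nz - 1e-9
  j0 <- floor(gx); i0 <- floor(gy); k0 <- floor(gz)
  fx <- gx - j0; fy <- gy - i0; fz <- gz - k0
  ok <- j0 >= 1 & j0 <= grid3$nx - 1 & i0 >= 1 & i0 <= grid3$ny - 1 &
    k0 >= 1 & k0 <= grid3$nz - 1
  vals <- rep(NA_real_, length(px))
  any_corner <- rep(FALSE, length(px))
  idx <- which(ok)
  if (length(idx)) {
    ny <- grid3$ny; nx <- grid3$nx
    lin <- function(i, j, k) i + ny * (j - 1L) + ny * nx * (k - 1L)
    i0i <- i0[idx]; j0i <- j0[idx]; k0i <- k0[idx]
    fxi <- fx[idx]; fyi <- fy[idx]; fzi <- fz[idx]
    acc <- numeric(length(idx))
    anyc <- logical(length(idx))
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      w <- (if (di) fyi else 1 - fyi) * (if (dj) fxi else 1 - fxi) *
        (if (dk) fzi else 1 - fzi)
      at <- lin(i0i + di, j0i + dj, k0i + dk)
      acc <- acc + w * A[at]
      if (!is.null(corner_any)) anyc <- anyc | corner_any[at]
    }
    vals[idx] <- acc
    any_corner[idx] <- anyc
  }
  list(values = vals, any_corner = any_corner, inside = ok)
}

#' Project a volumetric velocity series onto a plane
#'
#' Linearly (trilinearly) interpolates the three velocity components of a
#' volumetric series at the plane's nodes and keeps the two in-plane
#' projections (dot products with the plane's direction vectors); the
#' through-plane component is discarded. Plane nodes whose 8-voxel
#' interpolation stencil contains no masked voxel, or which fall outside the
#' volume, are unmasked.
#'
#' @param volume A [volume_velocity_series()].
#' @param plane A [plane_def()].
#' @return A [planar_velocity_series()] on the plane's grid.
#' @export
project_to_plane <- function(volume, plane) {
  stopifnot(inherits(volume, "volume_velocity_series"),
            inherits(plane, "plane_def"))
  g2 <- plane$grid
  xy <- grid_xy(g2)
  px <- plane$origin[1] + xy$x * plane$e1[1] + xy$y * plane$e2[1]
  py <- plane$origin[2] + xy$x * plane$e1[2] + xy$y * plane$e2[2]
  pz <- plane$origin[3] + xy$x * plane$e1[3] + xy$y * plane$e2[3]
  nt <- n_frames(volume)
  vel <- array(0, c(g2$ny, g2$nx, 2, nt))
  mask <- array(FALSE, c(g2$ny, g2$nx, nt))
  any_inside <- FALSE
  for (i in seq_len(nt)) {
    m3 <- volume$mask[, , , i]
    comps <- lapply(1:3, function(k)
      trilinear_sample(volume$velocity[, , , k, i], volume$grid,
                       px, py, pz, corner_any = m3))
    v3x <- comps[[1]]$values; v3y <- comps[[2]]$values
    v3z <- comps[[3]]$values
    ok <- comps[[1]]$inside & comps[[1]]$any_corner
    any_inside <- any_inside || any(comps[[1]]$inside)
    u1 <- v3x * plane$e1[1] + v3y * plane$e1[2] + v3z * plane$e1[3]
    u2 <- v3x * plane$e2[1] + v3y * plane$e2[2] + v3z * plane$e2[3]
    u1[!ok | is.na(u1)] <- 0
    u2[!ok | is.na(u2)] <- 0
    vel[, , 1, i] <- u1
    vel[, , 2, i] <- u2
    mask[, , i] <- matrix(ok, g2$ny, g2$nx)
  }
  if (!any_inside)
    stop("plane lies entirely outside the volume")
  planar_velocity_series(g2, volume$times, vel, mask,
                         period = volume$period, periodic = volume$periodic)
}
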