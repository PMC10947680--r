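#' Regular grid specification
#'
#' Describes a node-centered regular 2D (or 3D) grid in physical units.
#' Planar fields are stored as matrices with y along rows and x along
#' columns, so a field `F` has `dim(F) == c(ny, nx)`; node `(iy, ix)` sits at
#' `(x0 + (ix-1)*dx, y0 + (iy-1)*dy)` in meters. Volumetric grids add a third
#' index for z.
#'
#' @param nx,ny Node counts along x and y (both at least 8).
#' @param dx,dy Node spacings in meters (positive).
#' @param origin Numeric length-2 (or 3) vector, coordinates of node (1,1)
#'   in meters.
#' @param nz,dz Optional node count and spacing along z for volumetric grids.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(64, 64, 1e-3, 1e-3)
#' range(grid_x(g))
#' @export
grid_spec <- function(nx, ny, dx, dy, origin = c(0, 0), nz = NULL, dz = NULL) {
  stopifnot(nx >= 8, ny >= 8, dx > 0, dy > 0)
  is3d <- !is.null(nz)
  if (is3d) {
    stopifnot(nz >= 2, !is.null(dz), dz > 0)
    if (length(origin) == 2) origin <- c(origin, 0)
  }
  g <- list(nx = as.integer(nx), ny = as.integer(ny),
            dx = as.numeric(dx), dy = as.numeric(dy),
            origin = as.numeric(origin))
  if (is3d) {
    g$nz <- as.integer(nz)
    g$dz <- as.numeric(dz)
  }
  structure(g, class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  dims <- if (is.null(x$nz)) sprintf("%d x %d", x$nx, x$ny)
          else sprintf("%d x %d x %d", x$nx, x$ny, x$nz)
  sp <- if (is.null(x$nz)) sprintf("dx=%g dy=%g m", x$dx, x$dy)
        else sprintf("dx=%g dy=%g dz=%g m", x$dx, x$dy, x$dz)
  cat("<grid_spec>", dims, "nodes,", sp, "\n")
  invisible(x)
}

#' Node coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return `grid_x`/`grid_y`/`grid_z`: vector of node coordinates (m).
#'   `grid_xy`: list with matrices `x`, `y` of shape `c(ny, nx)`.
#' @export
grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx

#' @rdname grid_x
#' @export
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy

#' @rdname grid_x
#' @export
grid_z <- function(grid) {
  stopifnot(!is.null(grid$nz))
  grid$origin[3] + (seq_len(grid$nz) - 1) * grid$dz
}

#' @rdname grid_x
#' @export
grid_xy <- function(grid) {
  list(x = matrix(grid_x(grid), grid$ny, grid$nx, byrow = TRUE),
       y = matrix(grid_y(grid), grid$ny, grid$nx))
}

#' Cell area element dS (m^2), or volume element dV (m^3) for 3D grids
#' @param grid A [grid_spec()].
#' @export
grid_dS <- function(grid) {
  if (is.null(grid$nz)) grid$dx * grid$dy else grid$dx * grid$dy * grid$dz
}

is_grid3d <- function(grid) !is.null(grid$nz)
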