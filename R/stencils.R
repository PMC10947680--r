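# Masked finite differences on node-centered regular grids.
#
# Policy used by every differential operator in the package: second-order
# central differences wherever both stencil neighbors are masked; second-order
# one-sided (3-point) stencils where only one side is available; nodes with
# insufficient masked neighbors are marked invalid. Second derivatives fall
# back to a one-sided 3-point stencil (first-order) at mask boundaries.

# shifted copy: out[i, j] = F[i + di, j + dj], `fill` outside the grid
shift_mat <- function(F, di, dj, fill = NA) {
  ny <- nrow(F); nx <- ncol(F)
  out <- matrix(fill, ny, nx)
  rows <- seq_len(ny); cols <- seq_len(nx)
  src_r <- rows + di; src_c <- cols + dj
  ok_r <- src_r >= 1L & src_r <= ny
  ok_c <- src_c >= 1L & src_c <= nx
  out[rows[ok_r], cols[ok_c]] <- F[src_r[ok_r], src_c[ok_c]]
  out
}

# first derivative of F along x (dj) or y (di) under a mask
masked_deriv <- function(F, mask, h, along = c("x", "y")) {
  along <- match.arg(along)
  s <- function(k) if (along == "x") shift_mat(F, 0L, k, 0) else shift_mat(F, k, 0L, 0)
  m <- function(k) if (along == "x") shift_mat(mask, 0L, k, FALSE) else shift_mat(mask, k, 0L, FALSE)
  Fp1 <- s(1L); Fm1 <- s(-1L); Fp2 <- s(2L); Fm2 <- s(-2L)
  Mp1 <- m(1L); Mm1 <- m(-1L); Mp2 <- m(2L); Mm2 <- m(-2L)
  cen <- mask & Mp1 & Mm1
  fwd <- mask & !cen & Mp1 & Mp2
  bwd <- mask & !cen & !fwd & Mm1 & Mm2
  d <- matrix(NA_real_, nrow(F), ncol(F))
  d[cen] <- (Fp1[cen] - Fm1[cen]) / (2 * h)
  d[fwd] <- (-3 * F[fwd] + 4 * Fp1[fwd] - Fp2[fwd]) / (2 * h)
  d[bwd] <- (3 * F[bwd] - 4 * Fm1[bwd] + Fm2[bwd]) / (2 * h)
  list(d = d, valid = cen | fwd | bwd, central = cen)
}

# second derivative along one axis; central where possible, else one-sided
masked_second_deriv <- function(F, mask, h, along = c("x", "y")) {
  along <- match.arg(along)
  s <- function(k) if (along == "x") shift_mat(F, 0L, k, 0) else shift_mat(F, k, 0L, 0)
  m <- function(k) if (along == "x") shift_mat(mask, 0L, k, FALSE) else shift_mat(mask, k, 0L, FALSE)
  Fp1 <- s(1L); Fm1 <- s(-1L); Fp2 <- s(2L); Fm2 <- s(-2L)
  Mp1 <- m(1L); Mm1 <- m(-1L); Mp2 <- m(2L); Mm2 <- m(-2L)
  cen <- mask & Mp1 & Mm1
  fwd <- mask & !cen & Mp1 & Mp2
  bwd <- mask & !cen & !fwd & Mm1 & Mm2
  d <- matrix(NA_real_, nrow(F), ncol(F))
  d[cen] <- (Fp1[cen] - 2 * F[cen] + Fm1[cen]) / h^2
  d[fwd] <- (F[fwd] - 2 * Fp1[fwd] + Fp2[fwd]) / h^2
  d[bwd] <- (F[bwd] - 2 * Fm1[bwd] + Fm2[bwd]) / h^2
  list(d = d, valid = cen | fwd | bwd, central = cen)
}

#' Discrete divergence of a planar velocity frame
#'
#' Computes dvx/dx + dvy/dy with the package's standard stencil policy.
#' Used mainly to verify that generated fields are (discretely)
#' divergence-free.
#'
#' @param v Velocity array `c(ny, nx, 2)`.
#' @param mask Logical matrix `c(ny, nx)` restricting the stencils.
#' @param grid A [grid_spec()].
#' @return A [scalar_field_frame()]-like list with `values` (1/s) and `valid`;
#'   `central` marks nodes where both derivatives used central stencils.
#' @export
divergence_field <- function(v, mask, grid) {
  du <- masked_deriv(v[, , 1], mask, grid$dx, "x")
  dv <- masked_deriv(v[, , 2], mask, grid$dy, "y")
  vals <- du$d + dv$d
  list(values = vals, valid = du$valid & dv$valid,
       central = du$central & dv$central)
}

# derivative of a 3D array along dim 1 (y), 2 (x) or 3 (z), central +
# one-sided policy as in masked_deriv
masked_deriv3 <- function(F, mask, h, dim) {
  dims <- dim(F)
  shift3 <- function(A, k, fill) {
    out <- array(fill, dims)
    n <- dims[dim]
    src <- seq_len(n) + k
    ok <- src >= 1L & src <= n
    idx_to <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    idx_from <- idx_to
    idx_to[[dim]] <- which(ok)
    idx_from[[dim]] <- src[ok]
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      A[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    out
  }
  Fp1 <- shift3(F, 1L, 0); Fm1 <- shift3(F, -1L, 0)
  Fp2 <- shift3(F, 2L, 0); Fm2 <- shift3(F, -2L, 0)
  Mp1 <- shift3(mask, 1L, FALSE); Mm1 <- shift3(mask, -1L, FALSE)
  Mp2 <- shift3(mask, 2L, FALSE); Mm2 <- shift3(mask, -2L, FALSE)
  cen <- mask & Mp1 & Mm1
  fwd <- mask & !cen & Mp1 & Mp2
  bwd <- mask & !cen & !fwd & Mm1 & Mm2
  d <- array(NA_real_, dims)
  d[cen] <- (Fp1[cen] - Fm1[cen]) / (2 * h)
  d[fwd] <- (-3 * F[fwd] + 4 * Fp1[fwd] - Fp2[fwd]) / (2 * h)
  d[bwd] <- (3 * F[bwd] - 4 * Fm1[bwd] + Fm2[bwd]) / (2 * h)
  list(d = d, valid = cen | fwd | bwd)
}

# largest 4-connected component of a logical matrix (flood fill)
largest_component <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  sizes <- integer(0)
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    n_in <- 0L
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      n_in <- n_in + 1L
      i <- ((p - 1L) %% ny) + 1L
      j <- ((p - 1L) %/% ny) + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < ny) p + 1L,
              if (j > 1L) p - ny, if (j < nx) p + ny)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
    sizes[cur] <- n_in
  }
  if (cur == 0L) return(mask)  # empty mask unchanged
  lab == which.max(sizes)
}
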