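# The five intracardiac flow parameters: inflow velocity |V|, relative
# pressure / IVPD, vortex strength, total kinetic energy, viscous energy
# loss, computed from a masked planar velocity series.

#' Blood properties
#'
#' @param rho Density (kg/m^3). Default 1060, the standard value for whole
#'   blood.
#' @param mu Dynamic viscosity (Pa s). Default 0.004, standard for blood at
#'   physiological shear rates.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu = 0.004) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

PA_PER_MMHG <- 133.322

#' Vorticity of a planar velocity frame
#'
#' `omega = dvy/dx - dvx/dy` by second-order central differences at interior
#' masked nodes, with second-order one-sided stencils where a neighbor is
#' unmasked; nodes with insufficient masked neighbors are invalid. For a
#' solid-body rotation at rate `omega0` the result is exactly `2 * omega0`
#' (the stencils are exact on linear fields).
#'
#' @param series A [planar_velocity_series()].
#' @param frame Frame index.
#' @return A [scalar_field_frame()] with quantity `"vorticity"` (1/s).
#' @export
vorticity <- function(series, frame = 1L) {
  g <- series$grid
  m <- frame_mask(series, frame)
  v <- frame_velocity(series, frame)
  dvy_dx <- masked_deriv(v[, , 2], m, g$dx, "x")
  dvx_dy <- masked_deriv(v[, , 1], m, g$dy, "y")
  valid <- dvy_dx$valid & dvx_dy$valid
  w <- dvy_dx$d - dvx_dy$d
  w[!valid] <- NA_real_
  scalar_field_frame(g, w, valid, series$times[frame], "vorticity")
}

#' Vortex strength: integral of |vorticity| over the chamber
#'
#' `VS = sum(|omega|) * dS` over valid masked nodes — a surrogate for the
#' total fluid rotation of all vortex cores; opposite-signed cores add, they
#' do not cancel. For a well-resolved isolated Gaussian-core vortex of
#' circulation `Gamma` on a sufficiently large domain, VS converges to
#' `|Gamma|`.
#'
#' @param omega A [scalar_field_frame()] of vorticity.
#' @param mask Optional logical matrix further restricting the integral
#'   (defaults to the field's valid mask).
#' @return Vortex strength in m^2/s.
#' @export
vortex_strength <- function(omega, mask = NULL) {
  stopifnot(inherits(omega, "scalar_field_frame"),
            omega$quantity == "vorticity")
  sel <- omega$valid
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) {
    warning("vortex_strength: empty mask, returning 0")
    return(0)
  }
  sum(abs(omega$values[sel])) * grid_dS(omega$grid)
}

# strain-rate dissipation density at each node: 1/2 mu sum_ij (dvi/dxj + dvj/dxi)^2
dissipation_density <- function(v, mask, grid, mu) {
  ux <- masked_deriv(v[, , 1], mask, grid$dx, "x")
  uy <- masked_deriv(v[, , 1], mask, grid$dy, "y")
  vx <- masked_deriv(v[, , 2], mask, grid$dx, "x")
  vy <- masked_deriv(v[, , 2], mask, grid$dy, "y")
  valid <- ux$valid & uy$valid & vx$valid & vy$valid
  phi <- 0.5 * mu * ((2 * ux$d)^2 + (2 * vy$d)^2 + 2 * (uy$d + vx$d)^2)
  phi[!valid] <- NA_real_
  list(values = phi, valid = valid, div = ux$d + vy$d)
}

#' Viscous energy loss over the chamber
#'
#' `VEL = integral of 1/2 mu sum_ij (dvi/dxj + dvj/dxi)^2` over the masked
#' chamber (per unit out-of-plane thickness in 2D). The expression assumes a
#' divergence-free field; a warning is emitted when the discrete divergence
#' exceeds `div_tol` times peak speed / min(dx, dy). The default tolerance
#' (2%) accommodates the one-sided boundary stencils of solenoidal fields
#' while still flagging genuinely compressible input. Exactly zero for rigid
#' rotation (vanishing strain rate); `mu * gamma^2 * A` for a uniform shear
#' `v = (gamma * y, 0)` over area `A`.
#'
#' @param series A [planar_velocity_series()].
#' @param frame Frame index.
#' @param props [fluid_properties()].
#' @param div_tol Relative divergence tolerance for the warning check.
#' @return Viscous energy loss in W (per meter thickness).
#' @export
viscous_energy_loss <- function(series, frame = 1L, props = fluid_properties(),
                                div_tol = 0.02) {
  g <- series$grid
  m <- frame_mask(series, frame)
  if (!any(m)) return(0)
  v <- frame_velocity(series, frame)
  dd <- dissipation_density(v, m, g, props$mu)
  pk <- max(sqrt(v[, , 1]^2 + v[, , 2]^2)[m])
  if (pk > 0) {
    dv <- abs(dd$div[dd$valid])
    if (length(dv) && max(dv) > div_tol * pk / min(g$dx, g$dy))
      warning(sprintf("viscous_energy_loss: field is not divergence-free (max |div| = %g 1/s)",
                      max(dv)))
  }
  sum(dd$values[dd$valid & m]) * grid_dS(g)
}

#' Total kinetic energy over the chamber
#'
#' `KET = sum(1/2 rho |v|^2) * dS` over masked nodes (per unit out-of-plane
#' thickness in 2D).
#'
#' @inheritParams viscous_energy_loss
#' @return Kinetic energy in J (per meter thickness).
#' @export
kinetic_energy <- function(series, frame = 1L, props = fluid_properties()) {
  g <- series$grid
  m <- frame_mask(series, frame)
  if (!any(m)) return(0)
  v <- frame_velocity(series, frame)
  ke <- 0.5 * props$rho * (v[, , 1]^2 + v[, , 2]^2)
  sum(ke[m]) * grid_dS(g)
}

# masked nodes within `depth` of the valve segment on the chamber (apex) side
inflow_band <- function(grid, mask, lm) {
  xy <- grid_xy(grid)
  a <- lm$valve_a; b <- lm$valve_b
  ab <- b - a
  len2 <- sum(ab^2)
  # projection parameter along the segment and perpendicular offset
  tpar <- ((xy$x - a[1]) * ab[1] + (xy$y - a[2]) * ab[2]) / len2
  perpx <- xy$x - (a[1] + tpar * ab[1])
  perpy <- xy$y - (a[2] + tpar * ab[2])
  dist <- sqrt(perpx^2 + perpy^2)
  # unit normal pointing toward the apex
  nrm <- c(-ab[2], ab[1]) / sqrt(len2)
  apex_side <- sum((lm$apex - a) * nrm)
  if (apex_side < 0) nrm <- -nrm
  side <- perpx * nrm[1] + perpy * nrm[2]
  mask & tpar >= 0 & tpar <= 1 & side >= 0 & dist <= lm$inflow_depth
}

#' Inflow velocity: upper quantile of speed in the trans-valvular band
#'
#' Speed `|v|` is sampled over the masked nodes within `inflow_depth`
#' (default 1 cm) of the valve line on the chamber side, and summarized as
#' its 97.5% quantile (linear-interpolation definition) per frame — a robust
#' stand-in for the peak inflow-jet velocity.
#'
#' @param series A [planar_velocity_series()].
#' @param frame Frame index.
#' @param lm [landmarks()]; defaults to the series' own landmarks.
#' @param prob Quantile level (default 0.975).
#' @return Inflow velocity in m/s; `NA` (with a message) if the band contains
#'   no masked node.
#' @export
inflow_velocity <- function(series, frame = 1L, lm = series$landmarks,
                            prob = 0.975) {
  if (is.null(lm)) stop("inflow_velocity requires landmarks")
  m <- frame_mask(series, frame)
  band <- inflow_band(series$grid, m, lm)
  if (!any(band)) {
    message(sprintf("inflow_velocity: empty inflow band at frame %d", frame))
    return(NA_real_)
  }
  v <- frame_velocity(series, frame)
  sp <- sqrt(v[, , 1]^2 + v[, , 2]^2)[band]
  unname(stats::quantile(sp, prob, type = 7))
}

#' Pressure gradient from the Navier-Stokes momentum balance
#'
#' Evaluates `dP/dxi = -rho (dui/dt + uj dui/dxj) + mu d2ui/dxj dxj` at
#' masked nodes: local acceleration by central differences in time (with
#' periodic wrap for a phase-averaged single beat, one-sided at the ends
#' otherwise), convection and the viscous Laplacian by the package's masked
#' spatial stencils. Density multiplies the inertial terms and viscosity the
#' Laplacian, as in the incompressible momentum equation.
#'
#' @param series A [planar_velocity_series()] with at least 3 frames.
#' @param frame Frame index.
#' @param props [fluid_properties()].
#' @return List with matrices `gx`, `gy` (Pa/m) and logical `valid`.
#' @export
pressure_gradient_nse <- function(series, frame = 1L,
                                  props = fluid_properties()) {
  nt <- n_frames(series)
  if (nt < 3)
    stop("pressure_gradient_nse needs >= 3 frames for the temporal derivative")
  g <- series$grid
  m <- frame_mask(series, frame)
  v <- frame_velocity(series, frame)
  tt <- series$times

  # du/dt: central in time (periodic wrap when the series is one cycle)
  dudt <- matrix(0, g$ny, g$nx); dvdt <- dudt
  if (series$periodic && !is.null(series$period)) {
    ip <- if (frame == 1L) nt else frame - 1L
    im <- if (frame == nt) 1L else frame + 1L
    t_prev <- if (frame == 1L) tt[nt] - series$period else tt[frame - 1L]
    t_next <- if (frame == nt) tt[1L] + series$period else tt[frame + 1L]
    dt2 <- t_next - t_prev
    dudt <- (series$velocity[, , 1, im] - series$velocity[, , 1, ip]) / dt2
    dvdt <- (series$velocity[, , 2, im] - series$velocity[, , 2, ip]) / dt2
  } else if (frame == 1L) {
    dt <- tt[2] - tt[1]
    dudt <- (series$velocity[, , 1, 2] - series$velocity[, , 1, 1]) / dt
    dvdt <- (series$velocity[, , 2, 2] - series$velocity[, , 2, 1]) / dt
  } else if (frame == nt) {
    dt <- tt[nt] - tt[nt - 1]
    dudt <- (series$velocity[, , 1, nt] - series$velocity[, , 1, nt - 1]) / dt
    dvdt <- (series$velocity[, , 2, nt] - series$velocity[, , 2, nt - 1]) / dt
  } else {
    dt2 <- tt[frame + 1] - tt[frame - 1]
    dudt <- (series$velocity[, , 1, frame + 1] - series$velocity[, , 1, frame - 1]) / dt2
    dvdt <- (series$velocity[, , 2, frame + 1] - series$velocity[, , 2, frame - 1]) / dt2
  }

  ux <- masked_deriv(v[, , 1], m, g$dx, "x"); uy <- masked_deriv(v[, , 1], m, g$dy, "y")
  vx <- masked_deriv(v[, , 2], m, g$dx, "x"); vy <- masked_deriv(v[, , 2], m, g$dy, "y")
  uxx <- masked_second_deriv(v[, , 1], m, g$dx, "x")
  uyy <- masked_second_deriv(v[, , 1], m, g$dy, "y")
  vxx <- masked_second_deriv(v[, , 2], m, g$dx, "x")
  vyy <- masked_second_deriv(v[, , 2], m, g$dy, "y")

  valid <- m & ux$valid & uy$valid & vx$valid & vy$valid &
    uxx$valid & uyy$valid & vxx$valid & vyy$valid
  u <- v[, , 1]; w <- v[, , 2]
  gx <- -props$rho * (dudt + u * ux$d + w * uy$d) + props$mu * (uxx$d + uyy$d)
  gy <- -props$rho * (dvdt + u * vx$d + w * vy$d) + props$mu * (vxx$d + vyy$d)
  gx[!valid] <- NA_real_
  gy[!valid] <- NA_real_
  list(gx = gx, gy = gy, valid = valid)
}

# SOC gradient rows for unknowns `nodes` (index matrix positions within the
# component mask); returns sparse triplets for one direction
build_gradient_rows <- function(comp, grid, along = c("x", "y")) {
  along <- match.arg(along)
  ny <- grid$ny; nx <- grid$nx
  h <- if (along == "x") grid$dx else grid$dy
  id <- matrix(0L, ny, nx)
  nodes <- which(comp)
  id[nodes] <- seq_along(nodes)
  nb <- function(k) {
    if (along == "x") shift_mat(id, 0L, k, 0L) else shift_mat(id, k, 0L, 0L)
  }
  idp1 <- nb(1L); idm1 <- nb(-1L); idp2 <- nb(2L); idm2 <- nb(-2L)
  cen <- comp & idp1 > 0 & idm1 > 0
  fwd <- comp & !cen & idp1 > 0 & idp2 > 0
  bwd <- comp & !cen & !fwd & idm1 > 0 & idm2 > 0
  rows_i <- integer(0); cols_j <- integer(0); vals <- numeric(0)
  at <- integer(0)  # node (matrix index) each row differentiates at
  add <- function(sel, stencil_ids, coefs) {
    n <- sum(sel)
    if (!n) return()
    r0 <- length(at)
    for (s in seq_along(stencil_ids)) {
      rows_i <<- c(rows_i, r0 + seq_len(n))
      cols_j <<- c(cols_j, stencil_ids[[s]][sel])
      vals <<- c(vals, rep(coefs[s], n))
    }
    at <<- c(at, which(sel))
  }
  add(cen, list(idm1, idp1), c(-1, 1) / (2 * h))
  add(fwd, list(id, idp1, idp2), c(-3, 4, -1) / (2 * h))
  add(bwd, list(id, idm1, idm2), c(3, -4, 1) / (2 * h))
  list(i = rows_i, j = cols_j, x = vals, at = at, n_unknown = length(nodes),
       nodes = nodes)
}

#' Integrate a pressure-gradient field by weighted least squares
#'
#' Solves `min || W (G p - g) ||_2` where `G` is the masked discrete gradient
#' operator built with the second-order central (SOC) scheme (second-order
#' one-sided rows at mask boundaries) and `g` the evaluated pressure-gradient
#' samples. The diagonal weights are `w_i = 1 / (eps_w + c_i)` with `c_i` the
#' local curl magnitude of the evaluated gradient normalized by its masked
#' median — a true pressure gradient is curl-free, so the local curl flags
#' locally inconsistent (error-prone) samples and down-weights them. The
#' gauge is fixed by zero spatial mean over the mask. Only the largest
#' 4-connected component of the mask is solved (others are reported).
#'
#' @param gradient List with `gx`, `gy`, `valid` as returned by
#'   [pressure_gradient_nse()].
#' @param grid A [grid_spec()].
#' @param mask Logical chamber mask.
#' @param time Time stamp for the output frame (s).
#' @param weighting `"curl"` (default) or `"identity"` (ordinary least
#'   squares), or a user-supplied numeric matrix of positive node weights.
#' @param eps_w Weight floor relative to the median curl magnitude.
#' @return List with `pressure` (a [scalar_field_frame()], Pa, zero-mean
#'   gauge) and `system` (class `wls_system`: sparse `G`, `rhs`, `weights`,
#'   solved `p`, `residual_norm`).
#' @export
integrate_pressure_wls <- function(gradient, grid, mask, time = NA_real_,
                                   weighting = "curl", eps_w = 1e-2) {
  comp_all <- mask & gradient$valid
  comp <- largest_component(comp_all)
  dropped <- sum(comp_all) - sum(comp)
  if (dropped > 0)
    message(sprintf("integrate_pressure_wls: %d node(s) outside the largest connected component ignored",
                    dropped))
  if (sum(comp) < 4)
    stop("integrate_pressure_wls: masked gradient region too small to integrate")

  rx <- build_gradient_rows(comp, grid, "x")
  ry <- build_gradient_rows(comp, grid, "y")
  n_un <- rx$n_unknown
  Gx <- Matrix::sparseMatrix(i = rx$i, j = rx$j, x = rx$x,
                             dims = c(length(rx$at), n_un))
  Gy <- Matrix::sparseMatrix(i = ry$i, j = ry$j, x = ry$x,
                             dims = c(length(ry$at), n_un))
  G <- rbind(Gx, Gy)
  rhs <- c(gradient$gx[rx$at], gradient$gy[ry$at])

  # node weights from the curl of the evaluated gradient field
  if (is.matrix(weighting)) {
    wnode <- weighting
  } else if (identical(weighting, "identity")) {
    wnode <- matrix(1, grid$ny, grid$nx)
  } else {
    gx <- gradient$gx; gx[!comp] <- NA_real_
    gy <- gradient$gy; gy[!comp] <- NA_real_
    dgy_dx <- masked_deriv(ifelse(comp, gy, 0), comp, grid$dx, "x")
    dgx_dy <- masked_deriv(ifelse(comp, gx, 0), comp, grid$dy, "y")
    curl <- abs(dgy_dx$d - dgx_dy$d)
    cm <- stats::median(curl[comp & dgy_dx$valid & dgx_dy$valid], na.rm = TRUE)
    cn <- matrix(1, grid$ny, grid$nx)
    okc <- comp & dgy_dx$valid & dgx_dy$valid & is.finite(curl)
    if (is.finite(cm) && cm > 0) cn[okc] <- curl[okc] / cm
    wnode <- 1 / (eps_w + cn)
  }
  wrow <- c(wnode[rx$at], wnode[ry$at])
  stopifnot(all(wrow > 0))

  # gauge: the gradient rows are blind to the constant mode, so pin a single
  # node (keeps the normal equations sparse); the residual is gauge-invariant
  # and the zero-mean gauge is restored exactly after the solve
  pin_w <- max(abs(rx$x)) * mean(wrow)
  gauge <- Matrix::sparseMatrix(i = 1L, j = 1L, x = pin_w,
                                dims = c(1L, n_un))
  Gw <- rbind(G * wrow, gauge)
  bw <- c(rhs * wrow, 0)
  A <- Matrix::crossprod(Gw)
  b <- Matrix::crossprod(Gw, bw)
  p <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e)
                  stop(paste0("integrate_pressure_wls: normal equations are ",
                              "singular (disconnected or degenerate mask): ",
                              conditionMessage(e))))
  p <- p - mean(p)  # enforce the zero-mean gauge exactly
  resid <- sqrt(sum((wrow * (as.numeric(G %*% p) - rhs))^2))

  vals <- matrix(NA_real_, grid$ny, grid$nx)
  vals[rx$nodes] <- p
  valid <- comp
  pressure <- scalar_field_frame(grid, vals, valid, time, "pressure")
  system <- structure(list(G = G, rhs = rhs, weights = wrow, p = p,
                           residual_norm = resid, nodes = rx$nodes),
                      class = "wls_system")
  list(pressure = pressure, system = system)
}

#' @export
print.wls_system <- function(x, ...) {
  cat(sprintf("<wls_system> %d gradient rows, %d unknowns, weighted residual norm %g\n",
              nrow(x$G), ncol(x$G), x$residual_norm))
  invisible(x)
}

#' Intraventricular pressure difference (tricuspid valve minus apex)
#'
#' `IVPD = P_TV - P_Apex` in mmHg: the mean reconstructed relative pressure
#' over the 3x3 valid neighborhood of the valve-line midpoint minus the mean
#' over the 3x3 neighborhood of the apex. Differences are gauge-free, so the
#' reconstruction gauge does not matter.
#'
#' @param pressure A [scalar_field_frame()] of relative pressure (Pa).
#' @param lm [landmarks()].
#' @return IVPD in mmHg.
#' @export
ivpd <- function(pressure, lm) {
  stopifnot(inherits(pressure, "scalar_field_frame"),
            pressure$quantity == "pressure")
  g <- pressure$grid
  sample_site <- function(pt, name) {
    j <- round((pt[1] - g$origin[1]) / g$dx) + 1
    i <- round((pt[2] - g$origin[2]) / g$dy) + 1
    ii <- max(1, i - 1):min(g$ny, i + 1)
    jj <- max(1, j - 1):min(g$nx, j + 1)
    block <- pressure$values[ii, jj, drop = FALSE]
    vb <- pressure$valid[ii, jj, drop = FALSE]
    if (!any(vb))
      stop(sprintf("ivpd: no valid pressure near the %s landmark at (%g, %g) m",
                   name, pt[1], pt[2]))
    mean(block[vb])
  }
  # sample just inside the chamber from the valve midpoint
  mid <- (lm$valve_a + lm$valve_b) / 2
  (sample_site(mid, "tricuspid valve") - sample_site(lm$apex, "apex")) /
    PA_PER_MMHG
}

#' Per-frame hemodynamic parameter timeseries
#'
#' Runs the full parameter chain over a preprocessed single-beat series:
#' inflow velocity from the trans-valvular band, IVPD through the
#' Navier-Stokes gradient and weighted-least-squares pressure integration,
#' and vortex strength / kinetic energy / viscous energy loss as their
#' chamber integrals divided by the frame's masked area (indexed densities),
#' which makes planar and volumetric magnitudes comparable. A frame whose
#' pressure chain fails is marked `NA` rather than aborting the series.
#'
#' @param series A single-beat [planar_velocity_series()] (>= 3 frames).
#' @param lm [landmarks()]; defaults to the series' own.
#' @param props [fluid_properties()].
#' @param weighting Passed to [integrate_pressure_wls()].
#' @return A `data.frame` of class `hemo_timeseries` with columns `phase`,
#'   `time_s`, `inflow_v_mps`, `ivpd_mmhg`, `vs_indexed_per_s`,
#'   `ket_indexed_J_per_m3`, `vel_indexed_W_per_m3`,
#'   `denom_area_m2_or_vol_m3`.
#' @export
compute_timeseries <- function(series, lm = series$landmarks,
                               props = fluid_properties(),
                               weighting = "curl") {
  nt <- n_frames(series)
  Tc <- if (!is.null(series$period)) series$period
        else diff(range(series$times))
  dS <- grid_dS(series$grid)
  out <- data.frame(phase = (series$times - series$times[1]) / Tc,
                    time_s = series$times,
                    inflow_v_mps = NA_real_, ivpd_mmhg = NA_real_,
                    vs_indexed_per_s = NA_real_,
                    ket_indexed_J_per_m3 = NA_real_,
                    vel_indexed_W_per_m3 = NA_real_,
                    denom_area_m2_or_vol_m3 = NA_real_)
  for (i in seq_len(nt)) {
    m <- frame_mask(series, i)
    area <- sum(m) * dS
    out$denom_area_m2_or_vol_m3[i] <- area
    if (area <= 0) next
    res <- try({
      om <- vorticity(series, i)
      out$vs_indexed_per_s[i] <- vortex_strength(om) / area
      out$ket_indexed_J_per_m3[i] <- kinetic_energy(series, i, props) / area
      out$vel_indexed_W_per_m3[i] <-
        suppressWarnings(viscous_energy_loss(series, i, props)) / area
      if (!is.null(lm))
        out$inflow_v_mps[i] <- inflow_velocity(series, i, lm)
      grad <- pressure_gradient_nse(series, i, props)
      pw <- integrate_pressure_wls(grad, series$grid, m,
                                   time = series$times[i],
                                   weighting = weighting)
      if (!is.null(lm)) out$ivpd_mmhg[i] <- ivpd(pw$pressure, lm)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      message(sprintf("compute_timeseries: frame %d failed (%s); marked invalid",
                      i, attr(res, "condition")$message))
    }
  }
  class(out) <- c("hemo_timeseries", "data.frame")
  attr(out, "period") <- Tc
  out
}
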