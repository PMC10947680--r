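# Cleaning, denoising, phase-averaging and resampling of velocity series so
# that two modalities become comparable on a common single-beat time base.

#' Universal outlier detection (normalized median test)
#'
#' Flags spurious velocity vectors per frame. For each component, a node is
#' spurious when its normalized median residual
#' `r* = |v - median(neighbors)| / (median(|neighbors - median|) + eps)`
#' exceeds `threshold`; a node flagged in any component is flagged. Neighbors
#' are the masked nodes in the `window x window` box (excluding the center);
#' nodes with fewer than 3 masked neighbors are never flagged. The defaults
#' (3x3 window, threshold 2, eps = 0.1 m/s) are the standard configuration of
#' the normalized median test.
#'
#' @param series A [planar_velocity_series()] or [volume_velocity_series()].
#' @param window Odd window edge length in nodes (>= 3).
#' @param threshold Dimensionless detection threshold (> 0).
#' @param eps Velocity noise floor in m/s added to the residual denominator.
#' @return Logical array of flagged nodes with the shape of `series$mask`.
#' @export
detect_outliers_uod <- function(series, window = 3L, threshold = 2,
                                eps = 0.1) {
  stopifnot(window >= 3, window %% 2 == 1, threshold > 0, eps >= 0)
  h <- (window - 1L) %/% 2L
  spur <- array(FALSE, dim(series$mask))
  nt <- n_frames(series)
  vol <- inherits(series, "volume_velocity_series")
  ncomp <- if (vol) 3L else 2L
  for (i in seq_len(nt)) {
    m <- if (vol) series$mask[, , , i] else series$mask[, , i]
    if (!any(m)) next
    flag <- array(FALSE, dim(m))
    for (k in seq_len(ncomp)) {
      vc <- if (vol) series$velocity[, , , k, i] else series$velocity[, , k, i]
      st <- if (vol)
        neighbor_median_stats3d(as.numeric(vc), as.logical(m),
                                as.integer(dim(m)), h)
      else neighbor_median_stats(vc, m, h)
      rstar <- abs(vc - st$median) / (st$resmed + eps)
      f <- m & st$count >= 3L & !is.na(rstar) & rstar > threshold
      flag <- flag | f
    }
    if (vol) spur[, , , i] <- flag else spur[, , i] <- flag
  }
  spur
}

#' Replace flagged vectors by the local non-spurious median
#'
#' Each flagged node's velocity components are replaced by the componentwise
#' median of the non-spurious masked neighbors in the same window; a flagged
#' node with no valid neighbor is set to zero (reported via a message).
#' Non-flagged nodes are returned bit-unchanged.
#'
#' @inheritParams detect_outliers_uod
#' @param spurious Logical array as returned by [detect_outliers_uod()].
#' @return The series with flagged vectors replaced.
#' @export
replace_outliers <- function(series, spurious, window = 3L) {
  stopifnot(identical(dim(spurious), dim(series$mask)))
  h <- (window - 1L) %/% 2L
  nt <- n_frames(series)
  vol <- inherits(series, "volume_velocity_series")
  ncomp <- if (vol) 3L else 2L
  n_zeroed <- 0L
  for (i in seq_len(nt)) {
    m <- if (vol) series$mask[, , , i] else series$mask[, , i]
    sp <- if (vol) spurious[, , , i] else spurious[, , i]
    if (!any(sp)) next
    valid <- m & !sp
    for (k in seq_len(ncomp)) {
      vc <- if (vol) series$velocity[, , , k, i] else series$velocity[, , k, i]
      st <- if (vol)
        neighbor_median_stats3d(as.numeric(vc), as.logical(valid),
                                as.integer(dim(m)), h)
      else neighbor_median_stats(vc, valid, h)
      repl <- ifelse(st$count >= 1L, st$median, 0)
      if (k == 1L) n_zeroed <- n_zeroed + sum(sp & st$count < 1L)
      vc[sp] <- repl[sp]
      if (vol) series$velocity[, , , k, i] <- vc
      else series$velocity[, , k, i] <- vc
    }
  }
  if (n_zeroed > 0L)
    message(sprintf("replace_outliers: %d flagged node(s) had no valid neighbor and were zeroed",
                    n_zeroed))
  series
}

#' Low-rank (truncated SVD) denoising of a velocity series
#'
#' Stacks the two masked velocity components into a (space x time) matrix,
#' computes its singular value decomposition, and reconstructs from the
#' retained leading modes. Nodes outside each frame's mask are left
#' untouched. Two mode-selection rules are available:
#'
#' * `"energy"` (the classical truncation): keep the smallest leading mode
#'   count whose cumulative squared singular values reach `energy_fraction`
#'   of the total. Effective when noise is a small fraction of the total
#'   energy; at low SNR white noise spreads its energy evenly over all modes
#'   and an energy cut retains most of it.
#' * `"noise_floor"`: estimate the white-noise singular-value bulk edge from
#'   the median singular value via the Marchenko-Pastur aspect-ratio factor
#'   (`edge = median(d) * (1 + sqrt(p/n))` for an n x p stack), discard modes
#'   below it, and shrink the retained singular values to
#'   `sqrt(d^2 - edge^2)` to remove the noise variance they carry.
#'
#' @param series A [planar_velocity_series()] with at least 3 frames.
#' @param energy_fraction Fraction of squared-singular-value energy to
#'   retain under the `"energy"` rule, in (0, 1].
#' @param mode_rule Mode-selection rule, `"energy"` (default) or
#'   `"noise_floor"`.
#' @return The denoised series; the retained mode count is attached as
#'   attribute `"rank"`.
#' @export
lowrank_denoise <- function(series, energy_fraction = 0.95,
                            mode_rule = c("energy", "noise_floor")) {
  mode_rule <- match.arg(mode_rule)
  if (!(energy_fraction > 0 && energy_fraction <= 1))
    stop("energy_fraction must be in (0, 1]")
  nt <- n_frames(series)
  stopifnot(nt >= 3)
  union_mask <- apply(series$mask, c(1, 2), any)
  idx <- which(union_mask)
  if (!length(idx)) return(series)
  X <- matrix(0, 2 * length(idx), nt)
  for (i in seq_len(nt)) {
    X[, i] <- c(series$velocity[, , 1, i][idx], series$velocity[, , 2, i][idx])
  }
  sv <- svd(X)
  if (mode_rule == "energy") {
    energy <- cumsum(sv$d^2)
    r <- which(energy >= energy_fraction * energy[length(energy)])[1]
    dk <- sv$d[seq_len(r)]
  } else {
    edge <- stats::median(sv$d) * (1 + sqrt(ncol(X) / nrow(X)))
    r <- max(1L, sum(sv$d > edge))
    dk <- sqrt(pmax(sv$d[seq_len(r)]^2 - edge^2, 0))
  }
  Xr <- sv$u[, seq_len(r), drop = FALSE] %*%
    (dk * t(sv$v[, seq_len(r), drop = FALSE]))
  npt <- length(idx)
  for (i in seq_len(nt)) {
    m <- series$mask[, , i][idx]
    vx <- series$velocity[, , 1, i]
    vy <- series$velocity[, , 2, i]
    vx[idx[m]] <- Xr[seq_len(npt), i][m]
    vy[idx[m]] <- Xr[npt + seq_len(npt), i][m]
    series$velocity[, , 1, i] <- vx
    series$velocity[, , 2, i] <- vy
  }
  attr(series, "rank") <- r
  series
}

# linear interpolation of beat frames at query phases with periodic padding;
# V is (values x frames), ph in [0, 1) strictly increasing
interp_phases_periodic <- function(V, ph, qp) {
  ntk <- length(ph)
  Ve <- cbind(V[, ntk], V, V[, 1])
  phe <- c(ph[ntk] - 1, ph, ph[1] + 1)
  j <- findInterval(qp, phe, rightmost.closed = FALSE)
  j <- pmax(1L, pmin(j, length(phe) - 1L))
  w <- (qp - phe[j]) / (phe[j + 1] - phe[j])
  out <- matrix(0, nrow(V), length(qp))
  for (q in seq_along(qp)) {
    out[, q] <- (1 - w[q]) * Ve[, j[q]] + w[q] * Ve[, j[q] + 1]
  }
  out
}

#' Phase-average a multi-beat series into one representative beat
#'
#' Each annotated beat is mapped to normalized phase `t/T`, linearly
#' interpolated (with periodic wrap) onto a common phase grid and averaged
#' nodewise. Beats spanning fewer than 10 frames are excluded with a message;
#' if every beat is excluded the call fails. Masks are taken from the nearest
#' frame in phase and combined by majority vote across beats.
#'
#' @param series A [planar_velocity_series()] covering one or more beats.
#' @param beats A [beat_definition()].
#' @return A single-beat periodic [planar_velocity_series()] with
#'   `beats$n_phases` frames at times `phase * T`.
#' @export
phase_average <- function(series, beats) {
  stopifnot(inherits(beats, "beat_definition"))
  np <- beats$n_phases
  qp <- (seq_len(np) - 1) / np
  bd <- beats$boundaries
  ny <- series$grid$ny; nx <- series$grid$nx
  acc_v <- matrix(0, ny * nx * 2, np)
  acc_m <- matrix(0, ny * nx, np)
  n_used <- 0L
  for (k in seq_len(length(bd) - 1)) {
    inb <- which(series$times >= bd[k] & series$times < bd[k + 1])
    if (length(inb) < 10) {
      message(sprintf("phase_average: beat %d has %d frames (< 10), excluded",
                      k, length(inb)))
      next
    }
    ph <- (series$times[inb] - bd[k]) / (bd[k + 1] - bd[k])
    V <- matrix(series$velocity[, , , inb], ny * nx * 2, length(inb))
    acc_v <- acc_v + interp_phases_periodic(V, ph, qp)
    # nearest-phase frame for the mask (periodic distance)
    for (q in seq_len(np)) {
      dph <- abs(ph - qp[q])
      dph <- pmin(dph, 1 - dph)
      acc_m[, q] <- acc_m[, q] + as.numeric(series$mask[, , inb[which.min(dph)]])
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("phase_average: no beat with >= 10 frames available")
  vel <- array(acc_v / n_used, c(ny, nx, 2, np))
  mask <- array(acc_m > n_used / 2, c(ny, nx, np))
  planar_velocity_series(series$grid, qp * beats$period, vel, mask,
                         landmarks = series$landmarks,
                         period = beats$period, periodic = TRUE)
}

#' Resample a periodic series to a uniform phase grid
#'
#' Componentwise linear interpolation in time at `n_phases` uniformly spaced
#' phases over the cycle, wrapping periodically between the last and first
#' frames. Masks are taken from the nearest frame.
#'
#' @param series A [planar_velocity_series()] with a known `period` (or one
#'   whose frames span a full cycle, in which case the period is inferred
#'   from the median frame spacing).
#' @param n_phases Number of output phases (>= 2).
#' @return The resampled series (periodic).
#' @export
resample_time <- function(series, n_phases) {
  stopifnot(n_phases >= 2)
  Tc <- series$period
  if (is.null(Tc)) {
    dt <- stats::median(diff(series$times))
    Tc <- diff(range(series$times)) + dt
  }
  t0 <- series$times[1]
  np <- as.integer(n_phases)
  tq <- t0 + (seq_len(np) - 1) / np * Tc
  shifted <- series
  shifted$times <- series$times - t0
  shifted$period <- Tc
  sm <- sample_series_periodic(shifted, tq - t0)
  planar_velocity_series(series$grid, tq, sm$velocity, sm$mask,
                         landmarks = series$landmarks, period = Tc,
                         periodic = TRUE)
}

#' Estimate the cycle period by autocorrelation of mean speed
#'
#' Convenience helper for recordings without beat annotation: computes the
#' spatially averaged masked speed per frame and locates the first dominant
#' positive-lag peak of its autocorrelation. Clinical beat annotations should
#' be preferred when available.
#'
#' @param series A multi-beat [planar_velocity_series()] with uniform frame
#'   spacing.
#' @return Estimated period in seconds.
#' @export
estimate_period <- function(series) {
  nt <- n_frames(series)
  stopifnot(nt >= 6)
  sp <- vapply(seq_len(nt), function(i) {
    m <- frame_mask(series, i)
    if (!any(m)) return(0)
    v <- frame_velocity(series, i)
    mean(sqrt(v[, , 1]^2 + v[, , 2]^2)[m])
  }, numeric(1))
  dt <- stats::median(diff(series$times))
  s <- sp - mean(sp)
  n <- length(s)
  ac <- vapply(seq_len(n - 2), function(l) sum(s[1:(n - l)] * s[(1 + l):n]) /
                 (n - l), numeric(1))
  # first local maximum after the zero-lag peak has decayed
  lag <- which(diff(sign(diff(ac))) == -2) + 1L
  if (!length(lag)) stop("no periodicity detected in mean speed")
  lag[which.max(ac[lag])] * dt
}
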