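# Cross-modality agreement of hemodynamic timeseries: Pearson correlation,
# relative L2-norm difference, good/poor classification, cohort quartiles.

HEMO_PARAMS <- c("inflow_v_mps", "ivpd_mmhg", "vs_indexed_per_s",
                 "ket_indexed_J_per_m3", "vel_indexed_W_per_m3")
HEMO_LABELS <- c(inflow_v_mps = "|V|", ivpd_mmhg = "dP",
                 vs_indexed_per_s = "VS", ket_indexed_J_per_m3 = "KET",
                 vel_indexed_W_per_m3 = "VEL")

#' Align two hemodynamic timeseries onto a common phase grid
#'
#' Resamples series `a` linearly (with periodic wrap) onto the phase grid of
#' series `b`, the comparator-standard modality. Phases at which either
#' series is invalid (`NA`) are dropped (count reported via a message).
#'
#' @param a,b `hemo_timeseries` data frames as returned by
#'   [compute_timeseries()]; both must cover one full cycle.
#' @return A list of two aligned data frames (`a`, `b`) on `b`'s phase grid.
#' @export
align_pair <- function(a, b) {
  qp <- b$phase
  out_a <- data.frame(phase = qp)
  for (p in HEMO_PARAMS) {
    xa <- a[[p]]; pha <- a$phase
    keep <- !is.na(xa)
    if (sum(keep) < 2) {
      out_a[[p]] <- NA_real_
      next
    }
    # periodic padding for phases outside the sampled range
    phk <- pha[keep]; xk <- xa[keep]
    phe <- c(phk[length(phk)] - 1, phk, phk[1] + 1)
    xe <- c(xk[length(xk)], xk, xk[1])
    out_a[[p]] <- stats::approx(phe, xe, xout = qp)$y
  }
  ok <- rep(TRUE, length(qp))
  for (p in HEMO_PARAMS) ok <- ok & !is.na(out_a[[p]]) & !is.na(b[[p]])
  dropped <- sum(!ok)
  if (dropped > 0)
    message(sprintf("align_pair: %d phase(s) dropped for invalid values", dropped))
  if (sum(ok) < 5)
    stop("align_pair: fewer than 5 common valid phases")
  list(a = out_a[ok, , drop = FALSE], b = b[ok, , drop = FALSE])
}

#' Pearson correlation coefficient of two paired series
#'
#' @param x,y Paired numeric vectors (>= 3 values).
#' @return Pearson R, or `NA` (with a message) if either series has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("pearson_r: zero variance, correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Relative L2-norm difference in percent
#'
#' `100 * ||y - x||_2 / ||x||_2`, with `x` the reference (comparator
#' standard) series.
#'
#' @param x Reference series.
#' @param y Test series, paired with `x`.
#' @return Percentage, or `NA` if the reference has zero norm.
#' @export
l2_percent <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  nx <- sqrt(sum(x^2))
  if (nx == 0) {
    message("l2_percent: reference series has zero norm, undefined")
    return(NA_real_)
  }
  100 * sqrt(sum((y - x)^2)) / nx
}

#' Classify agreement as good or poor
#'
#' Good agreement requires both `R > 0.7` and `L2 < 25` percent (strict
#' inequalities).
#'
#' @param r Pearson correlation.
#' @param l2 Relative L2-norm difference in percent.
#' @return `"good"`, `"poor"`, or `NA` if either input is undefined.
#' @export
classify_agreement <- function(r, l2) {
  if (is.na(r) || is.na(l2)) return(NA_character_)
  if (r > 0.7 && l2 < 25) "good" else "poor"
}

#' Per-parameter agreement report for one modality pair
#'
#' Aligns the pair, then computes Pearson R, relative L2-norm difference and
#' the good/poor classification for each of the five hemodynamic parameters.
#'
#' @param a Test-role `hemo_timeseries` (e.g. echo-derived).
#' @param b Reference-role `hemo_timeseries` (e.g. 4D-flow-derived), whose
#'   phase grid and norms anchor the comparison.
#' @return A `data.frame` of class `agreement_report` with one row per
#'   parameter: `parameter`, `label`, `pearson_r`, `l2_percent`,
#'   `classification`.
#' @export
agreement_report <- function(a, b) {
  al <- align_pair(a, b)
  rows <- lapply(HEMO_PARAMS, function(p) {
    r <- pearson_r(al$a[[p]], al$b[[p]])
    l2 <- l2_percent(al$b[[p]], al$a[[p]])
    data.frame(parameter = p, label = unname(HEMO_LABELS[p]),
               pearson_r = r, l2_percent = l2,
               classification = classify_agreement(r, l2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' Cohort quartile summary of agreement statistics
#'
#' Summarizes per-subject agreement reports into 25th/50th/75th percentiles
#' (linear-interpolation quantiles) of R and L2 per parameter — the usual
#' cohort table layout.
#'
#' @param reports List of `agreement_report` objects, one per subject.
#' @return A `data.frame` with columns `parameter`, `label`, `statistic`
#'   (`"R"` or `"L2"`), `q25`, `q50`, `q75`, `n`.
#' @export
cohort_quartiles <- function(reports) {
  stopifnot(length(reports) >= 1)
  rows <- list()
  for (p in HEMO_PARAMS) {
    rs <- vapply(reports, function(rep) rep$pearson_r[rep$parameter == p],
                 numeric(1))
    l2 <- vapply(reports, function(rep) rep$l2_percent[rep$parameter == p],
                 numeric(1))
    for (stat in c("R", "L2")) {
      v <- if (stat == "R") rs else l2
      v <- v[!is.na(v)]
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
           else rep(NA_real_, 3)
      rows[[length(rows) + 1]] <-
        data.frame(parameter = p, label = unname(HEMO_LABELS[p]),
                   statistic = stat, q25 = unname(q[1]), q50 = unname(q[2]),
                   q75 = unname(q[3]), n = length(v),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Cross-modality timeseries agreement (reference: second modality)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s R = %6.3f   L2 = %6.2f %%   %s\n", x$label[i],
                x$pearson_r[i], x$l2_percent[i],
                ifelse(is.na(x$classification[i]), "undefined",
                       x$classification[i])))
  }
  invisible(x)
}
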