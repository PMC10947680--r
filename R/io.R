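# Field container, timeseries CSV, configuration and the pipeline driver.
#
# The container is a versioned, self-describing R serialization (RDS) of the
# gridded field plus units and provenance attributes; arrays round-trip
# bit-exactly. Timeseries and agreement reports are plain CSV ('.' decimal,
# fixed column order) so they stay human-checkable and locale-independent.

CONTAINER_VERSION <- "icflow-container-1"

#' Write / read a gridded velocity-field container
#'
#' `write_container()` serializes a planar or volumetric velocity series with
#' its grid attributes, units, optional landmarks and a provenance block;
#' `read_container()` validates the format version and units and
#' reconstitutes the identical in-memory object (arrays are bit-exact under
#' round-trip).
#'
#' @param series A [planar_velocity_series()] or [volume_velocity_series()].
#' @param path File path.
#' @param provenance Optional list describing how the field was produced
#'   (e.g. a [synthetic_spec()]).
#' @return `write_container()` returns `path` invisibly; `read_container()`
#'   returns the series with the provenance attached as attribute
#'   `"provenance"`.
#' @export
write_container <- function(series, path, provenance = NULL) {
  stopifnot(inherits(series, "planar_velocity_series") ||
            inherits(series, "volume_velocity_series"))
  payload <- list(version = CONTAINER_VERSION,
                  kind = class(series)[1],
                  units = list(length = "m", time = "s", velocity = "m/s"),
                  grid = unclass(series$grid),
                  times = series$times,
                  velocity = series$velocity,
                  mask = series$mask,
                  landmarks = if (!is.null(series$landmarks))
                    unclass(series$landmarks),
                  period = series$period,
                  periodic = series$periodic,
                  beats = attr(series, "beats"),
                  provenance = list(spec = provenance,
                                    tool = paste0("icflow ",
                                                  as.character(utils::packageVersion("icflow"))),
                                    created = format(Sys.time(), tz = "UTC")))
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$version) || !identical(payload$version, CONTAINER_VERSION))
    stop(sprintf("container version mismatch: expected '%s', found '%s'",
                 CONTAINER_VERSION, payload$version %||% "<missing>"))
  for (f in c("units", "grid", "times", "velocity", "mask"))
    if (is.null(payload[[f]]))
      stop(sprintf("container is missing required field '%s'", f))
  if (!identical(payload$units$velocity, "m/s"))
    stop("container is missing the velocity units attribute 'm/s'")
  g <- payload$grid
  grid <- if (is.null(g$nz)) grid_spec(g$nx, g$ny, g$dx, g$dy, g$origin)
          else grid_spec(g$nx, g$ny, g$dx, g$dy, g$origin, g$nz, g$dz)
  lm <- if (!is.null(payload$landmarks))
    do.call(landmarks, payload$landmarks)
  series <- if (identical(payload$kind, "volume_velocity_series"))
    volume_velocity_series(grid, payload$times, payload$velocity,
                           payload$mask, period = payload$period,
                           periodic = payload$periodic)
  else planar_velocity_series(grid, payload$times, payload$velocity,
                              payload$mask, landmarks = lm,
                              period = payload$period,
                              periodic = payload$periodic)
  if (!is.null(payload$beats)) attr(series, "beats") <- payload$beats
  attr(series, "provenance") <- payload$provenance
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a hemodynamic timeseries CSV
#'
#' Fixed column order: `phase, time_s, inflow_v_mps, ivpd_mmhg,
#' vs_indexed_per_s, ket_indexed_J_per_m3, vel_indexed_W_per_m3,
#' denom_area_m2_or_vol_m3`; '.' decimal separator, full double precision.
#'
#' @param ts A `hemo_timeseries` data frame.
#' @param path File path.
#' @return The path (write) or the timeseries (read).
#' @export
write_timeseries_csv <- function(ts, path) {
  cols <- c("phase", "time_s", HEMO_PARAMS, "denom_area_m2_or_vol_m3")
  df <- ts[, cols]
  for (cc in cols) df[[cc]] <- formatC(df[[cc]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in names(out)) out[[cc]] <- as.numeric(out[[cc]])
  class(out) <- c("hemo_timeseries", "data.frame")
  out
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical; comma-separated values become vectors.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop(sprintf("cannot parse config line: '%s'", ln))
    key <- m[2]
    raw <- trimws(strsplit(m[3], ",")[[1]])
    val <- suppressWarnings(as.numeric(raw))
    if (any(is.na(val))) {
      val <- raw
      val[raw %in% c("true", "TRUE")] <- TRUE
      val[raw %in% c("false", "FALSE")] <- FALSE
      if (all(val %in% c(TRUE, FALSE)) && all(raw %in%
          c("true", "TRUE", "false", "FALSE"))) val <- as.logical(val)
    }
    out[[key]] <- val
  }
  out
}

default_pipeline_config <- function() {
  list(family = "rv_filling", period = 0.8, frames_per_cycle = 40,
       nx = 64, ny = 48, dx = 0.0025, dy = 0.0025,
       jet_peak_speed = 0.8, core_radius = 0.008,
       noise = 0.05, echo_rate_hz = 20, echo_beats = 3, mri_phases = 25,
       plane_offset_x = 0, plane_offset_y = 0, plane_rotation = 0,
       seed = 1, uod_window = 3, uod_threshold = 2, uod_eps = 0.1,
       denoise_rule = "noise_floor", energy_fraction = 0.95,
       rho = 1060, mu = 0.004)
}

#' Run the synthetic two-modality analysis pipeline
#'
#' Mirrors the clinical processing order on a synthetic ground truth:
#' generate the filling flow, degrade it into an echo-like multi-beat
#' recording and an MRI-like phase-resolved cycle, preprocess each (low-rank
#' denoising, phase averaging and resampling for the echo role; outlier
#' detection and median replacement for the MRI role), compute the five
#' hemodynamic parameter timeseries for both, and quantify their agreement.
#' All randomness derives from `config$seed`, so a repeated run is
#' bit-identical.
#'
#' @param config Named list (see `icflow:::default_pipeline_config()` for
#'   keys and defaults) or path to a flat key-value config file.
#' @param out_dir Output directory for CSV artifacts and the run log; `NULL`
#'   to skip writing.
#' @return List with `truth`, `echo_series`, `mri_series` (preprocessed),
#'   `ts_echo`, `ts_mri` (timeseries), `report` (an `agreement_report`) and
#'   `log` (stage records).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  logrec <- list()
  stage <- function(name, ...) {
    logrec[[length(logrec) + 1]] <<- c(list(stage = name), list(...))
  }

  spec <- synthetic_spec(family = cfg$family, period = cfg$period,
                         frames_per_cycle = cfg$frames_per_cycle,
                         jet_peak_speed = cfg$jet_peak_speed,
                         core_radius = cfg$core_radius, noise = cfg$noise,
                         echo_rate_hz = cfg$echo_rate_hz,
                         echo_beats = cfg$echo_beats,
                         mri_phases = cfg$mri_phases,
                         plane_offset = c(cfg$plane_offset_x, cfg$plane_offset_y),
                         plane_rotation = cfg$plane_rotation, seed = cfg$seed)
  grid <- grid_spec(cfg$nx, cfg$ny, cfg$dx, cfg$dy)
  gen <- gen_rv_filling(grid, spec)
  truth <- gen$series
  stage("gen", family = cfg$family, seed = cfg$seed,
        frames = n_frames(truth))

  pair <- degrade_to_modalities(truth, spec)
  stage("degrade", noise = cfg$noise, echo_frames = n_frames(pair$echo),
        mri_frames = n_frames(pair$mri))

  # both roles: outlier detection + replacement, then low-rank denoising;
  # the echo role is additionally phase-averaged over its beats and
  # resampled onto the MRI phase grid
  cleanup <- function(s) {
    spur <- detect_outliers_uod(s, cfg$uod_window, cfg$uod_threshold,
                                cfg$uod_eps)
    s <- replace_outliers(s, spur, cfg$uod_window)
    s <- lowrank_denoise(s, cfg$energy_fraction, cfg$denoise_rule)
    attr(s, "flagged") <- sum(spur)
    s
  }
  echo <- cleanup(pair$echo)
  stage("cleanup_echo", flagged = attr(echo, "flagged"),
        rank = attr(echo, "rank"), rule = cfg$denoise_rule)
  beats <- attr(pair$echo, "beats")
  echo <- phase_average(echo, beats)
  echo <- resample_time(echo, cfg$mri_phases)
  stage("phase_average", beats = length(beats$boundaries) - 1,
        phases = cfg$mri_phases)
  mri <- cleanup(pair$mri)
  stage("cleanup_mri", flagged = attr(mri, "flagged"),
        rank = attr(mri, "rank"), rule = cfg$denoise_rule)

  props <- fluid_properties(cfg$rho, cfg$mu)
  ts_echo <- compute_timeseries(echo, gen$landmarks, props)
  ts_mri <- compute_timeseries(mri, gen$landmarks, props)
  stage("hemo", rho = cfg$rho, mu = cfg$mu)

  report <- agreement_report(ts_echo, ts_mri)
  stage("agreement", good = sum(report$classification == "good", na.rm = TRUE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_timeseries_csv(ts_echo, file.path(out_dir, "timeseries_echo.csv"))
    write_timeseries_csv(ts_mri, file.path(out_dir, "timeseries_mri.csv"))
    rep_out <- report
    rep_out$pearson_r <- formatC(rep_out$pearson_r, digits = 17, format = "g")
    rep_out$l2_percent <- formatC(rep_out$l2_percent, digits = 17, format = "g")
    utils::write.csv(rep_out, file.path(out_dir, "agreement_report.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(config = cfg, stages = logrec),
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(truth = truth, echo_series = echo, mri_series = mri,
       ts_echo = ts_echo, ts_mri = ts_mri, report = report, log = logrec)
}
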