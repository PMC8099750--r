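#' Pipeline configuration
#'
#' Bundles every tunable parameter of the landing-analysis pipeline with its
#' default. All tolerances are strictly positive; the segment-detection
#' sensitivity factor `f` is validated against its standard sweep range
#' \[0.25, 2.5\] unless `strict_f = FALSE`.
#'
#' @param sampling_rate sampling frequency of the tracks, Hz.
#' @param smooth_window Savitzky-Golay window length, samples (odd).
#' @param smooth_order Savitzky-Golay polynomial order (>= 2). The default 3
#'   removes the leading-order derivative bias that a quadratic fit leaves on
#'   exponential-like approaches while smoothing noise almost as strongly.
#' @param f sensitivity factor scaling the segment admissibility tolerances.
#' @param tol_r baseline tolerance on the normalized spread of r within a
#'   segment, dimensionless.
#' @param tol_slope baseline tolerance on the |slope of r vs t| normalized by
#'   mean r, 1/s per unit mean r.
#' @param dy_min minimum displacement of a candidate segment, m.
#' @param t_min minimum duration of a candidate segment, s.
#' @param y_td touchdown distance threshold, m.
#' @param eps_v approach-speed floor below which tau is undefined, m/s.
#' @param gap_max deceleration phases separated by gaps shorter than this are
#'   merged, s.
#' @param window_lo,window_hi distance window of the average-per-treatment
#'   set-point estimate, m.
#' @param bin_width distance bin width of the averaged profiles, m.
#' @param n_min_bin minimum number of tracks per reported bin.
#' @param y_ref reference distance for marginal set-point predictions, m.
#' @param r_star_estimator how a segment's set point is summarised: mean of r
#'   over the segment (default) or the through-origin slope of V on y.
#' @param seed default random seed.
#' @param strict_f validate `f` against \[0.25, 2.5\]?
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sampling_rate = 200,
                            smooth_window = 21,
                            smooth_order = 3,
                            f = 1,
                            tol_r = 0.10,
                            tol_slope = 0.20,
                            dy_min = 0.01,
                            t_min = 0.05,
                            y_td = 0.005,
                            eps_v = 1e-3,
                            gap_max = 0.05,
                            window_lo = 0.04,
                            window_hi = 0.11,
                            bin_width = 0.01,
                            n_min_bin = 5,
                            y_ref = 0.15,
                            r_star_estimator = c("mean", "slope"),
                            seed = 1L,
                            strict_f = TRUE) {
  r_star_estimator <- match.arg(r_star_estimator)
  cfg <- list(
    sampling_rate = sampling_rate, smooth_window = smooth_window,
    smooth_order = smooth_order, f = f, tol_r = tol_r,
    tol_slope = tol_slope, dy_min = dy_min, t_min = t_min, y_td = y_td,
    eps_v = eps_v, gap_max = gap_max, window_lo = window_lo,
    window_hi = window_hi, bin_width = bin_width, n_min_bin = n_min_bin,
    y_ref = y_ref, r_star_estimator = r_star_estimator,
    seed = as.integer(seed)
  )
  for (nm in c("sampling_rate", "tol_r", "tol_slope", "dy_min", "t_min",
               "y_td", "eps_v", "gap_max", "bin_width")) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_param("config field '", nm, "' must be a positive number")
    }
  }
  if (cfg$smooth_window %% 2 != 1 || cfg$smooth_window <= cfg$smooth_order) {
    stop_param("smooth_window must be odd and larger than smooth_order")
  }
  if (cfg$smooth_order < 2) stop_param("smooth_order must be >= 2")
  if (strict_f && (f < 0.25 || f > 2.5)) {
    stop_param("f = ", f, " outside [0.25, 2.5]; pass strict_f = FALSE to override")
  }
  if (f <= 0) stop_param("f must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields present in the file override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @param ... further overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_param("reading YAML configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, c(vals[keep], list(...)))
}

track_csv_columns <- c("track_id", "time_s", "x_m", "y_m", "z_m",
                       "light", "pattern", "landing_type")

light_levels <- c("low", "medium", "high")
pattern_levels <- c("checkerboard", "spoke")
landing_type_levels <- c("takeoff", "free_flight")

# Illuminance is metadata only; it never enters any computation.
light_illuminance_lx <- c(low = 13.7, medium = 33.3, high = 144.9)

#' Read landing tracks from CSV
#'
#' Expects columns `track_id, time_s, x_m, y_m, z_m, light, pattern,
#' landing_type`; `y_m` is the perpendicular distance in front of the landing
#' platform. Rows are sorted by time within each track. Tracks with
#' non-uniform sampling (relative jitter of the time step above `1e-6`) are
#' skipped with a warning; metadata that varies within a track is an error.
#'
#' @param path CSV file.
#' @param format only `"csv"` is supported.
#' @return a tibble of tracks with columns `track_id, t, x, y, z, light,
#'   pattern, landing_type` (one row per sample).
#' @export
read_tracks <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_param("track file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(track_csv_columns, names(raw))
  if (length(missing) > 0) {
    stop_param("track CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  tracks <- tibble::tibble(
    track_id = as.character(raw$track_id),
    t = as.numeric(raw$time_s),
    x = as.numeric(raw$x_m),
    y = as.numeric(raw$y_m),
    z = as.numeric(raw$z_m),
    light = as.character(raw$light),
    pattern = as.character(raw$pattern),
    landing_type = as.character(raw$landing_type)
  )
  tracks <- tracks[order(tracks$track_id, tracks$t), , drop = FALSE]
  validate_tracks(tracks)
}

#' @keywords internal
validate_tracks <- function(tracks) {
  keep <- character(0)
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    for (meta in c("light", "pattern", "landing_type")) {
      if (length(unique(tr[[meta]])) != 1L) {
        stop_param("track '", id, "' has inconsistent metadata in column '",
                   meta, "'")
      }
    }
    dt <- diff(tr$t)
    med <- stats::median(dt)
    if (any(dt <= 0) || med <= 0 || any(abs(dt - med) / med >= 1e-6)) {
      log_track_skip(id, "non-uniform or non-increasing time sampling")
      next
    }
    keep <- c(keep, id)
  }
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Write landing tracks to CSV
#'
#' Inverse of [read_tracks()]: `read_tracks(write_tracks(x, p))` reproduces
#' `x` up to floating-point round-trip.
#'
#' @param tracks track tibble as returned by [read_tracks()] or the
#'   simulators.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- data.frame(
    track_id = tracks$track_id %||% character(0),
    time_s = tracks$t %||% numeric(0),
    x_m = tracks$x %||% numeric(0),
    y_m = tracks$y %||% numeric(0),
    z_m = tracks$z %||% numeric(0),
    light = tracks$light %||% character(0),
    pattern = tracks$pattern %||% character(0),
    landing_type = tracks$landing_type %||% character(0)
  )
  write_csv_full_precision(out, path)
  invisible(path)
}

#' Write detected constant-r segments to CSV
#'
#' @param segments segment tibble from [detect_constant_r_segments()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  write_csv_full_precision(as.data.frame(segments), path)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path CSV file.
#' @return a tibble.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_param("segment file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# 17 significant digits give an exact double round-trip.
write_csv_full_precision <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_param("cannot write file '", path, "': ", conditionMessage(ok))
  invisible(path)
}
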