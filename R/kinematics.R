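# Kinematic state estimation: smoothed position, approach speed V = -dy/dt,
# approach acceleration A = -d2y/dt2 (so A = dV/dt), relative rate of
# expansion r = V/y and time to contact tau = y/V.

#' Savitzky-Golay smoothing and differentiation
#'
#' Fits a polynomial of the given order in a centred sliding window by local
#' least squares and evaluates the fitted value and its first two
#' derivatives. The `(window - 1) / 2` samples at each end, where the window
#' does not fit, are reported but should be masked by callers (see the
#' `valid` column of [compute_state_variables()]).
#'
#' @param series numeric series, uniformly sampled.
#' @param window window length, samples (odd, > order).
#' @param order polynomial order (>= 2).
#' @param dt sampling interval, s.
#' @param track_id used in the rejection error for traceability.
#' @return a list with numeric vectors `value`, `d1`, `d2`.
#' @export
smooth_and_differentiate <- function(series, window, order, dt,
                                     track_id = "<series>") {
  if (window %% 2 != 1 || window <= order || order < 2) {
    stop_param("need odd window > order >= 2")
  }
  if (length(series) < window) {
    stop_param("track '", track_id, "' rejected: length ", length(series),
               " is shorter than the smoothing window (", window, ")")
  }
  list(
    value = signal::sgolayfilt(series, p = order, n = window, m = 0, ts = dt),
    d1 = signal::sgolayfilt(series, p = order, n = window, m = 1, ts = dt),
    d2 = signal::sgolayfilt(series, p = order, n = window, m = 2, ts = dt)
  )
}

#' Compute per-sample kinematic state variables
#'
#' Converts raw tracks into per-sample state: smoothed position, approach
#' velocity `V = -dy/dt` (positive toward the platform), approach
#' acceleration `A = -d2y/dt2` (equal to `dV/dt`), relative rate of expansion
#' `r = V / y`, and time to contact `tau = y / V` (defined only where
#' `V > eps_v`). A `valid` mask excludes the half-window at each end and
#' samples at or past touchdown (`y <= y_td`). `u_start` is the 3-D ground
#' speed at the start of the landing maneuver, defined as the first sample of
#' the last contiguous interval with `V > eps_v` that ends at touchdown;
#' `maneuver_start` flags that sample.
#'
#' Tracks shorter than the smoothing window are dropped with a warning.
#'
#' @param tracks track tibble (one or many tracks).
#' @param config a [pipeline_config()].
#' @return a kinematic tibble: the track columns plus `y` (smoothed), `y_raw`,
#'   `V`, `A`, `r`, `tau`, `valid`, `decel`, `maneuver_start`, `u_start`.
#' @export
compute_state_variables <- function(tracks, config = pipeline_config()) {
  out <- lapply(split_tracks(tracks), function(tr) {
    tryCatch(compute_state_one(tr, config), error = function(e) {
      log_track_skip(tr$track_id[1], conditionMessage(e))
      NULL
    })
  })
  dplyr::bind_rows(out)
}

split_tracks <- function(tracks) {
  split(tracks, factor(tracks$track_id, levels = unique(tracks$track_id)))
}

compute_state_one <- function(tr, config) {
  n <- nrow(tr)
  w <- config$smooth_window
  if (n < w) {
    stop_param("length ", n, " shorter than smoothing window ", w)
  }
  if (!all(is.finite(tr$y)) || !all(is.finite(tr$t))) {
    stop_param("non-finite coordinates")
  }
  dt <- stats::median(diff(tr$t))
  sy <- smooth_and_differentiate(tr$y, w, config$smooth_order, dt,
                                 tr$track_id[1])
  sx <- smooth_and_differentiate(tr$x, w, config$smooth_order, dt,
                                 tr$track_id[1])
  sz <- smooth_and_differentiate(tr$z, w, config$smooth_order, dt,
                                 tr$track_id[1])
  h <- (w - 1L) / 2L
  V <- -sy$d1
  A <- -sy$d2
  y_s <- sy$value
  r <- V / y_s
  tau <- ifelse(V > config$eps_v, y_s / V, NA_real_)
  valid <- rep(FALSE, n)
  valid[(h + 1L):(n - h)] <- TRUE
  valid <- valid & y_s > config$y_td

  ktr <- tr
  ktr$y_raw <- tr$y
  ktr$y <- y_s
  ktr$x <- sx$value
  ktr$z <- sz$value
  ktr$V <- V
  ktr$A <- A
  ktr$r <- r
  ktr$tau <- tau
  ktr$valid <- valid

  # maneuver start: first sample of the last contiguous run of V > eps_v
  # (within the valid region) that ends at touchdown
  vi <- which(valid)
  m_start <- NA_integer_
  if (length(vi) > 0) {
    last_valid <- vi[length(vi)]
    approaching <- valid & V > config$eps_v
    i <- last_valid
    while (i >= 1 && approaching[i]) i <- i - 1L
    if (i < last_valid) m_start <- i + 1L
  }
  ktr$maneuver_start <- FALSE
  ground_speed <- sqrt(sx$d1^2 + sy$d1^2 + sz$d1^2)
  if (!is.na(m_start)) {
    ktr$maneuver_start[m_start] <- TRUE
    ktr$u_start <- ground_speed[m_start]
  } else {
    ktr$u_start <- NA_real_
  }

  phases <- deceleration_phases_one(ktr, config)
  decel <- rep(FALSE, n)
  for (k in seq_len(nrow(phases))) {
    decel[phases$i_start[k]:phases$i_end[k]] <- TRUE
  }
  ktr$decel <- decel & valid & V > config$eps_v & A < 0
  ktr
}

#' Deceleration phases of a kinematic track
#'
#' Maximal sample intervals in which the bee approaches the platform
#' (`V > eps_v`, `y > y_td`, both within the valid mask) while slowing down
#' (`dV/dt < 0`, i.e. `A < 0`). Gaps shorter than `gap_max` seconds between
#' consecutive intervals are merged (hysteresis against jitter around zero
#' acceleration).
#'
#' @param ktracks kinematic tibble from [compute_state_variables()].
#' @param config a [pipeline_config()].
#' @return a tibble with columns `track_id`, `i_start`, `i_end` (sample
#'   indices within each track); zero rows when no deceleration occurs.
#' @export
deceleration_phases <- function(ktracks, config = pipeline_config()) {
  out <- lapply(split_tracks(ktracks), function(tr) {
    ph <- deceleration_phases_one(tr, config)
    if (nrow(ph) > 0) ph$track_id <- tr$track_id[1]
    ph
  })
  dplyr::bind_rows(out)
}

deceleration_phases_one <- function(ktr, config) {
  ok <- ktr$valid & ktr$V > config$eps_v & ktr$A < 0
  ok[is.na(ok)] <- FALSE
  iv <- runs_true(ok)
  if (nrow(iv) > 1) {
    dt <- stats::median(diff(ktr$t))
    gap_samples <- config$gap_max / dt
    merged <- iv[1, , drop = FALSE]
    for (k in 2:nrow(iv)) {
      gap <- iv$i_start[k] - merged$i_end[nrow(merged)] - 1L
      if (gap < gap_samples) {
        merged$i_end[nrow(merged)] <- iv$i_end[k]
      } else {
        merged <- rbind(merged, iv[k, , drop = FALSE])
      }
    }
    iv <- merged
  }
  iv
}

runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(i_start = starts[keep], i_end = ends[keep])
}
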