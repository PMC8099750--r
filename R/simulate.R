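# Trajectory generators for the three landing guidance laws.
#
# All generators integrate the 1-D approach dynamics dy/dt = -r(t) * y in
# closed form and sample the result on a uniform grid, so downstream stages
# can be tested against exact references. Lateral coordinates get a small
# smooth deterministic drift only; there is no lateral guidance law and no
# body-dynamics model.

new_track <- function(track_id, t, y, light, pattern, landing_type,
                      x0 = 0, z0 = 0) {
  # gentle lateral drift, a few mm over a typical approach
  tibble::tibble(
    track_id = track_id,
    t = t,
    x = x0 + 0.004 * sin(1.3 * t),
    y = y,
    z = z0 + 0.003 * sin(0.9 * t + 0.5),
    light = light,
    pattern = pattern,
    landing_type = landing_type
  )
}

check_approach_geometry <- function(y0, y_td) {
  if (!is_scalar_number(y0) || !is_scalar_number(y_td) ||
      y0 <= y_td || y_td <= 0) {
    stop_param("need y0 > y_td > 0 (got y0 = ", y0, ", y_td = ", y_td, ")")
  }
}

#' Simulate a constant-r landing approach
#'
#' Under the constant-r law the relative rate of expansion is held at the set
#' point `r_set`, so the distance decays exponentially,
#' `y(t) = y0 * exp(-r_set * t)`, and the approach speed `V = r_set * y`
#' decreases linearly with distance. The track is sampled at `sampling_rate`
#' until the first sample with `y <= y_td`.
#'
#' @param y0 start distance from the platform, m.
#' @param r_set expansion-rate set point, 1/s. Defaults to `V0 / y0`.
#' @param V0 start approach speed, m/s; used only to derive a default
#'   `r_set`.
#' @param sampling_rate sampling frequency, Hz.
#' @param y_td touchdown distance, m.
#' @param track_id,light,pattern,landing_type track metadata.
#' @return a track tibble (columns `track_id, t, x, y, z, light, pattern,
#'   landing_type`).
#' @export
simulate_constant_r <- function(y0 = 0.3, r_set = NULL, V0 = 0.3,
                                sampling_rate = 200, y_td = 0.005,
                                track_id = "constant_r",
                                light = "high", pattern = "checkerboard",
                                landing_type = "free_flight") {
  check_approach_geometry(y0, y_td)
  r_set <- r_set %||% (V0 / y0)
  if (!is_scalar_number(r_set) || r_set <= 0) stop_param("r_set must be > 0")
  t_td <- log(y0 / y_td) / r_set
  t <- seq(0, by = 1 / sampling_rate, length.out = ceiling(t_td * sampling_rate) + 1L)
  y <- y0 * exp(-r_set * t)
  new_track(track_id, t, y, light, pattern, landing_type)
}

#' Simulate a constant-tau-dot landing approach
#'
#' Under the constant-tau-dot law the time to contact decreases linearly,
#' `tau(t) = tau0 + c * t` with `tau0 = y0 / V0` and `c` in (-1, 0), giving
#' `y(t) = y0 * (1 + c * t / tau0)^(-1/c)`. Along the track, `log r` is an
#' exact affine function of `log y` with slope `c`. Contact would occur at
#' `t = tau0 / |c|`; the sampled track is truncated at the first sample with
#' `y <= y_td`.
#'
#' @param c time-to-contact rate (tau-dot), dimensionless, in (-1, 0).
#' @param V0 start approach speed, m/s.
#' @inheritParams simulate_constant_r
#' @return a track tibble.
#' @export
simulate_constant_taudot <- function(y0 = 0.3, V0 = 0.3, c = -0.75,
                                     sampling_rate = 200, y_td = 0.005,
                                     track_id = "constant_taudot",
                                     light = "high", pattern = "checkerboard",
                                     landing_type = "free_flight") {
  check_approach_geometry(y0, y_td)
  if (!is_scalar_number(c) || c <= -1 || c >= 0) {
    stop_param("c must lie in (-1, 0) for a soft touchdown; got ", c)
  }
  if (!is_scalar_number(V0) || V0 <= 0) stop_param("V0 must be > 0")
  tau0 <- y0 / V0
  t_td <- tau0 * ((y_td / y0)^(-c) - 1) / c
  t <- seq(0, by = 1 / sampling_rate, length.out = ceiling(t_td * sampling_rate) + 1L)
  y <- y0 * (1 + c * t / tau0)^(-1 / c)
  new_track(track_id, t, y, light, pattern, landing_type)
}

# --- hybrid generator ------------------------------------------------------

# One phase of the hybrid approach: r relaxes first-order from its value at
# phase start toward r_target with time constant tau_relax (tau_relax = 0
# means r is held at r_target throughout, i.e. a constant-r bout).
# y(t) = y_start * exp(-I(t)) with I(t) the integral of r.
phase_integral_r <- function(tt, r_start, r_target, tau_relax) {
  if (tau_relax <= 0) return(r_target * tt)
  r_target * tt + (r_start - r_target) * tau_relax * (1 - exp(-tt / tau_relax))
}

phase_duration <- function(r_start, r_target, tau_relax, log_drop) {
  # solve integral_r(T) == log_drop for T
  if (log_drop <= 0) return(0)
  if (tau_relax <= 0) return(log_drop / r_target)
  f <- function(tt) phase_integral_r(tt, r_start, r_target, tau_relax) - log_drop
  upper <- log_drop / min(r_start, r_target) + 10 * tau_relax
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-13)$root
}

phase_r_at <- function(tt, r_start, r_target, tau_relax) {
  if (tau_relax <= 0) return(rep(r_target, length(tt)))
  r_target + (r_start - r_target) * exp(-tt / tau_relax)
}

# logarithmic mean of the distance across a bout; equals the time-mean of y
# under exponential decay, matching how y* is summarised within a segment.
log_mean <- function(y_a, y_b) (y_a - y_b) / log(y_a / y_b)

#' Simulate a hybrid landing approach
#'
#' The hybrid law consists of `n_bouts` constant-r bouts separated by smooth
#' transition phases in which `r` relaxes first-order toward the next set
#' point with time constant `transition_tau`. Set points follow a
#' constant-tau-dot schedule in distance:
#' `log r_k = c * log y_k + const`, anchored at each bout's mid-distance
#' (the time-mean of `y` within the bout) and at the first set point
#' `r1`.
#'
#' The approach is laid out in displacement fractions of the total travel
#' `y0 - y_td`: an optional lead-in (`lead_fraction`), `n_bouts` bouts of
#' `bout_fraction` each, transitions of `transition_fraction` each, and a
#' final tail (the remainder). Lead-in and tail follow the track's own
#' constant-tau-dot schedule continuously (the idealized hybrid picture: the
#' bouts hold piecewise-constant what the schedule prescribes continuously),
#' so every part of the track is consistent with the same tau-dot law. With
#' `n_bouts = 1`, `bout_fraction = 1` and no lead the track reduces exactly
#' to [simulate_constant_r()].
#'
#' @param r1 first expansion-rate set point, 1/s.
#' @param c time-to-contact rate governing the set-point schedule, in (-1, 0).
#' @param n_bouts number of constant-r bouts (>= 1).
#' @param bout_fraction displacement fraction of one bout, in (0, 1\].
#' @param transition_fraction displacement fraction of one transition.
#' @param lead_fraction displacement fraction before the first bout.
#' @param transition_tau first-order relaxation time constant of `r`, s.
#' @param transition_style `"relax"` for a plain first-order transition;
#'   `"dip"` additionally lets the approach speed sag toward `v_dip` halfway
#'   through each transition (some observed transitions contain near-zero
#'   approach velocity).
#' @param v_dip target sag speed of `"dip"` transitions, m/s.
#' @inheritParams simulate_constant_r
#' @return a list with elements `track` (tibble) and `bouts` (ground-truth
#'   annotations: one row per bout with exact sample interval, time bounds,
#'   distance bounds and set point `r_star`).
#' @export
simulate_hybrid <- function(y0 = 0.3, r1 = 1.5, c = -0.85, n_bouts = 2,
                            bout_fraction = 0.13,
                            transition_fraction = 0.165,
                            lead_fraction = 0,
                            transition_tau = 0.15,
                            transition_style = c("relax", "dip"),
                            v_dip = 0.05,
                            sampling_rate = 200, y_td = 0.005,
                            track_id = "hybrid",
                            light = "high", pattern = "checkerboard",
                            landing_type = "free_flight") {
  transition_style <- match.arg(transition_style)
  check_approach_geometry(y0, y_td)
  if (!is_scalar_number(r1) || r1 <= 0) stop_param("r1 must be > 0")
  if (!is_scalar_number(c) || c <= -1 || c >= 0) {
    stop_param("c must lie in (-1, 0); got ", c)
  }
  n_bouts <- as.integer(n_bouts)
  if (n_bouts < 1) stop_param("n_bouts must be >= 1")
  if (bout_fraction <= 0 || bout_fraction > 1) {
    stop_param("bout_fraction must lie in (0, 1]")
  }
  used <- lead_fraction + n_bouts * bout_fraction +
    (n_bouts - 1) * transition_fraction
  if (used > 1 + 1e-12) {
    stop_param("displacement fractions exceed 1 (", round(used, 4), ")")
  }

  D <- y0 - y_td
  # distance boundaries of bouts (start/end, decreasing y)
  bout_start <- bout_end <- numeric(n_bouts)
  pos <- y0 - lead_fraction * D
  for (k in seq_len(n_bouts)) {
    bout_start[k] <- pos
    bout_end[k] <- pos - bout_fraction * D
    pos <- bout_end[k] - if (k < n_bouts) transition_fraction * D else 0
  }
  y_mid <- log_mean(bout_start, bout_end)
  r_star <- r1 * (y_mid / y_mid[1])^c
  if (any(!is.finite(r_star)) || any(r_star <= 0)) {
    stop_param("set-point schedule produced a non-positive set point")
  }
  # schedule: r_sched(y) = r1 * (y / y_mid[1])^c
  r_sched <- function(y) r1 * (y / y_mid[1])^c

  # assemble phases; two types:
  #   relax : r relaxes first-order from r_start toward r_target (tau = 0
  #           holds r at r_target: a constant-r bout)
  #   taudot: r follows the schedule continuously (constant-tau-dot arc)
  phases <- list()
  add_phase <- function(y_a, y_b, r_s, r_t, tau) {
    if (y_a - y_b > 1e-12) {
      phases[[length(phases) + 1L]] <<- list(
        type = "relax",
        y_start = y_a, y_end = y_b, r_start = r_s, r_target = r_t, tau = tau)
    }
  }
  add_taudot_phase <- function(y_a, y_b) {
    if (y_a - y_b > 1e-12) {
      phases[[length(phases) + 1L]] <<- list(
        type = "taudot", y_start = y_a, y_end = y_b, r_a = r_sched(y_a))
    }
  }
  if (lead_fraction > 0) add_taudot_phase(y0, bout_start[1])
  r_now <- r_star[1]
  bout_phase_index <- integer(n_bouts)
  for (k in seq_len(n_bouts)) {
    add_phase(bout_start[k], bout_end[k], r_star[k], r_star[k], 0)
    bout_phase_index[k] <- length(phases)
    r_now <- r_star[k]
    if (k < n_bouts) {
      y_a <- bout_end[k]; y_b <- bout_start[k + 1]
      if (transition_style == "dip") {
        y_half <- sqrt(y_a * y_b)  # split transition at the log midpoint
        r_dip <- v_dip / y_half
        add_phase(y_a, y_half, r_now, r_dip, transition_tau / 2)
        r_now <- phase_r_at(phase_duration(r_now, r_dip, transition_tau / 2,
                                           log(y_a / y_half)),
                            r_now, r_dip, transition_tau / 2)
        add_phase(y_half, y_b, r_now, r_star[k + 1], transition_tau / 2)
        r_now <- phase_r_at(phase_duration(r_now, r_star[k + 1],
                                           transition_tau / 2,
                                           log(y_half / y_b)),
                            r_now, r_star[k + 1], transition_tau / 2)
      } else {
        add_phase(y_a, y_b, r_now, r_star[k + 1], transition_tau)
        r_now <- phase_r_at(phase_duration(r_now, r_star[k + 1],
                                           transition_tau,
                                           log(y_a / y_b)),
                            r_now, r_star[k + 1], transition_tau)
      }
    }
  }
  if (bout_end[n_bouts] - y_td > 1e-12) {
    add_taudot_phase(bout_end[n_bouts], y_td)
  }

  phase_dur <- function(p) {
    if (p$type == "taudot") {
      tau_a <- 1 / p$r_a
      (tau_a / c) * ((p$y_end / p$y_start)^(-c) - 1)
    } else {
      phase_duration(p$r_start, p$r_target, p$tau, log(p$y_start / p$y_end))
    }
  }
  phase_y_at <- function(p, tt) {
    if (p$type == "taudot") {
      # clamp at contact: a sample can fall just past the arc's touchdown
      p$y_start * pmax(1 + c * tt * p$r_a, 0)^(-1 / c)
    } else {
      p$y_start * exp(-phase_integral_r(tt, p$r_start, p$r_target, p$tau))
    }
  }
  durations <- vapply(phases, phase_dur, numeric(1))
  t_start_phase <- cumsum(c(0, durations[-length(durations)]))
  t_total <- sum(durations)

  dt <- 1 / sampling_rate
  t <- seq(0, by = dt, length.out = ceiling(t_total / dt) + 1L)
  idx <- findInterval(t, t_start_phase, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[t >= t_total] <- length(phases)
  y <- numeric(length(t))
  for (p in seq_along(phases)) {
    sel <- idx == p
    if (!any(sel)) next
    tt <- t[sel] - t_start_phase[p]
    y[sel] <- phase_y_at(phases[[p]], tt)
  }

  track <- new_track(track_id, t, y, light, pattern, landing_type)
  t_b_start <- t_start_phase[bout_phase_index]
  t_b_end <- t_b_start + durations[bout_phase_index]
  bouts <- tibble::tibble(
    track_id = track_id,
    bout = seq_len(n_bouts),
    t_start = t_b_start,
    t_end = t_b_end,
    i_start = pmin(findInterval(t_b_start - 1e-12, t) + 1L, length(t)),
    i_end = findInterval(t_b_end + 1e-12, t),
    y_start = bout_start,
    y_end = bout_end,
    y_mid = y_mid,
    r_star = r_star,
    c = c,
    light = light, pattern = pattern, landing_type = landing_type
  )
  list(track = track, bouts = bouts)
}

#' Add positional tracking noise to a track
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma_pos`
#' independently to the `x`, `y` and `z` coordinates, emulating videographic
#' triangulation error. Deterministic given `seed`; `sigma_pos = 0` returns
#' the input unchanged.
#'
#' @param track a track tibble.
#' @param sigma_pos noise standard deviation, m (>= 0).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return the noisy track tibble.
#' @export
add_tracking_noise <- function(track, sigma_pos, seed = NULL) {
  if (!is_scalar_number(sigma_pos) || sigma_pos < 0) {
    stop_param("sigma_pos must be >= 0")
  }
  if (sigma_pos == 0) return(track)
  n <- nrow(track)
  noise <- with_seed(seed, rnorm(3L * n, sd = sigma_pos))
  track$x <- track$x + noise[seq_len(n)]
  track$y <- track$y + noise[n + seq_len(n)]
  track$z <- track$z + noise[2L * n + seq_len(n)]
  track
}

#' Specification of a synthetic landing dataset
#'
#' Defines the statistical structure of a simulated dataset across the full
#' treatment design (3 light levels x 2 platform patterns x 2 landing
#' types). First-bout set points are drawn from a gamma distribution and
#' shifted on the log scale by a per-light-level intercept offset; the
#' schedule tau-dot `c` differs by landing type and platform pattern.
#' Defaults emulate the recorded field conditions: approaches start within
#' 0.41 m of the platform at 0.1-0.5 m/s, most tracks hold 1-3 constant-r
#' bouts covering ~13% of the displacement each, and positions carry 0.2 mm
#' tracking noise.
#'
#' @param n_per_cell tracks per treatment cell.
#' @param gamma_shape,gamma_scale gamma parameters of the first-bout
#'   set-point distribution (1/s scale).
#' @param light_offsets named log-scale intercept offsets per light level.
#' @param c_landing_type named schedule tau-dot per landing type.
#' @param c_pattern_adj named additive adjustment of the schedule tau-dot per
#'   platform pattern.
#' @param p_bouts probabilities of a track holding 1, 2, ... bouts.
#' @param y0_range start-distance range, m.
#' @param bout_fraction,transition_fraction,transition_tau hybrid layout
#'   parameters, see [simulate_hybrid()].
#' @param sigma_pos positional tracking noise sd, m.
#' @param sampling_rate sampling frequency, Hz.
#' @param y_td touchdown distance, m.
#' @param seed integer seed; the generated dataset is fully reproducible.
#' @return a list of class `dataset_spec`.
#' @export
dataset_spec <- function(n_per_cell = 10,
                         gamma_shape = 3.59,
                         gamma_scale = 0.65,
                         light_offsets = c(low = 0, medium = 0.08, high = 0.17),
                         c_landing_type = c(takeoff = -0.94, free_flight = -0.73),
                         c_pattern_adj = c(checkerboard = -0.045, spoke = 0.045),
                         p_bouts = c(0.72, 0.22, 0.06),
                         y0_range = c(0.25, 0.41),
                         bout_fraction = 0.13,
                         transition_fraction = 0.165,
                         transition_tau = 0.15,
                         sigma_pos = 2e-4,
                         sampling_rate = 200,
                         y_td = 0.005,
                         seed = 1L) {
  if (gamma_shape <= 0 || gamma_scale <= 0) {
    stop_param("gamma parameters must be > 0")
  }
  if (sigma_pos < 0) stop_param("sigma_pos must be >= 0")
  if (n_per_cell < 0) stop_param("n_per_cell must be >= 0")
  structure(list(
    n_per_cell = as.integer(n_per_cell),
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    light_offsets = light_offsets, c_landing_type = c_landing_type,
    c_pattern_adj = c_pattern_adj, p_bouts = p_bouts / sum(p_bouts),
    y0_range = y0_range,
    bout_fraction = bout_fraction,
    transition_fraction = transition_fraction,
    transition_tau = transition_tau,
    sigma_pos = sigma_pos, sampling_rate = sampling_rate, y_td = y_td,
    seed = as.integer(seed)
  ), class = "dataset_spec")
}

#' Generate a synthetic landing dataset with ground truth
#'
#' Draws tracks per treatment cell according to a [dataset_spec()]: the
#' first-bout set point comes from the configured gamma distribution shifted by
#' the cell's log intercept offset, later set points follow the cell's
#' constant-tau-dot schedule, the bouts are placed with a random lead-in so
#' set points occur over a range of distances, and positional tracking noise
#' is added. Returns the exact bout annotations so detection and model
#' recovery can be tested against ground truth.
#'
#' @param spec a [dataset_spec()].
#' @return a list with elements `tracks` (tibble of all samples), `truth`
#'   (one row per generated bout: interval, set point, schedule `c`, cell)
#'   and `spec`.
#' @export
generate_dataset <- function(spec = dataset_spec()) {
  stopifnot(inherits(spec, "dataset_spec"))
  cells <- expand.grid(light = light_levels, pattern = pattern_levels,
                       landing_type = landing_type_levels,
                       stringsAsFactors = FALSE)
  tracks <- list(); truths <- list(); id <- 0L
  with_seed(spec$seed, {
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      c_cell <- spec$c_landing_type[[cell$landing_type]] +
        spec$c_pattern_adj[[cell$pattern]]
      off <- spec$light_offsets[[cell$light]]
      for (k in seq_len(spec$n_per_cell)) {
        id <- id + 1L
        tid <- sprintf("trk%05d", id)
        n_bouts <- sample.int(length(spec$p_bouts), 1L, prob = spec$p_bouts)
        r1 <- exp(log(rgamma(1, shape = spec$gamma_shape,
                             scale = spec$gamma_scale)) + off)
        y0 <- runif(1, spec$y0_range[1], spec$y0_range[2])
        spare <- 1 - n_bouts * spec$bout_fraction -
          (n_bouts - 1) * spec$transition_fraction
        lead <- runif(1, 0.05, 0.9) * max(spare, 0)
        sim <- simulate_hybrid(
          y0 = y0, r1 = r1, c = c_cell, n_bouts = n_bouts,
          bout_fraction = spec$bout_fraction,
          transition_fraction = spec$transition_fraction,
          lead_fraction = lead,
          transition_tau = spec$transition_tau,
          sampling_rate = spec$sampling_rate, y_td = spec$y_td,
          track_id = tid, light = cell$light, pattern = cell$pattern,
          landing_type = cell$landing_type)
        tracks[[id]] <- add_tracking_noise(sim$track, spec$sigma_pos)
        truths[[id]] <- sim$bouts
      }
    }
  })
  list(tracks = dplyr::bind_rows(tracks),
       truth = dplyr::bind_rows(truths),
       spec = spec)
}
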