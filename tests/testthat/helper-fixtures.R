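# Shared fixtures and oracles for the test suite.

# Match generated bouts to detected segments by sample-interval overlap:
# a bout is matched when some detected segment covers at least
# `min_overlap` of the bout's samples. Returns one row per bout with the
# matching segment's set-point estimate (NA when unmatched).
match_bouts <- function(truth, segments, min_overlap = 0.5) {
  out <- truth[, c("track_id", "bout", "i_start", "i_end", "r_star")]
  names(out)[names(out) == "r_star"] <- "r_true"
  out$matched <- FALSE
  out$r_detected <- NA_real_
  for (k in seq_len(nrow(out))) {
    seg <- segments[segments$track_id == out$track_id[k], ]
    if (nrow(seg) == 0) next
    ov <- pmin(seg$i_end, out$i_end[k]) - pmax(seg$i_start, out$i_start[k]) + 1L
    frac <- ov / (out$i_end[k] - out$i_start[k] + 1L)
    best <- which.max(frac)
    if (frac[best] >= min_overlap) {
      out$matched[k] <- TRUE
      out$r_detected[k] <- seg$r_star[best]
    }
  }
  out
}

# Fraction of deceleration-phase samples covered by detected segments.
covered_fraction <- function(ktracks, segments, config) {
  ph <- deceleration_phases(ktracks, config)
  n_decel <- sum(ph$i_end - ph$i_start + 1L)
  if (n_decel == 0) return(NA_real_)
  sum(segments$i_end - segments$i_start + 1L) / n_decel
}

# Numerically integrate dy/dt = -r(y, t) * y with deSolve at tight
# tolerance; independent oracle for the closed-form generators.
integrate_approach <- function(y0, times, r_fun) {
  sol <- deSolve::lsoda(
    y = c(y = y0), times = times,
    func = function(t, state, parms) list(-r_fun(state[["y"]], t) * state[["y"]]),
    rtol = 1e-12, atol = 1e-14)
  unname(sol[, "y"])
}

quiet_fit <- function(...) suppressWarnings(fit_loglog_model(...))

# Tracks for treatment-ordering checks: every track follows a population
# schedule ln r = c * ln y + B + eps_track (B the cell's log intercept at
# the 0.15 m reference distance, eps_track ~ N(0, sd_track) the per-track
# scatter). Set points held at any distance sit on the track's own line, so
# speeds stay in the behavioural range at every distance and detectability
# does not depend on the cell.
make_ordering_tracks <- function(n, seed, c, B, sd_track = 0.3,
                                 sigma_pos = 2e-4, light = "high",
                                 pattern = "checkerboard",
                                 landing_type = "free_flight",
                                 prefix = "ord") {
  y_td <- 0.005
  tracks <- list()
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      y0 <- runif(1, 0.25, 0.41)
      nb <- sample(1:3, 1)
      spare <- 1 - nb * 0.16 - (nb - 1) * 0.15
      lead <- runif(1, 0.05, 0.8) * spare
      # first-bout mid-distance implied by the layout, then the set point
      # that puts this track's first bout on its schedule
      D <- y0 - y_td
      s1 <- y0 - lead * D
      e1 <- s1 - 0.16 * D
      y_mid1 <- (s1 - e1) / log(s1 / e1)
      eps <- rnorm(1, 0, sd_track)
      r1 <- exp(B + eps) * (y_mid1 / 0.15)^c
      h <- simulate_hybrid(
        y0 = y0, r1 = r1, c = c, n_bouts = nb,
        bout_fraction = 0.16, transition_fraction = 0.15,
        lead_fraction = lead, track_id = sprintf("%s%04d", prefix, i),
        light = light, pattern = pattern, landing_type = landing_type)
      tracks[[i]] <- add_tracking_noise(h$track, sigma_pos)
    }
  })
  dplyr::bind_rows(tracks)
}

# Hybrid tracks for detector-recovery checks. The recovery property is about
# bouts the detector could in principle resolve, so the generator enforces
# detectability: set points drawn from the empirical gamma law truncated to
# the range typical of held set points, bout displacements >= 0.02 m, and
# every bout lasting at least 0.1 s (twice the detector's minimum window;
# tracks violating this are redrawn). Tracking noise 0.2 mm.
make_recovery_tracks <- function(n, seed, c = -0.85, sigma_pos = 2e-4,
                                 n_bouts_range = 1:3, min_bout_s = 0.1,
                                 r_offset = 0, light = "high",
                                 pattern = "checkerboard",
                                 landing_type = "free_flight",
                                 prefix = "rec") {
  tracks <- list(); truths <- list()
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      for (attempt in 1:50) {
        r1 <- 0
        while (r1 < 0.8 || r1 > 3) r1 <- rgamma(1, 3.59, scale = 0.65)
        r1 <- r1 * exp(r_offset)
        nb <- sample(n_bouts_range, 1)
        spare <- 1 - nb * 0.16 - (nb - 1) * 0.15
        h <- simulate_hybrid(
          y0 = runif(1, 0.25, 0.41), r1 = r1, c = c, n_bouts = nb,
          bout_fraction = 0.16, transition_fraction = 0.15,
          lead_fraction = runif(1, 0.05, 0.8) * spare,
          track_id = sprintf("%s%04d", prefix, i),
          light = light, pattern = pattern, landing_type = landing_type)
        if (all(h$bouts$t_end - h$bouts$t_start >= min_bout_s)) break
      }
      tracks[[i]] <- add_tracking_noise(h$track, sigma_pos)
      truths[[i]] <- h$bouts
    }
  })
  list(tracks = dplyr::bind_rows(tracks), truth = dplyr::bind_rows(truths))
}
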