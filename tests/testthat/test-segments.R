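cfg <- pipeline_config()

test_that("a noise-free constant-r track yields one segment covering the phase", {
  tr <- simulate_constant_r(y0 = 0.3, r_set = 2.0)
  kt <- compute_state_variables(tr, cfg)
  seg <- detect_constant_r_segments(kt, f = 1, cfg)
  expect_equal(nrow(seg), 1L)
  expect_gt(seg$r_star, 1.99); expect_lt(seg$r_star, 2.01)
  expect_gte(covered_fraction(kt, seg, cfg), 0.95)
  expect_gt(seg$dy1, 0)
  expect_error(detect_constant_r_segments(kt, f = -1), "f must be")
})

test_that("a two-bout hybrid is resolved into its bouts with the transition uncovered", {
  h <- simulate_hybrid(y0 = 0.3, r1 = 1.5, c = -0.87, n_bouts = 2,
                       bout_fraction = 0.2, transition_fraction = 0.2)
  tr <- add_tracking_noise(h$track, 1e-4, seed = 21)
  kt <- compute_state_variables(tr, cfg)
  seg <- detect_constant_r_segments(kt, f = 1, cfg)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$r_star, h$bouts$r_star, tolerance = 0.05)
  # the middle of the transition is not covered by any segment
  mid <- round((h$bouts$i_end[1] + h$bouts$i_start[2]) / 2)
  expect_false(any(seg$i_start <= mid & seg$i_end >= mid))
  # segments are time-ordered and non-overlapping
  expect_lt(seg$i_end[1], seg$i_start[2])
})

test_that("constant-taudot tracks are mostly rejected at low f", {
  tr <- simulate_constant_taudot(y0 = 0.3, V0 = 0.3, c = -0.87)
  kt <- compute_state_variables(tr, cfg)
  seg <- detect_constant_r_segments(kt, f = 0.25, cfg)
  cov <- covered_fraction(kt, seg, cfg)
  expect_lte(ifelse(is.na(cov), 0, cov), 0.20)
})

test_that("brute force and greedy agree on clean tracks and empty inputs", {
  tr <- simulate_constant_r(y0 = 0.3, r_set = 2.0)
  kt <- compute_state_variables(tr, cfg)
  g <- detect_constant_r_segments(kt, f = 1, cfg)
  b <- brute_force_segments(kt, f = 1, cfg)
  expect_equal(g$i_start, b$i_start)
  expect_equal(g$i_end, b$i_end)
  expect_equal(g$r_star, b$r_star, tolerance = 1e-12)

  # accelerating track: no deceleration phase, both empty
  t <- seq(0, 1.5, by = 1 / 200)
  V <- 0.05 + 0.2 * t
  y <- 0.8 - cumsum(c(0, (V[-1] + V[-length(V)]) / 2 * diff(t)))
  acc <- tibble::tibble(track_id = "acc", t = t, x = 0, y = y, z = 0,
                        light = "low", pattern = "spoke",
                        landing_type = "free_flight")
  ka <- compute_state_variables(acc, cfg)
  expect_equal(nrow(detect_constant_r_segments(ka, 1, cfg)), 0L)
  expect_equal(nrow(brute_force_segments(ka, 1, cfg)), 0L)

  long <- kt[rep(seq_len(nrow(kt)), length.out = 2500), ]
  expect_error(brute_force_segments(long, 1, cfg), "2000")
})

test_that("greedy coverage is at least 90% of the brute-force optimum", {
  set.seed(101)
  for (k in 1:15) {
    r1 <- exp(log(rgamma(1, 3.59, scale = 0.65)))
    nb <- sample(1:3, 1)
    h <- simulate_hybrid(y0 = runif(1, 0.25, 0.41), r1 = max(r1, 0.4),
                         c = runif(1, -0.95, -0.6), n_bouts = nb,
                         lead_fraction = runif(1, 0, 0.3))
    tr <- add_tracking_noise(h$track, 2e-4)
    kt <- compute_state_variables(tr, cfg)
    g <- detect_constant_r_segments(kt, f = 1, cfg)
    b <- brute_force_segments(kt, f = 1, cfg)
    cov_g <- sum(g$i_end - g$i_start + 1)
    cov_b <- sum(b$i_end - b$i_start + 1)
    if (cov_b > 0) expect_gte(cov_g, 0.9 * cov_b)
  }
})

test_that("the f sweep reports a monotone yield and collapses duplicates", {
  set.seed(5)
  ds <- generate_dataset(dataset_spec(n_per_cell = 2, seed = 5))
  kts <- compute_state_variables(ds$tracks, cfg)
  grid <- c(0.25, 0.5, 1.0, 1.5, 2.0, 2.5)
  sw <- sweep_f(kts, grid, cfg)
  expect_equal(nrow(sw), 6L)
  expect_equal(sw$f, grid)
  expect_true(all(diff(sw$n_segments) >= 0 | diff(sw$coverage) >= -1e-12))
  # per-track coverage is non-decreasing in f
  for (id in unique(kts$track_id)[1:5]) {
    kt <- kts[kts$track_id == id, ]
    covered <- vapply(grid, function(f) {
      s <- detect_constant_r_segments(kt, f, cfg)
      sum(s$i_end - s$i_start + 1)
    }, numeric(1))
    expect_true(all(diff(covered) >= 0))
  }
  expect_warning(sw2 <- sweep_f(kts, c(1, 1, 2), cfg), "duplicated")
  expect_equal(sw2$f, c(1, 2))
  # single f equals the direct detection summary
  sw1 <- sweep_f(kts, 1, cfg)
  segs <- detect_constant_r_segments(kts, 1, cfg)
  expect_equal(sw1$n_segments, nrow(segs))
  expect_equal(sw1$r_star_mean, mean(segs$r_star))
})

test_that("consecutive segments pair up with displacement and set-point change", {
  h <- simulate_hybrid(y0 = 0.35, r1 = 1.6, c = -0.85, n_bouts = 3,
                       bout_fraction = 0.15, transition_fraction = 0.15)
  kt <- compute_state_variables(h$track, cfg)
  seg <- detect_constant_r_segments(kt, f = 1, cfg)
  pairs <- pair_consecutive_segments(seg, kt)
  expect_equal(nrow(pairs), nrow(seg) - 1L)
  expect_true(all(pairs$i_start2 > pairs$i_end1))
  expect_true(all(pairs$dy2 >= pairs$dy1_first + pairs$dy1_second - 1e-9))
  expect_equal(pairs$dr_star, diff(seg$r_star), tolerance = 1e-12)
  # displacements across consecutive bouts are bracketed by the annotation
  # bounds: detected windows are interior subsets of their bouts, so dy2
  # lies between the bout-end-to-bout-start gap and the full two-bout span
  m <- match_bouts(h$bouts, seg)
  if (all(m$matched) && nrow(seg) == 3) {
    upper <- h$bouts$y_start[-nrow(h$bouts)] - h$bouts$y_end[-1]
    lower <- h$bouts$y_end[-nrow(h$bouts)] - h$bouts$y_start[-1]
    expect_true(all(pairs$dy2 <= upper + 1e-9))
    expect_true(all(pairs$dy2 >= lower - 1e-9))
    expect_true(all(pairs$dy2 >= 0.8 * upper))  # clipping stays modest
  }
  # single segment: no pairs
  expect_equal(nrow(pair_consecutive_segments(seg[1, ], kt)), 0L)
})

test_that("detection is deterministic", {
  h <- simulate_hybrid(n_bouts = 2)
  tr <- add_tracking_noise(h$track, 2e-4, seed = 3)
  kt <- compute_state_variables(tr, cfg)
  s1 <- detect_constant_r_segments(kt, f = 1, cfg)
  s2 <- detect_constant_r_segments(kt, f = 1, cfg)
  expect_identical(s1, s2)
})
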