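test_that("constant-r generator matches its closed form and an ODE oracle", {
  tr <- simulate_constant_r(y0 = 0.3, r_set = 2.0)
  # closed-form spot value
  expect_equal(tr$y[tr$t == 0.5], 0.3 * exp(-1), tolerance = 1e-12)
  # independent numerical integration of dy/dt = -r y
  y_num <- integrate_approach(0.3, tr$t, function(y, t) 2.0)
  expect_lt(max(abs(tr$y - y_num)), 1e-6)
  # r implied by V0 when r_set missing
  tr2 <- simulate_constant_r(y0 = 0.3, V0 = 0.3, r_set = NULL)
  expect_equal(diff(log(tr2$y))[1] * -200, 1.0, tolerance = 1e-9)
  # noise-free: relative decay per step is exactly constant
  expect_equal(var(diff(log(tr$y))), 0, tolerance = 1e-20)
  expect_error(simulate_constant_r(r_set = -1), "r_set")
})

test_that("constant-taudot generator matches its closed form and an ODE oracle", {
  tr <- simulate_constant_taudot(y0 = 0.3, V0 = 0.3, c = -0.75)
  expect_equal(tr$y[abs(tr$t - 1) < 1e-9], 0.3 * 0.25^(4 / 3),
               tolerance = 1e-12)
  tau0 <- 1
  y_num <- integrate_approach(0.3, tr$t, function(y, t) 1 / (tau0 - 0.75 * t))
  expect_lt(max(abs(tr$y - y_num)), 1e-6)
  # log r is affine in log y with slope c (analytic kinematics)
  V <- 0.3 * (1 - 0.75 * tr$t / tau0)^(-1 / -0.75 - 1)
  r <- V / tr$y
  fit <- lm(log(r) ~ log(tr$y))
  expect_equal(unname(coef(fit)[2]), -0.75, tolerance = 1e-6)
  expect_error(simulate_constant_taudot(c = -1.2), "soft touchdown")
  expect_error(simulate_constant_taudot(c = 0.1), "soft touchdown")
})

test_that("constant-taudot tends to constant-r as c tends to 0-", {
  tr_r <- simulate_constant_r(y0 = 0.3, r_set = 1)
  tr_c <- simulate_constant_taudot(y0 = 0.3, V0 = 0.3, c = -0.01)
  n <- min(nrow(tr_r), nrow(tr_c))
  # r(t) deviates from r(0) by at most ~|c| in relative terms
  tau0 <- 1
  r_c <- 1 / (tau0 - 0.01 * tr_c$t)
  expect_lt(max(abs(r_c / r_c[1] - 1)) , 0.06)
  expect_lt(max(abs(tr_c$y[1:n] - tr_r$y[1:n])), 0.01)
})

test_that("hybrid with a single full-width bout degenerates to constant-r", {
  h <- simulate_hybrid(y0 = 0.3, r1 = 1.5, n_bouts = 1, bout_fraction = 1,
                       lead_fraction = 0)
  tr <- simulate_constant_r(y0 = 0.3, r_set = 1.5)
  n <- min(nrow(h$track), nrow(tr))
  expect_equal(h$track$y[1:n], tr$y[1:n], tolerance = 1e-9)
  expect_equal(nrow(h$bouts), 1L)
  expect_equal(h$bouts$r_star, 1.5)
})

test_that("hybrid set points increase along the schedule and annotations are exact", {
  h <- simulate_hybrid(y0 = 0.3, r1 = 1.5, c = -0.87, n_bouts = 3,
                       bout_fraction = 0.13)
  expect_true(all(diff(h$bouts$r_star) > 0))
  # schedule: log-linear in the bout mid-distances with slope c
  sl <- coef(lm(log(r_star) ~ log(y_mid), data = h$bouts))[2]
  expect_equal(unname(sl), -0.87, tolerance = 1e-9)
  # annotation self-consistency: r from finite differences of y within each
  # bout equals the annotated set point to 0.1%
  tr <- h$track
  for (k in seq_len(nrow(h$bouts))) {
    i <- h$bouts$i_start[k]:h$bouts$i_end[k]
    i <- i[-length(i)]
    r_fd <- -diff(log(tr$y))[i] * 200
    expect_equal(mean(r_fd), h$bouts$r_star[k], tolerance = 1e-3)
  }
  # y at annotated bout boundaries matches the annotation
  expect_equal(tr$y[h$bouts$i_start[1]], h$bouts$y_start[1], tolerance = 0.01)
})

test_that("hybrid layout validation rejects impossible geometries", {
  expect_error(simulate_hybrid(n_bouts = 5, bout_fraction = 0.3), "exceed")
  expect_error(simulate_hybrid(n_bouts = 0), "n_bouts")
  expect_error(simulate_hybrid(c = -1.5), "c must lie")
})

test_that("every noise-free track conserves displacement (integral of V)", {
  tracks <- list(
    simulate_constant_r(y0 = 0.3, r_set = 2),
    simulate_constant_taudot(y0 = 0.3, V0 = 0.3, c = -0.6),
    simulate_hybrid(y0 = 0.35, r1 = 1.8, n_bouts = 2, lead_fraction = 0.2)$track
  )
  for (tr in tracks) {
    v_mid <- -diff(tr$y) / diff(tr$t)  # midpoint speeds
    travelled <- sum(v_mid * diff(tr$t))
    expect_equal(travelled, tr$y[1] - tr$y[nrow(tr)], tolerance = 1e-10)
  }
})

test_that("constant-taudot traverses a span faster than constant-r", {
  # analytic inequality (1 - x^a)/a < -ln x for x in (0,1), a in (0,1)
  for (c in seq(-0.95, -0.05, by = 0.1)) {
    t_r <- time_constant_r(0.3, 0.02, 1.5)
    t_td <- time_constant_taudot(0.3, 0.02, 1 / 1.5, c)
    expect_lt(t_td, t_r)
  }
})

test_that("tracking noise is seeded, unbiased and optional", {
  tr <- simulate_constant_r(y0 = 0.3, r_set = 1.2)
  expect_identical(add_tracking_noise(tr, 0), tr)
  n1 <- add_tracking_noise(tr, 1e-3, seed = 7)
  n2 <- add_tracking_noise(tr, 1e-3, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1$y, tr$y))
  # Monte-Carlo sd of the added noise
  big <- tr[rep(1, 1e5), ]
  noisy <- add_tracking_noise(big, 1e-3, seed = 1)
  expect_equal(sd(noisy$y - big$y), 1e-3, tolerance = 0.01)
  expect_error(add_tracking_noise(tr, -1), "sigma_pos")
})

test_that("generate_dataset honours the cell design and is reproducible", {
  sp <- dataset_spec(n_per_cell = 2, seed = 9)
  ds <- generate_dataset(sp)
  ids <- unique(ds$tracks$track_id)
  expect_length(ids, 24L)  # 12 cells x 2
  cells <- unique(ds$tracks[, c("light", "pattern", "landing_type")])
  expect_equal(nrow(cells), 12L)
  expect_true(all(table(unique(
    ds$tracks[, c("track_id", "light", "pattern", "landing_type")]
  )[, c("light")]) == 8L))
  # truth table covers every track
  expect_setequal(unique(ds$truth$track_id), ids)
  # same seed, byte-identical output
  ds2 <- generate_dataset(sp)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_tracks(ds$tracks, p1); write_tracks(ds2$tracks, p2)
  expect_identical(readLines(p1), readLines(p2))
  # metadata never leaks across cells within a track
  meta <- unique(ds$tracks[, c("track_id", "light")])
  expect_equal(nrow(meta), 24L)
})

test_that("first-bout set points follow the shifted gamma law", {
  sp <- dataset_spec(n_per_cell = 30, seed = 15,
                     light_offsets = c(low = 0, medium = 0, high = 0),
                     p_bouts = 1)
  ds <- generate_dataset(sp)
  first <- ds$truth[ds$truth$bout == 1, ]
  expect_equal(nrow(first), 360L)
  # wide LLN band at this n: mean of gamma(3.59, 0.65) = 2.3335
  expect_equal(mean(first$r_star), 3.59 * 0.65, tolerance = 0.1)
})
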