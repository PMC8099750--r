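test_that("the log-log model recovers an exact line", {
  y <- seq(0.03, 0.3, length.out = 40)
  recs <- tibble::tibble(track_id = sprintf("t%02d", 1:40),
                         y_star = y, r_star = exp(1 - 0.8 * log(y)))
  fit <- fit_loglog_model(recs, random = "none")
  expect_equal(fit$slope, -0.8, tolerance = 1e-8)
  expect_lt(fit$slope_se, 1e-8)
  expect_true(fit$slope >= fit$slope_ci[1] && fit$slope <= fit$slope_ci[2])

  flat <- tibble::tibble(track_id = recs$track_id, y_star = y, r_star = 2)
  fit0 <- fit_loglog_model(flat, random = "none")
  expect_equal(fit0$slope, 0, tolerance = 1e-10)

  expect_error(fit_loglog_model(recs[1, ]), "at least 2")
  one_y <- tibble::tibble(track_id = c("a", "b"), y_star = 0.1,
                          r_star = c(1, 2))
  expect_error(fit_loglog_model(one_y), "distinct")
})

test_that("cell-specific slopes are recovered from schedule-generated records", {
  set.seed(42)
  make_cell <- function(cc, type, n) {
    # 3 segments per track on an exact per-track schedule + small noise
    do.call(rbind, lapply(seq_len(n), function(i) {
      b <- rnorm(1, 0.9, 0.3)
      y <- exp(runif(3, log(0.03), log(0.35)))
      tibble::tibble(
        track_id = paste0(type, i), y_star = y,
        r_star = exp(cc * log(y) + b + rnorm(3, 0, 0.05)),
        landing_type = type)
    }))
  }
  recs <- rbind(make_cell(-0.9, "takeoff", 120),
                make_cell(-0.7, "free_flight", 120))
  fit <- quiet_fit(recs, factors = "landing_type",
                   interactions = "landing_type", select = FALSE)
  sl <- fit$slopes_by_cell
  expect_equal(sort(sl[["ln_y.trend"]]),
               c(-0.9, -0.7), tolerance = 0.05)
  # average slope sits between the two cells
  expect_lt(fit$slope, -0.7); expect_gt(fit$slope, -0.9)
})

test_that("interaction selection keeps real interactions and drops null ones", {
  set.seed(8)
  n <- 150
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    type <- if (i %% 2 == 0) "takeoff" else "free_flight"
    patt <- if (i %% 3 == 0) "spoke" else "checkerboard"
    cc <- if (type == "takeoff") -0.95 else -0.65
    b <- rnorm(1, 0.9, 0.2)
    y <- exp(runif(3, log(0.03), log(0.35)))
    tibble::tibble(track_id = paste0("t", i), y_star = y,
                   r_star = exp(cc * log(y) + b + rnorm(3, 0, 0.05)),
                   landing_type = type, pattern = patt)
  }))
  fit <- quiet_fit(recs, factors = c("pattern", "landing_type"),
                   interactions = c("pattern", "landing_type"))
  sel <- fit$selection
  expect_equal(nrow(sel), 2L)
  expect_true(all(is.finite(sel$p_value)))
  # the real slope difference is detected with overwhelming evidence; the
  # null interaction can only be retained at the nominal 5% type-I rate
  expect_true(sel$retained[sel$interaction == "landing_type"])
  expect_lt(sel$p_value[sel$interaction == "landing_type"], 1e-6)
  expect_gt(sel$p_value[sel$interaction == "pattern"], 1e-3)
  expect_true("landing_type" %in% fit$interactions_kept)
})

test_that("marginal means back-transform the linear predictor", {
  y <- seq(0.03, 0.3, length.out = 30)
  recs <- tibble::tibble(track_id = sprintf("t%02d", 1:30),
                         y_star = y, r_star = exp(1 - 0.8 * log(y)))
  fit <- fit_loglog_model(recs, random = "none")
  mm <- marginal_means(fit, y_ref = 0.15)
  expect_equal(mm$r_star, exp(1 - 0.8 * log(0.15)), tolerance = 1e-8)
  expect_equal(mm$v_star / mm$r_star, 0.15, tolerance = 1e-12)
  expect_error(marginal_means(fit, y_ref = -1), "y_ref")
})

test_that("marginal means recover a known cell offset", {
  set.seed(31)
  recs <- do.call(rbind, lapply(1:300, function(i) {
    light <- if (i %% 2 == 0) "high" else "low"
    off <- if (light == "high") 0.1 else 0
    y <- exp(runif(2, log(0.04), log(0.3)))
    tibble::tibble(track_id = paste0("t", i), y_star = y,
                   r_star = exp(-0.8 * log(y) + 0.8 + off + rnorm(2, 0, 0.1)),
                   light = light)
  }))
  fit <- quiet_fit(recs, factors = "light", interactions = character(0))
  mm <- marginal_means(fit, y_ref = 0.15)
  d <- log(mm$r_star[mm$light == "high"]) - log(mm$r_star[mm$light == "low"])
  se_d <- sqrt(sum(mm$se^2))
  expect_lt(abs(d - 0.1), 1.96 * se_d + 0.02)
})

test_that("gamma MLE matches an established fitter and handles edge cases", {
  set.seed(6)
  x <- rgamma(500, shape = 3.59, scale = 0.65)
  fit <- fit_gamma_setpoints(x, n_boot = 200, seed = 1)
  ref <- fitdistrplus::fitdist(x, "gamma")
  # the profile-equation solve and fitdist's numerical optimiser agree to
  # the optimiser's own tolerance
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, 1 / unname(ref$estimate["rate"]), tolerance = 1e-3)
  expect_equal(fit$median,
               qgamma(0.5, shape = fit$shape, scale = fit$scale))
  expect_true(fit$ci_shape[1] < fit$shape && fit$shape < fit$ci_shape[2])

  # exponential special case: shape CI contains 1
  e <- rexp(800)
  fe <- fit_gamma_setpoints(e, n_boot = 300, seed = 2)
  expect_true(fe$ci_shape[1] <= 1 && 1 <= fe$ci_shape[2])

  expect_error(fit_gamma_setpoints(rep(2, 50)), "degenerate")
  expect_error(fit_gamma_setpoints(c(1, 2, 3)), "at least 10")
  expect_error(fit_gamma_setpoints(c(rep(1, 20), -1)), "> 0")
  # bootstrap is seeded
  f1 <- fit_gamma_setpoints(x, n_boot = 50, seed = 9)
  f2 <- fit_gamma_setpoints(x, n_boot = 50, seed = 9)
  expect_identical(f1$ci_shape, f2$ci_shape)
})

test_that("transition statistics summarise increases and near-zero dips", {
  pairs <- tibble::tibble(
    track_id = c("a", "a", "b"),
    dr_star = c(1.5, -0.2, 0.3),
    dy2 = c(0.1, 0.08, 0.12),
    near_zero_v = c(FALSE, TRUE, FALSE)
  )
  st <- transition_statistics(pairs)
  expect_equal(st$n, 3L)
  expect_equal(st$frac_increasing, 2 / 3)
  expect_equal(st$mean_increase, mean(c(1.5, 0.3)))
  expect_equal(st$frac_near_zero_v, 1 / 3)

  empty <- transition_statistics(pairs[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$frac_increasing))
})

test_that("a monotone generator schedule yields almost only increasing transitions", {
  cfg <- pipeline_config()
  set.seed(77)
  segs_all <- list(); kts_all <- list()
  for (k in 1:25) {
    h <- simulate_hybrid(y0 = runif(1, 0.28, 0.4), r1 = runif(1, 1.2, 2.5),
                         c = -0.85, n_bouts = sample(2:3, 1),
                         track_id = paste0("trk", k),
                         lead_fraction = runif(1, 0, 0.2))
    tr <- add_tracking_noise(h$track, 2e-4)
    kt <- compute_state_variables(tr, cfg)
    segs_all[[k]] <- detect_constant_r_segments(kt, 1, cfg)
    kts_all[[k]] <- kt
  }
  segs <- dplyr::bind_rows(segs_all)
  kts <- dplyr::bind_rows(kts_all)
  pairs <- pair_consecutive_segments(segs, kts)
  st <- transition_statistics(pairs, segs, kts)
  expect_gte(st$frac_increasing, 0.95)
  expect_true(st$mean_dy2_frac > st$mean_dy1_frac)
})
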