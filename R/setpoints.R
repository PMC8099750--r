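# Set-point dynamics: how the constant-r set points r* vary with distance
# y*. Under a constant-tau-dot schedule, log r* is affine in log y* with
# slope equal to tau-dot, so the mixed-model slope below is the tau-dot
# estimate. Natural logarithms throughout.

#' Fit the log-log set-point model
#'
#' Fits `ln r* ~ ln y*` with optional treatment fixed effects (light,
#' pattern, landing type), optional `pattern x ln y*` and
#' `landing_type x ln y*` (and `light x ln y*`) interactions, and a random
#' intercept per track. Estimation is by REML through [lme4::lmer()]; when
#' the data carry at most one segment per track (or `random = "none"`) an
#' ordinary linear model is used instead. Factors enter with sum-to-zero
#' contrasts so the `ln y*` coefficient is the average slope across cells:
#' the tau-dot estimate.
#'
#' Model selection (`select = TRUE`): starting from all requested
#' interactions, each interaction is dropped when a likelihood-ratio test
#' (ML refits) gives p > 0.05, mirroring a minimal-model strategy. Both the
#' full and the minimal fit are kept.
#'
#' @param segments segment tibble (needs `r_star`, `y_star`, `track_id` and
#'   any factor columns used); rows with non-positive `r_star` or `y_star`
#'   are dropped with a warning.
#' @param factors character vector of treatment factors to include as main
#'   effects (those with at least two levels present are kept).
#' @param interactions subset of `factors` allowed to interact with
#'   `ln y*`.
#' @param random `"auto"` (random intercept per track when any track has
#'   more than one segment), `"track"`, or `"none"`.
#' @param select drop non-significant interactions via likelihood-ratio
#'   tests?
#' @return an object of class `setpoint_fit`: a list with the minimal
#'   `model`, the `model_full`, the tau-dot estimate `slope` with `slope_se`
#'   and `slope_ci`, per-cell slopes `slopes_by_cell` (when interactions are
#'   retained), the `selection` table of LRT p values, the factors used and
#'   the model `data`.
#' @export
fit_loglog_model <- function(segments,
                             factors = c("light", "pattern", "landing_type"),
                             interactions = c("light", "pattern", "landing_type"),
                             random = c("auto", "track", "none"),
                             select = TRUE) {
  random <- match.arg(random)
  dat <- as.data.frame(segments)
  if (nrow(dat) < 2) stop_param("need at least 2 segments to fit the model")
  bad <- !(dat$r_star > 0 & dat$y_star > 0)
  if (any(bad)) {
    warning(sum(bad), " segment(s) with non-positive r* or y* dropped",
            call. = FALSE)
    dat <- dat[!bad, , drop = FALSE]
  }
  dat$ln_r <- log(dat$r_star)
  dat$ln_y <- log(dat$y_star)
  if (length(unique(dat$ln_y)) < 2) {
    stop_param("need at least 2 distinct y* values")
  }

  factors <- intersect(factors, names(dat))
  usable <- factors[vapply(factors,
                           function(f) length(unique(dat[[f]])) >= 2,
                           logical(1))]
  if (length(setdiff(factors, usable)) > 0) {
    warning("factor(s) with a single level dropped from the model: ",
            paste(setdiff(factors, usable), collapse = ", "), call. = FALSE)
  }
  interactions <- intersect(interactions, usable)
  for (f in usable) {
    dat[[f]] <- factor(dat[[f]])
    stats::contrasts(dat[[f]]) <- stats::contr.sum(nlevels(dat[[f]]))
  }

  use_lmer <- switch(random,
    none = FALSE,
    track = TRUE,
    auto = anyDuplicated(dat$track_id) > 0
  )

  rhs <- function(inter) {
    terms <- c("ln_y", usable,
               if (length(inter) > 0) paste0("ln_y:", inter))
    paste(terms, collapse = " + ")
  }
  fit_fun <- function(inter, reml = TRUE) {
    if (use_lmer) {
      fml <- stats::as.formula(paste("ln_r ~", rhs(inter), "+ (1 | track_id)"))
      lme4::lmer(fml, data = dat, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      stats::lm(stats::as.formula(paste("ln_r ~", rhs(inter))), data = dat)
    }
  }

  model_full <- fit_fun(interactions)
  selection <- tibble::tibble(interaction = character(0), p_value = numeric(0),
                              retained = logical(0))
  kept <- interactions
  if (select && length(interactions) > 0) {
    for (f in interactions) {
      with_f <- fit_fun(kept, reml = FALSE)
      without_f <- fit_fun(setdiff(kept, f), reml = FALSE)
      p <- stats::anova(without_f, with_f)[["Pr(>Chisq)"]] %||%
        stats::anova(without_f, with_f)[["Pr(>F)"]]
      p <- p[length(p)]
      retained <- is.finite(p) && p <= 0.05
      selection <- rbind(selection,
                         tibble::tibble(interaction = f, p_value = p,
                                        retained = retained))
      if (!retained) kept <- setdiff(kept, f)
    }
  }
  model <- if (identical(sort(kept), sort(interactions))) model_full
           else fit_fun(kept)

  slope <- slope_estimate(model, use_lmer)
  slopes_by_cell <- if (length(kept) > 0) {
    em <- emmeans::emtrends(model, stats::as.formula(
      paste("~", paste(kept, collapse = "*"))), var = "ln_y",
      lmer.df = "asymptotic", data = dat)
    tibble::as_tibble(as.data.frame(em))
  } else NULL

  structure(list(
    model = model, model_full = model_full,
    slope = slope$est, slope_se = slope$se, slope_ci = slope$ci,
    slopes_by_cell = slopes_by_cell,
    selection = selection, interactions_kept = kept,
    factors = usable, used_lmer = use_lmer, data = dat
  ), class = "setpoint_fit")
}

slope_estimate <- function(model, use_lmer) {
  cf <- if (use_lmer) lme4::fixef(model) else stats::coef(model)
  est <- cf[["ln_y"]]
  vc <- as.matrix(stats::vcov(model))
  se <- sqrt(vc["ln_y", "ln_y"])
  ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  list(est = est, se = se, ci = ci)
}

#' @export
print.setpoint_fit <- function(x, ...) {
  cat("Log-log set-point model (slope = tau-dot estimate)\n")
  cat(sprintf("  tau-dot: %.4f (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$slope, x$slope_se, x$slope_ci[1], x$slope_ci[2]))
  cat("  n segments:", nrow(x$data),
      "| random intercept per track:", x$used_lmer, "\n")
  if (nrow(x$selection) > 0) {
    cat("  interaction selection (LRT):\n")
    print(as.data.frame(x$selection), row.names = FALSE)
  }
  invisible(x)
}

#' Marginal set-point predictions at a reference distance
#'
#' Predicts the set point `r*` (and the corresponding approach speed
#' `V* = y_ref * r*`) at distance `y_ref` for each treatment cell, averaging
#' over non-focal factors on the log scale and back-transforming without
#' smearing correction.
#'
#' @param fit a `setpoint_fit`.
#' @param y_ref reference distance, m (> 0).
#' @param by factors to condition on; defaults to all factors in the fit
#'   (overall mean when none).
#' @return a tibble with the factor columns plus `r_star`, `r_star_se`,
#'   `v_star`, `v_star_se` and the log-scale `emmean`, `se`, `lower`,
#'   `upper`.
#' @export
marginal_means <- function(fit, y_ref = 0.15, by = fit$factors) {
  stopifnot(inherits(fit, "setpoint_fit"))
  if (!is_scalar_number(y_ref) || y_ref <= 0) {
    stop_param("y_ref must be > 0")
  }
  spec <- if (length(by) > 0) {
    stats::as.formula(paste("~", paste(by, collapse = "*")))
  } else ~1
  em <- emmeans::emmeans(fit$model, spec, at = list(ln_y = log(y_ref)),
                         lmer.df = "asymptotic", data = fit$data)
  tab <- as.data.frame(em)
  se_col <- if ("SE" %in% names(tab)) "SE" else "std.error"
  lo_col <- grep("lower", names(tab), value = TRUE)[1]
  hi_col <- grep("upper", names(tab), value = TRUE)[1]
  r_star <- exp(tab$emmean)
  res <- tibble::as_tibble(tab[, setdiff(names(tab), c("df", lo_col, hi_col)),
                               drop = FALSE])
  res$lower <- tab[[lo_col]]
  res$upper <- tab[[hi_col]]
  names(res)[names(res) == se_col] <- "se"
  res$r_star <- r_star
  res$r_star_se <- r_star * res$se      # delta method on the log scale
  res$v_star <- y_ref * r_star
  res$v_star_se <- y_ref * res$r_star_se
  res$y_ref <- y_ref
  res
}

#' Gamma fit to the set-point distribution
#'
#' Maximum-likelihood shape/scale fit with percentile bootstrap confidence
#' intervals (nonparametric resampling). The shape MLE solves the profile
#' equation `log(a) - digamma(a) = log(mean x) - mean(log x)` by Newton
#' iteration; the scale follows as `mean(x) / a`.
#'
#' @param r_values positive set-point values (n >= 10).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed seed for the bootstrap resampling.
#' @return an object of class `gamma_fit`: `shape`, `scale`, `ci_shape`,
#'   `ci_scale`, `median` (of the fitted distribution), `n`, `n_boot`.
#' @export
fit_gamma_setpoints <- function(r_values, n_boot = 1000, conf = 0.95,
                                seed = NULL) {
  x <- r_values[is.finite(r_values)]
  if (length(x) < 10) stop_param("need at least 10 values")
  if (any(x <= 0)) stop_param("all values must be > 0")
  if (stats::var(x) == 0) stop_param("degenerate fit: zero-variance input")
  mle <- gamma_mle(mean(x), mean(log(x)))
  boot <- with_seed(seed, {
    n <- length(x)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    xs <- matrix(x[idx], nrow = n)
    gamma_mle(colMeans(xs), colMeans(log(xs)))
  })
  alpha <- (1 - conf) / 2
  structure(list(
    shape = mle$shape, scale = mle$scale,
    ci_shape = stats::quantile(boot$shape, c(alpha, 1 - alpha), names = FALSE),
    ci_scale = stats::quantile(boot$scale, c(alpha, 1 - alpha), names = FALSE),
    median = stats::qgamma(0.5, shape = mle$shape, scale = mle$scale),
    n = length(x), n_boot = n_boot, conf = conf
  ), class = "gamma_fit")
}

# Vectorized Newton solve of log(a) - digamma(a) = s; standard
# Greenwood-Durand style initialisation.
gamma_mle <- function(mean_x, mean_log_x) {
  s <- log(mean_x) - mean_log_x
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (k in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    a_new[a_new <= 0] <- a[a_new <= 0] / 2
    if (max(abs(a_new - a) / a) < 1e-12) {
      a <- a_new
      break
    }
    a <- a_new
  }
  list(shape = a, scale = mean_x / a)
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma fit: shape %.3f [%.3f, %.3f], scale %.3f [%.3f, %.3f], median %.3f (n = %d)\n",
    x$shape, x$ci_shape[1], x$ci_shape[2],
    x$scale, x$ci_scale[1], x$ci_scale[2], x$median, x$n))
  invisible(x)
}

#' Transition statistics between consecutive set points
#'
#' Summarises the paired-segment table: number of transitions, fraction with
#' a strictly increasing set point, mean and sd of the increase among
#' increasing transitions, the displacement fractions `dy1 / dy` and
#' `dy2 / dy` (with `dy` the track's total maneuver displacement, from
#' maneuver start to touchdown), and the fraction of transitions containing
#' near-zero approach velocity.
#'
#' @param pairs pair tibble from [pair_consecutive_segments()].
#' @param segments segment tibble (for the single-segment displacement
#'   fraction); may be NULL.
#' @param ktracks kinematic tibble (for per-track total displacement); may
#'   be NULL, in which case the displacement fractions are NA.
#' @return a list of class `transition_stats`.
#' @export
transition_statistics <- function(pairs, segments = NULL, ktracks = NULL) {
  n <- nrow(pairs)
  if (n == 0) {
    return(structure(list(
      n = 0L, frac_increasing = NA_real_, mean_increase = NA_real_,
      sd_increase = NA_real_, mean_dy1_frac = NA_real_,
      mean_dy2_frac = NA_real_, frac_near_zero_v = NA_real_
    ), class = "transition_stats"))
  }
  dy_total <- NULL
  if (!is.null(ktracks)) {
    dy_total <- vapply(split_tracks(ktracks), function(tr) {
      vi <- which(tr$valid)
      m <- which(tr$maneuver_start)
      if (length(vi) == 0 || length(m) == 0) return(NA_real_)
      tr$y[m[1]] - tr$y[vi[length(vi)]]
    }, numeric(1))
  }
  inc <- pairs$dr_star > 0
  frac_dy <- function(dy, ids) {
    if (is.null(dy_total)) return(NA_real_)
    mean(dy / dy_total[ids], na.rm = TRUE)
  }
  structure(list(
    n = n,
    frac_increasing = mean(inc),
    mean_increase = if (any(inc)) mean(pairs$dr_star[inc]) else NA_real_,
    sd_increase = if (sum(inc) > 1) stats::sd(pairs$dr_star[inc]) else NA_real_,
    mean_dy1_frac = if (!is.null(segments)) {
      frac_dy(segments$dy1, segments$track_id)
    } else NA_real_,
    mean_dy2_frac = frac_dy(pairs$dy2, pairs$track_id),
    frac_near_zero_v = mean(pairs$near_zero_v)
  ), class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf(
    "Transitions: n = %d; increasing %.1f%%; mean increase %.2f 1/s; near-zero-V %.1f%%\n",
    x$n, 100 * (x$frac_increasing %||% NA), x$mean_increase,
    100 * (x$frac_near_zero_v %||% NA)))
  invisible(x)
}
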