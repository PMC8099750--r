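# Average-per-treatment analysis: the classical approach of averaging many
# tracks' V(y) profiles per treatment cell and reading one expansion-rate
# set point from a fixed distance window. Contrasts with the per-track
# segment analysis, with which it agrees exactly when no set-point
# switching exists.

#' Bin-averaged approach profiles per treatment cell
#'
#' Restricts to deceleration-phase samples, bins them by distance to the
#' platform, and averages approach speed and relative rate of expansion
#' across tracks (each track contributes its own per-bin mean, so tracks are
#' weighted equally regardless of sampling density). Bins supported by fewer
#' than `n_min_bin` tracks are flagged `masked`.
#'
#' @param ktracks kinematic tibble from [compute_state_variables()].
#' @param config a [pipeline_config()] (`bin_width`, `n_min_bin`).
#' @param by_cell average within treatment cells (default) or pool all
#'   tracks.
#' @return a profile tibble: cell columns (if `by_cell`), `y_bin` (bin
#'   center, m), `mean_v`, `mean_r`, `n_tracks`, `masked`. Empty input gives
#'   an empty profile with a warning.
#' @export
bin_average_tracks <- function(ktracks, config = pipeline_config(),
                               by_cell = TRUE) {
  sel <- ktracks$valid & ktracks$decel
  d <- ktracks[sel, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no deceleration-phase samples; empty profile", call. = FALSE)
    return(tibble::tibble(y_bin = numeric(0), mean_v = numeric(0),
                          mean_r = numeric(0), n_tracks = integer(0),
                          masked = logical(0)))
  }
  bw <- config$bin_width
  d$y_bin <- (floor(d$y / bw) + 0.5) * bw
  keys <- if (by_cell) c("light", "pattern", "landing_type") else character(0)
  per_track <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(
      c(keys, "track_id", "y_bin")))),
    v = mean(.data$V), r = mean(.data$r), .groups = "drop")
  prof <- dplyr::summarise(
    dplyr::group_by(per_track, dplyr::across(dplyr::all_of(
      c(keys, "y_bin")))),
    mean_v = mean(.data$v), mean_r = mean(.data$r),
    n_tracks = dplyr::n(), .groups = "drop")
  prof$masked <- prof$n_tracks < config$n_min_bin
  prof[order(prof$y_bin), , drop = FALSE]
}

#' Window-mean relative rate of expansion
#'
#' The average-per-treatment set-point estimate: the mean relative rate of
#' expansion over deceleration-phase samples with distance inside
#' `[y_lo, y_hi]`. Tracks are weighted equally (per-track mean first), and
#' the standard error is computed across tracks.
#'
#' @param ktracks kinematic tibble (filter to one treatment cell upstream if
#'   a per-cell estimate is wanted).
#' @param y_lo,y_hi distance window bounds, m.
#' @param config a [pipeline_config()].
#' @param weighting `"track"` (default) weights tracks equally;
#'   `"sample"` pools all samples.
#' @return a list with `r_star`, `se`, `n_tracks`.
#' @export
window_mean_expansion_rate <- function(ktracks, y_lo = 0.04, y_hi = 0.11,
                                       config = pipeline_config(),
                                       weighting = c("track", "sample")) {
  weighting <- match.arg(weighting)
  per_track <- window_means_by_track(ktracks, y_lo, y_hi)
  if (nrow(per_track) == 0) {
    stop_param("no deceleration-phase samples inside [", y_lo, ", ", y_hi,
               "] m")
  }
  if (weighting == "track") {
    list(r_star = mean(per_track$r),
         se = stats::sd(per_track$r) / sqrt(nrow(per_track)),
         n_tracks = nrow(per_track))
  } else {
    sel <- ktracks$valid & ktracks$decel & ktracks$y >= y_lo &
      ktracks$y <= y_hi
    list(r_star = mean(ktracks$r[sel]),
         se = stats::sd(ktracks$r[sel]) / sqrt(sum(sel)),
         n_tracks = nrow(per_track))
  }
}

window_means_by_track <- function(ktracks, y_lo, y_hi) {
  sel <- ktracks$valid & ktracks$decel & ktracks$y >= y_lo & ktracks$y <= y_hi
  d <- ktracks[sel, , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble::tibble(track_id = character(0), r = numeric(0)))
  }
  dplyr::summarise(
    dplyr::group_by(d, .data$track_id, .data$light, .data$pattern,
                    .data$landing_type),
    r = mean(.data$r), v = mean(.data$V), .groups = "drop")
}

#' Treatment effects on the window-mean set point
#'
#' Linear model of the per-track window-mean relative rate of expansion on
#' light, pattern and landing type (one value per track, so no random
#' effect is needed). Reports per-contrast estimates, confidence intervals
#' and p values.
#'
#' @param ktracks kinematic tibble spanning at least two treatment cells.
#' @param config a [pipeline_config()] (`window_lo`, `window_hi`).
#' @return a list with the fitted `model` and a tidy `table` of contrasts.
#' @export
treatment_comparison <- function(ktracks, config = pipeline_config()) {
  d <- window_means_by_track(ktracks, config$window_lo, config$window_hi)
  cells <- unique(d[, c("light", "pattern", "landing_type")])
  if (nrow(cells) < 2) {
    stop_param("need at least 2 treatment cells")
  }
  terms <- c("light", "pattern", "landing_type")
  terms <- terms[vapply(terms, function(f) length(unique(d[[f]])) >= 2,
                        logical(1))]
  d$light <- factor(d$light, levels = intersect(light_levels, d$light))
  model <- stats::lm(stats::as.formula(
    paste("r ~", paste(terms, collapse = " + "))), data = d)
  sm <- summary(model)$coefficients
  ci <- stats::confint(model)
  table <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    lower = ci[, 1], upper = ci[, 2],
    p_value = sm[, "Pr(>|t|)"]
  )
  list(model = model, table = table, n_tracks = nrow(d))
}
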