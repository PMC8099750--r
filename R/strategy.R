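# Speed comparison between the observed hybrid approach and the two pure
# reference strategies over the span of two consecutive constant-r segments.

#' Traversal time under the constant-r law
#'
#' Exact solution of `dy/dt = -r_set * y`:
#' `t = log(y_start / y_end) / r_set`.
#'
#' @param y_start,y_end span bounds, m (`y_start > y_end > 0`; equal bounds
#'   give 0).
#' @param r_set expansion-rate set point, 1/s (> 0).
#' @return time in seconds (vectorized).
#' @export
time_constant_r <- function(y_start, y_end, r_set) {
  if (any(y_end <= 0) || any(y_start < y_end)) {
    stop_param("need y_start >= y_end > 0")
  }
  if (any(r_set <= 0)) stop_param("r_set must be > 0")
  log(y_start / y_end) / r_set
}

#' Traversal time under the constant-tau-dot law
#'
#' Exact solution of `dy/dt = -y / (tau0 + c * t)`:
#' `t = (tau0 / c) * ((y_end / y_start)^(-c) - 1)`. As `c -> 0` this tends
#' to the constant-r limit `tau0 * log(y_start / y_end)`.
#'
#' @param y_start,y_end span bounds, m (`y_start > y_end > 0`).
#' @param tau0 time to contact at span start, s (> 0).
#' @param c time-to-contact rate, in (-1, 0).
#' @return time in seconds (vectorized).
#' @export
time_constant_taudot <- function(y_start, y_end, tau0, c) {
  if (any(y_end <= 0) || any(y_start < y_end)) {
    stop_param("need y_start >= y_end > 0")
  }
  if (any(tau0 <= 0)) stop_param("tau0 must be > 0")
  if (any(c <= -1) || any(c >= 0)) stop_param("c must lie in (-1, 0)")
  (tau0 / c) * ((y_end / y_start)^(-c) - 1)
}

#' Speed ratios of the hybrid strategy against pure references
#'
#' For each pair of consecutive constant-r segments, compares the observed
#' mean approach speed over the combined span (`UH = dy2 / elapsed time`)
#' against the speed the same span would take under (i) a constant-r
#' strategy at the first segment's set point (`Ur`) and (ii) a
#' constant-tau-dot strategy at rate `c_ref`, speed-matched at span start by
#' `tau0 = 1 / r*_1` (`Utaudot`). `Utaudot > Ur` holds strictly for every
#' `c_ref` in (-1, 0).
#'
#' @param pairs pair tibble from [pair_consecutive_segments()].
#' @param c_ref reference time-to-contact rate, in (-1, 0); typically the
#'   dataset-average slope from [fit_loglog_model()].
#' @return a tibble with per-pair `u_h`, `u_r`, `u_taudot`,
#'   `ratio_hybrid_r = UH/Ur` and `ratio_hybrid_taudot = UH/Utaudot`.
#'   Degenerate spans (non-positive duration or displacement) are skipped
#'   with a warning.
#' @export
speed_ratios <- function(pairs, c_ref) {
  if (!is_scalar_number(c_ref) || c_ref <= -1 || c_ref >= 0) {
    stop_param("c_ref must lie in (-1, 0)")
  }
  ok <- pairs$t_span > 0 & pairs$dy2 > 0 & pairs$y_span_end > 0
  if (any(!ok)) {
    warning(sum(!ok), " degenerate pair span(s) skipped", call. = FALSE)
  }
  p <- pairs[ok, , drop = FALSE]
  u_h <- p$dy2 / p$t_span
  t_r <- time_constant_r(p$y_span_start, p$y_span_end, p$r_star1)
  t_td <- time_constant_taudot(p$y_span_start, p$y_span_end,
                               1 / p$r_star1, c_ref)
  u_r <- p$dy2 / t_r
  u_taudot <- p$dy2 / t_td
  tibble::tibble(
    track_id = p$track_id,
    u_h = u_h, u_r = u_r, u_taudot = u_taudot,
    ratio_hybrid_r = u_h / u_r,
    ratio_hybrid_taudot = u_h / u_taudot,
    c_ref = c_ref,
    light = p$light, pattern = p$pattern, landing_type = p$landing_type
  )
}
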