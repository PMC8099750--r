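# Detection of constant-r segments within deceleration phases.
#
# Admissibility of a candidate window [i, j] is defined by two criteria,
# both scaled by the sensitivity factor f:
#   spread: (max r - min r) / (2 * mean r) <= f * tol_r
#   drift : |least-squares slope of r vs t| / mean r <= f * tol_slope
# plus a minimum displacement (dy_min) and duration (t_min). The spread
# criterion bounds how far r wanders from its set point; the drift guard
# rejects windows where r trends monotonically but happens to have a small
# range. Raising f relaxes both, which yields more (and wider) segments --
# fewer false negatives at the cost of more false positives.

# Enumerate all admissible windows within one deceleration phase.
# r_p, y_p, t_p: state over the phase samples. Returns absolute-index
# windows (offset added by caller). Vectorized over the window end for each
# window start: cummax/cummin give the running range, cumulative sums give
# the running mean and the running regression slope in O(1) per window.
admissible_windows <- function(r_p, y_p, t_p, f, config) {
  n <- length(r_p)
  dt <- if (n > 1) t_p[2] - t_p[1] else Inf
  # duration >= t_min with a guard against binary round-off in t_min / dt
  min_len <- max(2L, as.integer(ceiling(config$t_min / dt - 1e-9)) + 1L)
  if (n < min_len) {
    return(list(i = integer(0), j = integer(0), len = integer(0),
                residual = numeric(0)))
  }
  out_i <- vector("list", n); out_j <- vector("list", n)
  out_res <- vector("list", n)
  tol_r <- f * config$tol_r
  tol_s <- f * config$tol_slope
  for (i in seq_len(n - min_len + 1L)) {
    seg <- r_p[i:n]
    m <- seq_along(seg)                       # window lengths
    rng <- cummax(seg) - cummin(seg)
    s_r <- cumsum(seg)
    mean_r <- s_r / m
    tt <- t_p[i:n] - t_p[i]
    s_t <- cumsum(tt)
    s_tt <- cumsum(tt * tt)
    s_tr <- cumsum(tt * seg)
    denom <- s_tt - s_t^2 / m
    slope <- ifelse(denom > 0, (s_tr - s_t * s_r / m) / denom, 0)
    dy <- y_p[i] - y_p[i:n]
    spread <- rng / (2 * mean_r)
    ok <- m >= min_len & dy >= config$dy_min & mean_r > 0 &
      spread <= tol_r & abs(slope) / mean_r <= tol_s
    if (any(ok)) {
      jj <- which(ok)
      out_i[[i]] <- rep.int(i, length(jj))
      out_j[[i]] <- i + jj - 1L
      out_res[[i]] <- spread[jj]
    }
  }
  list(i = unlist(out_i) %||% integer(0),
       j = unlist(out_j) %||% integer(0),
       len = (unlist(out_j) %||% integer(0)) - (unlist(out_i) %||% integer(0)) + 1L,
       residual = unlist(out_res) %||% numeric(0))
}

window_admissible <- function(r_w, y_w, t_w, f, config) {
  n <- length(r_w)
  if (n < 2) return(FALSE)
  dy <- y_w[1] - y_w[n]
  if (dy < config$dy_min || (t_w[n] - t_w[1]) < config$t_min - 1e-9) {
    return(FALSE)
  }
  mean_r <- mean(r_w)
  if (mean_r <= 0) return(FALSE)
  spread <- (max(r_w) - min(r_w)) / (2 * mean_r)
  if (spread > f * config$tol_r) return(FALSE)
  tt <- t_w - t_w[1]
  slope <- stats::cov(tt, r_w) / stats::var(tt)
  abs(slope) / mean_r <= f * config$tol_slope
}

summarise_segment <- function(ktr, i, j, f, config) {
  idx <- i:j
  r_star <- if (config$r_star_estimator == "slope") {
    sum(ktr$V[idx] * ktr$y[idx]) / sum(ktr$y[idx]^2)
  } else {
    mean(ktr$r[idx])
  }
  spread <- (max(ktr$r[idx]) - min(ktr$r[idx])) / (2 * mean(ktr$r[idx]))
  tibble::tibble(
    track_id = ktr$track_id[1],
    i_start = i, i_end = j,
    t_start = ktr$t[i], t_end = ktr$t[j],
    y_star = mean(ktr$y[idx]),
    v_star = mean(ktr$V[idx]),
    a_star = mean(ktr$A[idx]),
    r_star = r_star,
    dy1 = ktr$y[i] - ktr$y[j],
    f_used = f,
    residual = spread,
    light = ktr$light[1], pattern = ktr$pattern[1],
    landing_type = ktr$landing_type[1]
  )
}

#' Detect constant-r segments in landing tracks
#'
#' Within each deceleration phase of each track, enumerates all candidate
#' windows with displacement of at least `dy_min` and duration of at least
#' `t_min`, keeps those admissible at sensitivity `f` (see Details), selects
#' the non-overlapping set with maximum total sample coverage (exact dynamic
#' programme; ties resolved toward longer, earlier windows), and finally
#' merges adjacent selected windows whose pooled window is itself
#' admissible. Maximum-coverage selection makes the detected coverage
#' provably non-decreasing in `f` (the admissible set only grows). Each
#' final segment is summarised by the segment means `y*`, `V*`, `A*`, `r*`
#' (the set-point estimate) and its displacement `dy1`.
#'
#' @details A window is admissible when the normalized spread of r,
#'   `(max r - min r) / (2 mean r)`, is at most `f * tol_r` and the absolute
#'   least-squares slope of r against time, normalized by mean r, is at most
#'   `f * tol_slope`. Higher `f` therefore detects more, and wider, segments.
#'
#' @param ktracks kinematic tibble from [compute_state_variables()].
#' @param f sensitivity factor (> 0).
#' @param config a [pipeline_config()].
#' @return a segment tibble, time-ordered within each track, with columns
#'   `track_id, i_start, i_end, t_start, t_end, y_star, v_star, a_star,
#'   r_star, dy1, f_used, residual` and the treatment metadata. Segments
#'   never overlap and never span two deceleration phases.
#' @export
detect_constant_r_segments <- function(ktracks, f = 1,
                                       config = pipeline_config()) {
  if (!is_scalar_number(f) || f <= 0) stop_param("f must be > 0")
  out <- lapply(split_tracks(ktracks), detect_one_track, f = f,
                config = config)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_segments())
  res
}

empty_segments <- function() {
  tibble::tibble(track_id = character(0), i_start = integer(0),
                 i_end = integer(0), t_start = numeric(0), t_end = numeric(0),
                 y_star = numeric(0), v_star = numeric(0),
                 a_star = numeric(0), r_star = numeric(0), dy1 = numeric(0),
                 f_used = numeric(0), residual = numeric(0),
                 light = character(0), pattern = character(0),
                 landing_type = character(0))
}

detect_one_track <- function(ktr, f, config) {
  phases <- deceleration_phases_one(ktr, config)
  segs <- list()
  for (p in seq_len(nrow(phases))) {
    a <- phases$i_start[p]; b <- phases$i_end[p]
    idx <- a:b
    cand <- admissible_windows(ktr$r[idx], ktr$y[idx], ktr$t[idx], f, config)
    if (length(cand$i) == 0) next
    sel <- select_max_coverage(cand, length(idx))
    if (nrow(sel) == 0) next
    sel <- merge_adjacent(sel, ktr, a, f, config)
    for (k in seq_len(nrow(sel))) {
      segs[[length(segs) + 1L]] <-
        summarise_segment(ktr, a + sel$i[k] - 1L, a + sel$j[k] - 1L, f, config)
    }
  }
  res <- dplyr::bind_rows(segs)
  if (nrow(res) > 1) res <- res[order(res$i_start), , drop = FALSE]
  res
}

# Exact maximum-coverage selection of non-overlapping windows by dynamic
# programming over window ends. best[j + 1] is the maximum number of
# covered samples using samples 1..j; candidates are scanned in enumeration
# order (ascending start), so among ties the longer window ending at j
# wins. The result is maximal: no admissible window fits in the uncovered
# remainder (it would increase coverage).
select_max_coverage <- function(cand, n) {
  by_end <- split(seq_along(cand$j), cand$j)
  best <- numeric(n + 1L)
  take <- integer(n + 1L)
  for (j in seq_len(n)) {
    best[j + 1L] <- best[j]
    ids <- by_end[[as.character(j)]]
    for (w in ids) {
      v <- best[cand$i[w]] + (j - cand$i[w] + 1L)
      if (v > best[j + 1L]) {
        best[j + 1L] <- v
        take[j + 1L] <- w
      }
    }
  }
  keep_i <- integer(0); keep_j <- integer(0)
  j <- n
  while (j > 0) {
    w <- take[j + 1L]
    if (w == 0L) {
      j <- j - 1L
    } else {
      keep_i <- c(cand$i[w], keep_i)
      keep_j <- c(j, keep_j)
      j <- cand$i[w] - 1L
    }
  }
  tibble::tibble(i = keep_i, j = keep_j)
}

merge_adjacent <- function(sel, ktr, offset, f, config) {
  k <- 1L
  while (k < nrow(sel)) {
    i1 <- offset + sel$i[k] - 1L
    j2 <- offset + sel$j[k + 1L] - 1L
    idx <- i1:j2
    if (window_admissible(ktr$r[idx], ktr$y[idx], ktr$t[idx], f, config)) {
      sel$j[k] <- sel$j[k + 1L]
      sel <- sel[-(k + 1L), , drop = FALSE]
    } else {
      k <- k + 1L
    }
  }
  sel
}

#' Exhaustive maximum-coverage segment detection (testing oracle)
#'
#' Independent re-implementation of the detection problem for cross-checking
#' [detect_constant_r_segments()]: enumerates every window by plain double
#' loop with scalar running statistics (no shared code with the vectorized
#' production enumerator), applies the same admissibility definition, and
#' selects the exact maximum-coverage non-overlapping set with its own
#' interval dynamic programme. Quadratic in track length; refuses tracks
#' longer than 2000 samples. Intended for tests, not analysis use.
#'
#' @param ktrack kinematic tibble of a single track.
#' @param f sensitivity factor.
#' @param config a [pipeline_config()].
#' @return a segment tibble (same columns as
#'   [detect_constant_r_segments()]).
#' @export
brute_force_segments <- function(ktrack, f = 1, config = pipeline_config()) {
  if (length(unique(ktrack$track_id)) != 1L) {
    stop_param("brute_force_segments expects a single track")
  }
  if (nrow(ktrack) > 2000) {
    stop_param("track too long for brute force (", nrow(ktrack),
               " > 2000 samples)")
  }
  phases <- deceleration_phases_one(ktrack, config)
  segs <- list()
  for (p in seq_len(nrow(phases))) {
    a <- phases$i_start[p]; b <- phases$i_end[p]
    r_p <- ktrack$r[a:b]; y_p <- ktrack$y[a:b]; t_p <- ktrack$t[a:b]
    np <- length(r_p)
    wins <- list()
    for (i in seq_len(np)) {
      run_max <- r_p[i]; run_min <- r_p[i]
      s_r <- r_p[i]; s_t <- 0; s_tt <- 0; s_tr <- 0
      if (i >= np) break
      for (j in (i + 1L):np) {
        rr <- r_p[j]; tt <- t_p[j] - t_p[i]
        if (rr > run_max) run_max <- rr
        if (rr < run_min) run_min <- rr
        s_r <- s_r + rr; s_t <- s_t + tt
        s_tt <- s_tt + tt * tt; s_tr <- s_tr + tt * rr
        m <- j - i + 1L
        if (t_p[j] - t_p[i] < config$t_min - 1e-9) next
        if (y_p[i] - y_p[j] < config$dy_min) next
        mean_r <- s_r / m
        if (mean_r <= 0) next
        if ((run_max - run_min) / (2 * mean_r) > f * config$tol_r) next
        denom <- s_tt - s_t^2 / m
        slope <- if (denom > 0) (s_tr - s_t * s_r / m) / denom else 0
        if (abs(slope) / mean_r > f * config$tol_slope) next
        wins[[length(wins) + 1L]] <- c(i, j)
      }
    }
    if (length(wins) == 0) next
    sel <- oracle_dp(wins, np)
    for (k in seq_len(nrow(sel))) {
      segs[[length(segs) + 1L]] <-
        summarise_segment(ktrack, a + sel$i[k] - 1L, a + sel$j[k] - 1L, f,
                          config)
    }
  }
  res <- dplyr::bind_rows(segs)
  if (nrow(res) == 0) return(empty_segments())
  res[order(res$i_start), , drop = FALSE]
}

# Weighted interval scheduling on the enumerated windows (weight = length),
# solved over windows sorted by end; independent of the production DP.
oracle_dp <- function(wins, n) {
  ends <- vapply(wins, `[`, numeric(1), 2L)
  ord <- order(ends)
  wins <- wins[ord]
  m <- length(wins)
  starts <- vapply(wins, `[`, numeric(1), 1L)
  ends <- ends[ord]
  # p[k]: last window (by end order) finishing before wins[[k]] starts
  p <- findInterval(starts - 1, ends)
  opt <- numeric(m + 1L)
  for (k in seq_len(m)) {
    w <- ends[k] - starts[k] + 1
    opt[k + 1L] <- max(opt[k], opt[p[k] + 1L] + w)
  }
  keep <- list(); k <- m
  while (k > 0) {
    w <- ends[k] - starts[k] + 1
    if (opt[p[k] + 1L] + w >= opt[k + 1L] &&
        opt[k + 1L] > opt[k]) {
      keep[[length(keep) + 1L]] <- c(starts[k], ends[k])
      k <- p[k]
    } else {
      k <- k - 1L
    }
  }
  if (length(keep) == 0) return(tibble::tibble(i = integer(0), j = integer(0)))
  ii <- vapply(keep, `[`, numeric(1), 1L)
  jj <- vapply(keep, `[`, numeric(1), 2L)
  o <- order(ii)
  tibble::tibble(i = as.integer(ii[o]), j = as.integer(jj[o]))
}

#' Sensitivity sweep over the detection factor f
#'
#' Runs [detect_constant_r_segments()] at each value of `f` and summarises
#' the yield: number of segments, number of tracks with at least one
#' segment, fraction of deceleration-phase samples covered, and the
#' distribution of detected set points. Duplicated `f` values are collapsed
#' with a warning.
#'
#' @param ktracks kinematic tibble.
#' @param f_values ascending vector of sensitivity factors.
#' @param config a [pipeline_config()].
#' @return a tibble with one row per `f`: `f, n_segments,
#'   n_tracks_with_segments, coverage, r_star_mean, r_star_median, r_star_sd,
#'   dy1_mean`.
#' @export
sweep_f <- function(ktracks, f_values = c(0.25, 0.5, 1.0, 1.5, 2.0, 2.5),
                    config = pipeline_config()) {
  if (anyDuplicated(f_values)) {
    warning("duplicated f values collapsed", call. = FALSE)
    f_values <- unique(f_values)
  }
  f_values <- sort(f_values)
  n_decel <- sum(vapply(split_tracks(ktracks), function(tr) {
    ph <- deceleration_phases_one(tr, config)
    sum(ph$i_end - ph$i_start + 1L)
  }, numeric(1)))
  rows <- lapply(f_values, function(f) {
    segs <- detect_constant_r_segments(ktracks, f = f, config = config)
    tibble::tibble(
      f = f,
      n_segments = nrow(segs),
      n_tracks_with_segments = length(unique(segs$track_id)),
      coverage = if (n_decel > 0) {
        sum(segs$i_end - segs$i_start + 1L) / n_decel
      } else NA_real_,
      r_star_mean = mean(segs$r_star),
      r_star_median = stats::median(segs$r_star),
      r_star_sd = stats::sd(segs$r_star),
      dy1_mean = mean(segs$dy1)
    )
  })
  dplyr::bind_rows(rows)
}

#' Pair consecutive constant-r segments within tracks
#'
#' For every couple of adjacent detected segments within a track, computes
#' the combined displacement `dy2` (distance at the first segment's start
#' minus distance at the second segment's end), the set-point change
#' `dr_star`, and whether the transition between them contains near-zero
#' approach velocity (`V < 0.05` m/s). Tracks with K segments yield K - 1
#' pairs.
#'
#' @param segments segment tibble from [detect_constant_r_segments()].
#' @param ktracks the kinematic tibble the segments were detected in.
#' @return a pair tibble: `track_id, i_start1, i_end1, i_start2, i_end2,
#'   r_star1, r_star2, dy1_first, dy1_second, dy2, dr_star, near_zero_v,
#'   t_span, y_span_start, y_span_end` plus treatment metadata.
#' @export
pair_consecutive_segments <- function(segments, ktracks) {
  kt <- split_tracks(ktracks)
  out <- list()
  for (id in unique(segments$track_id)) {
    seg <- segments[segments$track_id == id, ]
    seg <- seg[order(seg$i_start), ]
    if (nrow(seg) < 2) next
    ktr <- kt[[id]]
    for (k in seq_len(nrow(seg) - 1L)) {
      s1 <- seg[k, ]; s2 <- seg[k + 1L, ]
      between <- (s1$i_end):(s2$i_start)
      out[[length(out) + 1L]] <- tibble::tibble(
        track_id = id,
        i_start1 = s1$i_start, i_end1 = s1$i_end,
        i_start2 = s2$i_start, i_end2 = s2$i_end,
        r_star1 = s1$r_star, r_star2 = s2$r_star,
        dy1_first = s1$dy1, dy1_second = s2$dy1,
        dy2 = ktr$y[s1$i_start] - ktr$y[s2$i_end],
        dr_star = s2$r_star - s1$r_star,
        near_zero_v = any(ktr$V[between] < 0.05),
        t_span = ktr$t[s2$i_end] - ktr$t[s1$i_start],
        y_span_start = ktr$y[s1$i_start],
        y_span_end = ktr$y[s2$i_end],
        light = s1$light, pattern = s1$pattern,
        landing_type = s1$landing_type
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(track_id = character(0), i_start1 = integer(0),
                          i_end1 = integer(0), i_start2 = integer(0),
                          i_end2 = integer(0), r_star1 = numeric(0),
                          r_star2 = numeric(0), dy1_first = numeric(0),
                          dy1_second = numeric(0), dy2 = numeric(0),
                          dr_star = numeric(0), near_zero_v = logical(0),
                          t_span = numeric(0), y_span_start = numeric(0),
                          y_span_end = numeric(0), light = character(0),
                          pattern = character(0), landing_type = character(0))
  }
  res
}
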