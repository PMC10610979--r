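#' Parameters of the movement-index extraction
#'
#' Thresholds turning an angle time series into discrete posture events.
#' The defaults are explicit analysis settings, not estimates: a stable
#' segment holds every sample within `tolerance_deg` of the segment median
#' for at least `min_duration_s`; a posture change is a level shift of at
#' least `delta_deg` between consecutive stable segments; missing runs up
#' to `gap_fill_s` are interpolated, longer ones split the segmentation.
#'
#' @param tolerance_deg Stability band half-width, degrees (default 5).
#' @param delta_deg Minimum level shift counted as a change, degrees
#'   (default 10). Must be at least `tolerance_deg`.
#' @param min_duration_s Minimum stable-segment length, seconds (default 2).
#' @param gap_fill_s Maximum missing gap to interpolate, seconds (default 1).
#' @return list of class `index_params`.
#' @export
index_params <- function(tolerance_deg = 5, delta_deg = 10,
                         min_duration_s = 2, gap_fill_s = 1) {
  if (any(c(tolerance_deg, delta_deg, min_duration_s, gap_fill_s) <= 0))
    np_stop("napscope_domain_error", "all index parameters must be positive")
  if (delta_deg < tolerance_deg)
    np_stop("napscope_domain_error",
            "delta_deg must be at least tolerance_deg")
  structure(list(tolerance_deg = tolerance_deg, delta_deg = delta_deg,
                 min_duration_s = min_duration_s, gap_fill_s = gap_fill_s),
            class = "index_params")
}

# greedy scan of one gap-free block: grow a segment while its running range
# stays within 2 * tolerance (a necessary condition for every sample to sit
# within +/- tolerance of the segment median), then verify the median
# criterion and trim from the right if violated.
scan_block <- function(x, t, dt, params) {
  tol <- params$tolerance_deg
  segs <- list()
  s <- 1L
  n <- length(x)
  while (s <= n) {
    xs <- x[s:n]
    over <- cummax(xs) - cummin(xs) > 2 * tol
    e <- if (any(over)) s + which.max(over) - 2L else n
    while (e > s) {
      m <- stats::median(x[s:e])
      bad <- which(abs(x[s:e] - m) > tol)
      if (!length(bad)) break
      e <- s + bad[1] - 2L
    }
    if (e >= s) {
      dur <- (e - s + 1) * dt
      if (dur >= params$min_duration_s - 1e-9) {
        segs[[length(segs) + 1]] <- data.frame(
          start_s = t[s], end_s = t[e] + dt,
          level_deg = stats::median(x[s:e]), n_samples = e - s + 1L)
      }
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  segs
}

#' Detect stable segments of an angle series
#'
#' Maximal intervals of at least `min_duration_s` in which every sample lies
#' within `tolerance_deg` of the interval median. Missing runs longer than
#' `gap_fill_s` (left unfilled by [fill_gaps()]) split the series; samples
#' inside shorter unfilled runs are skipped. Segments are returned in time
#' order and do not overlap. Segment duration counts whole frames
#' (`end_s - start_s` includes the last frame's dwell of one frame period).
#'
#' @param series A gap-filled [angle_series()].
#' @param params An [index_params()].
#' @return data.frame with columns `start_s`, `end_s`, `level_deg`,
#'   `n_samples` (possibly 0 rows).
#' @export
segment_stable_periods <- function(series, params = index_params()) {
  x <- series$value_deg
  t <- series$time_s
  dt <- 1 / series$fps
  segs <- list()
  runs <- na_runs(x)
  bounds <- c(0L, if (nrow(runs)) as.vector(t(runs)), length(x) + 1L)
  # blocks of consecutive present samples
  starts <- bounds[seq(1, length(bounds), 2)] + 1L
  ends <- bounds[seq(2, length(bounds), 2)] - 1L
  for (b in seq_along(starts)) {
    if (ends[b] < starts[b]) next
    idx <- starts[b]:ends[b]
    segs <- c(segs, scan_block(x[idx], t[idx], dt, params))
  }
  if (!length(segs))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      level_deg = numeric(0), n_samples = integer(0)))
  do.call(rbind, segs)
}

#' Count posture changes between stable segments
#'
#' Number of consecutive stable-segment pairs whose level difference is at
#' least `delta_deg`.
#'
#' @param segments Output of [segment_stable_periods()].
#' @param params An [index_params()].
#' @return Non-negative integer count.
#' @export
count_changes <- function(segments, params = index_params()) {
  if (nrow(segments) < 2) return(0L)
  sum(abs(diff(segments$level_deg)) >= params$delta_deg - 1e-9)
}

#' Maximum change of an angle series
#'
#' The range (max - min) over present samples — the session's largest
#' excursion of the angle, regardless of whether it was held.
#'
#' @param series An [angle_series()].
#' @return Degrees, non-negative.
#' @export
max_change <- function(series) {
  v <- series$value_deg[!is.na(series$value_deg)]
  if (!length(v))
    np_stop("napscope_data_error", "series '%s' has no present samples",
            series$angle)
  max(v) - min(v)
}

#' Longest and shortest stable times
#'
#' @param segments Output of [segment_stable_periods()].
#' @return list with `max_stable_s`, `min_stable_s` and `flag` ("ok", or
#'   "no_stable_segment" with both times 0).
#' @export
stable_times <- function(segments) {
  if (!nrow(segments))
    return(list(max_stable_s = 0, min_stable_s = 0,
                flag = "no_stable_segment"))
  d <- segments$end_s - segments$start_s
  list(max_stable_s = max(d), min_stable_s = min(d), flag = "ok")
}

#' Movement indices for a whole session
#'
#' Computes, per angle: the number of posture changes, the maximum change
#' (series range), the largest single between-segment level shift, the
#' maximum and minimum stable times, and the session duration. Angles whose
#' series is entirely missing are flagged and reported with NA indices.
#'
#' @param series Named list of 12 [angle_series()] (see
#'   [angle_table_series()]), or an angle table data.frame.
#' @param params An [index_params()].
#' @param subject,condition Optional identifiers copied into the output.
#' @return data.frame with one row per angle: `subject`, `condition`,
#'   `angle`, `n_changes`, `max_change_deg`, `max_event_change_deg`,
#'   `max_stable_s`, `min_stable_s`, `duration_s`, `flag`.
#' @export
session_indices <- function(series, params = index_params(),
                            subject = NA_character_,
                            condition = NA_character_) {
  if (is.data.frame(series)) series <- angle_table_series(series)
  rows <- lapply(angle_columns(), function(a) {
    s <- series[[a]]
    dur <- diff(range(s$time_s)) + 1 / s$fps
    if (all(is.na(s$value_deg))) {
      return(data.frame(subject = subject, condition = condition, angle = a,
                        n_changes = NA_integer_, max_change_deg = NA_real_,
                        max_event_change_deg = NA_real_,
                        max_stable_s = NA_real_, min_stable_s = NA_real_,
                        duration_s = dur, flag = "all_missing",
                        stringsAsFactors = FALSE))
    }
    sf <- fill_gaps(s, params$gap_fill_s)
    seg <- segment_stable_periods(sf, params)
    st <- stable_times(seg)
    data.frame(
      subject = subject, condition = condition, angle = a,
      n_changes = count_changes(seg, params),
      max_change_deg = max_change(sf),
      max_event_change_deg = if (nrow(seg) > 1)
        max(abs(diff(seg$level_deg))) else 0,
      max_stable_s = st$max_stable_s, min_stable_s = st$min_stable_s,
      duration_s = dur, flag = st$flag, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
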