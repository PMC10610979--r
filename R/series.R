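#' Construct an angle time series
#'
#' One joint angle's trajectory over a session, in degrees, with missing
#' samples allowed (NA).
#'
#' @param angle Angle label (one of [angle_columns()]).
#' @param time_s Strictly increasing timestamps in seconds.
#' @param value_deg Angle values in \[0, 180\] or NA.
#' @param fps Frames per second; inferred from timestamps when NULL,
#'   falling back to 30 for single-sample series.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(angle, time_s, value_deg, fps = NULL) {
  if (length(time_s) != length(value_deg))
    np_stop("napscope_domain_error", "times and values must have equal length")
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    np_stop("napscope_domain_error", "timestamps must be strictly increasing")
  v <- value_deg[!is.na(value_deg)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 180 + 1e-9))
    np_stop("napscope_domain_error", "angles must lie in [0, 180] degrees")
  if (is.null(fps))
    fps <- if (length(time_s) > 1) 1 / stats::median(diff(time_s)) else 30
  structure(
    list(angle = angle, time_s = as.numeric(time_s),
         value_deg = as.numeric(value_deg), fps = fps),
    class = "angle_series"
  )
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("angle_series %s: %d samples (%.1f%% missing), %.4g fps\n",
              x$angle, length(x$time_s),
              100 * mean(is.na(x$value_deg)), x$fps))
  invisible(x)
}

#' Split an angle table into per-angle series
#'
#' @param table Angle table as produced by [stream_angles()] or
#'   [read_angle_csv()]: columns `frame`, `time_s`, then the 12 angles.
#' @return Named list of 12 [angle_series()].
#' @export
angle_table_series <- function(table) {
  miss <- setdiff(c("time_s", angle_columns()), names(table))
  if (length(miss))
    np_stop("napscope_format_error", "angle table misses column(s): %s",
            paste(miss, collapse = ", "))
  out <- lapply(angle_columns(), function(a)
    angle_series(a, table$time_s, table[[a]]))
  stats::setNames(out, angle_columns())
}

# runs of NA in a vector, as (start, end) index pairs
na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Fill short missing gaps by linear interpolation
#'
#' Missing runs whose time span is at most `gap_fill_s` and that are
#' bounded by present samples on both sides are linearly interpolated;
#' longer (or boundary) runs are preserved and later split the series
#' during stable-segment detection.
#'
#' @param series An [angle_series()].
#' @param gap_fill_s Maximum interpolatable gap, seconds.
#' @return The gap-filled [angle_series()].
#' @export
fill_gaps <- function(series, gap_fill_s = 1) {
  x <- series$value_deg
  runs <- na_runs(x)
  if (!nrow(runs)) return(series)
  t <- series$time_s
  n <- length(x)
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, "start"]; e <- runs[i, "end"]
    if (s == 1 || e == n) next
    span <- t[e + 1] - t[s - 1]
    if (span > gap_fill_s + 1e-9) next
    x[s:e] <- stats::approx(x = t[c(s - 1, e + 1)], y = x[c(s - 1, e + 1)],
                            xout = t[s:e])$y
  }
  angle_series(series$angle, t, x, series$fps)
}
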