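#' Construct a pose-landmark stream
#'
#' Container for a whole session of landmark frames: an n x 12 x 2 array of
#' normalized coordinates (NA = absent landmark), a matching visibility
#' matrix, strictly increasing timestamps and fixed frame dimensions.
#'
#' @param time_s Strictly increasing timestamps in seconds.
#' @param width,height Frame dimensions in pixels.
#' @param coords n x 12 x 2 array, second dimension named by
#'   [landmark_names()].
#' @param visibility Optional n x 12 matrix in \[0, 1\]; defaults to 1 where
#'   coordinates are present, 0 elsewhere.
#' @param fps Frames per second; inferred from timestamps when NULL.
#' @return An object of class `pose_stream`.
#' @export
pose_stream <- function(time_s, width, height, coords, visibility = NULL,
                        fps = NULL) {
  n <- length(time_s)
  if (n < 1)
    np_stop("napscope_input_error", "a pose stream needs at least one frame")
  if (n > 1 && any(diff(time_s) <= 0))
    np_stop("napscope_domain_error", "timestamps must be strictly increasing")
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[1] != n ||
        dim(coords)[2] != 12 || dim(coords)[3] != 2)
    np_stop("napscope_domain_error", "coords must be an n x 12 x 2 array")
  if (is.null(dimnames(coords)[[2]]))
    dimnames(coords)[[2]] <- landmark_names()
  ok <- !is.na(coords[, , 1, drop = FALSE]) &
    !is.na(coords[, , 2, drop = FALSE])
  rng <- range(coords[!is.na(coords)])
  if (length(rng) == 2 && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    np_stop("napscope_domain_error",
            "normalized coordinates must lie in [0, 1]")
  if (is.null(visibility)) {
    visibility <- matrix(as.numeric(ok[, , 1]), n, 12,
                         dimnames = list(NULL, dimnames(coords)[[2]]))
  }
  if (is.null(fps)) {
    fps <- if (n > 1) 1 / stats::median(diff(time_s)) else 30
  }
  structure(
    list(time_s = as.numeric(time_s), width = as.integer(width),
         height = as.integer(height), coords = coords,
         visibility = visibility, fps = fps),
    class = "pose_stream"
  )
}

#' Number of frames in a pose stream
#' @param stream A [pose_stream()].
#' @return Integer frame count.
#' @export
n_frames <- function(stream) length(stream$time_s)

#' Extract one frame from a pose stream
#'
#' @param stream A [pose_stream()].
#' @param i Frame position (1-based).
#' @return A [pose_frame()]; absent landmarks are dropped from its points.
#' @export
stream_frame <- function(stream, i) {
  if (i < 1 || i > n_frames(stream))
    np_stop("napscope_input_error", "frame index %d out of range", i)
  pts <- stream$coords[i, , ]
  present <- stats::complete.cases(pts)
  pose_frame(
    frame = i - 1L, time_s = stream$time_s[i],
    width = stream$width, height = stream$height,
    points = pts[present, , drop = FALSE],
    visibility = stream$visibility[i, present]
  )
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("pose_stream: %d frames, %dx%d px, %.4g fps, %.1f s\n",
              n_frames(x), x$width, x$height, x$fps,
              diff(range(x$time_s)) + 1 / x$fps))
  miss <- mean(is.na(x$coords[, , 1]))
  if (miss > 0) cat(sprintf("  missing landmarks: %.1f%%\n", 100 * miss))
  invisible(x)
}
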