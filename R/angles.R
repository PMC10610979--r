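#' Convert normalized coordinates to pixel coordinates
#'
#' Multiplies normalized (x, y) in \[0, 1\] by the frame dimensions. Accepts
#' a length-2 vector or an n x 2 matrix.
#'
#' @param xy Normalized coordinates.
#' @param width,height Frame dimensions in pixels (positive).
#' @return Pixel coordinates with the same shape as `xy`.
#' @export
#' @examples
#' to_pixels(c(0.5, 0.5), 640, 480) # (320, 240)
to_pixels <- function(xy, width, height) {
  if (width <= 0 || height <= 0)
    np_stop("napscope_domain_error", "frame dimensions must be positive")
  m <- if (is.matrix(xy)) xy else matrix(as.numeric(xy), ncol = 2)
  ok <- stats::complete.cases(m)
  if (any(m[ok, ] < 0 | m[ok, ] > 1))
    np_stop("napscope_domain_error",
            "normalized coordinates must lie in [0, 1]")
  m[, 1] <- m[, 1] * width
  m[, 2] <- m[, 2] * height
  if (is.matrix(xy)) m else drop(m)
}

#' Limb vectors at a joint
#'
#' The two limb vectors entering and leaving vertex B: AB = B - A and
#' BC = C - B, componentwise in pixel space.
#'
#' @param A,B,C Length-2 pixel coordinates (first, vertex, last).
#' @return list with elements `AB` and `BC`.
#' @export
limb_vectors <- function(A, B, C) {
  list(AB = c(B[1] - A[1], B[2] - A[2]),
       BC = c(C[1] - B[1], C[2] - B[2]))
}

#' Angle between the two limb vectors at a joint
#'
#' Computes theta = acos( (AB.BC) / (|AB| |BC|) ) in degrees, the angle
#' between vectors AB and BC at vertex B. Under this convention a straight
#' limb scores 0 degrees and a fully folded one 180; the interior joint
#' angle is `180 - theta`. The acos argument is clamped to \[-1, 1\] to
#' absorb floating-point overshoot.
#'
#' @param A,B,C Length-2 pixel coordinates (first, vertex, last).
#' @return Angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' joint_angle(c(0, 0), c(1, 0), c(2, 0)) # straight: 0
#' joint_angle(c(0, 0), c(1, 0), c(1, 1)) # right angle: 90
joint_angle <- function(A, B, C) {
  v <- limb_vectors(A, B, C)
  nab <- sqrt(sum(v$AB^2))
  nbc <- sqrt(sum(v$BC^2))
  if (nab == 0)
    np_stop("napscope_geometry_error",
            "degenerate geometry: limb vector AB has zero length (A == B)")
  if (nbc == 0)
    np_stop("napscope_geometry_error",
            "degenerate geometry: limb vector BC has zero length (B == C)")
  arg <- sum(v$AB * v$BC) / (nab * nbc)
  acos(min(1, max(-1, arg))) * 180 / pi
}

#' All 12 joint angles of one frame
#'
#' Applies [joint_angle()] to every triplet of the topology whose three
#' landmarks are present with sufficient visibility; other angles are
#' reported missing (NA), never raised.
#'
#' @param frame A [pose_frame()].
#' @param topology Triplet table (default [napscope_topology()]).
#' @param min_visibility Visibility threshold for a landmark to be used.
#' @return data.frame with columns `angle`, `time_s`, `theta_deg` (12 rows,
#'   in [angle_columns()] order).
#' @export
frame_angles <- function(frame, topology = napscope_topology(),
                         min_visibility = 0.5) {
  rep_v <- validate_frame(frame, min_visibility)
  usable <- names(rep_v$status)[rep_v$status == "present"]
  px <- frame$points
  px[, 1] <- px[, 1] * frame$width
  px[, 2] <- px[, 2] * frame$height
  out <- vapply(angle_columns(), function(a) {
    tr <- triplet_for(a, topology)
    pts <- c(tr$first, tr$vertex, tr$last)
    if (!all(pts %in% usable)) return(NA_real_)
    tryCatch(
      joint_angle(px[tr$first, ], px[tr$vertex, ], px[tr$last, ]),
      napscope_geometry_error = function(e) NA_real_
    )
  }, numeric(1))
  data.frame(angle = angle_columns(), time_s = frame$time_s,
             theta_deg = unname(out), stringsAsFactors = FALSE)
}

#' Joint angles for a whole landmark stream
#'
#' Vectorized equivalent of applying [frame_angles()] to every frame of a
#' [pose_stream()]: for each triplet, the per-frame pixel-space angle, with
#' NA wherever a required landmark is absent or below the visibility
#' threshold.
#'
#' @param stream A [pose_stream()].
#' @param topology Triplet table.
#' @param min_visibility Visibility threshold.
#' @return An angle table: data.frame with columns `frame`, `time_s` and one
#'   column per angle in [angle_columns()] order.
#' @export
stream_angles <- function(stream, topology = napscope_topology(),
                          min_visibility = 0.5) {
  stopifnot(inherits(stream, "pose_stream"))
  n <- length(stream$time_s)
  co <- stream$coords # n x 12 x 2, normalized
  px <- co
  px[, , 1] <- co[, , 1] * stream$width
  px[, , 2] <- co[, , 2] * stream$height
  usable <- stream$visibility >= min_visibility &
    !is.na(px[, , 1]) & !is.na(px[, , 2])
  out <- matrix(NA_real_, n, 12, dimnames = list(NULL, angle_columns()))
  for (a in angle_columns()) {
    tr <- triplet_for(a, topology)
    ok <- usable[, tr$first] & usable[, tr$vertex] & usable[, tr$last]
    abx <- px[, tr$vertex, 1] - px[, tr$first, 1]
    aby <- px[, tr$vertex, 2] - px[, tr$first, 2]
    bcx <- px[, tr$last, 1] - px[, tr$vertex, 1]
    bcy <- px[, tr$last, 2] - px[, tr$vertex, 2]
    nab <- sqrt(abx^2 + aby^2)
    nbc <- sqrt(bcx^2 + bcy^2)
    ok <- ok & nab > 0 & nbc > 0
    arg <- pmin(1, pmax(-1, (abx * bcx + aby * bcy) / (nab * nbc)))
    th <- acos(arg) * 180 / pi
    th[!ok] <- NA_real_
    out[, a] <- th
  }
  cbind(data.frame(frame = seq_len(n) - 1L, time_s = stream$time_s),
        as.data.frame(out))
}
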