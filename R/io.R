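# ---- file formats -----------------------------------------------------------
#
# angle CSV: header "frame,time_s,KR,KL,ANR,ANL,HR,HL,ELR,ELL,SHR,SHL,WR,WL",
#   one row per frame, empty cell = missing angle, '.' decimal, UTF-8.
# landmark stream: JSON Lines, one frame per line:
#   {"frame":0,"time_s":0.0,"width":640,"height":480,
#    "points":{"SHL":[x,y,visibility],...}}; absent landmarks are omitted.

angle_csv_header <- function() c("frame", "time_s", angle_columns())

#' Write an angle table to CSV
#'
#' Writes the session's per-frame angles in the fixed column order
#' `frame, time_s, KR, KL, ANR, ANL, HR, HL, ELR, ELL, SHR, SHL, WR, WL`.
#' Missing angles become empty cells. With `append = TRUE` the header is
#' written only when the file does not yet exist, so a session can be
#' streamed out incrementally.
#'
#' @param table Angle table (see [stream_angles()]).
#' @param path Output path.
#' @param append Append to an existing file instead of truncating.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(table, path, append = FALSE) {
  miss <- setdiff(angle_csv_header(), names(table))
  if (length(miss))
    np_stop("napscope_format_error", "angle table misses column(s): %s",
            paste(miss, collapse = ", "))
  tab <- table[, angle_csv_header()]
  fmt <- function(x, digits) ifelse(is.na(x), "", sprintf(digits, x))
  lines <- paste(
    tab$frame,
    sprintf("%.6f", tab$time_s),
    apply(vapply(angle_columns(), function(a) fmt(tab[[a]], "%.6f"),
                 character(nrow(tab))), 1, paste, collapse = ","),
    sep = ","
  )
  header_needed <- !(append && file.exists(path))
  con <- tryCatch(file(path, open = if (append) "a" else "w",
                       encoding = "UTF-8"),
                  error = function(e)
                    np_stop("napscope_input_error",
                            "cannot open '%s' for writing", path))
  on.exit(close(con))
  if (header_needed)
    writeLines(paste(angle_csv_header(), collapse = ","), con)
  writeLines(lines, con)
  invisible(path)
}

#' Read an angle CSV into per-angle series
#'
#' Validates the exact header, reports the first mismatched column on
#' format errors, and cites the offending line on parse errors. Empty
#' cells become missing samples.
#'
#' @param path Path to an angle CSV written by [write_angle_csv()].
#' @return Named list of 12 [angle_series()], with the full angle table
#'   attached as attribute `"table"`.
#' @export
read_angle_csv <- function(path) {
  if (!file.exists(path))
    np_stop("napscope_input_error", "angle CSV not found: %s", path)
  raw <- readLines(path, encoding = "UTF-8")
  if (!length(raw))
    np_stop("napscope_format_error", "empty angle CSV: %s", path)
  got <- strsplit(raw[1], ",", fixed = TRUE)[[1]]
  want <- angle_csv_header()
  if (length(got) != length(want) || any(got != want)) {
    i <- which(got[seq_along(want)] != want | is.na(got[seq_along(want)]))[1]
    np_stop("napscope_format_error",
            "angle CSV header mismatch at column %d: expected '%s', found '%s'",
            i, want[i], if (is.na(got[i])) "<missing>" else got[i])
  }
  if (length(raw) < 2)
    np_stop("napscope_format_error", "angle CSV has no data rows: %s", path)
  cells <- strsplit(raw[-1], ",", fixed = TRUE)
  m <- matrix(NA_character_, length(cells), length(want))
  for (i in seq_along(cells)) m[i, seq_along(cells[[i]])] <- cells[[i]]
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
  bad <- which(is.na(num) & !is.na(m) & m != "", arr.ind = TRUE)
  if (nrow(bad))
    np_stop("napscope_parse_error",
            "non-numeric cell '%s' at line %d, column '%s'",
            m[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L, want[bad[1, 2]])
  colnames(num) <- want
  tab <- as.data.frame(num)
  tab$frame <- as.integer(tab$frame)
  out <- angle_table_series(tab)
  attr(out, "table") <- tab
  out
}

#' Write a pose stream as JSON Lines
#'
#' @param stream A [pose_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_jsonl <- function(stream, path) {
  n <- n_frames(stream)
  lm <- dimnames(stream$coords)[[2]]
  lines <- vapply(seq_len(n), function(i) {
    present <- which(!is.na(stream$coords[i, , 1]))
    pts <- lapply(present, function(j)
      c(stream$coords[i, j, 1], stream$coords[i, j, 2],
        stream$visibility[i, j]))
    names(pts) <- lm[present]
    jsonlite::toJSON(list(frame = i - 1L, time_s = stream$time_s[i],
                          width = stream$width, height = stream$height,
                          points = pts),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-Lines landmark stream
#'
#' @param path Path written by [write_pose_jsonl()] (or by an external
#'   pose-estimation backend emitting the same schema).
#' @return A [pose_stream()].
#' @export
read_pose_jsonl <- function(path) {
  if (!file.exists(path))
    np_stop("napscope_input_error", "landmark stream not found: %s", path)
  raw <- readLines(path, encoding = "UTF-8")
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw))
    np_stop("napscope_input_error", "landmark stream is empty: %s", path)
  n <- length(raw)
  co <- array(NA_real_, c(n, 12, 2),
              dimnames = list(NULL, landmark_names(), c("x", "y")))
  vis <- matrix(0, n, 12, dimnames = list(NULL, landmark_names()))
  time_s <- numeric(n)
  width <- height <- NA_integer_
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(raw[i], simplifyVector = TRUE),
                    error = function(e)
                      np_stop("napscope_parse_error",
                              "malformed JSON at line %d of %s", i, path))
    time_s[i] <- rec$time_s
    width <- rec$width; height <- rec$height
    for (nm in names(rec$points)) {
      if (!nm %in% landmark_names())
        np_stop("napscope_topology_error",
                "unknown landmark '%s' at line %d", nm, i)
      v <- rec$points[[nm]]
      co[i, nm, ] <- v[1:2]
      vis[i, nm] <- if (length(v) >= 3) v[3] else 1
    }
  }
  pose_stream(time_s, width, height, co, vis)
}

#' Write / read a movement-index CSV
#'
#' @param indices Index table (see [session_indices()]).
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_indices_csv <- function(indices, path) {
  utils::write.csv(indices, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indices_csv
#' @export
read_indices_csv <- function(path) {
  if (!file.exists(path))
    np_stop("napscope_input_error", "indices CSV not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a study design CSV (subject, condition, body_weight)
#'
#' @param design Design table.
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path))
    np_stop("napscope_input_error", "design CSV not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject", "condition", "body_weight"), names(d))
  if (length(miss))
    np_stop("napscope_format_error", "design CSV misses column(s): %s",
            paste(miss, collapse = ", "))
  d
}

#' Extract joint angles from a landmark source
#'
#' The batch equivalent of the capture loop: every frame is checked for
#' the required landmarks, angles are computed for complete triplets, and
#' incomplete frames are recorded with missing cells — never fabricated.
#' The pose-estimation backend is pluggable: `source` may be a
#' [pose_stream()], a path to a JSON-Lines landmark file, a list of
#' [pose_frame()]s, or — together with `estimator` — a list of arbitrary
#' per-frame payloads (e.g. decoded video frames) that the estimator maps
#' to [pose_frame()]s. Video decoding itself is the backend's job.
#'
#' @param source Landmark source (see Details).
#' @param estimator Optional function mapping one element of `source` to a
#'   [pose_frame()] (or NULL for an undetected frame).
#' @param topology Triplet table.
#' @param min_visibility Visibility threshold.
#' @param csv Optional output path for [write_angle_csv()].
#' @param append Append to the CSV instead of truncating.
#' @return The angle table, invisibly when `csv` is given.
#' @export
extract_angles <- function(source, estimator = NULL,
                           topology = napscope_topology(),
                           min_visibility = 0.5, csv = NULL,
                           append = FALSE) {
  if (is.character(source)) source <- read_pose_jsonl(source)
  if (inherits(source, "pose_stream")) {
    tab <- stream_angles(source, topology, min_visibility)
  } else {
    if (!is.list(source) || !length(source))
      np_stop("napscope_input_error", "no frames in landmark source")
    frames <- if (is.null(estimator)) source else lapply(source, estimator)
    rows <- lapply(seq_along(frames), function(i) {
      fr <- frames[[i]]
      if (is.null(fr)) {
        # estimator failure: frame recorded as fully missing
        ths <- rep(NA_real_, 12)
        tm <- NA_real_
      } else {
        fa <- frame_angles(fr, topology, min_visibility)
        ths <- fa$theta_deg[match(angle_columns(), fa$angle)]
        tm <- fr$time_s
      }
      out <- c(list(frame = i - 1L, time_s = tm),
               stats::setNames(as.list(ths), angle_columns()))
      as.data.frame(out)
    })
    tab <- do.call(rbind, rows)
    # fall back to a 30 fps clock when timestamps are absent
    if (anyNA(tab$time_s)) tab$time_s <- (tab$frame) / 30
  }
  if (!is.null(csv)) {
    write_angle_csv(tab, csv, append = append)
    return(invisible(tab))
  }
  tab
}
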