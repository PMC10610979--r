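#' The 12 monitored body landmarks
#'
#' Returns the names of the 12 body landmarks tracked by the pipeline, in
#' their canonical index order (1-12): left/right shoulder, elbow, wrist,
#' hip, knee and ankle. All user-facing output uses these abbreviations and
#' 1-based indices.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' landmark_names()
landmark_names <- function() {
  c("SHL", "SHR", "ELL", "ELR", "WL", "WR",
    "HL", "HR", "KL", "KR", "ANL", "ANR")
}

#' Canonical angle column order
#'
#' Column order of every angle CSV and indices table (knees first, then
#' ankles, hips, elbows, shoulders, wrists).
#'
#' @return Character vector of the 12 angle labels.
#' @export
angle_columns <- function() {
  c("KR", "KL", "ANR", "ANL", "HR", "HL",
    "ELR", "ELL", "SHR", "SHL", "WR", "WL")
}

#' Skeleton adjacency of the 12-point topology
#'
#' Edges of the reduced 12-point skeleton: same-side shoulder-elbow,
#' elbow-wrist, shoulder-hip, hip-knee and knee-ankle chains, the two girdle
#' edges (shoulder-shoulder, hip-hip), plus the two same-side measurement
#' chords (wrist-hip, ankle-hip) used by the wrist and ankle angle triplets,
#' which have no distal neighbour within the 12-point set.
#'
#' @return A data.frame with columns `from` and `to`.
#' @export
skeleton_edges <- function() {
  e <- rbind(
    c("SHL", "ELL"), c("ELL", "WL"), c("SHL", "HL"),
    c("HL", "KL"), c("KL", "ANL"), c("WL", "HL"), c("ANL", "HL"),
    c("SHR", "ELR"), c("ELR", "WR"), c("SHR", "HR"),
    c("HR", "KR"), c("KR", "ANR"), c("WR", "HR"), c("ANR", "HR"),
    c("SHL", "SHR"), c("HL", "HR")
  )
  data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE)
}

# default vertex-triplet table. Each of the 12 angles is labelled by its
# vertex landmark; first/vertex/last are all same-side. Elbow and knee
# follow the classic shoulder-elbow-wrist / hip-knee-ankle definition;
# shoulder and hip use the torso chain; wrist and ankle (terminal joints
# with no distal neighbour among the 12 points) measure the chord back to
# the same-side hip. The table is a documented, overridable convention
# (see `read_topology()`).
default_triplets <- function() {
  t <- rbind(
    c("ELR", "SHR", "ELR", "WR"),
    c("ELL", "SHL", "ELL", "WL"),
    c("KR",  "HR",  "KR",  "ANR"),
    c("KL",  "HL",  "KL",  "ANL"),
    c("HR",  "SHR", "HR",  "KR"),
    c("HL",  "SHL", "HL",  "KL"),
    c("SHR", "HR",  "SHR", "ELR"),
    c("SHL", "HL",  "SHL", "ELL"),
    c("WR",  "ELR", "WR",  "HR"),
    c("WL",  "ELL", "WL",  "HL"),
    c("ANR", "KR",  "ANR", "HR"),
    c("ANL", "KL",  "ANL", "HL")
  )
  data.frame(angle = t[, 1], first = t[, 2], vertex = t[, 3], last = t[, 4],
             stringsAsFactors = FALSE)
}

validate_topology <- function(topology) {
  need <- c("angle", "first", "vertex", "last")
  if (!is.data.frame(topology) || !all(need %in% names(topology)))
    np_stop("napscope_topology_error",
            "topology must be a data.frame with columns angle, first, vertex, last")
  lm <- landmark_names()
  vals <- unlist(topology[need])
  bad <- setdiff(unique(vals), lm)
  if (length(bad))
    np_stop("napscope_topology_error", "unknown landmark name(s): %s",
            paste(bad, collapse = ", "))
  if (!setequal(topology$angle, lm) || anyDuplicated(topology$angle))
    np_stop("napscope_topology_error",
            "topology must define each of the 12 angles exactly once")
  if (!all(topology$vertex == topology$angle))
    np_stop("napscope_topology_error",
            "each angle must be labelled by its vertex landmark")
  if (any(topology$first == topology$vertex | topology$last == topology$vertex |
            topology$first == topology$last))
    np_stop("napscope_topology_error",
            "triplet points must be pairwise distinct")
  ed <- skeleton_edges()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- key(ed$from, ed$to)
  used <- c(key(topology$first, topology$vertex),
            key(topology$vertex, topology$last))
  if (!all(used %in% edges))
    np_stop("napscope_topology_error",
            "triplet uses a non-adjacent landmark pair: %s",
            paste(setdiff(used, edges), collapse = ", "))
  topology
}

#' The default angle-triplet topology
#'
#' The table mapping each of the 12 angle labels to the (first, vertex, last)
#' landmark triplet used to measure it. The same table ships as a YAML file
#' in `inst/extdata/topology.yaml` so deployments can substitute their own
#' convention via [read_topology()].
#'
#' @return data.frame with columns `angle`, `first`, `vertex`, `last`.
#' @export
#' @examples
#' napscope_topology()
napscope_topology <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- validate_topology(default_triplets())
    cached
  }
})

#' Read an angle-triplet topology from YAML
#'
#' The file maps each angle name to a `[first, vertex, last]` landmark list,
#' e.g. `ELR: [SHR, ELR, WR]`. The result is validated against the 12-point
#' skeleton adjacency.
#'
#' @param path Path to a YAML topology file.
#' @return Validated topology data.frame (see [napscope_topology()]).
#' @export
read_topology <- function(path) {
  if (!file.exists(path))
    np_stop("napscope_input_error", "topology file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!length(y))
    np_stop("napscope_topology_error", "empty topology file: %s", path)
  tab <- data.frame(
    angle = names(y),
    first = vapply(y, function(v) as.character(v[[1]]), ""),
    vertex = vapply(y, function(v) as.character(v[[2]]), ""),
    last = vapply(y, function(v) as.character(v[[3]]), ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  validate_topology(tab)
}

#' Vertex triplet for a named angle
#'
#' @param name Angle label (one of [landmark_names()]).
#' @param topology Triplet table; defaults to [napscope_topology()].
#' @return A list with elements `name`, `first`, `vertex`, `last`.
#' @export
#' @examples
#' triplet_for("ELR") # shoulder-elbow-wrist
triplet_for <- function(name, topology = napscope_topology()) {
  i <- match(name, topology$angle)
  if (is.na(i))
    np_stop("napscope_topology_error", "unknown angle name: '%s'", name)
  list(name = topology$angle[i], first = topology$first[i],
       vertex = topology$vertex[i], last = topology$last[i])
}

#' Construct a single pose frame
#'
#' One timestamped set of normalized landmarks. Coordinates are normalized
#' to the frame, i.e. lie in \[0, 1\]; landmarks may be absent. Visibility
#' defaults to 1 for every present landmark (backends that supply no
#' visibility are treated as fully confident).
#'
#' @param frame Non-negative frame index (0-based).
#' @param time_s Timestamp in seconds.
#' @param width,height Frame dimensions in pixels.
#' @param points Named list or 2-column matrix (rows named by landmark) of
#'   normalized (x, y).
#' @param visibility Optional named numeric vector in \[0, 1\].
#' @return An object of class `pose_frame`.
#' @export
pose_frame <- function(frame, time_s, width, height, points,
                       visibility = NULL) {
  if (width <= 0 || height <= 0)
    np_stop("napscope_domain_error", "frame dimensions must be positive")
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p[1:2])))
    rownames(points) <- nm
  }
  if (is.null(rownames(points)))
    np_stop("napscope_domain_error", "points must be named by landmark")
  bad <- setdiff(rownames(points), landmark_names())
  if (length(bad))
    np_stop("napscope_topology_error", "unknown landmark name(s): %s",
            paste(bad, collapse = ", "))
  ok <- stats::complete.cases(points)
  if (any(points[ok, ] < 0 | points[ok, ] > 1))
    np_stop("napscope_domain_error",
            "normalized coordinates must lie in [0, 1]")
  if (is.null(visibility)) {
    visibility <- stats::setNames(as.numeric(ok), rownames(points))
  }
  structure(
    list(frame = as.integer(frame), time_s = as.numeric(time_s),
         width = as.integer(width), height = as.integer(height),
         points = points, visibility = visibility),
    class = "pose_frame"
  )
}

#' Check a frame for required landmarks
#'
#' Report-only completeness check of a pose frame: a frame is complete iff
#' all 12 landmarks are present with visibility at or above the threshold.
#' Raising the threshold can only shrink the set of complete frames.
#'
#' @param frame A [pose_frame()].
#' @param min_visibility Minimum visibility in \[0, 1\] (default 0.5).
#' @return A list of class `visibility_report` with elements `complete`
#'   (logical), `missing`, `below_threshold` (character vectors) and
#'   `status` (named character vector over all 12 landmarks).
#' @export
validate_frame <- function(frame, min_visibility = 0.5) {
  lm <- landmark_names()
  pts <- frame$points
  present <- lm %in% rownames(pts)
  present[present] <- stats::complete.cases(
    pts[lm[present], , drop = FALSE])
  vis <- rep(0, 12)
  vis[present] <- frame$visibility[lm[present]]
  status <- ifelse(!present, "absent",
                   ifelse(vis < min_visibility, "below_threshold", "present"))
  names(status) <- lm
  structure(
    list(complete = all(status == "present"),
         missing = lm[status == "absent"],
         below_threshold = lm[status == "below_threshold"],
         status = status,
         min_visibility = min_visibility),
    class = "visibility_report"
  )
}

#' @export
print.visibility_report <- function(x, ...) {
  cat(if (x$complete) "complete frame" else "incomplete frame",
      sprintf("(min visibility %.2f)\n", x$min_visibility))
  if (length(x$missing))
    cat(" missing:", paste(x$missing, collapse = " "), "\n")
  if (length(x$below_threshold))
    cat(" below threshold:", paste(x$below_threshold, collapse = " "), "\n")
  invisible(x)
}
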