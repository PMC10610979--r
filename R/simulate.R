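# ---- synthetic nap-session simulator ----------------------------------------
#
# Landmarks are placed on a canonical supine skeleton in an abstract 2D
# plane (hip width = 1 unit, camera overhead, whole bed in frame), then the
# whole session is isotropically mapped into the pixel frame — angles are
# invariant under that map, so every monitored triplet realizes its
# scheduled angle exactly. Placement order is proximal before distal:
# hips/shoulders are fixed anchors; knees and elbows are rotated about
# their proximal joint to realize the hip/shoulder and knee/elbow angles;
# ankle and wrist chord angles (terminal joints) are realized exactly by
# solving the distal limb length in closed form. Their schedules are
# parameterized as offsets above the geometric lower bound of the chord
# angle, so every scheduled configuration is reachable.

sim_anchor <- function() {
  list(HR = c(0, -0.5), HL = c(0, 0.5),
       SHR = c(1.4, -0.6), SHL = c(1.4, 0.6),
       L_thigh = 0.9, L_upper = 0.7)
}

default_level_ranges <- function() {
  # chord-angle offsets start well above zero so that measurement noise can
  # never push a target under the geometric lower bound of the chord, and
  # stay below the knee range minimum so the ankle chord stays under 180
  list(hip = c(5, 50), knee = c(50, 120), shoulder = c(90, 160),
       elbow = c(30, 120), ankle_delta = c(12, 48), wrist_delta = c(12, 48))
}

default_min_shift <- function() {
  list(hip = 15, knee = 20, shoulder = 20, elbow = 20,
       ankle_delta = 15, wrist_delta = 15)
}

# angle column -> (sampler class, side)
angle_class <- function() {
  data.frame(
    angle = angle_columns(),
    class = c("knee", "knee", "ankle_delta", "ankle_delta", "hip", "hip",
              "elbow", "elbow", "shoulder", "shoulder",
              "wrist_delta", "wrist_delta"),
    side = c("R", "L", "R", "L", "R", "L", "R", "L", "R", "L", "R", "L"),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration for one nap session
#'
#' All values have defaults chosen to emulate a ~7-8 minute midday nap
#' with a handful of repositioning events; every random draw flows through
#' R's RNG so a fixed `seed` reproduces the stream bit for bit.
#'
#' @param duration_s Session length in seconds; when NULL, drawn from
#'   N(460, 50) truncated above 60 s.
#' @param fps Frames per second (default 30).
#' @param noise_sigma_deg SD of the per-frame angle measurement noise
#'   (default 1).
#' @param n_events Number of repositioning events; when NULL, drawn from
#'   Poisson(`event_rate`), capped so dwell times of at least `min_dwell_s`
#'   fit in the session.
#' @param event_rate Mean of the Poisson event count (default 5).
#' @param min_dwell_s Minimum time between consecutive events and to the
#'   session boundaries (default 10).
#' @param level_ranges,min_shift_deg Named lists (classes `hip`, `knee`,
#'   `shoulder`, `elbow`, `ankle_delta`, `wrist_delta`) giving the sampling
#'   range of each angle level and the minimum level shift at an event.
#'   Ankle and wrist entries are offsets above the geometric lower bound of
#'   their chord angle, in degrees.
#' @param magnitude_mult Multiplier contracting event level shifts toward
#'   the previous level (1 = none); applied to `effect_angles`.
#' @param effect_angles Angle labels the multiplier applies to; NULL = all.
#' @param occlusion_rate_hz Landmark gap starts per second per landmark
#'   (default 0 = no occlusion).
#' @param occlusion_mean_s Mean gap length in seconds.
#' @param width_px,height_px Frame dimensions (default 640 x 480).
#' @param seed Optional integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration_s = NULL, fps = 30, noise_sigma_deg = 1,
                       n_events = NULL, event_rate = 5, min_dwell_s = 10,
                       level_ranges = default_level_ranges(),
                       min_shift_deg = default_min_shift(),
                       magnitude_mult = 1, effect_angles = NULL,
                       occlusion_rate_hz = 0, occlusion_mean_s = 0.5,
                       width_px = 640, height_px = 480, seed = NULL) {
  if (fps <= 0 || noise_sigma_deg < 0 || event_rate < 0 || min_dwell_s <= 0 ||
        magnitude_mult <= 0 || occlusion_rate_hz < 0 || occlusion_mean_s <= 0 ||
        width_px <= 0 || height_px <= 0)
    np_stop("napscope_config_error", "invalid simulator configuration value")
  if (!is.null(duration_s) && duration_s <= 0)
    np_stop("napscope_config_error", "duration_s must be positive")
  for (cl in names(default_level_ranges())) {
    r <- level_ranges[[cl]]; ms <- min_shift_deg[[cl]]
    if (is.null(r) || is.null(ms) || diff(r) <= 2 * ms)
      np_stop("napscope_config_error",
              "level range for '%s' must be wider than twice its minimum shift",
              cl)
  }
  if (!is.null(effect_angles)) {
    bad <- setdiff(effect_angles, angle_columns())
    if (length(bad))
      np_stop("napscope_config_error", "unknown effect angle(s): %s",
              paste(bad, collapse = ", "))
  }
  structure(
    list(duration_s = duration_s, fps = fps,
         noise_sigma_deg = noise_sigma_deg, n_events = n_events,
         event_rate = event_rate, min_dwell_s = min_dwell_s,
         level_ranges = level_ranges, min_shift_deg = min_shift_deg,
         magnitude_mult = magnitude_mult, effect_angles = effect_angles,
         occlusion_rate_hz = occlusion_rate_hz,
         occlusion_mean_s = occlusion_mean_s,
         width_px = width_px, height_px = height_px, seed = seed),
    class = "sim_config"
  )
}

# uniform draw from [lo, hi] excluding the open interval (base-ms, base+ms);
# the exclusion guarantees a detectable shift relative to `base`
draw_shifted <- function(lo, hi, base, ms) {
  l_lo <- lo; l_hi <- min(hi, base - ms)
  r_lo <- max(lo, base + ms); r_hi <- hi
  wl <- max(0, l_hi - l_lo); wr <- max(0, r_hi - r_lo)
  if (wl + wr <= 0)
    np_stop("napscope_config_error",
            "cannot draw a level shift of %g within [%g, %g]", ms, lo, hi)
  u <- stats::runif(1, 0, wl + wr)
  if (u < wl) l_lo + u else r_lo + (u - wl)
}

# sequential level schedule: start uniform in range, each event moves by at
# least min_shift relative to `base` (= previous own level plus any induced
# drift), contracted toward the previous level by `mag`
sample_levels <- function(k, range_, ms, mag = 1, induced = numeric(k)) {
  lv <- numeric(k + 1)
  lv[1] <- stats::runif(1, range_[1], range_[2])
  for (j in seq_len(k)) {
    base <- lv[j] + induced[j]
    raw <- draw_shifted(range_[1], range_[2], base, ms)
    lv[j + 1] <- lv[j] + mag * (raw - lv[j])
  }
  lv
}

rot2 <- function(dx, dy, a) {
  cbind(dx * cos(a) - dy * sin(a), dx * sin(a) + dy * cos(a))
}

# distal limb length t so that the chord angle at P = V + t*u back to
# anchor C equals theta: angle(u, C - V - t*u) = theta. Closed form from
# the quadratic in t; t <= 0 means the angle is below its geometric lower
# bound (unreachable).
solve_chord_length <- function(u, V, C, theta_deg, what) {
  w <- cbind(C[1] - V[, 1], C[2] - V[, 2])
  a <- u[, 1] * w[, 1] + u[, 2] * w[, 2]
  b2 <- w[, 1]^2 + w[, 2]^2
  cc <- cos(theta_deg * pi / 180)
  s2 <- 1 - cc^2
  if (any(s2 < 1e-12))
    np_stop("napscope_config_error",
            "unreachable %s angle: target of 0 or 180 degrees", what)
  t <- a - cc * sqrt(pmax(0, b2 - a^2) / s2)
  if (any(t <= 1e-9))
    np_stop("napscope_config_error",
            "unreachable %s angle: target below geometric lower bound", what)
  t
}

# place one side of the skeleton for per-frame angle targets (degrees).
# Targets: hip, knee, shoulder, elbow are joint angles; ankle, wrist are
# the full chord-angle targets. Returns K, AN, EL, W (n x 2 each).
place_side <- function(th, side, anc = sim_anchor()) {
  sgn <- if (side == "R") 1 else -1
  H <- anc[[paste0("H", side)]]
  SH <- anc[[paste0("SH", side)]]
  rad <- pi / 180
  d_hs <- (H - SH) / sqrt(sum((H - SH)^2))
  dirK <- rot2(d_hs[1], d_hs[2], sgn * th$hip * rad)
  K <- cbind(H[1] + anc$L_thigh * dirK[, 1], H[2] + anc$L_thigh * dirK[, 2])
  u_sh <- rot2(dirK[, 1], dirK[, 2], sgn * th$knee * rad)
  t_an <- solve_chord_length(u_sh, K, H, th$ankle, "ankle")
  AN <- K + t_an * u_sh
  d_sh <- -d_hs
  dirE <- rot2(d_sh[1], d_sh[2], sgn * th$shoulder * rad)
  EL <- cbind(SH[1] + anc$L_upper * dirE[, 1],
              SH[2] + anc$L_upper * dirE[, 2])
  u_fa <- rot2(dirE[, 1], dirE[, 2], sgn * th$elbow * rad)
  t_w <- solve_chord_length(u_fa, EL, H, th$wrist, "wrist")
  W <- EL + t_w * u_fa
  list(K = K, AN = AN, EL = EL, W = W)
}

# geometric lower bound of the wrist chord angle, per shoulder/elbow level
# (the direction the forearm points relative to the elbow-hip chord)
wrist_alpha0 <- function(shoulder_deg, elbow_deg, side, anc = sim_anchor()) {
  sgn <- if (side == "R") 1 else -1
  H <- anc[[paste0("H", side)]]
  SH <- anc[[paste0("SH", side)]]
  rad <- pi / 180
  d_sh <- (SH - H) / sqrt(sum((SH - H)^2))
  dirE <- rot2(d_sh[1], d_sh[2], sgn * shoulder_deg * rad)
  EL <- cbind(SH[1] + anc$L_upper * dirE[, 1],
              SH[2] + anc$L_upper * dirE[, 2])
  u_fa <- rot2(dirE[, 1], dirE[, 2], sgn * elbow_deg * rad)
  w <- cbind(H[1] - EL[, 1], H[2] - EL[, 2])
  arg <- (u_fa[, 1] * w[, 1] + u_fa[, 2] * w[, 2]) /
    sqrt(w[, 1]^2 + w[, 2]^2)
  acos(pmin(1, pmax(-1, arg))) / rad
}

draw_duration <- function() {
  repeat {
    d <- stats::rnorm(1, 460, 50)
    if (d > 60) return(d)
  }
}

mag_for <- function(config, angle) {
  if (is.null(config$effect_angles) || angle %in% config$effect_angles)
    config$magnitude_mult else 1
}

# realized per-segment levels for all 12 angles (k+1 x 12, degrees)
build_schedule_levels <- function(config, k) {
  ac <- angle_class()
  L <- matrix(NA_real_, k + 1, 12, dimnames = list(NULL, angle_columns()))
  for (side in c("R", "L")) {
    nm <- function(cl) ac$angle[ac$class == cl & ac$side == side]
    for (cl in c("hip", "knee", "shoulder", "elbow")) {
      a <- nm(cl)
      L[, a] <- sample_levels(k, config$level_ranges[[cl]],
                              config$min_shift_deg[[cl]], mag_for(config, a))
    }
    # ankle chord angle = 180 - knee + delta; the induced drift from knee
    # events is compensated so every event remains detectable
    knee <- L[, nm("knee")]
    d_an <- sample_levels(k, config$level_ranges$ankle_delta,
                          config$min_shift_deg$ankle_delta,
                          mag_for(config, nm("ankle_delta")),
                          induced = diff(knee))
    L[, nm("ankle_delta")] <- 180 - knee + d_an
    # wrist chord angle = alpha0(shoulder, elbow) + delta
    a0 <- wrist_alpha0(L[, nm("shoulder")], L[, nm("elbow")], side)
    d_w <- sample_levels(k, config$level_ranges$wrist_delta,
                         config$min_shift_deg$wrist_delta,
                         mag_for(config, nm("wrist_delta")),
                         induced = -diff(a0))
    L[, nm("wrist_delta")] <- a0 + d_w
  }
  L
}

#' Generate one synthetic nap session
#'
#' Produces a landmark stream whose 12 monitored joint angles follow a
#' piecewise-stable schedule with discrete repositioning events, additive
#' Gaussian measurement noise in angle space, and optional landmark
#' occlusion gaps — together with the ground-truth schedule. With zero
#' noise and no occlusion, recomputing angles from the stream reproduces
#' the schedule at every frame.
#'
#' @param config A [sim_config()].
#' @param render Build the landmark stream (default TRUE); FALSE returns
#'   only the ground-truth schedule (used for large study-level
#'   simulations).
#' @return list of class `nap_session`: `stream` (a [pose_stream()] or
#'   NULL) and `schedule` (class `event_schedule`: `event_times_s`,
#'   `levels` — a (k+1) x 12 matrix of realized angle levels —,
#'   `duration_s`, `fps`).
#' @export
generate_session <- function(config = sim_config(), render = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  duration <- config$duration_s %||% draw_duration()
  n <- max(2L, as.integer(round(duration * config$fps)))
  times <- (seq_len(n) - 1) / config$fps
  k_max <- max(0L, as.integer(floor(duration / config$min_dwell_s)) - 1L)
  k <- config$n_events %||% stats::rpois(1, config$event_rate)
  k <- min(k, k_max)
  ev <- if (k > 0) {
    sort(stats::runif(k, 0, duration - (k + 1) * config$min_dwell_s)) +
      config$min_dwell_s * seq_len(k)
  } else numeric(0)
  L <- build_schedule_levels(config, k)
  schedule <- structure(
    list(event_times_s = ev, levels = L, duration_s = n / config$fps,
         fps = config$fps),
    class = "event_schedule"
  )
  if (!render)
    return(structure(list(stream = NULL, schedule = schedule),
                     class = "nap_session"))
  seg <- findInterval(times, ev) + 1L
  tgt <- L[seg, , drop = FALSE] +
    matrix(stats::rnorm(n * 12, 0, config$noise_sigma_deg), n, 12)
  colnames(tgt) <- angle_columns()
  anc <- sim_anchor()
  co <- array(NA_real_, c(n, 12, 2),
              dimnames = list(NULL, landmark_names(), c("x", "y")))
  for (side in c("R", "L")) {
    th <- list(hip = tgt[, paste0("H", side)],
               knee = tgt[, paste0("K", side)],
               ankle = tgt[, paste0("AN", side)],
               shoulder = tgt[, paste0("SH", side)],
               elbow = tgt[, paste0("EL", side)],
               wrist = tgt[, paste0("W", side)])
    pl <- place_side(th, side, anc)
    co[, paste0("H", side), ] <- rep(anc[[paste0("H", side)]], each = n)
    co[, paste0("SH", side), ] <- rep(anc[[paste0("SH", side)]], each = n)
    co[, paste0("K", side), ] <- pl$K
    co[, paste0("AN", side), ] <- pl$AN
    co[, paste0("EL", side), ] <- pl$EL
    co[, paste0("W", side), ] <- pl$W
  }
  # isotropic map of the whole session into the pixel frame (angle
  # preserving), then normalization by the frame dimensions
  xr <- range(co[, , 1]); yr <- range(co[, , 2])
  s <- min(0.9 * config$width_px / max(diff(xr), 1e-9),
           0.9 * config$height_px / max(diff(yr), 1e-9))
  px <- (co[, , 1] - mean(xr)) * s + config$width_px / 2
  py <- (co[, , 2] - mean(yr)) * s + config$height_px / 2
  co[, , 1] <- px / config$width_px
  co[, , 2] <- py / config$height_px
  vis <- matrix(1, n, 12, dimnames = list(NULL, landmark_names()))
  if (config$occlusion_rate_hz > 0) {
    for (j in seq_len(12)) {
      ng <- stats::rpois(1, duration * config$occlusion_rate_hz)
      if (ng == 0) next
      starts <- stats::runif(ng, 0, duration)
      lens <- stats::rexp(ng, 1 / config$occlusion_mean_s)
      drop <- rep(FALSE, n)
      for (g in seq_len(ng))
        drop <- drop | (times >= starts[g] & times < starts[g] + lens[g])
      co[drop, j, ] <- NA_real_
      vis[drop, j] <- 0
    }
  }
  stream <- pose_stream(times, config$width_px, config$height_px, co, vis,
                        fps = config$fps)
  structure(list(stream = stream, schedule = schedule),
            class = "nap_session")
}

#' @export
print.nap_session <- function(x, ...) {
  cat(sprintf("nap_session: %.1f s, %d repositioning events\n",
              x$schedule$duration_s, length(x$schedule$event_times_s)))
  if (!is.null(x$stream)) print(x$stream)
  invisible(x)
}

#' Ground-truth movement indices of a schedule
#'
#' The indices a perfect (noise-free) analysis would recover from an event
#' schedule: number of level shifts of at least `delta_deg`, the range of
#' realized levels, the largest single shift, and dwell times between
#' counted shifts.
#'
#' @param schedule An `event_schedule` (see [generate_session()]).
#' @param params An [index_params()].
#' @param subject,condition Optional identifiers copied into the output.
#' @return data.frame in the schema of [session_indices()].
#' @export
true_indices <- function(schedule, params = index_params(),
                         subject = NA_character_,
                         condition = NA_character_) {
  rows <- lapply(angle_columns(), function(a) {
    lv <- schedule$levels[, a]
    shifts <- diff(lv)
    big <- abs(shifts) >= params$delta_deg - 1e-9
    bounds <- schedule$event_times_s[big]
    dwell <- diff(c(0, bounds, schedule$duration_s))
    data.frame(
      subject = subject, condition = condition, angle = a,
      n_changes = sum(big),
      max_change_deg = max(lv) - min(lv),
      max_event_change_deg = if (length(shifts)) max(abs(shifts)) else 0,
      max_stable_s = max(dwell), min_stable_s = min(dwell),
      duration_s = schedule$duration_s, flag = "truth",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Study configuration: subjects x conditions
#'
#' Describes a repeated-measures study in which every subject naps once
#' under each exposure condition. Condition effects enter as multipliers on
#' the repositioning event rate and on event magnitudes; heavier subjects
#' can be made to move less via a log-linear coupling of the event rate to
#' standardized body weight (negative coupling = fewer movements when
#' heavier).
#'
#' @param n_subjects Number of subjects (default 10).
#' @param conditions Condition labels (default negative/neutral/positive).
#' @param rate_mult,mag_mult Named per-condition multipliers (> 0) on the
#'   event rate and on event level shifts; default all 1 (null study).
#' @param effect_angles Angle labels the magnitude multiplier applies to;
#'   NULL = all.
#' @param weight_mean,weight_sd Body-weight distribution in kg (truncated
#'   to \[45, 120\]).
#' @param weight_coupling Coefficient of standardized body weight in the
#'   log event rate (default 0).
#' @param sim Session-level [sim_config()] template.
#' @param seed Optional integer seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_subjects = 10,
                         conditions = c("negative", "neutral", "positive"),
                         rate_mult = NULL, mag_mult = NULL,
                         effect_angles = NULL,
                         weight_mean = 75, weight_sd = 12,
                         weight_coupling = 0,
                         sim = sim_config(), seed = NULL) {
  if (n_subjects < 2 || length(conditions) < 2)
    np_stop("napscope_config_error",
            "need at least 2 subjects and 2 conditions")
  ones <- stats::setNames(rep(1, length(conditions)), conditions)
  rate_mult <- if (is.null(rate_mult)) ones else rate_mult[conditions]
  mag_mult <- if (is.null(mag_mult)) ones else mag_mult[conditions]
  if (anyNA(rate_mult) || anyNA(mag_mult) ||
        any(rate_mult <= 0) || any(mag_mult <= 0))
    np_stop("napscope_config_error",
            "condition multipliers must be positive and named by condition")
  structure(
    list(n_subjects = n_subjects, conditions = conditions,
         rate_mult = rate_mult, mag_mult = mag_mult,
         effect_angles = effect_angles, weight_mean = weight_mean,
         weight_sd = weight_sd, weight_coupling = weight_coupling,
         sim = sim, seed = seed),
    class = "study_config"
  )
}

#' Generate a multi-subject nap study
#'
#' One session per subject x condition, with condition multipliers applied
#' to event rates and magnitudes and the body-weight coupling applied to
#' event rates. With all multipliers 1 and zero coupling the three
#' conditions are exchangeable (a null study).
#'
#' @param config A [study_config()].
#' @param render "stream" builds full landmark streams; "indices" keeps
#'   only ground-truth schedules (fast; for calibration experiments).
#' @return list of class `nap_study`: `design` (subject, condition,
#'   body_weight), `sessions` (named `subject.condition` list of
#'   `nap_session`), `config`.
#' @export
generate_study <- function(config = study_config(),
                           render = c("stream", "indices")) {
  stopifnot(inherits(config, "study_config"))
  render <- match.arg(render)
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(ns))
  w <- numeric(ns)
  for (i in seq_len(ns)) {
    repeat {
      wi <- stats::rnorm(1, config$weight_mean, config$weight_sd)
      if (wi >= 45 && wi <= 120) break
    }
    w[i] <- wi
  }
  zw <- if (stats::sd(w) > 0) (w - mean(w)) / stats::sd(w) else rep(0, ns)
  grid <- expand.grid(subject = subjects, condition = config$conditions,
                      stringsAsFactors = FALSE)
  seeds <- sample.int(.Machine$integer.max - 1, nrow(grid))
  sessions <- vector("list", nrow(grid))
  names(sessions) <- paste(grid$subject, grid$condition, sep = ".")
  for (r in seq_len(nrow(grid))) {
    i <- match(grid$subject[r], subjects)
    cond <- grid$condition[r]
    rate <- config$sim$event_rate * config$rate_mult[[cond]] *
      exp(config$weight_coupling * zw[i])
    sim_r <- config$sim
    sim_r$seed <- seeds[r]
    sim_r$n_events <- NULL
    sim_r$event_rate <- rate
    sim_r$magnitude_mult <- config$mag_mult[[cond]]
    sim_r$effect_angles <- config$effect_angles
    sessions[[r]] <- generate_session(sim_r, render = render == "stream")
  }
  design <- data.frame(subject = grid$subject, condition = grid$condition,
                       body_weight = w[match(grid$subject, subjects)],
                       stringsAsFactors = FALSE)
  structure(list(design = design, sessions = sessions, config = config),
            class = "nap_study")
}

#' @export
print.nap_study <- function(x, ...) {
  cat(sprintf("nap_study: %d subjects x %d conditions (%s)\n",
              x$config$n_subjects, length(x$config$conditions),
              paste(x$config$conditions, collapse = ", ")))
  invisible(x)
}

#' Ground-truth index table of a study
#'
#' @param study A `nap_study`.
#' @param params An [index_params()].
#' @return data.frame: one [true_indices()] row per session x angle.
#' @export
study_true_indices <- function(study, params = index_params()) {
  rows <- lapply(seq_len(nrow(study$design)), function(r)
    true_indices(study$sessions[[r]]$schedule, params,
                 subject = study$design$subject[r],
                 condition = study$design$condition[r]))
  do.call(rbind, rows)
}

#' Recover index table of a rendered study through the full pipeline
#'
#' Recomputes angles from every session's landmark stream and extracts the
#' movement indices — the estimate the analysis pipeline would produce for
#' real recordings.
#'
#' @param study A `nap_study` generated with `render = "stream"`.
#' @param params An [index_params()].
#' @param topology Triplet table.
#' @param min_visibility Visibility threshold for angle computation.
#' @return data.frame: one [session_indices()] row per session x angle.
#' @export
recover_study_indices <- function(study, params = index_params(),
                                  topology = napscope_topology(),
                                  min_visibility = 0.5) {
  rows <- lapply(seq_len(nrow(study$design)), function(r) {
    st <- study$sessions[[r]]$stream
    if (is.null(st))
      np_stop("napscope_input_error",
              "study was generated with render = 'indices'; no streams to analyze")
    tab <- stream_angles(st, topology, min_visibility)
    session_indices(tab, params, subject = study$design$subject[r],
                    condition = study$design$condition[r])
  })
  do.call(rbind, rows)
}

#' Reshape a wide index table into the long study format
#'
#' @param indices Wide table from [session_indices()],
#'   [study_true_indices()] or [recover_study_indices()].
#' @param which Index columns to keep (default the four session indices).
#' @return Long data.frame `subject`, `condition`, `angle`, `index`,
#'   `value` suitable for [condition_comparison()].
#' @export
indices_long <- function(indices,
                         which = c("n_changes", "max_change_deg",
                                   "max_stable_s", "min_stable_s")) {
  rows <- lapply(which, function(idx)
    data.frame(subject = indices$subject, condition = indices$condition,
               angle = indices$angle, index = idx,
               value = as.numeric(indices[[idx]]),
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
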