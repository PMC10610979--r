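test_that("index_params validates its thresholds", {
  expect_error(index_params(tolerance_deg = -1),
               class = "napscope_domain_error")
  expect_error(index_params(tolerance_deg = 5, delta_deg = 3),
               class = "napscope_domain_error")
})

test_that("fill_gaps interpolates short gaps and preserves long ones", {
  s <- make_series(c(90, 91, 92))
  expect_equal(fill_gaps(s, 2)$value_deg, s$value_deg)

  s2 <- make_series(c(90, NA, 92))
  expect_equal(fill_gaps(s2, 2)$value_deg, c(90, 91, 92))

  # 10 s hole at 1 fps with a 2 s budget stays missing
  s3 <- make_series(c(90, rep(NA, 10), 92))
  expect_equal(is.na(fill_gaps(s3, 2)$value_deg),
               is.na(s3$value_deg))
  # boundary gaps are never extrapolated
  s4 <- make_series(c(NA, 91, 92))
  expect_true(is.na(fill_gaps(s4, 5)$value_deg[1]))
})

test_that("stable segments recover constant and single-step series", {
  p <- index_params()
  s <- make_series(rep(90, 300))
  seg <- segment_stable_periods(s, p)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_s, 0)
  expect_equal(seg$end_s, 300)
  expect_equal(seg$level_deg, 90)

  s2 <- make_series(c(rep(90, 100), rep(130, 200)))
  seg2 <- segment_stable_periods(s2, p)
  expect_equal(nrow(seg2), 2)
  expect_equal(seg2$level_deg, c(90, 130))
  expect_equal(seg2$end_s - seg2$start_s, c(100, 200))
  expect_equal(count_changes(seg2, p), 1)
  expect_equal(stable_times(seg2)$max_stable_s, 200)
  expect_equal(stable_times(seg2)$min_stable_s, 100)
})

test_that("segmentation of a noisy known schedule recovers the event structure", {
  p <- index_params()
  set.seed(7)
  # 5 events at known times, sigma = 1 deg, 10 fps
  levels <- c(90, 120, 75, 110, 60, 100)
  bounds <- c(0, 50, 110, 150, 230, 280, 340)
  values <- unlist(lapply(1:6, function(i)
    rep(levels[i], (bounds[i + 1] - bounds[i]) * 10)))
  values <- values + rnorm(length(values), 0, 1)
  s <- make_series(values, fps = 10)
  seg <- segment_stable_periods(s, p)
  expect_equal(nrow(seg), 6)
  expect_equal(seg$level_deg, levels, tolerance = 0.05)
  # boundaries within one frame of the schedule
  expect_lt(max(abs(seg$start_s - bounds[1:6])), 0.1 + 1e-9)
  expect_equal(count_changes(seg, p), 5)
})

test_that("max_change is the series range and errors on all-missing input", {
  expect_equal(max_change(make_series(rep(42, 10))), 0)
  expect_equal(max_change(make_series(c(60, 100, 145, 80))), 85)
  expect_error(max_change(make_series(rep(NA_real_, 5))),
               class = "napscope_data_error")
})

test_that("stable_times flags the no-segment case", {
  st <- stable_times(segment_stable_periods(make_series(c(0, 50, 100, 150)),
                                            index_params()))
  expect_equal(st$max_stable_s, 0)
  expect_equal(st$flag, "no_stable_segment")
})

test_that("session_indices matches ground truth on a simulated session and flags absent angles", {
  cfg <- sim_config(duration_s = 120, fps = 10, noise_sigma_deg = 1,
                    n_events = 3, seed = 99)
  ses <- generate_session(cfg)
  tab <- stream_angles(ses$stream)
  idx <- session_indices(tab)
  tru <- true_indices(ses$schedule)
  expect_equal(idx$n_changes, tru$n_changes)
  expect_lt(max(abs(idx$max_stable_s - tru$max_stable_s)), 0.1 + 1e-9)
  expect_lt(max(abs(idx$min_stable_s - tru$min_stable_s)), 0.1 + 1e-9)
  expect_equal(unique(idx$duration_s), unique(tru$duration_s))
  # noise can only widen the observed range, and by no more than a few sigma
  expect_true(all(idx$max_change_deg >= tru$max_change_deg - 1e-9))
  expect_true(all(idx$max_change_deg <= tru$max_change_deg + 10))

  tab2 <- tab
  tab2$KL <- NA_real_
  idx2 <- session_indices(tab2)
  expect_equal(idx2$flag[idx2$angle == "KL"], "all_missing")
  expect_true(is.na(idx2$n_changes[idx2$angle == "KL"]))
  expect_equal(sum(idx2$flag == "ok"), 11)
})

test_that("an all-constant session yields zero changes and stability over the whole duration", {
  tab <- data.frame(frame = 0:99, time_s = (0:99) / 10)
  for (a in setdiff(colnames_angle <- c("KR", "KL", "ANR", "ANL", "HR", "HL",
                                        "ELR", "ELL", "SHR", "SHL", "WR",
                                        "WL"), character(0)))
    tab[[a]] <- 70
  idx <- session_indices(tab)
  expect_equal(idx$n_changes, rep(0L, 12))
  expect_equal(idx$max_change_deg, rep(0, 12))
  expect_equal(idx$max_stable_s, rep(10, 12))
  expect_equal(idx$max_stable_s, idx$duration_s)
})

test_that("indices are deterministic and respond monotonically to thresholds", {
  set.seed(21)
  values <- unlist(lapply(c(80, 100, 60, 115), rep, 80)) + rnorm(320, 0, 1.5)
  s <- make_series(values, fps = 4)
  p <- index_params()
  seg <- segment_stable_periods(s, p)
  expect_identical(segment_stable_periods(s, p), seg)

  # increasing delta never increases the change count
  deltas <- c(10, 15, 20, 30, 50)
  counts <- vapply(deltas, function(d)
    count_changes(seg, index_params(delta_deg = d)), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # increasing tolerance never decreases the longest stable time
  tols <- c(3, 5, 8, 12)
  longest <- vapply(tols, function(tl) {
    sg <- segment_stable_periods(s, index_params(tolerance_deg = tl,
                                                 delta_deg = 2 * tl))
    stable_times(sg)$max_stable_s
  }, numeric(1))
  expect_true(all(diff(longest) >= -1e-9))

  # the largest single level shift never exceeds the full range
  expect_lte(max(abs(diff(seg$level_deg))), max_change(s) + 1e-9)
})
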