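test_that("zero-noise sessions reproduce their schedule at every frame", {
  cfg <- sim_config(duration_s = 60, fps = 10, noise_sigma_deg = 0,
                    n_events = 3, min_dwell_s = 5, seed = 11)
  ses <- generate_session(cfg)
  tab <- stream_angles(ses$stream)
  seg <- findInterval(ses$stream$time_s, ses$schedule$event_times_s) + 1
  want <- ses$schedule$levels[seg, ]
  got <- as.matrix(tab[, colnames(want)])
  expect_lt(max(abs(got - want)), 1e-6)

  # zero events: constant at initial levels
  cfg0 <- sim_config(duration_s = 20, fps = 10, noise_sigma_deg = 0,
                     n_events = 0, seed = 5)
  ses0 <- generate_session(cfg0)
  tab0 <- stream_angles(ses0$stream)
  for (a in colnames(ses0$schedule$levels))
    expect_lt(max(abs(tab0[[a]] - ses0$schedule$levels[1, a])), 1e-6)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(duration_s = 15, fps = 10, n_events = 2, min_dwell_s = 3,
                    occlusion_rate_hz = 0.1, seed = 77)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$stream$coords, b$stream$coords)
  expect_identical(a$schedule, b$schedule)
})

test_that("session duration and event dwell respect the configuration", {
  cfg <- sim_config(duration_s = 45, fps = 30, n_events = 3, min_dwell_s = 6,
                    seed = 13)
  ses <- generate_session(cfg)
  expect_equal(ses$schedule$duration_s, 45, tolerance = 1 / 30)
  ev <- ses$schedule$event_times_s
  expect_true(all(diff(c(0, ev, 45)) >= 6 - 1e-9))
  # consecutive realized levels always shift detectably at full magnitude
  expect_true(all(abs(apply(ses$schedule$levels, 2, diff)) >= 10 - 1e-9))
})

test_that("landmark coordinates stay normalized and angles live in [0, 180]", {
  for (seed in 1:5) {
    cfg <- sim_config(duration_s = 30, fps = 10, n_events = 4,
                      min_dwell_s = 3, noise_sigma_deg = 2, seed = seed)
    ses <- generate_session(cfg)
    co <- ses$stream$coords
    expect_true(all(co >= 0 & co <= 1, na.rm = TRUE))
    expect_true(all(ses$schedule$levels >= 0 & ses$schedule$levels <= 180))
  }
})

test_that("occlusion drops landmarks at roughly the configured rate and splits series", {
  cfg <- sim_config(duration_s = 120, fps = 10, n_events = 0,
                    occlusion_rate_hz = 0.05, occlusion_mean_s = 2,
                    seed = 404)
  ses <- generate_session(cfg)
  miss <- mean(is.na(ses$stream$coords[, , 1]))
  # expected missingness ~ rate * mean length = 10%
  expect_gt(miss, 0.02)
  expect_lt(miss, 0.3)
  tab <- stream_angles(ses$stream)
  expect_gt(mean(is.na(as.matrix(tab[, angle_columns_ <- setdiff(names(tab),
    c("frame", "time_s"))]))), 0.02)
})

test_that("the pipeline recovers a 5-event schedule through noise", {
  cfg <- sim_config(duration_s = 460, fps = 30, noise_sigma_deg = 1,
                    n_events = 5, seed = 2024)
  ses <- generate_session(cfg)
  idx <- session_indices(stream_angles(ses$stream))
  tru <- true_indices(ses$schedule)
  expect_equal(idx$n_changes, tru$n_changes)
  expect_equal(idx$n_changes, rep(5L, 12))
})

test_that("unreachable chord angles raise a config error", {
  # ankle offsets below the feasible band push the chord angle under its
  # geometric lower bound: the generator must refuse, not clamp
  cfg <- sim_config(duration_s = 5, fps = 5, n_events = 0, seed = 8)
  cfg$level_ranges$ankle_delta <- c(-60, -20)
  expect_error(generate_session(cfg), class = "napscope_config_error")
  expect_error(sim_config(fps = -1), class = "napscope_config_error")
  expect_error(sim_config(level_ranges = list(hip = c(5, 20))),
               class = "napscope_config_error")
})

test_that("null studies are exchangeable and effect studies suppress the targeted angles", {
  null_cfg <- study_config(n_subjects = 6, seed = 55)
  study <- generate_study(null_cfg, render = "indices")
  expect_equal(nrow(study$design), 18)
  expect_equal(sort(unique(study$design$condition)),
               c("negative", "neutral", "positive"))
  tru <- study_true_indices(study)
  expect_equal(nrow(tru), 18 * 12)

  eff_cfg <- study_config(
    n_subjects = 8,
    mag_mult = c(negative = 1, neutral = 1, positive = 0.4),
    effect_angles = c("KR", "KL", "HR", "HL"),
    seed = 56
  )
  eff <- generate_study(eff_cfg, render = "indices")
  tru_e <- study_true_indices(eff)
  knee <- tru_e[tru_e$angle %in% c("KR", "KL", "HR", "HL"), ]
  by_cond <- tapply(knee$max_change_deg, knee$condition, mean)
  expect_lt(by_cond["positive"], by_cond["negative"])
  expect_lt(by_cond["positive"], by_cond["neutral"])
})

test_that("negative weight coupling yields negative Spearman correlation with movement counts", {
  cfg <- study_config(n_subjects = 12, weight_coupling = -0.8, seed = 57)
  study <- generate_study(cfg, render = "indices")
  tru <- study_true_indices(study)
  per_subject <- tapply(tru$n_changes, tru$subject, mean)
  w <- study$design$body_weight[match(names(per_subject),
                                      study$design$subject)]
  expect_lt(spearman_cor(w, as.numeric(per_subject))$rho, 0)
})

test_that("rendered studies agree with their ground truth through the full pipeline", {
  cfg <- study_config(n_subjects = 3,
                      sim = sim_config(duration_s = 60, fps = 10,
                                       min_dwell_s = 5, event_rate = 3),
                      seed = 58)
  study <- generate_study(cfg, render = "stream")
  rec <- recover_study_indices(study)
  tru <- study_true_indices(study)
  expect_equal(rec$n_changes, tru$n_changes)
  expect_equal(rec$subject, tru$subject)

  idx_only <- generate_study(cfg, render = "indices")
  expect_error(recover_study_indices(idx_only),
               class = "napscope_input_error")
})
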