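test_that("mobility traces are deterministic per seed and respect the profile", {
  prof <- mobility_profile(test_anchors(), c(0.5, 0.3, 0.2))
  a <- simulate_mobility_trace(prof, days = 3, seed = 11)
  b <- simulate_mobility_trace(prof, days = 3, seed = 11)
  expect_identical(a, b)
  c <- simulate_mobility_trace(prof, days = 3, seed = 12)
  expect_false(identical(a, c))

  # single anchor, no jitter: every fix sits exactly on the anchor
  one <- mobility_profile(test_anchors()[1, ], 1, jitter_sd_km = 0,
                          missingness = 0)
  fx <- simulate_mobility_trace(one, days = 1, seed = 4)
  expect_true(all(fx$lat == test_anchors()$lat[1]))
  expect_true(all(fx$lon == test_anchors()$lon[1]))
  # 2 fixes a minute for a day
  expect_equal(nrow(fx), 2 * 60 * 24)

  expect_error(mobility_profile(test_anchors(), c(0.6, 0.3, 0.2)), "sum to 1")
})

test_that("out-of-region episodes place fixes at the remote location", {
  prof <- mobility_profile(
    test_anchors(), c(0.5, 0.3, 0.2), missingness = 0,
    out_of_region_episodes = list(list(start_day = 1, duration_days = 1,
                                       lat = 39.77, lon = -86.16))
  )
  fx <- simulate_mobility_trace(prof, days = 3, seed = 21)
  flagged <- flag_out_of_region(fx)
  away <- fx$t >= 86400 & fx$t < 2 * 86400
  expect_true(all(!flagged$in_region[away]))
  expect_true(all(flagged$in_region[!away]))
})

test_that("wifi logs honor the roster and record programmed ground truth", {
  roster <- tibble::tibble(
    ssid = c("HomeNet", "Starbucks-Guest"),
    rate_per_day = c(2, 0.5),
    mean_session_minutes = c(40, 15)
  )
  a <- simulate_wifi_log(roster, days = 10, seed = 31)
  b <- simulate_wifi_log(roster, days = 10, seed = 31)
  expect_identical(a, b)
  expect_false(is.unsorted(a$t))
  truth <- attr(a, "truth")
  expect_true(nrow(truth) > 0)

  # reconstruction recovers programmed minutes within event-spacing error
  sessions <- segment_sessions(a)
  recovered <- sum(sessions$duration) / 60
  programmed <- sum(truth$programmed_minutes)
  expect_lt(abs(recovered - programmed), 2 * nrow(truth))
  expect_equal(nrow(sessions), nrow(truth))

  # zero session rate: empty log
  none <- simulate_wifi_log(
    tibble::tibble(ssid = "X", rate_per_day = 0, mean_session_minutes = 10),
    days = 5, seed = 1
  )
  expect_equal(nrow(none), 0)

  # an all-guest roster forces private share to zero
  guests <- simulate_wifi_log(
    tibble::tibble(ssid = c("A-Guest", "B-Guest"), rate_per_day = c(1, 1),
                   mean_session_minutes = c(20, 20)),
    days = 10, seed = 5
  )
  feats <- wifi_feature_table(guests)
  expect_equal(feats$private_share, 0)
})

test_that("symptom generation follows the programmed linear model", {
  feats <- tibble::tibble(
    participant_id = c("P1", "P2"),
    entropy = c(1, 2),
    mean_daily_wifi_minutes = c(100, 200),
    employed = c(TRUE, FALSE), student = c(FALSE, TRUE),
    shelter = c("A", "B")
  )
  eff <- true_effects(noise_sd_pcl5 = 0, noise_sd_phq9 = 0)
  got <- simulate_symptoms(feats, effects = eff, seed = 41)
  exp_pcl5 <- round(
    eff$beta0_pcl5 + eff$beta_wifi * feats$mean_daily_wifi_minutes +
      eff$beta_entropy_pcl5 * feats$entropy +
      eff$beta_employed_pcl5 * feats$employed +
      eff$beta_student_pcl5 * feats$student +
      eff$beta_shelterB_pcl5 * (feats$shelter == "B")
  )
  expect_equal(got$pcl5_total, as.integer(pmin(pmax(exp_pcl5, 0), 80)))
  expect_true(all(got$phq9_total >= 0 & got$phq9_total <= 27))
  expect_true(is.numeric(attr(got, "clipping_rate")))

  expect_error(true_effects(nonsense = 1), "unknown effect")
})

test_that("a small cohort simulates deterministically with sane features", {
  cfg <- cohort_config(n_participants = 3, study_days = 25,
                       mean_active_days = 20, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gps, b$gps)
  expect_identical(a$wifi, b$wifi)
  expect_identical(a$participants, b$participants)

  expect_setequal(a$truth$participant_id, a$participants$participant_id)
  expect_true(all(a$participants$phq9_total >= 0 & a$participants$phq9_total <= 27))
  expect_true(all(a$participants$pcl5_total >= 0 & a$participants$pcl5_total <= 80))
  expect_true(all(a$truth$entropy >= 0))

  dir <- withr::local_tempdir()
  write_cohort(a, dir)
  expect_true(all(file.exists(file.path(
    dir, c("gps.csv", "wifi.csv", "participants.csv", "truth.json")
  ))))
  # the written dialect round-trips through the readers
  traces <- read_traces(file.path(dir, "gps.csv"), file.path(dir, "wifi.csv"),
                        file.path(dir, "participants.csv"), quiet = TRUE)
  expect_equal(nrow(traces$participants), 3)
  expect_equal(sum(traces$rejected), 0)
})

test_that("splitting a stream across devices then merging changes nothing", {
  prof <- mobility_profile(test_anchors(), c(0.5, 0.3, 0.2))
  gps <- simulate_mobility_trace(prof, days = 10, seed = 55)
  split <- gps
  split$device_index[split$t >= 5 * 86400] <- 1L
  merged <- merge_device_streams(split)
  merged$device_index <- 0L
  expect_equal(as.data.frame(merged), as.data.frame(gps))
  expect_equal(
    as.data.frame(compute_mobility_features(merged)),
    as.data.frame(compute_mobility_features(gps))
  )
})
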