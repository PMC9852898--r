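test_that("invalid configurations are rejected with the field named", {
  expect_error(study_config(n_participants = 0), "n_participants")
  expect_error(study_config(timeout = 0), "timeout")
  expect_error(study_config(ddm_truth = default_ddm_truth()[1:4, ]),
               "ddm_truth")
  expect_error(rating_model(health_means = c(80, 60, 40, 120)),
               "health_means")
  expect_error(rating_model(rating_sd = 0), "rating_sd")
  expect_error(contamination_rates(low_resolution_rate = 0.7),
               "low_resolution_rate")
})

test_that("a study has the designed trial census and is seed-reproducible", {
  cfg <- study_config(n_participants = 2, pairs_per_combo = 15, rng_seed = 5,
                      contamination = contamination_rates(0, 0, 0, 0))
  study <- simulate_study(cfg)
  # 3 contexts x 2 label blocks x 90 pairs = 540 trials per participant
  expect_equal(unname(table(study$trials$participant_id)),
               array(c(540L, 540L)))
  # the same pairs repeat across the two label blocks of a context
  for (ctx in cfg$contexts) {
    a <- study$trials[study$trials$participant_id == "P001" &
                        study$trials$context == ctx, ]
    expect_equal(a$left_image[!a$nwl_shown], a$left_image[a$nwl_shown])
    expect_equal(a$pair_id[!a$nwl_shown], a$pair_id[a$nwl_shown])
  }
  # every trial condition maps to exactly one ground-truth entry
  key <- unique(study$trials[, c("context", "nwl_shown")])
  m <- merge(key, study$truth$ddm_truth, by = c("context", "nwl_shown"))
  expect_equal(nrow(m), nrow(key))

  study2 <- simulate_study(cfg)
  expect_identical(study$trials, study2$trials)
  expect_identical(study$paths, study2$paths)
  expect_identical(study$ratings, study2$ratings)
})

test_that("ratings follow the configured NWL-indexed means", {
  imgs <- synthetic_image_table()
  m0 <- rating_model(health_means = c(80, 60, 40, 25), rating_sd = 1e-9,
                     recognition_prob = 1)
  set.seed(9)
  r <- simulate_ratings(m0, imgs)
  expect_true(all(r$recognized))
  expect_equal(r$health, c(80, 60, 40, 25)[r$nwl_count + 1],
               tolerance = 1e-6)

  # large-sample check: health declines from 0 to 3 NWL (Welch test)
  md <- rating_model()
  set.seed(10)
  big <- do.call(rbind, replicate(110, simulate_ratings(md, imgs),
                                  simplify = FALSE))
  h0 <- big$health[big$nwl_count == 0]; h3 <- big$health[big$nwl_count == 3]
  expect_gt(length(h0) + length(h3), 1e4 / 2)
  wt <- t.test(h0, h3, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  expect_gt(mean(h0), mean(h3))
})

test_that("choice simulation honors bias, drift and the deadline", {
  set.seed(12)
  sym <- simulate_trial(ddm_params(1.5, 0.2, 0.5, 0), timeout = 10, n = 1e5)
  expect_equal(mean(sym$choice == "healthy"), 0.5, tolerance = 0.01)

  bias9 <- simulate_trial(ddm_params(1.5, 0.2, 0.9, 0), timeout = 10,
                          n = 2e4)
  expect_equal(mean(bias9$choice == "healthy"),
               hit_probability(ddm_params(1.5, 0.2, 0.9, 0)),
               tolerance = 0.015)

  off <- simulate_trial(ddm_params(1.5, 0.3, 0.5, 1), timeout = 10, n = 2000)
  expect_gte(min(off$rt), 0.3)

  slow <- simulate_trial(ddm_params(3, 0.3, 0.5, 0), timeout = 1, n = 2000)
  expect_true(any(slow$censored))
  expect_true(all(slow$rt[slow$censored] == 1))
  expect_equal(nrow(slow), 2000)   # censored trials retained
})

test_that("contaminants are injected at their rates and tagged", {
  rates <- contamination_rates(low_resolution_rate = 0.05,
                               multicross_rate = 0.04,
                               rt_outlier_rate = 0.02,
                               unrecognized_pair_rate = 0)
  study <- make_test_study(n_participants = 4, pairs_per_combo = 15,
                           seed = 33, contamination = rates)
  n <- nrow(study$trials)   # 2160 trials
  for (col_rate in list(c("tag_low_res", 0.05), c("tag_multicross", 0.04),
                        c("tag_rt_outlier", 0.02))) {
    rate <- as.numeric(col_rate[2])
    cnt <- sum(study$trials[[col_rate[1]]])
    expect_lt(abs(cnt - n * rate), 3 * sqrt(n * rate * (1 - rate)) + 1)
  }
  # low-resolution trials really are below 10 Hz on the recorded path
  m <- compute_trial_metrics(study$trials, study$paths)
  expect_true(all(m$sampling_rate_hz[m$tag_low_res] < 10))
  expect_true(all(m$sampling_rate_hz[!m$tag_low_res &
                                       !m$tag_multicross] >= 15))
  # multicross paths really cross three or more times
  expect_true(all(m$y_crossings[m$tag_multicross] >= 3))

  # zero rates leave the study untouched
  clean <- make_test_study(n_participants = 2, pairs_per_combo = 2,
                           seed = 44)
  same <- inject_contaminants(clean, contamination_rates(0, 0, 0, 0))
  expect_identical(same, clean)

  # certain unrecognized contamination hits every selected trial
  study_u <- make_test_study(
    n_participants = 2, pairs_per_combo = 2, seed = 55,
    contamination = contamination_rates(0, 0, 0, 0.5),
    rating_model = rating_model(recognition_prob = 1))
  tagged <- study_u$trials$tag_unrecognized
  expect_gt(sum(tagged), 0)
  rat <- study_u$ratings
  for (i in which(tagged)[1:20]) {
    tr <- study_u$trials[i, ]
    rec <- rat[rat$participant_id == tr$participant_id &
                 rat$image_id %in% c(tr$left_image, tr$right_image), ]
    expect_true(any(!rec$recognized))
  }
})

test_that("trial conflict is larger when choosing against the drift", {
  study <- make_test_study(n_participants = 3, pairs_per_combo = 10,
                           seed = 8)
  tr <- study$trials[study$trials$context == "healthy" &
                       !study$trials$censored, ]
  expect_gt(mean(tr$conflict[!tr$healthy_choice]),
            mean(tr$conflict[tr$healthy_choice]))
})
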