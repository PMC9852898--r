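test_that("sampling rate is (n-1)/span and degenerate spans error", {
  expect_equal(estimate_sampling_rate(seq(0, 2, length.out = 121)), 60)
  expect_equal(estimate_sampling_rate(c(0, 0.25)), 4)
  expect_error(estimate_sampling_rate(c(1, 1)), "span")
  expect_error(estimate_sampling_rate(0.5), "2 samples")
})

test_that("side normalization is an involution and leaves AUC invariant", {
  set.seed(3)
  path <- cbind(t = seq(0, 1, length.out = 40),
                x = cumsum(rnorm(40, 0.02, 0.05)),
                y = seq(0, 1.5, length.out = 40))
  left <- normalize_trajectory(path, "left")
  expect_equal(left[, c("x", "y")], {
    p0 <- path; sweep(p0[, c("x", "y")], 2, p0[1, c("x", "y")])
  })
  # a right-choice path and its mirror give identical AUC
  mirrored <- path; mirrored[, "x"] <- -mirrored[, "x"]
  expect_equal(compute_auc(normalize_trajectory(mirrored, "right")),
               compute_auc(normalize_trajectory(path, "left")))
  # double reflection is the identity
  twice <- normalize_trajectory(normalize_trajectory(path, "right"), "right")
  expect_equal(twice[, "x"], path[, "x"] - path[1, "x"])
})

test_that("AUC matches simple geometry and the shoelace oracle", {
  p <- cbind(x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(compute_auc(p), 0.5)
  line <- cbind(x = seq(0, -1, length.out = 25),
                y = seq(0, 1.5, length.out = 25))
  expect_equal(compute_auc(line), 0, tolerance = 1e-12)
  expect_error(compute_auc(cbind(x = c(0, 0), y = c(0, 0))), "degenerate")

  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    if (x[1] == x[n] && y[1] == y[n]) next
    p <- cbind(x = x, y = y)
    expect_equal(compute_auc(p), shoelace_auc(x, y), tolerance = 1e-9)
  }
})

test_that("AUC scales quadratically with the coordinate scale", {
  set.seed(8)
  p <- cbind(x = cumsum(rnorm(30)), y = cumsum(rnorm(30)))
  for (c_scale in c(0.5, 2, 7)) {
    expect_equal(compute_auc(p * c_scale), c_scale^2 * compute_auc(p),
                 tolerance = 1e-9)
  }
})

test_that("y-axis crossings count strict sign changes with zeros bridged", {
  expect_equal(count_y_crossings(c(0, 0.1, 0.2, 0.3)), 0L)
  expect_equal(count_y_crossings(c(0, 0.1, -0.2, 0.3, -0.1)), 3L)
  expect_equal(count_y_crossings(c(0, 0.1, 0.0, -0.2)), 1L)
  # invariant under sign-preserving resampling (duplicating samples)
  x <- c(0, 0.1, -0.2, 0.3)
  expect_equal(count_y_crossings(rep(x, each = 3)), count_y_crossings(x))
  # straight path: zero crossings
  expect_equal(count_y_crossings(rep(0.2, 10)), 0L)
})

test_that("response and initiation times come from press, click and movement", {
  path <- cbind(t = c(0, 0.1, 0.25, 0.5, 1.8),
                x = c(0, 0.001, 0.05, 0.4, 1),
                y = c(0, 0.002, 0.03, 0.6, 1.5))
  tm <- compute_times(path)
  expect_equal(tm$rt_s, 1.8)
  expect_equal(tm$init_time_s, 0.25)  # first displacement > 0.02
  expect_false(tm$no_movement)

  still <- cbind(t = c(0, 0.5, 1), x = c(0, 0.001, 0.002),
                 y = c(0, 0.001, 0))
  tm2 <- compute_times(still)
  expect_true(tm2$no_movement)
  expect_equal(tm2$init_time_s, tm2$rt_s)
})

test_that("simulated trajectories have the expected shape and conflict scaling", {
  set.seed(21)
  tr <- simulate_trajectory("left", rt = 2, conflict = 0, rate = 60)
  expect_equal(nrow(tr), 121, tolerance = 0)
  expect_equal(tr[1, c("x", "y")], c(x = 0, y = 0))
  expect_lt(sqrt(sum((tr[nrow(tr), c("x", "y")] - c(-1, 1.5))^2)), 0.1)
  expect_true(all(diff(tr[, "t"]) >= 0))

  # no-conflict path is straight up to sampling noise
  auc0 <- replicate(50, compute_auc(
    normalize_trajectory(simulate_trajectory("left", 1.5, 0, 60), "left")))
  expect_lt(mean(abs(auc0)), 0.02)

  # expected AUC strictly increasing in conflict (Monte-Carlo check)
  mean_auc <- function(conf) mean(replicate(500, compute_auc(
    normalize_trajectory(simulate_trajectory("right", 1.5, conf, 60),
                         "right"))))
  a1 <- mean_auc(0.2); a2 <- mean_auc(0.6)
  expect_gt(a2, a1)
  expect_gt(a1, 0)
})

test_that("compute_trial_metrics recomputes per-trial metrics from paths", {
  study <- make_test_study(n_participants = 2, pairs_per_combo = 2)
  m <- compute_trial_metrics(study$trials, study$paths)
  expect_equal(nrow(m), nrow(study$trials))
  expect_true(all(m$rt_s > 0))
  expect_true(all(m$sampling_rate_hz > 19))
  # path-derived response time agrees with the generated one
  expect_equal(m$rt_s, study$trials$rt_s, tolerance = 1e-8)
  expect_true(all(is.finite(m$auc)))
})
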