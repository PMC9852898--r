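test_that("the parameter population matches hand-computed moments", {
  fits <- data.frame(
    alpha = c(1.2, 1.5, 1.4, 1.6, 1.3, 1.7),
    tau   = c(0.30, 0.28, 0.35, 0.32, 0.29, 0.31),
    beta  = c(0.55, 0.60, 0.58, 0.62, 0.57, 0.59),
    delta = c(0.8, 1.0, 0.9, 1.1, 0.7, 1.2))
  pop <- fit_param_population(fits)
  # hand oracle: plain sums, no cov()/colMeans()
  hand_mean <- vapply(fits, function(v) sum(v) / 6, numeric(1))
  expect_equal(unname(pop$mean_vec), unname(hand_mean))
  hand_cov_ab <- sum((fits$alpha - hand_mean["alpha"]) *
                       (fits$delta - hand_mean["delta"])) / 5
  expect_equal(pop$cov["alpha", "delta"], hand_cov_ab)
  expect_equal(pop$n_source, 6)

  # identical fits: degenerate zero covariance, logged
  same <- fits[rep(1, 6), ]
  pop0 <- fit_param_population(same)
  expect_true(pop0$degenerate)
  expect_true(all(abs(pop0$cov) <= 1e-10))

  expect_error(fit_param_population(fits[1:3, ]), "at least 5")
})

test_that("quantile-based outlier flags use type-7 empirical bounds", {
  rec <- matrix(rep(1:1000, 4), ncol = 4,
                dimnames = list(NULL, c("alpha", "tau", "beta", "delta")))
  src <- data.frame(alpha = c(10, 990, 500), tau = c(500, 500, 500),
                    beta = c(500, 500, 500), delta = c(500, 500, 1500))
  fl <- flag_outlier_params(src, rec)
  expect_equal(fl$bounds[, "alpha"], c(25.975, 975.025), tolerance = 1e-9,
               ignore_attr = TRUE)
  # 10 lies below the lower bound and 990 above the upper bound: both flag
  expect_equal(unname(fl$flags[, "alpha"]), c(TRUE, TRUE, FALSE))
  # a value above the recovered maximum is flagged
  expect_equal(unname(fl$flags[, "delta"]), c(FALSE, FALSE, TRUE))
  # the recovered median is never flagged
  expect_false(fl$flags[3, "beta"])
  # one-sided readings
  fl_lo <- flag_outlier_params(src, rec, side = "lower")
  expect_equal(unname(fl_lo$flags[, "alpha"]), c(TRUE, FALSE, FALSE))
  fl_up <- flag_outlier_params(src, rec, side = "upper")
  expect_equal(unname(fl_up$flags[, "alpha"]), c(FALSE, TRUE, FALSE))
})

test_that("recovery correlations behave at the identity, null and hand oracle", {
  set.seed(19)
  draws <- matrix(rnorm(4000), ncol = 4,
                  dimnames = list(NULL, c("alpha", "tau", "beta", "delta")))
  # refits identical to draws: r = 1 everywhere
  r1 <- recovery_correlation(draws, draws)
  expect_equal(unname(r1), rep(1, 4), ignore_attr = TRUE)
  # refits independent of draws: |r| small at n = 1000
  shuffled <- draws[sample(nrow(draws)), ]
  r0 <- recovery_correlation(draws, shuffled)
  expect_true(all(abs(r0) < 0.1))
  # 5-pair hand oracle
  d5 <- matrix(c(1, 2, 3, 4, 5), 5, 4,
               dimnames = list(NULL, c("alpha", "tau", "beta", "delta")))
  f5 <- matrix(c(1.2, 1.9, 3.4, 3.8, 5.1), 5, 4,
               dimnames = list(NULL, c("alpha", "tau", "beta", "delta")))
  rh <- recovery_correlation(d5, f5)
  expect_equal(unname(rh["delta"]), hand_pearson(d5[, 1], f5[, 1]))
  # zero-variance columns are reported as NA
  dflat <- d5; dflat[, "beta"] <- 1
  expect_true(is.na(recovery_correlation(dflat, f5)["beta"]))
  expect_error(recovery_correlation(d5[1:2, , drop = FALSE],
                                    f5[1:2, , drop = FALSE]), "at least 3")
})

test_that("a degenerate population reproduces its mean and refits scatter", {
  fits <- data.frame(alpha = rep(1.5, 6), tau = rep(0.3, 6),
                     beta = rep(0.6, 6), delta = rep(0.9, 6))
  pop <- fit_param_population(fits)
  set.seed(23)
  rec <- run_recovery(pop, n_sets = 6, n_rt = 150,
                      settings = ddm_fit_settings(restarts = 2,
                                                  min_trials = 20,
                                                  maxit = 400))
  expect_equal(unname(rec$draws[, "delta"]), rep(0.9, 6))
  expect_equal(nrow(rec$refits), 6)
  expect_gt(sum(rec$valid), 0)
  # refits scatter around the generating values by simulation noise only
  expect_lt(abs(median(rec$refits[rec$valid, "beta"]) - 0.6), 0.1)
})

test_that("invalid draws are clamped, not dropped", {
  fits <- data.frame(alpha = c(0.4, 0.5, 0.45, 0.55, 0.5, 0.6),
                     tau = rep(0.05, 6), beta = rep(0.5, 6),
                     delta = rep(0, 6))
  pop <- fit_param_population(fits)
  pop$cov <- diag(c(1, 0.2, 0.5, 1))  # wide enough to leave the valid region
  dimnames(pop$cov) <- list(c("alpha", "tau", "beta", "delta"),
                            c("alpha", "tau", "beta", "delta"))
  set.seed(29)
  rec <- suppressWarnings(
    run_recovery(pop, n_sets = 30, n_rt = 40,
                 settings = ddm_fit_settings(restarts = 1, min_trials = 10,
                                             maxit = 200)))
  expect_equal(nrow(rec$draws), 30)
  expect_gt(rec$n_clamped, 0)
  expect_true(all(rec$draws[, "alpha"] >= 0.05))
  expect_true(all(rec$draws[, "beta"] > 0 & rec$draws[, "beta"] < 1))
})
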