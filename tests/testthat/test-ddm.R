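test_that("parameter constructor enforces the valid region", {
  expect_s3_class(ddm_params(1.5, 0.3, 0.6, 0.8), "ddm_params")
  expect_error(ddm_params(0, 0.3, 0.5, 1), "boundary_sep")
  expect_error(ddm_params(1, -0.1, 0.5, 1), "non_decision")
  expect_error(ddm_params(1, 0.3, 1, 1), "bias")
  expect_error(ddm_params(1, 0.3, 0.5, Inf), "drift")
})

test_that("the density normalizes to one and obeys reflection symmetry", {
  set.seed(14)
  for (i in 1:8) {
    p <- ddm_params(runif(1, 0.6, 3), runif(1, 0, 0.4), runif(1, 0.2, 0.8),
                    runif(1, -2, 2))
    iu <- integrate(function(t) wiener_pdf(t, "upper", p), 0, Inf,
                    rel.tol = 1e-8)$value
    il <- integrate(function(t) wiener_pdf(t, "lower", p), 0, Inf,
                    rel.tol = 1e-8)$value
    expect_equal(iu + il, 1, tolerance = 1e-3)
    # upper mass equals the closed-form hit probability
    expect_equal(iu, hit_probability(p), tolerance = 1e-3)
    # pdf(t, upper; delta, beta) = pdf(t, lower; -delta, 1-beta)
    pr <- ddm_params(p$boundary_sep, p$non_decision, 1 - p$bias, -p$drift)
    tg <- p$non_decision + c(0.05, 0.2, 0.5, 1, 2)
    expect_equal(wiener_pdf(tg, "upper", p), wiener_pdf(tg, "lower", pr),
                 tolerance = 1e-12)
  }
  # density is zero at or below the non-decision time
  p <- ddm_params(1.5, 0.3, 0.5, 1)
  expect_equal(wiener_pdf(c(0.1, 0.3), "upper", p), c(0, 0))
})

test_that("hit probability matches limits and simulation", {
  expect_equal(hit_probability(ddm_params(2, 0, 0.7, 0)), 0.7)
  expect_equal(hit_probability(ddm_params(2, 0, 0.5, 50)), 1, tolerance = 1e-6)
  p <- ddm_params(2, 0, 0.5, 1)
  set.seed(31)
  sim <- rwiener(1e5, p)
  p_true <- hit_probability(p)
  expect_lt(abs(mean(sim$upper) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("simulated response times respect the non-decision offset", {
  set.seed(4)
  sim <- rwiener(2000, ddm_params(1.5, 0.3, 0.5, 1))
  expect_true(all(sim$rt >= 0.3))
})

test_that("mean decision time at beta = 0.5 matches the closed form", {
  # E[T] = (alpha / (2 delta)) * tanh(alpha * delta / 2) for unbiased starts
  set.seed(17)
  for (i in 1:3) {
    a <- runif(1, 1, 2.5); v <- runif(1, 0.4, 1.5)
    p <- ddm_params(a, 0, 0.5, v)
    sim <- rwiener(2e4, p)
    m_th <- (a / (2 * v)) * tanh(a * v / 2)
    se <- sd(sim$rt) / sqrt(length(sim$rt))
    expect_lt(abs(mean(sim$rt) - m_th), 3 * se)
  }
})

test_that("density matches a large Euler-simulated sample (KS)", {
  p <- ddm_params(2, 0, 0.5, 1)
  set.seed(100)
  sim <- rwiener(4e4, p, dt = 2e-4)
  expect_lt(signed_rt_ks(sim$rt, sim$upper, p), 0.012)
})

test_that("the log-likelihood is additive, guarded and peaked at truth", {
  p <- ddm_params(1.5, 0.3, 0.6, 0.8)
  rt <- c(0.8, 1.1); up <- c(TRUE, FALSE)
  ll <- wiener_loglik(rt, up, p)
  expect_equal(wiener_loglik(rep(rt, 2), rep(up, 2), p), 2 * ll)
  # tau >= rt gives the guarded floor
  bad <- ddm_params(1.5, 0.9, 0.6, 0.8)
  expect_equal(wiener_loglik(0.8, TRUE, bad), -1e10)
  expect_error(wiener_loglik(numeric(0), logical(0), p), "empty")

  set.seed(6)
  sim <- rwiener(1e4, p)
  ll_true <- wiener_loglik(sim$rt, sim$upper, p)
  for (pert in list(c(0.2, 0, 0, 0), c(0, 0.1, 0, 0), c(0, 0, 0.15, 0),
                    c(0, 0, 0, 0.5))) {
    pp <- ddm_params(p$boundary_sep + pert[1], p$non_decision + pert[2],
                     p$bias + pert[3], p$drift + pert[4])
    expect_gt(ll_true, wiener_loglik(sim$rt, sim$upper, pp))
  }
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  set.seed(50)
  truth <- ddm_params(1.5, 0.3, 0.6, 0.8)
  sim <- rwiener(1000, truth)
  fit <- fit_ddm(sim$rt, sim$upper)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$boundary_sep - 1.5) / 1.5, 0.10)
  expect_lt(abs(fit$params$non_decision - 0.3) / 0.3, 0.10)
  expect_lt(abs(fit$params$bias - 0.6), 0.05)
  expect_lt(abs(fit$params$drift - 0.8) / 0.8, 0.15)

  # refitting from the optimum does not improve the likelihood materially
  refit <- fit_ddm(sim$rt, sim$upper)
  expect_lt(abs(refit$log_likelihood - fit$log_likelihood), 1e-4)

  expect_error(fit_ddm(sim$rt[1:5], sim$upper[1:5]), "at least 20")
})

test_that("per-condition fitting keeps the bookkeeping and flags degenerates", {
  study <- make_test_study(n_participants = 2, pairs_per_combo = 5, seed = 2)
  fast <- ddm_fit_settings(restarts = 2, maxit = 400)
  fits <- fit_all_conditions(study$trials, fast)
  expect_equal(nrow(fits), 2 * 6)   # participants x contexts x label blocks
  expect_true(all(fits$n_trials + fits$n_censored == 30))

  # an all-healthy condition still returns a (flagged/bounded) fit
  tr <- study$trials[study$trials$participant_id == "P001" &
                       study$trials$context == "healthy" &
                       !study$trials$nwl_shown, ]
  tr$healthy_choice <- TRUE
  one <- fit_all_conditions(tr, fast)
  expect_equal(nrow(one), 1L)
  expect_false(is.na(one$beta))

  # under-sized conditions are flagged, not dropped
  small <- fit_all_conditions(study$trials[1:10, ], fast)
  expect_true(all(is.na(small$converged)))
  expect_equal(nrow(small), 1L)
})
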