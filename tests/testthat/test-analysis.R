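test_that("healthy-choice labeling follows the lower-NWL rule", {
  expect_true(label_healthy_choice("left", 0, 3))
  expect_false(label_healthy_choice("left", 2, 1))
  expect_equal(label_healthy_choice(c("left", "right"), c(0, 0), c(1, 1)),
               c(TRUE, FALSE))
  expect_error(label_healthy_choice("left", 2, 2), "design violation")
})

test_that("decision paths classify and conserve the census", {
  paired <- data.frame(choice_no_nwl = c(TRUE, TRUE, FALSE, FALSE),
                       choice_nwl = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.character(classify_decision_path(paired)),
               c("HH", "HU", "UH", "UU"))
  expect_equal(unname(table(classify_decision_path(paired))),
               array(rep(1L, 4)), ignore_attr = TRUE)
})

make_paired <- function() {
  # 2 participants x 10 pairs with known choice patterns
  set.seed(1)
  data.frame(
    participant_id = rep(c("P1", "P2"), each = 10),
    context = "typical", pair_id = rep(1:10, 2),
    choice_no_nwl = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 4),
    choice_nwl = rep(c(TRUE, TRUE, FALSE, TRUE, FALSE), 4),
    auc_no_nwl = runif(20, 0.2, 0.6), auc_nwl = runif(20, 0.1, 0.5),
    rt_no_nwl = runif(20, 0.8, 1.5), rt_nwl = runif(20, 0.8, 1.5),
    delta_nwl = rep(1:2, 10), stringsAsFactors = FALSE)
}

test_that("pairing joins the two label blocks and drops incomplete pairs", {
  study <- make_test_study(n_participants = 2, pairs_per_combo = 3)
  m <- compute_trial_metrics(study$trials, study$paths)
  paired <- pair_trials(m)
  expect_equal(nrow(paired), 2 * 3 * 18)
  expect_equal(attr(paired, "n_incomplete"), 0)
  # drop one block of one pair: that pair becomes incomplete
  m2 <- m[-which(m$participant_id == "P001" & m$context == "healthy" &
                   m$pair_id == 1 & m$nwl_shown)[1], ]
  paired2 <- pair_trials(m2)
  expect_equal(nrow(paired2), nrow(paired) - 1)
  expect_equal(attr(paired2, "n_incomplete"), 1)
})

test_that("proportions, reversal identity and path census agree exactly", {
  paired <- make_paired()
  census <- decision_path_census(paired)
  expect_equal(sum(census$n), nrow(paired))
  rev <- reversal_probability(paired, n_boot = 200, seed = 3)
  n_uh <- census$n[census$path == "UH"]; n_uu <- census$n[census$path == "UU"]
  expect_equal(rev$estimate, n_uh / (n_uh + n_uu))
  expect_equal(rev$n_trials, n_uh + n_uu)

  # P(healthy | labels shown) = P(HH or UH) over the same pairs
  trials_nwl <- data.frame(participant_id = paired$participant_id,
                           context = paired$context,
                           healthy_choice = paired$choice_nwl)
  p <- healthy_choice_prob(trials_nwl, n_boot = 100, seed = 4)
  expect_equal(p$estimate,
               sum(census$n[census$path %in% c("HH", "UH")]) /
                 sum(census$n))

  # degenerate all-healthy group has a degenerate interval
  allh <- within(trials_nwl, healthy_choice <- TRUE)
  p1 <- healthy_choice_prob(allh, n_boot = 100, seed = 5)
  expect_equal(unname(unlist(p1[, c("estimate", "lower", "upper")])),
               c(1, 1, 1))

  # single-participant proportion without resampling noise in the estimate
  one <- data.frame(participant_id = "P1", context = "x",
                    healthy_choice = c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(healthy_choice_prob(one, n_boot = 50, seed = 6)$estimate, 0.6)

  # no unhealthy-first trials: reversal reported as missing/empty
  hh <- make_paired(); hh$choice_no_nwl <- TRUE
  expect_equal(nrow(reversal_probability(hh, n_boot = 50)), 0)
})

test_that("conflict deltas carry the label-minus-baseline sign convention", {
  paired <- make_paired()
  d <- compute_deltas(paired)
  expect_equal(d$delta_auc, paired$auc_nwl - paired$auc_no_nwl)
  expect_equal(d$delta_rt, paired$rt_nwl - paired$rt_no_nwl)
  # a reduction caused by labels is negative
  expect_equal(d$delta_auc[1] < 0, paired$auc_nwl[1] < paired$auc_no_nwl[1])
  stopifnot(!is.null(d$path))
})

test_that("baseline-adjusted delta summaries flag sign shifts", {
  set.seed(31)
  n <- 400
  base <- rnorm(n, 0, 0.15)   # baselines centered for the exactness check
  d <- data.frame(
    participant_id = rep(sprintf("P%d", 1:20), each = n / 20),
    context = rep(c("healthy", "typical"), each = n / 2),
    path = factor(rep(c("HH", "UU"), n / 2), levels = c("HH", "HU", "UH",
                                                        "UU")),
    auc_baseline = base,
    delta_auc = ifelse(rep(c(TRUE, FALSE), n / 2),
                       -0.2 + rnorm(n, 0, 0.05),   # HH shifted negative
                       0 + rnorm(n, 0, 0.05)))
  s <- delta_summary(d, "auc", n_boot = 300, seed = 7)
  hh <- s[s$path == "HH", ]
  expect_true(all(hh$estimate < 0))
  expect_true(all(hh$excludes_zero))
  uu <- s[s$path == "UU", ]
  expect_lt(max(abs(uu$estimate)), 0.03)

  # perfect adjustment: delta = -baseline gives identical cell estimates
  d2 <- d
  d2$delta_auc <- -d2$auc_baseline
  s2 <- delta_summary(d2, "auc", n_boot = 50, seed = 8)
  expect_lt(max(abs(s2$estimate)), 0.05)
  expect_lt(diff(range(s2$estimate)), 1e-10)
})

test_that("the NWL-difference profile is recovered exactly on a fixture", {
  grid <- expand.grid(participant_id = sprintf("P%d", 1:5),
                      context = "typical", delta_nwl = 1:3,
                      rep = 1:20, stringsAsFactors = FALSE)
  prob <- c(0.5, 0.6, 0.7)[grid$delta_nwl]
  # deterministic fixture: healthy iff rep index below the level quota
  grid$healthy_choice <- grid$rep <= 20 * prob
  grid$nwl_shown <- TRUE
  eff <- delta_nwl_effect(grid, n_boot = 100, seed = 9)
  expect_equal(eff$estimate[order(eff$delta_nwl)], c(0.5, 0.6, 0.7))
  # flat fixture gives a flat profile
  grid$healthy_choice <- grid$rep <= 10
  eff2 <- delta_nwl_effect(grid, n_boot = 50, seed = 10)
  expect_equal(unique(eff2$estimate), 0.5)
  # missing levels are reported, not dropped
  sub <- grid[grid$delta_nwl < 3, ]
  eff3 <- delta_nwl_effect(sub, n_boot = 50, seed = 11)
  expect_true(any(eff3$n_trials == 0))
})
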