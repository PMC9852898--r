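# Independent oracles and small fixtures used across the suite.

# Shoelace signed area of the polygon formed by a polyline closed by the
# straight chord from its last back to its first vertex. Independent of the
# trapezoidal perpendicular-frame integration used by compute_auc().
shoelace_auc <- function(x, y) {
  n <- length(x)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  0.5 * sum(xs[-(n + 1)] * ys[-1] - xs[-1] * ys[-(n + 1)])
}

# Theoretical CDF of the signed response time (negative sign = lower
# boundary) by trapezoidal integration of the Wiener density on a fine grid.
signed_rt_cdf <- function(params, t_max = 15, n_grid = 6000) {
  tau <- params$non_decision
  tg <- seq(tau + 1e-6, tau + t_max, length.out = n_grid)
  fu <- wiener_pdf(tg, "upper", params)
  fl <- wiener_pdf(tg, "lower", params)
  cum <- function(f) c(0, cumsum((f[-1] + f[-n_grid]) / 2 * diff(tg)))
  Fu <- cum(fu); Fl <- cum(fl)
  p_low <- Fl[n_grid]
  function(s) {
    out <- numeric(length(s))
    neg <- s < 0
    if (any(neg))
      out[neg] <- p_low - approx(tg, Fl, xout = -s[neg], rule = 2)$y
    if (any(!neg))
      out[!neg] <- p_low + approx(tg, Fu, xout = s[!neg], rule = 2)$y
    out
  }
}

# Kolmogorov-Smirnov distance between a signed-rt sample and the
# theoretical signed CDF.
signed_rt_ks <- function(rt, upper, params) {
  s <- sort(ifelse(upper, rt, -rt))
  Fth <- signed_rt_cdf(params)(s)
  n <- length(s)
  max(abs(Fth - seq_len(n) / n), abs(Fth - (seq_len(n) - 1) / n))
}

# Pocket-calculator Pearson correlation (no stats::cor).
hand_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# Small complete study used by several module tests.
make_test_study <- function(n_participants = 4, pairs_per_combo = 3,
                            seed = 11, contamination = contamination_rates(
                              low_resolution_rate = 0,
                              multicross_rate = 0,
                              rt_outlier_rate = 0,
                              unrecognized_pair_rate = 0),
                            ...) {
  simulate_study(study_config(n_participants = n_participants,
                              pairs_per_combo = pairs_per_combo,
                              contamination = contamination,
                              rng_seed = seed, ...))
}

# A minimal clean metrics table for filter tests: `n` trials for one
# participant with specified columns overridable per trial.
make_metrics <- function(n, participant = "P1",
                         rate = 60, init = 0.2, auc = 0.3, rt = 1,
                         crossings = 0) {
  data.frame(trial_id = seq_len(n), participant_id = participant,
             context = "healthy", nwl_shown = FALSE, pair_id = seq_len(n),
             left_image = "a", right_image = "b",
             sampling_rate_hz = rep_len(rate, n),
             init_time_s = rep_len(init, n), auc = rep_len(auc, n),
             rt_s = rep_len(rt, n), y_crossings = rep_len(crossings, n),
             stringsAsFactors = FALSE)
}
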