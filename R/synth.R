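#' Rating model for subjective health/like/want scores
#'
#' Visual-analogue-scale (0--100) rating means indexed by the actual NWL
#' count of a food (0..3). The defaults emulate the qualitative pattern seen
#' in label studies: perceived healthiness falls monotonically with the
#' number of warning labels, while liking and wanting are U-shaped (lowest
#' at 2 labels, recovering for the most indulgent 3-label foods). Draws are
#' normal with common `rating_sd` and clamped to `[0, 100]`.
#'
#' @param health_means,like_means,want_means Length-4 numeric vectors of VAS
#'   means for NWL counts 0..3, all within `[0, 100]`.
#' @param rating_sd Rating noise SD in VAS units (> 0).
#' @param recognition_prob Probability that a participant recognizes an
#'   image.
#' @return A `rating_model` list.
#' @export
rating_model <- function(health_means = c(80, 62, 42, 26),
                         like_means = c(66, 56, 48, 60),
                         want_means = c(62, 53, 46, 58),
                         rating_sd = 12, recognition_prob = 0.95) {
  for (nm in c("health_means", "like_means", "want_means")) {
    v <- get(nm)
    if (length(v) != 4L || any(!is.finite(v)) || any(v < 0 | v > 100))
      stop_config(nm, "must be 4 values within [0, 100]")
  }
  if (!is.finite(rating_sd) || rating_sd <= 0)
    stop_config("rating_sd", "must be > 0")
  if (recognition_prob < 0 || recognition_prob > 1)
    stop_config("recognition_prob", "must be in [0, 1]")
  structure(list(health_means = health_means, like_means = like_means,
                 want_means = want_means, rating_sd = rating_sd,
                 recognition_prob = recognition_prob),
            class = "rating_model")
}

#' Per-trial contamination rates
#'
#' Rates of the four contaminant types injected by [inject_contaminants()]
#' to exercise the quality-control filters: paths resampled below 10 Hz,
#' vacillating multi-crossing paths, inflated response-time outliers, and
#' pairs containing an unrecognized image.
#'
#' @param low_resolution_rate,multicross_rate,rt_outlier_rate,unrecognized_pair_rate
#'   Per-trial probabilities, each in `[0, 0.5]`.
#' @return A `contamination_rates` list.
#' @export
contamination_rates <- function(low_resolution_rate = 0.02,
                                multicross_rate = 0.02,
                                rt_outlier_rate = 0.01,
                                unrecognized_pair_rate = 0.01) {
  r <- list(low_resolution_rate = low_resolution_rate,
            multicross_rate = multicross_rate,
            rt_outlier_rate = rt_outlier_rate,
            unrecognized_pair_rate = unrecognized_pair_rate)
  for (nm in names(r))
    if (!is.finite(r[[nm]]) || r[[nm]] < 0 || r[[nm]] > 0.5)
      stop_config(nm, "must be in [0, 0.5]")
  structure(r, class = "contamination_rates")
}

#' Default ground-truth DDM parameters per condition
#'
#' One parameter set per eating context x label condition (6 in total),
#' chosen so the generated population reproduces the qualitative structure
#' of context/label effects reported for this paradigm: the healthy context
#' has the largest bias and drift toward the healthy boundary and the
#' shortest non-decision time, the unrestricted context the opposite;
#' showing NWL raises the drift rate in every context (close to doubling it
#' in the healthy and typical contexts and more than fourfold in the
#' unrestricted one), raises the bias only in the healthy (+7.6%) and
#' typical (+6.9%) contexts, and shortens the non-decision time everywhere
#' (most strongly, -16.8%, in the healthy context). Boundary separation is
#' held common across conditions.
#'
#' @return Data frame with columns `context`, `nwl_shown`, `boundary_sep`,
#'   `non_decision`, `bias`, `drift`.
#' @export
default_ddm_truth <- function() {
  base <- data.frame(
    context = rep(c("healthy", "typical", "unrestricted"), each = 2),
    nwl_shown = rep(c(FALSE, TRUE), 3),
    boundary_sep = 1.5,
    non_decision = c(0.30, 0.30 * (1 - 0.168),
                     0.34, 0.34 * (1 - 0.096),
                     0.36, 0.36 * (1 - 0.088)),
    bias = c(0.62, 0.62 * 1.076,
             0.58, 0.58 * 1.069,
             0.54, 0.54),
    drift = c(1.00, 1.00 * 1.883,
              0.70, 0.70 * 1.891,
              0.25, 0.25 * 4.675),
    stringsAsFactors = FALSE)
  base
}

#' Study configuration for the synthetic generator
#'
#' Collects every knob of the simulated study. Defaults reproduce the study
#' design: 128 participants, three eating contexts, two label blocks per
#' context over the same 90 pairs (15 per NWL combination), a 4-second
#' response deadline, and a ~60 Hz mouse-sampling rate.
#'
#' @param n_participants Number of participants (>= 1).
#' @param contexts Character vector of the three context labels.
#' @param pairs_per_combo Pairs per NWL-count combination (default 15).
#' @param timeout Response deadline in seconds (default 4).
#' @param ddm_truth Data frame of ground-truth parameters, one row per
#'   context x label condition (exactly `2 * length(contexts)` rows);
#'   defaults to [default_ddm_truth()].
#' @param rating_model A [rating_model()].
#' @param contamination A [contamination_rates()].
#' @param sampling_rate Named vector `c(mean=, sd=)` of the per-trial mouse
#'   sampling rate (Hz); draws are truncated at 20 Hz so clean trials never
#'   trip the 10 Hz filter.
#' @param between_sd Named vector of between-participant SDs for
#'   `boundary_sep`, `non_decision`, `bias`, `drift` (one additive
#'   participant effect per parameter, shared across conditions).
#' @param nwl_gradient Additive drift increment per unit of the within-pair
#'   NWL difference above 1, applied in label-shown blocks only (default 0:
#'   label effects act through `ddm_truth`).
#' @param strata_spec Per-context image strata, see [default_strata_spec()].
#' @param rng_seed Master seed; every downstream draw derives from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 128L,
                         contexts = c("healthy", "typical", "unrestricted"),
                         pairs_per_combo = 15L,
                         timeout = 4.0,
                         ddm_truth = default_ddm_truth(),
                         rating_model = nwlchoice::rating_model(),
                         contamination = contamination_rates(),
                         sampling_rate = c(mean = 60, sd = 8),
                         between_sd = c(boundary_sep = 0.10,
                                        non_decision = 0.03,
                                        bias = 0.04, drift = 0.15),
                         nwl_gradient = 0,
                         strata_spec = default_strata_spec(),
                         rng_seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop_config("n_participants", "must be >= 1")
  if (length(contexts) != 3L || anyDuplicated(contexts))
    stop_config("contexts", "must be 3 distinct labels")
  if (!is.numeric(timeout) || timeout <= 0)
    stop_config("timeout", "must be > 0")
  if (!is.data.frame(ddm_truth) || nrow(ddm_truth) != 2L * length(contexts))
    stop_config("ddm_truth",
                sprintf("must have exactly %d rows (context x label)",
                        2L * length(contexts)))
  if (!all(sort(unique(ddm_truth$context)) == sort(contexts)))
    stop_config("ddm_truth", "contexts must match the contexts field")
  for (i in seq_len(nrow(ddm_truth)))
    as_ddm_params(as.list(ddm_truth[i, c("boundary_sep", "non_decision",
                                         "bias", "drift")]))
  if (!inherits(rating_model, "rating_model"))
    stop_config("rating_model", "must be a rating_model()")
  if (!inherits(contamination, "contamination_rates"))
    stop_config("contamination", "must be contamination_rates()")
  if (sampling_rate[["mean"]] <= 0 || sampling_rate[["sd"]] < 0)
    stop_config("sampling_rate", "mean must be > 0 and sd >= 0")
  if (pairs_per_combo < 1) stop_config("pairs_per_combo", "must be >= 1")
  structure(list(n_participants = as.integer(n_participants),
                 contexts = contexts,
                 pairs_per_combo = as.integer(pairs_per_combo),
                 timeout = timeout, ddm_truth = ddm_truth,
                 rating_model = rating_model, contamination = contamination,
                 sampling_rate = sampling_rate, between_sd = between_sd,
                 nwl_gradient = nwl_gradient, strata_spec = strata_spec,
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

#' Simulate per-image subjective ratings and recognition for one participant
#'
#' Health, like and want VAS scores are drawn per image from the rating
#' model's NWL-count-indexed means and clamped to `[0, 100]`; recognition is
#' Bernoulli per image.
#'
#' @param model A [rating_model()].
#' @param images Data frame with columns `image_id`, `nwl_count`.
#' @return Data frame: `image_id`, `nwl_count`, `health`, `like`, `want`,
#'   `recognized`.
#' @export
simulate_ratings <- function(model, images) {
  stopifnot(inherits(model, "rating_model"))
  if (nrow(images) == 0L) stop("empty image inventory", call. = FALSE)
  k <- images$nwl_count + 1L
  n <- nrow(images)
  clamp01 <- function(x) pmin(pmax(x, 0), 100)
  data.frame(
    image_id = images$image_id, nwl_count = images$nwl_count,
    health = clamp01(rnorm(n, model$health_means[k], model$rating_sd)),
    like = clamp01(rnorm(n, model$like_means[k], model$rating_sd)),
    want = clamp01(rnorm(n, model$want_means[k], model$rating_sd)),
    recognized = runif(n) < model$recognition_prob,
    stringsAsFactors = FALSE)
}

#' Simulate choice/response-time trials with a response deadline
#'
#' Draws first-passage outcomes from the drift-diffusion process (healthy
#' choice = upper boundary). Trials whose response time exceeds the deadline
#' are flagged censored with the response time truncated at the deadline;
#' they are retained, never dropped.
#'
#' @param params A [ddm_params()] object.
#' @param timeout Response deadline (s).
#' @param n Number of trials.
#' @param dt Simulation step (s).
#' @return Data frame: `choice` (`"healthy"`/`"unhealthy"`), `rt` (s),
#'   `censored`.
#' @export
simulate_trial <- function(params, timeout = 4.0, n = 1L, dt = 1e-3) {
  stopifnot(timeout > 0)
  sim <- rwiener(n, params, dt = dt, tmax = max(timeout * 4, 20))
  cens <- is.na(sim$rt) | sim$rt > timeout
  # runaway accumulations (NA) are censored with a coin-flip recorded side
  upper <- sim$upper
  if (any(is.na(upper))) upper[is.na(upper)] <- runif(sum(is.na(upper))) < 0.5
  data.frame(choice = ifelse(upper, "healthy", "unhealthy"),
             rt = ifelse(cens, timeout, sim$rt),
             censored = cens, stringsAsFactors = FALSE)
}

#' Simulate one mouse trajectory
#'
#' Quadratic Bezier path from the start zone to the chosen top corner whose
#' control point is pulled horizontally toward the unchosen side in
#' proportion to `conflict`, plus white positional noise; before the
#' initiation time the cursor jitters in place at the start. A `zigzag` path
#' (used for the multi-crossing contaminant) instead oscillates across the
#' vertical axis before committing.
#'
#' @param chosen_side `"left"` or `"right"`.
#' @param rt Response time (s), > 0.
#' @param conflict Nonnegative conflict scalar; 0 gives a straight path.
#' @param rate Sampling rate (Hz), > 0.
#' @param init_time Initiation time (s); default drawn uniformly within
#'   `[0.08, 0.35] * rt` (capped).
#' @param geometry Screen geometry, see [default_geometry()].
#' @param noise_sd Positional noise SD after initiation.
#' @param zigzag Produce a vacillating multi-crossing path.
#' @return Matrix with columns `t`, `x`, `y`; the first sample is at the
#'   start press, the last at the click inside the chosen corner.
#' @export
simulate_trajectory <- function(chosen_side, rt, conflict, rate,
                                init_time = NULL,
                                geometry = default_geometry(),
                                noise_sd = 0.008, zigzag = FALSE) {
  if (rt <= 0) stop("rt must be > 0", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (conflict < 0) stop("conflict must be >= 0", call. = FALSE)
  target <- if (chosen_side == "left") geometry$target_left else
    geometry$target_right
  # the final sample is the click at t = rt, so the realized sampling rate
  # (n - 1) / span never exceeds the nominal rate
  k <- max(1L, floor(rt * rate))
  tgrid <- (0:k) / rate
  tgrid[k + 1L] <- rt
  n <- length(tgrid)
  init_time <- init_time %||% runif(1, 0.08, max(0.081, min(0.35, 0.45 * rt)))
  init_time <- min(init_time, 0.9 * rt)

  pre <- tgrid < init_time
  s <- numeric(n)
  s[!pre] <- (tgrid[!pre] - init_time) / (rt - init_time)
  s <- pmin(pmax(s, 0), 1)
  se <- s * s * (3 - 2 * s)   # smooth easing of progress along the path

  if (zigzag) {
    # explicit vacillation: cross the start abscissa several times, then
    # commit to the chosen side; sampled densely enough (>= 10 intervals,
    # linear progress) that no oscillation falls between samples
    k <- max(10L, floor(rt * rate))
    tgrid <- (0:k) / k * rt
    n <- k + 1L
    u <- (0:k) / k
    kx <- c(0, 0.30, -0.30, 0.28, -0.26, target[1])
    ks <- c(0, 0.15, 0.30, 0.45, 0.60, 1)
    x <- stats::approx(ks, kx, xout = u)$y
    y <- target[2] * u
    se <- u
  } else {
    pull <- 0.9 * conflict * (-sign(target[1]))  # toward the unchosen side
    p1 <- c(target[1] / 2 + pull, target[2] / 2)
    x <- 2 * se * (1 - se) * p1[1] + se^2 * target[1]
    y <- 2 * se * (1 - se) * p1[2] + se^2 * target[2]
  }
  # the cursor dwells exactly on the start button before initiation and the
  # noise envelope vanishes at both endpoints, so spurious axis crossings do
  # not arise from jitter around the start abscissa
  env <- 4 * se * (1 - se)
  x <- x + rnorm(n, 0, noise_sd) * env
  y <- y + rnorm(n, 0, noise_sd) * env
  # the click lands inside the chosen corner
  x[n] <- target[1] + rnorm(1, 0, 0.01)
  y[n] <- target[2] + rnorm(1, 0, 0.01)
  x[1] <- 0; y[1] <- 0
  cbind(t = tgrid, x = x, y = y)
}

# participant-level parameter set: condition truth plus one additive
# participant effect per parameter, clamped to the valid region
participant_truth <- function(truth, effects) {
  out <- truth
  out$boundary_sep <- pmax(truth$boundary_sep + effects[["boundary_sep"]], 0.3)
  out$non_decision <- pmax(truth$non_decision + effects[["non_decision"]], 0.05)
  out$bias <- pmin(pmax(truth$bias + effects[["bias"]], 0.05), 0.95)
  out$drift <- truth$drift + effects[["drift"]]
  out
}

#' Simulate a complete synthetic study
#'
#' Generates participants, per-image ratings and recognition flags,
#' constrained pair sequences (shared between the two label blocks of a
#' context), drift-diffusion choices and response times per condition,
#' and curved mouse paths whose deviation scales with decision conflict
#' (defined per trial as one minus the model probability of the chosen
#' boundary). Contaminants are then injected at the configured rates. All
#' ground truth (condition parameters, participant effects, contaminant
#' tags) is retained so downstream estimates can be scored against it.
#'
#' @param config A [study_config()].
#' @return An `nwl_study` list: `trials`, `paths`, `ratings`,
#'   `participants`, `truth`, `config`.
#' @examples
#' cfg <- study_config(n_participants = 2, pairs_per_combo = 2, rng_seed = 42)
#' study <- simulate_study(cfg)
#' nrow(study$trials) # 2 participants x 3 contexts x 2 blocks x 12 pairs
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "study_config"))
    stop("config must be a study_config()", call. = FALSE)
  with_seed(derive_seed(config$rng_seed, "study"), {
    imgs <- synthetic_image_table(seed = derive_seed(config$rng_seed, "pool"))
    names(config$strata_spec) <- config$contexts[seq_along(config$strata_spec)]
    inv <- build_inventories(imgs, config$strata_spec,
                             seed = derive_seed(config$rng_seed, "inventory"))
    all_images <- do.call(rbind, lapply(inv, function(z)
      z$images[, c("image_id", "nwl_count")]))
    rownames(all_images) <- NULL

    np <- config$n_participants
    pids <- sprintf("P%03d", seq_len(np))
    participants <- data.frame(
      participant_id = pids,
      age = round(runif(np, 18, 45)),
      sex = sample(c("female", "male"), np, replace = TRUE),
      bmi = round(pmin(pmax(rnorm(np, 23.3, 2.3), 20), 29.9), 1),
      stringsAsFactors = FALSE)

    eff <- as.data.frame(t(replicate(np, rnorm(4, 0, config$between_sd))))
    names(eff) <- c("boundary_sep", "non_decision", "bias", "drift")
    eff$participant_id <- pids

    ratings <- do.call(rbind, lapply(seq_len(np), function(i)
      cbind(participant_id = pids[i],
            simulate_ratings(config$rating_model, all_images),
            stringsAsFactors = FALSE)))

    trial_rows <- vector("list", np * 3L * 2L)
    path_rows <- vector("list", np * 3L * 2L)
    slot <- 0L
    trial_counter <- 0L
    n_block <- 6L * config$pairs_per_combo

    for (i in seq_len(np)) {
      ctx_order <- sample(config$contexts)
      order_in_session <- 0L
      for (ctx in ctx_order) {
        seq_df <- generate_pair_sequence(inv[[ctx]], config$pairs_per_combo)
        dnwl <- abs(seq_df$nwl_left - seq_df$nwl_right)
        for (block in c(FALSE, TRUE)) {
          base <- config$ddm_truth[config$ddm_truth$context == ctx &
                                     config$ddm_truth$nwl_shown == block, ]
          # one simulation batch per distinct within-pair NWL difference,
          # since the optional label gradient acts on the drift rate
          choice <- character(n_block); rts <- numeric(n_block)
          cens <- logical(n_block); pconf <- numeric(n_block)
          for (dv in unique(dnwl)) {
            sel <- which(dnwl == dv)
            tr <- base
            if (block) tr$drift <- tr$drift + config$nwl_gradient * (dv - 1)
            pp <- participant_truth(tr, eff[i, ])
            pars <- ddm_params(pp$boundary_sep, pp$non_decision, pp$bias,
                               pp$drift)
            sim <- simulate_trial(pars, config$timeout, n = length(sel))
            choice[sel] <- sim$choice
            rts[sel] <- sim$rt
            cens[sel] <- sim$censored
            ph <- hit_probability(pars)
            pconf[sel] <- ifelse(sim$choice == "healthy", 1 - ph, ph)
          }
          healthy_side <- ifelse(seq_df$nwl_left < seq_df$nwl_right,
                                 "left", "right")
          chosen_side <- ifelse(choice == "healthy", healthy_side,
                                ifelse(healthy_side == "left", "right",
                                       "left"))
          rate <- pmax(rnorm(n_block, config$sampling_rate[["mean"]],
                             config$sampling_rate[["sd"]]), 20)
          ids <- trial_counter + seq_len(n_block)
          trial_counter <- trial_counter + n_block

          pl <- vector("list", n_block)
          for (j in seq_len(n_block)) {
            pm <- simulate_trajectory(chosen_side[j], rts[j], pconf[j],
                                      rate[j])
            pl[[j]] <- cbind(trial_id = ids[j], pm)
          }
          path_rows[[slot + 1L]] <- do.call(rbind, pl)

          trial_rows[[slot + 1L]] <- data.frame(
            trial_id = ids, participant_id = pids[i], context = ctx,
            nwl_shown = block, pair_id = seq_df$position,
            trial_order = order_in_session + seq_len(n_block),
            left_image = seq_df$left_image, right_image = seq_df$right_image,
            nwl_left = seq_df$nwl_left, nwl_right = seq_df$nwl_right,
            delta_nwl = dnwl, chosen_side = chosen_side,
            healthy_choice = choice == "healthy", rt_s = rts,
            censored = cens, conflict = pconf,
            tag_low_res = FALSE, tag_multicross = FALSE,
            tag_rt_outlier = FALSE, tag_unrecognized = FALSE,
            stringsAsFactors = FALSE)
          slot <- slot + 1L
          order_in_session <- order_in_session + n_block
        }
      }
    }
    trials <- do.call(rbind, trial_rows)
    rownames(trials) <- NULL
    pm <- do.call(rbind, path_rows)
    paths <- data.frame(trial_id = pm[, "trial_id"], t_s = pm[, "t"],
                        x = pm[, "x"], y = pm[, "y"])

    study <- structure(list(
      trials = trials, paths = paths, ratings = ratings,
      participants = participants,
      truth = list(ddm_truth = config$ddm_truth,
                   participant_effects = eff,
                   contamination = config$contamination),
      config = config), class = "nwl_study")
    inject_contaminants(study, config$contamination)
  })
}

#' @export
print.nwl_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic NWL study: %d participants, %d trials, %d path samples\n",
    x$config$n_participants, nrow(x$trials), nrow(x$paths)))
  invisible(x)
}

#' Inject tagged contaminant trials into a study
#'
#' Applies the four contaminant types independently at their configured
#' per-trial rates, rewriting the affected trials' paths (or recognition
#' flags) and tagging them so filter recall and precision are computable:
#' `low_res` resamples the path below 10 Hz, `multicross` substitutes a
#' vacillating path with at least three axis crossings, `rt_outlier`
#' inflates the response time toward the deadline and regenerates the path,
#' and `unrecognized` marks one image of the pair as unrecognized for that
#' participant (tagging every trial that shows the image). With all rates
#' zero the study is returned unchanged.
#'
#' @param study An `nwl_study`.
#' @param rates A [contamination_rates()].
#' @return The study with tagged contaminated trials.
#' @export
inject_contaminants <- function(study, rates) {
  stopifnot(inherits(study, "nwl_study"),
            inherits(rates, "contamination_rates"))
  if (all(unlist(rates) == 0)) return(study)
  tr <- study$trials
  n <- nrow(tr)
  timeout <- study$config$timeout

  redo_path <- function(trial_id, chosen_side, rt, conflict, rate,
                        zigzag = FALSE) {
    pm <- simulate_trajectory(chosen_side, rt, conflict, rate,
                              zigzag = zigzag)
    data.frame(trial_id = trial_id, t_s = pm[, "t"], x = pm[, "x"],
               y = pm[, "y"])
  }
  drop_ids <- integer(0)
  new_paths <- list()

  hit_low <- which(runif(n) < rates$low_resolution_rate)
  for (i in hit_low) {
    r <- runif(1, 2, 9)
    new_paths[[length(new_paths) + 1L]] <-
      redo_path(tr$trial_id[i], tr$chosen_side[i], tr$rt_s[i],
                tr$conflict[i], r)
  }
  tr$tag_low_res[hit_low] <- TRUE

  hit_zz <- setdiff(which(runif(n) < rates$multicross_rate), hit_low)
  for (i in hit_zz) {
    rate_i <- max(rnorm(1, study$config$sampling_rate[["mean"]],
                        study$config$sampling_rate[["sd"]]), 20)
    new_paths[[length(new_paths) + 1L]] <-
      redo_path(tr$trial_id[i], tr$chosen_side[i], tr$rt_s[i],
                tr$conflict[i], rate_i, zigzag = TRUE)
  }
  tr$tag_multicross[hit_zz] <- TRUE

  hit_rt <- setdiff(which(runif(n) < rates$rt_outlier_rate),
                    c(hit_low, hit_zz))
  for (i in hit_rt) {
    new_rt <- max(tr$rt_s[i], runif(1, 0.875, 0.9875) * timeout)
    tr$rt_s[i] <- new_rt
    rate_i <- max(rnorm(1, study$config$sampling_rate[["mean"]],
                        study$config$sampling_rate[["sd"]]), 20)
    new_paths[[length(new_paths) + 1L]] <-
      redo_path(tr$trial_id[i], tr$chosen_side[i], new_rt,
                tr$conflict[i], rate_i)
  }
  tr$tag_rt_outlier[hit_rt] <- TRUE

  hit_un <- which(runif(n) < rates$unrecognized_pair_rate)
  if (length(hit_un)) {
    rat <- study$ratings
    for (i in hit_un) {
      img <- if (runif(1) < 0.5) tr$left_image[i] else tr$right_image[i]
      rat$recognized[rat$participant_id == tr$participant_id[i] &
                       rat$image_id == img] <- FALSE
      affected <- tr$participant_id == tr$participant_id[i] &
        (tr$left_image == img | tr$right_image == img)
      tr$tag_unrecognized[affected] <- TRUE
    }
    study$ratings <- rat
  }

  if (length(new_paths)) {
    np <- do.call(rbind, new_paths)
    drop_ids <- unique(np$trial_id)
    study$paths <- rbind(study$paths[!(study$paths$trial_id %in% drop_ids), ],
                         np)
    study$paths <- study$paths[order(study$paths$trial_id,
                                     study$paths$t_s), ]
    rownames(study$paths) <- NULL
  }
  study$trials <- tr
  study
}
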