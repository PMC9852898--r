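#' Label a choice as healthy or unhealthy
#'
#' A choice is healthy when the selected image carries strictly fewer
#' nutrient warning labels than the rejected one. Pairs with equal counts
#' violate the design (every combination pairs distinct counts) and raise
#' an error.
#'
#' @param chosen_side `"left"` or `"right"` (vectorized).
#' @param nwl_left,nwl_right NWL counts of the two images.
#' @return Logical vector: `TRUE` for healthy choices.
#' @export
label_healthy_choice <- function(chosen_side, nwl_left, nwl_right) {
  if (any(nwl_left == nwl_right))
    stop("design violation: pair with equal NWL counts", call. = FALSE)
  chosen <- ifelse(chosen_side == "left", nwl_left, nwl_right)
  other <- ifelse(chosen_side == "left", nwl_right, nwl_left)
  chosen < other
}

#' Pair the two label blocks of each food pair
#'
#' Joins, per participant x context x pair, the trial made without labels
#' with the trial made with labels, carrying choices, AUC and response
#' times from both blocks. Pairs with either block missing (e.g. filtered
#' out) are dropped with a logged count (`n_incomplete` attribute).
#'
#' @param trials Trial/metrics table with columns `participant_id`,
#'   `context`, `pair_id`, `nwl_shown`, `healthy_choice`, `auc`, `rt_s`,
#'   `delta_nwl`.
#' @return Data frame of paired trials with columns `choice_no_nwl`,
#'   `choice_nwl` (logical healthy flags), `auc_no_nwl`, `auc_nwl`,
#'   `rt_no_nwl`, `rt_nwl`, `delta_nwl`, and the keys.
#' @export
pair_trials <- function(trials) {
  need <- c("participant_id", "context", "pair_id", "nwl_shown",
            "healthy_choice", "auc", "rt_s", "delta_nwl")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  a <- trials[!trials$nwl_shown, need]
  b <- trials[trials$nwl_shown, need]
  key <- c("participant_id", "context", "pair_id")
  m <- merge(a, b, by = key, suffixes = c("_no", "_yes"))
  out <- data.frame(
    participant_id = m$participant_id, context = m$context,
    pair_id = m$pair_id,
    choice_no_nwl = m$healthy_choice_no, choice_nwl = m$healthy_choice_yes,
    auc_no_nwl = m$auc_no, auc_nwl = m$auc_yes,
    rt_no_nwl = m$rt_s_no, rt_nwl = m$rt_s_yes,
    delta_nwl = m$delta_nwl_no, stringsAsFactors = FALSE)
  n_pairs_possible <- length(unique(paste(trials$participant_id,
                                          trials$context, trials$pair_id)))
  attr(out, "n_incomplete") <- n_pairs_possible - nrow(out)
  out
}

#' Classify the decision path of a paired trial
#'
#' Four-level factor coding the choices across the two blocks of the same
#' pair: first letter without labels, second with labels (`H` healthy,
#' `U` unhealthy). `UH` is a label-induced reversal of an unhealthy choice.
#'
#' @param paired Data frame from [pair_trials()], or two logical vectors
#'   via `choice_no_nwl`/`choice_nwl`.
#' @param choice_no_nwl,choice_nwl Logical healthy flags (used when
#'   `paired` is missing).
#' @return Factor with levels `HH`, `HU`, `UH`, `UU`.
#' @export
classify_decision_path <- function(paired = NULL, choice_no_nwl = NULL,
                                   choice_nwl = NULL) {
  if (!is.null(paired)) {
    choice_no_nwl <- paired$choice_no_nwl
    choice_nwl <- paired$choice_nwl
  }
  lab <- paste0(ifelse(choice_no_nwl, "H", "U"),
                ifelse(choice_nwl, "H", "U"))
  factor(lab, levels = c("HH", "HU", "UH", "UU"))
}

# Percentile bootstrap over participant clusters of a ratio estimator
# sum(num) / sum(den), where num/den are per-participant totals.
cluster_boot_ratio <- function(num, den, n_boot = 2000L, conf = 0.95,
                               seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed,
    cluster_boot_ratio(num, den, n_boot, conf, seed = NULL)))
  k <- length(num)
  est <- sum(num) / sum(den)
  if (k == 1L) return(c(estimate = est, lower = est, upper = est))
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ix <- sample.int(k, k, replace = TRUE)
    stat[b] <- sum(num[ix]) / sum(den[ix])
  }
  qs <- quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  c(estimate = est, lower = qs[1], upper = qs[2])
}

boot_group_table <- function(df, num_col, den_col, group_cols, n_boot, conf,
                             seed) {
  key <- interaction(df[group_cols], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    d <- df[key == lv, ]
    info <- d[1, group_cols, drop = FALSE]
    if (sum(d[[den_col]]) == 0) {
      cbind(info, data.frame(estimate = NA_real_, lower = NA_real_,
                             upper = NA_real_, n_trials = 0L,
                             n_participants = 0L))
    } else {
      ci <- cluster_boot_ratio(d[[num_col]], d[[den_col]], n_boot, conf,
                               seed = seed)
      cbind(info, data.frame(estimate = ci[["estimate"]],
                             lower = ci[["lower"]], upper = ci[["upper"]],
                             n_trials = sum(d[[den_col]]),
                             n_participants = nrow(d)))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Healthy-choice probability with cluster-bootstrap intervals
#'
#' Pooled proportion of healthy choices per group, with a 95% percentile
#' bootstrap interval over participant resamples (participants are the
#' clusters; repeated trials within a participant are not independent).
#'
#' @param trials Trial table with `participant_id`, `healthy_choice` and
#'   the grouping columns.
#' @param grouping Character vector of grouping columns (default
#'   `"context"`).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resamples.
#' @return Data frame: grouping columns, `estimate`, `lower`, `upper`,
#'   `n_trials`, `n_participants`.
#' @export
healthy_choice_prob <- function(trials, grouping = "context",
                                n_boot = 2000L, conf = 0.95, seed = 1L) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  agg <- stats::aggregate(
    cbind(num = trials$healthy_choice, den = 1),
    by = c(trials[grouping], list(participant_id = trials$participant_id)),
    FUN = sum)
  boot_group_table(agg, "num", "den", grouping, n_boot, conf, seed)
}

#' Probability that labels reverse an unhealthy choice
#'
#' Conditional probability that the label-shown choice is healthy given the
#' label-free choice on the same pair was unhealthy, per group, with
#' participant-cluster bootstrap intervals. Identically equal to
#' `|UH| / (|UH| + |UU|)` in the decision-path census.
#'
#' @param paired Paired trials from [pair_trials()].
#' @param grouping Grouping columns (default `"context"`).
#' @inheritParams healthy_choice_prob
#' @return Data frame with `estimate`, `lower`, `upper`, `n_trials`
#'   (the U-first denominator) and `n_participants` per group.
#' @export
reversal_probability <- function(paired, grouping = "context",
                                 n_boot = 2000L, conf = 0.95, seed = 1L) {
  u <- paired[!paired$choice_no_nwl, ]
  if (nrow(u) == 0L)
    return(data.frame(context = character(0), estimate = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      n_trials = integer(0), n_participants = integer(0)))
  agg <- stats::aggregate(
    cbind(num = u$choice_nwl, den = 1),
    by = c(u[grouping], list(participant_id = u$participant_id)),
    FUN = sum)
  boot_group_table(agg, "num", "den", grouping, n_boot, conf, seed)
}

#' Label-induced change in conflict per paired trial
#'
#' \eqn{\Delta = \mathrm{value}_{NWL} - \mathrm{value}_{noNWL}} for AUC and
#' response time, so a negative value means the labels reduced conflict
#' (smaller AUC) or sped the choice up. The label-free baselines are
#' carried for covariate adjustment.
#'
#' @param paired Paired trials from [pair_trials()].
#' @return The input with columns `delta_auc`, `delta_rt`, `path`
#'   (decision path), `auc_baseline`, `rt_baseline` appended.
#' @export
compute_deltas <- function(paired) {
  paired$delta_auc <- paired$auc_nwl - paired$auc_no_nwl
  paired$delta_rt <- paired$rt_nwl - paired$rt_no_nwl
  paired$auc_baseline <- paired$auc_no_nwl
  paired$rt_baseline <- paired$rt_no_nwl
  paired$path <- classify_decision_path(paired)
  paired
}

#' Baseline-adjusted group means of conflict changes
#'
#' Per context x decision-path cell, the mean label-induced change adjusted
#' for its baseline: the change is regressed on the grand-mean-centered
#' baseline within the cell (simple least squares) and evaluated at the
#' grand mean, which removes the regression-to-the-mean component carried
#' by cells with unusual baselines. Cells with an (almost) constant
#' baseline fall back to the unadjusted mean, with a note. Confidence
#' intervals are participant-cluster bootstrap percentiles; cells whose
#' interval excludes zero are flagged.
#'
#' @param deltas Output of [compute_deltas()].
#' @param which `"auc"` or `"rt"`.
#' @param n_boot,conf,seed Bootstrap controls.
#' @return Data frame per cell: `context`, `path`, `estimate`, `lower`,
#'   `upper`, `excludes_zero`, `n_trials`, `adjusted`.
#' @export
delta_summary <- function(deltas, which = c("auc", "rt"), n_boot = 2000L,
                          conf = 0.95, seed = 1L) {
  which <- match.arg(which)
  dcol <- paste0("delta_", which)
  bcol <- paste0(which, "_baseline")
  gm <- mean(deltas[[bcol]])
  key <- interaction(deltas$context, deltas$path, drop = TRUE, sep = "\r")

  adj_mean <- function(d) {
    bc <- d[[bcol]] - gm
    if (nrow(d) < 2L || sd(bc) < 1e-12)
      return(list(est = mean(d[[dcol]]), adjusted = FALSE))
    co <- stats::coef(stats::lm.fit(cbind(1, bc), d[[dcol]]))
    list(est = co[1], adjusted = TRUE)   # prediction at the grand mean
  }
  rows <- lapply(levels(key), function(lv) {
    d <- deltas[key == lv, ]
    a <- adj_mean(d)
    pid <- unique(d$participant_id)
    est_b <- if (length(pid) > 1L) with_seed(seed, vapply(seq_len(n_boot),
      function(b) {
        ix <- unlist(split(seq_len(nrow(d)), d$participant_id)[
          sample.int(length(pid), length(pid), replace = TRUE)],
          use.names = FALSE)
        adj_mean(d[ix, ])$est
      }, numeric(1))) else rep(a$est, 2)
    qs <- quantile(est_b, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE, na.rm = TRUE)
    data.frame(context = d$context[1], path = as.character(d$path[1]),
               estimate = a$est, lower = qs[1], upper = qs[2],
               excludes_zero = qs[1] > 0 | qs[2] < 0,
               n_trials = nrow(d), adjusted = a$adjusted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Healthy-choice probability by within-pair NWL difference
#'
#' For label-shown trials only: the pooled healthy-choice proportion per
#' context and per absolute NWL-count difference (1..3), with
#' participant-cluster bootstrap intervals. Missing difference levels are
#' reported as missing rows, not dropped silently.
#'
#' @param trials Trial table (label-shown trials are selected via
#'   `nwl_shown` when present).
#' @inheritParams healthy_choice_prob
#' @return Data frame: `context`, `delta_nwl`, `estimate`, `lower`,
#'   `upper`, `n_trials`, `n_participants`.
#' @export
delta_nwl_effect <- function(trials, n_boot = 2000L, conf = 0.95,
                             seed = 1L) {
  if ("nwl_shown" %in% names(trials)) trials <- trials[trials$nwl_shown, ]
  if (nrow(trials) == 0L) stop("no label-shown trials", call. = FALSE)
  res <- healthy_choice_prob(trials, grouping = c("context", "delta_nwl"),
                             n_boot = n_boot, conf = conf, seed = seed)
  # report missing levels explicitly
  full <- expand.grid(context = unique(trials$context), delta_nwl = 1:3,
                      stringsAsFactors = FALSE)
  out <- merge(full, res, by = c("context", "delta_nwl"), all.x = TRUE)
  out$n_trials[is.na(out$n_trials)] <- 0L
  out[order(out$context, out$delta_nwl), ]
}

#' Decision-path census
#'
#' Counts of the four decision paths per group; `HH + HU + UH + UU` equals
#' the number of complete paired trials.
#'
#' @param paired Paired trials from [pair_trials()].
#' @param grouping Grouping columns (default `"context"`).
#' @return Data frame of counts per group and path.
#' @export
decision_path_census <- function(paired, grouping = "context") {
  paired$path <- classify_decision_path(paired)
  as.data.frame(table(paired[c(grouping, "path")]),
                responseName = "n")
}
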