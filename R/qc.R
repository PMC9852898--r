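#' Trial-filter parameters
#'
#' Thresholds of the standard mouse-tracking quality rules: minimum sampling
#' rate (strictly below excludes), per-participant outlier multiplier
#' (strictly above `mean + sd_mult * SD` excludes, for initiation time, AUC
#' and response time), maximum axis-crossing count (exclusion at or above),
#' and the requirement that both images of the pair were recognized.
#'
#' @param min_rate_hz Minimum sampling rate (default 10 Hz).
#' @param sd_mult Outlier multiplier (default 3).
#' @param max_crossings Crossing count at which a trial is excluded
#'   (default 3, i.e. exclusion when crossings >= 3).
#' @param require_both_recognized Require both pair images recognized
#'   (default `TRUE`).
#' @param per_context Compute the participant outlier baselines per context
#'   rather than over the whole session (default `FALSE`).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_rate_hz = 10, sd_mult = 3, max_crossings = 3L,
                          require_both_recognized = TRUE,
                          per_context = FALSE) {
  stopifnot(min_rate_hz > 0, sd_mult > 0, max_crossings >= 1)
  structure(list(min_rate_hz = min_rate_hz, sd_mult = sd_mult,
                 max_crossings = as.integer(max_crossings),
                 require_both_recognized = require_both_recognized,
                 per_context = per_context),
            class = "filter_params")
}

#' Classify recognition of a pair of images
#'
#' @param left_recognized,right_recognized Logical recognition flags;
#'   missing values are treated as unrecognized (with a warning).
#' @return `"both"`, `"one"` or `"none"` (vectorized).
#' @export
recognition_pair_check <- function(left_recognized, right_recognized) {
  if (anyNA(left_recognized) || anyNA(right_recognized))
    warning("missing recognition flags treated as unrecognized")
  l <- !is.na(left_recognized) & left_recognized
  r <- !is.na(right_recognized) & right_recognized
  c("none", "one", "both")[l + r + 1L]
}

#' Apply the trial-exclusion rules
#'
#' Marks each trial against the quality rules, applied conjunctively in a
#' single pass: sampling resolution below `min_rate_hz`; initiation time,
#' AUC or response time strictly above the participant's mean plus
#' `sd_mult` standard deviations (baselines computed over the participant's
#' resolution-passing trials); `max_crossings` or more axis crossings; and
#' fewer than two recognized images in the pair. A trial may trip several
#' rules; the report lists the marginal fraction per rule.
#'
#' @param metrics Trial metrics from [compute_trial_metrics()] (columns
#'   `participant_id`, `sampling_rate_hz`, `init_time_s`, `auc`, `rt_s`,
#'   `y_crossings`, `left_image`, `right_image`, and `context` when
#'   `per_context` baselines are requested).
#' @param recognition Data frame with `participant_id`, `image_id`,
#'   `recognized` (may be `NULL` when recognition is not checked).
#' @param params A [filter_params()].
#' @param baselines Optional precomputed participant baselines (as found in
#'   a previous report's `$baselines`); when supplied they are used as-is,
#'   which makes re-filtering reproducible on the same base set.
#' @return List of class `exclusion_report`: `retained` (data frame),
#'   `excluded` (data frame), `report` (per-rule counts/fractions in the
#'   conventional order), `tags` (per-trial logical matrix), `baselines`.
#' @export
apply_trial_filters <- function(metrics, recognition = NULL,
                                params = filter_params(),
                                baselines = NULL) {
  need <- c("participant_id", "sampling_rate_hz", "init_time_s", "auc",
            "rt_s", "y_crossings")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metrics is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(metrics)
  rule_res <- metrics$sampling_rate_hz < params$min_rate_hz

  grp_key <- if (params$per_context)
    interaction(metrics$participant_id, metrics$context, drop = TRUE)
  else factor(metrics$participant_id)

  if (is.null(baselines)) {
    base_ok <- !rule_res   # baselines over resolution-passing trials
    baselines <- do.call(rbind, lapply(split(which(base_ok), grp_key[base_ok]),
                                       function(idx) {
      data.frame(
        n_base = length(idx),
        init_mean = mean(metrics$init_time_s[idx]),
        init_sd = sd(metrics$init_time_s[idx]),
        auc_mean = mean(metrics$auc[idx]), auc_sd = sd(metrics$auc[idx]),
        rt_mean = mean(metrics$rt_s[idx]), rt_sd = sd(metrics$rt_s[idx]))
    }))
    baselines$group <- rownames(baselines)
    rownames(baselines) <- NULL
  }
  bix <- match(as.character(grp_key), baselines$group)
  few <- is.na(bix) | baselines$n_base[bix] < 2L
  if (any(few))
    warning(sprintf(paste0(
      "%d trial(s) belong to participants with fewer than 2 ",
      "resolution-passing trials; outlier rules skipped there"), sum(few)))
  thr <- function(mean_col, sd_col)
    baselines[[mean_col]][bix] + params$sd_mult * baselines[[sd_col]][bix]

  rule_init <- !few & metrics$init_time_s > thr("init_mean", "init_sd")
  rule_auc <- !few & metrics$auc > thr("auc_mean", "auc_sd")
  rule_rt <- !few & metrics$rt_s > thr("rt_mean", "rt_sd")
  rule_init[is.na(rule_init)] <- FALSE
  rule_auc[is.na(rule_auc)] <- FALSE
  rule_rt[is.na(rule_rt)] <- FALSE
  rule_cross <- metrics$y_crossings >= params$max_crossings

  if (params$require_both_recognized && !is.null(recognition)) {
    key <- function(p, i) paste(p, i, sep = "\r")
    rec <- stats::setNames(recognition$recognized,
                           key(recognition$participant_id,
                               recognition$image_id))
    lrec <- rec[key(metrics$participant_id, metrics$left_image)]
    rrec <- rec[key(metrics$participant_id, metrics$right_image)]
    pc <- suppressWarnings(recognition_pair_check(lrec, rrec))
    if (anyNA(lrec) || anyNA(rrec))
      warning("recognition flags missing for some trials; treated as unrecognized")
    rule_recog <- pc != "both"
  } else {
    rule_recog <- rep(FALSE, n)
  }

  tags <- cbind(resolution = rule_res, init_time = rule_init, auc = rule_auc,
                rt = rule_rt, crossings = rule_cross,
                recognition = rule_recog)
  any_rule <- rowSums(tags) > 0
  report <- data.frame(
    rule = colnames(tags),
    excluded = colSums(tags),
    fraction = colSums(tags) / n,
    stringsAsFactors = FALSE)
  rownames(report) <- NULL

  structure(list(retained = metrics[!any_rule, , drop = FALSE],
                 excluded = metrics[any_rule, , drop = FALSE],
                 report = report, tags = tags, baselines = baselines,
                 n_total = n),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Trial filters: %d/%d retained (%.2f%%)\n",
              nrow(x$retained), x$n_total,
              100 * nrow(x$retained) / max(x$n_total, 1)))
  for (i in seq_len(nrow(x$report)))
    cat(sprintf("  %-12s %5d excluded (%.2f%%)\n", x$report$rule[i],
                x$report$excluded[i], 100 * x$report$fraction[i]))
  invisible(x)
}
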