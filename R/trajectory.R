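#' Screen geometry of the choice task
#'
#' Normalized coordinate frame used for all trajectory work: the start button
#' is at the origin (bottom center) and the two response images sit in the
#' upper corners at `(-1, 1.5)` (left) and `(1, 1.5)` (right). Working in a
#' normalized space makes the area under the curve unit-free.
#'
#' @return List with `start`, `target_left`, `target_right`.
#' @export
default_geometry <- function() {
  list(start = c(0, 0), target_left = c(-1, 1.5), target_right = c(1, 1.5))
}

#' Estimate the sampling rate of a recorded mouse path
#'
#' `(n_samples - 1) / (t_last - t_first)` in Hz.
#'
#' @param t Numeric vector of sample timestamps (s), nondecreasing.
#' @return Sampling rate in Hz.
#' @examples
#' estimate_sampling_rate(seq(0, 2, length.out = 121)) # 60 Hz
#' @export
estimate_sampling_rate <- function(t) {
  if (length(t) < 2L) stop("need at least 2 samples", call. = FALSE)
  span <- t[length(t)] - t[1]
  if (span <= 0) stop("zero or negative time span", call. = FALSE)
  (length(t) - 1) / span
}

#' Remap a trajectory to the side-invariant frame
#'
#' Translates the path so its first sample is at the origin and reflects it
#' horizontally when the right image was chosen, so every path ends near the
#' left target and curvature metrics are invariant to the chosen side.
#' The reflection is an involution: applying it twice returns the input.
#'
#' @param path Data frame or matrix with columns `x`, `y` (and optionally
#'   `t`).
#' @param chosen_side `"left"` or `"right"`.
#' @return The remapped path (same shape as the input).
#' @export
normalize_trajectory <- function(path, chosen_side = c("left", "right")) {
  chosen_side <- match.arg(chosen_side)
  x <- path[, "x"] - path[1, "x"]
  y <- path[, "y"] - path[1, "y"]
  if (chosen_side == "right") x <- -x
  out <- path
  out[, "x"] <- x
  out[, "y"] <- y
  out
}

#' Signed area between a path and its direct line
#'
#' Area between the piecewise-linear mouse path and the straight line from
#' its first to its last sample, computed by trapezoidal integration of the
#' perpendicular deviation in the rotated (along-line, across-line) frame.
#' On a side-normalized path (chosen target on the left), deviation toward
#' the unchosen side counts positive, so larger values mean more attraction
#' toward the non-chosen option. Equivalent to the signed shoelace area of
#' the polygon formed by the path plus the reversed direct line.
#'
#' @param path Data frame or matrix with columns `x`, `y`, already passed
#'   through [normalize_trajectory()].
#' @param signed If `FALSE`, return the absolute value.
#' @return Area in squared normalized screen units.
#' @examples
#' p <- cbind(x = c(0, 1, 1), y = c(0, 0, 1))
#' compute_auc(p)   # right-triangle area 0.5
#' @export
compute_auc <- function(path, signed = TRUE) {
  x <- as.numeric(path[, "x"]); y <- as.numeric(path[, "y"])
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("degenerate path: start equals end", call. = FALSE)
  ux <- dx / len; uy <- dy / len
  # along-line coordinate s and signed across-line deviation d; with the
  # chosen target up-left, d > 0 lies to the right of travel = unchosen side
  s <- (x - x[1]) * ux + (y - y[1]) * uy
  d <- (x - x[1]) * uy - (y - y[1]) * ux
  auc <- sum((d[-1] + d[-n]) / 2 * diff(s))
  if (signed) auc else abs(auc)
}

#' Count y-axis crossings of a path
#'
#' Number of strict sign changes of the horizontal coordinate relative to
#' the start abscissa. Samples exactly on the axis are bridged (the previous
#' sign is carried through), and leading on-axis samples are ignored, so a
#' path that leaves the axis once and never returns has zero crossings.
#'
#' @param x Numeric vector of horizontal coordinates, or a path with an `x`
#'   column; the first element defines the start abscissa.
#' @return Integer count of crossings.
#' @examples
#' count_y_crossings(c(0, 0.1, -0.2, 0.3, -0.1)) # 3
#' @export
count_y_crossings <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) x <- as.numeric(x[, "x"])
  rel <- x - x[1]
  sgn <- sign(rel)
  sgn <- sgn[sgn != 0]          # bridge exact zeros
  if (length(sgn) < 2L) return(0L)
  sum(sgn[-1] != sgn[-length(sgn)])
}

#' Response and initiation times of a trial
#'
#' The response time is the interval from the start press to the click; the
#' initiation time is the interval from the start press to the first sample
#' whose Euclidean displacement from the starting position exceeds
#' `threshold` (in normalized screen units). A path that never exceeds the
#' threshold is flagged and its initiation time set equal to the response
#' time.
#'
#' @param path Data frame/matrix with columns `t`, `x`, `y`; timestamps are
#'   relative to the start press.
#' @param start_press_t,click_t Start-press and click timestamps (s);
#'   default to the first and last sample times.
#' @param threshold Movement-detection displacement (default 0.02).
#' @return List with `rt_s`, `init_time_s`, `no_movement`.
#' @export
compute_times <- function(path, start_press_t = NULL, click_t = NULL,
                          threshold = 0.02) {
  t <- as.numeric(path[, "t"])
  x <- as.numeric(path[, "x"]); y <- as.numeric(path[, "y"])
  start_press_t <- start_press_t %||% t[1]
  click_t <- click_t %||% t[length(t)]
  if (click_t < start_press_t)
    stop("click precedes start press", call. = FALSE)
  rt <- click_t - start_press_t
  disp <- sqrt((x - x[1])^2 + (y - y[1])^2)
  moved <- which(disp > threshold)
  if (length(moved)) {
    list(rt_s = rt, init_time_s = t[moved[1]] - start_press_t,
         no_movement = FALSE)
  } else {
    list(rt_s = rt, init_time_s = rt, no_movement = TRUE)
  }
}

#' Per-trial trajectory metrics for a whole study
#'
#' Joins a trial table with its raw paths and computes, per trial, the
#' sampling rate, response and initiation times, side-normalized signed AUC
#' and y-axis crossing count, carried together with the design columns
#' needed downstream.
#'
#' @param trials Trial table (columns `trial_id`, `participant_id`,
#'   `context`, `nwl_shown`, `pair_id`, `left_image`, `right_image`,
#'   `chosen_side`, plus any pass-through columns).
#' @param paths Long path table (columns `trial_id`, `t_s`, `x`, `y`),
#'   ordered within trial by time.
#' @param movement_threshold Displacement threshold for initiation time.
#' @param signed_auc Use the signed area (default) or its absolute value.
#' @return Data frame of trial metrics, one row per trial with a recorded
#'   path; trials without any path samples are dropped with a warning.
#' @export
compute_trial_metrics <- function(trials, paths, movement_threshold = 0.02,
                                  signed_auc = TRUE) {
  stopifnot(all(c("trial_id", "t_s", "x", "y") %in% names(paths)),
            "trial_id" %in% names(trials))
  ord <- order(paths$trial_id, paths$t_s)
  tid <- paths$trial_id[ord]
  tt <- paths$t_s[ord]; xx <- paths$x[ord]; yy <- paths$y[ord]
  idx <- split(seq_along(tid), tid)

  # recomputed metric columns replace any same-named columns in the input
  trials <- trials[, setdiff(names(trials),
                             c("auc", "y_crossings", "rt_s", "init_time_s",
                               "sampling_rate_hz")), drop = FALSE]
  keep <- trials$trial_id %in% names(idx)
  if (!all(keep)) {
    warning(sprintf("%d trial(s) have no path samples and were dropped",
                    sum(!keep)))
    trials <- trials[keep, ]
  }
  m <- matrix(NA_real_, nrow = nrow(trials), ncol = 5,
              dimnames = list(NULL, c("auc", "y_crossings", "rt_s",
                                      "init_time_s", "sampling_rate_hz")))
  for (i in seq_len(nrow(trials))) {
    ii <- idx[[as.character(trials$trial_id[i])]]
    p <- cbind(t = tt[ii], x = xx[ii], y = yy[ii])
    if (nrow(p) < 2L) next
    pn <- normalize_trajectory(p, trials$chosen_side[i])
    tm <- compute_times(pn, threshold = movement_threshold)
    m[i, "auc"] <- compute_auc(pn, signed = signed_auc)
    m[i, "y_crossings"] <- count_y_crossings(pn[, "x"])
    m[i, "rt_s"] <- tm$rt_s
    m[i, "init_time_s"] <- tm$init_time_s
    m[i, "sampling_rate_hz"] <- estimate_sampling_rate(pn[, "t"])
  }
  cbind(trials, as.data.frame(m))
}
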