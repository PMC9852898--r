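ddm_par_cols <- c("alpha", "tau", "beta", "delta")

#' Summarize fitted parameters into a multivariate-normal population
#'
#' Sample mean vector and covariance matrix of the converged individual
#' fits for one condition, used to draw plausible parameter sets for the
#' Monte-Carlo recovery study. Covariance matrices that are not positive
#' semi-definite (possible with few fits) are repaired by clipping negative
#' eigenvalues at `1e-10`, with a note recorded.
#'
#' @param fits Data frame of fits for one condition (columns `alpha`,
#'   `tau`, `beta`, `delta`, and optionally `converged`).
#' @param min_fits Minimum number of converged fits required (default 5).
#' @return A `param_population` list: `mean_vec`, `cov`, `n_source`,
#'   `degenerate`, `notes`.
#' @export
fit_param_population <- function(fits, min_fits = 5L) {
  if (!all(ddm_par_cols %in% names(fits)))
    stop("fits must contain columns alpha, tau, beta, delta", call. = FALSE)
  if ("converged" %in% names(fits)) fits <- fits[isTRUE_vec(fits$converged), ]
  fits <- fits[stats::complete.cases(fits[, ddm_par_cols]), ]
  if (nrow(fits) < min_fits)
    stop(sprintf("need at least %d converged fits, got %d", min_fits,
                 nrow(fits)), call. = FALSE)
  m <- colMeans(fits[, ddm_par_cols])
  v <- stats::cov(fits[, ddm_par_cols])
  notes <- character(0)
  degenerate <- all(abs(v) < 1e-12)
  if (degenerate) notes <- c(notes, "zero covariance: identical source fits")
  ev <- eigen(v, symmetric = TRUE)
  if (any(ev$values < 0)) {
    v <- ev$vectors %*% diag(pmax(ev$values, 1e-10)) %*% t(ev$vectors)
    dimnames(v) <- list(ddm_par_cols, ddm_par_cols)
    notes <- c(notes, "covariance clipped to positive semi-definite")
  }
  structure(list(mean_vec = m, cov = v, n_source = nrow(fits),
                 degenerate = degenerate, notes = notes),
            class = "param_population")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.param_population <- function(x, ...) {
  cat(sprintf("DDM parameter population from %d fits\n", x$n_source))
  cat("  mean:", paste(sprintf("%s=%.3f", names(x$mean_vec), x$mean_vec),
                       collapse = ", "), "\n")
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# draws outside the valid parameter region are clamped to the boundary +/-
# epsilon rather than redrawn, preserving the nominal draw count
clamp_draws <- function(d) {
  n_clamped <- 0L
  fix <- function(x, lo, hi) {
    bad <- x < lo | x > hi
    n_clamped <<- n_clamped + sum(bad)
    pmin(pmax(x, lo), hi)
  }
  d[, "alpha"] <- fix(d[, "alpha"], 0.05, 10)
  d[, "tau"] <- fix(d[, "tau"], 0, 5)
  d[, "beta"] <- fix(d[, "beta"], 0.01, 0.99)
  d[, "delta"] <- fix(d[, "delta"], -10, 10)
  attr(d, "n_clamped") <- n_clamped
  d
}

#' Monte-Carlo parameter-recovery run
#'
#' Draws `n_sets` parameter sets from the population's multivariate normal,
#' simulates `n_rt` choice/response-time pairs from each, and refits the
#' model with the same settings as the original fits, yielding a recovered
#' parameter distribution. Invalid draws are clamped to the valid region
#' (count logged) and failed refits flagged, never silently dropped.
#'
#' @param pop A [fit_param_population()] result.
#' @param n_sets Number of parameter draws (default 1000).
#' @param n_rt Simulated trials per draw (default 128).
#' @param settings [ddm_fit_settings()] used for the refits.
#' @param dt Simulation step for the synthetic response times.
#' @return A `recovery_result` list: `draws` and `refits` (`n_sets` x 4
#'   matrices), `valid` flags, `n_clamped`, `n_failed`.
#' @export
run_recovery <- function(pop, n_sets = 1000L, n_rt = 128L,
                         settings = ddm_fit_settings(), dt = 1e-3) {
  stopifnot(inherits(pop, "param_population"), n_sets >= 1, n_rt >= 1)
  if (n_rt < settings$min_trials)
    settings$min_trials <- as.integer(n_rt)
  draws <- MASS::mvrnorm(n_sets, mu = pop$mean_vec, Sigma = pop$cov)
  if (n_sets == 1L) draws <- matrix(draws, nrow = 1,
                                    dimnames = list(NULL, ddm_par_cols))
  colnames(draws) <- ddm_par_cols
  draws <- clamp_draws(draws)
  refits <- matrix(NA_real_, n_sets, 4, dimnames = list(NULL, ddm_par_cols))
  valid <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    pars <- ddm_params(draws[i, "alpha"],
                       max(draws[i, "tau"], 0),
                       min(max(draws[i, "beta"], 0.011), 0.989),
                       draws[i, "delta"])
    sim <- rwiener(n_rt, pars, dt = dt)
    ok <- is.finite(sim$rt)
    if (sum(ok) < settings$min_trials) next
    fit <- tryCatch(fit_ddm(sim$rt[ok], sim$upper[ok], settings),
                    error = function(e) NULL)
    if (is.null(fit) || is.null(fit$params)) next
    refits[i, ] <- c(fit$params$boundary_sep, fit$params$non_decision,
                     fit$params$bias, fit$params$drift)
    valid[i] <- isTRUE(fit$converged)
  }
  n_failed <- sum(!valid)
  if (n_failed > 0.5 * n_sets)
    warning(sprintf("more than half of the refits failed (%d/%d)",
                    n_failed, n_sets))
  structure(list(draws = draws, refits = refits, valid = valid,
                 n_clamped = attr(draws, "n_clamped"), n_failed = n_failed),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Recovery run: %d draws, %d valid refits (%d clamped draws)\n",
              nrow(x$draws), sum(x$valid), x$n_clamped))
  r <- recovery_correlation(x)
  cat("  recovery r:", paste(sprintf("%s=%.3f", names(r), r),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Flag source fits outside the recovered parameter distribution
#'
#' A source (individual) parameter is flagged when it falls outside the
#' central mass of the recovered marginal distribution; with the default
#' two-sided reading and `q = 0.05`, below the 2.5% or above the 97.5%
#' empirical quantile (type-7 interpolation). One-sided readings are
#' selectable.
#'
#' @param source_fits Data frame of individual fits (columns `alpha`,
#'   `tau`, `beta`, `delta`).
#' @param recovery A `recovery_result` (or a matrix of recovered
#'   parameters with those columns).
#' @param q Total tail mass (default 0.05).
#' @param side `"two.sided"` (default), `"lower"` or `"upper"`.
#' @return List: `flags` (logical matrix, one row per source fit),
#'   `bounds` (per-parameter quantile bounds), `any_flag`.
#' @export
flag_outlier_params <- function(source_fits, recovery, q = 0.05,
                                side = c("two.sided", "lower", "upper")) {
  side <- match.arg(side)
  rec <- if (inherits(recovery, "recovery_result"))
    recovery$refits[recovery$valid, , drop = FALSE] else as.matrix(recovery)
  if (nrow(rec) == 0L) stop("empty recovered distribution", call. = FALSE)
  src <- as.matrix(source_fits[, ddm_par_cols])
  bounds <- sapply(ddm_par_cols, function(p) {
    v <- rec[, p]
    switch(side,
           two.sided = quantile(v, c(q / 2, 1 - q / 2), names = FALSE,
                                type = 7),
           lower = c(quantile(v, q, names = FALSE, type = 7), Inf),
           upper = c(-Inf, quantile(v, 1 - q, names = FALSE, type = 7)))
  })
  flags <- sapply(ddm_par_cols, function(p)
    src[, p] < bounds[1, p] | src[, p] > bounds[2, p])
  if (is.null(dim(flags)))
    flags <- matrix(flags, nrow = nrow(src), dimnames = list(NULL,
                                                             ddm_par_cols))
  list(flags = flags, bounds = bounds, any_flag = rowSums(flags) > 0)
}

#' Pearson correlation between generating draws and their refits
#'
#' Per-parameter correlation over the valid (draw, refit) pairs — the
#' pairing that measures whether the estimation pipeline returns what
#' generated the data. Parameters with zero variance in either column are
#' reported as `NA`.
#'
#' @param recovery A `recovery_result`, or a matrix/data frame of draws
#'   when `refits` is given separately.
#' @param refits Optional matrix of refitted parameters aligned with
#'   `recovery` rows.
#' @return Named numeric vector of Pearson correlations, with an
#'   `n_excluded` attribute counting invalid pairs.
#' @export
recovery_correlation <- function(recovery, refits = NULL) {
  if (inherits(recovery, "recovery_result")) {
    draws <- recovery$draws; refit <- recovery$refits
    ok <- recovery$valid
  } else {
    draws <- as.matrix(recovery); refit <- as.matrix(refits)
    ok <- stats::complete.cases(refit)
  }
  if (sum(ok) < 3L)
    stop("need at least 3 valid (draw, refit) pairs", call. = FALSE)
  r <- vapply(ddm_par_cols, function(p) {
    x <- draws[ok, p]; y <- refit[ok, p]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  attr(r, "n_excluded") <- sum(!ok)
  r
}
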