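#' Drift-diffusion model parameters
#'
#' Bundles the four parameters of the two-boundary drift-diffusion model
#' (unit diffusion coefficient) used throughout the package. The *upper*
#' boundary is the healthy choice by convention, so a positive drift rate
#' accumulates evidence toward the healthier food.
#'
#' @param boundary_sep Boundary separation \eqn{\alpha > 0} (evidence units).
#' @param non_decision Non-decision time \eqn{\tau \ge 0} in seconds
#'   (encoding and motor components of the response time).
#' @param bias Relative starting point \eqn{\beta \in (0, 1)}; 0.5 is
#'   unbiased, values above 0.5 start closer to the healthy boundary.
#' @param drift Drift rate \eqn{\delta} (evidence units per second); positive
#'   values favor the healthy choice.
#'
#' @return An object of class `ddm_params` (named list).
#' @examples
#' ddm_params(boundary_sep = 1.5, non_decision = 0.3, bias = 0.6, drift = 0.8)
#' @export
ddm_params <- function(boundary_sep, non_decision, bias, drift) {
  stopifnot(is.numeric(boundary_sep), is.numeric(non_decision),
            is.numeric(bias), is.numeric(drift))
  if (!is.finite(boundary_sep) || boundary_sep <= 0)
    stop("boundary_sep must be finite and > 0", call. = FALSE)
  if (!is.finite(non_decision) || non_decision < 0)
    stop("non_decision must be finite and >= 0", call. = FALSE)
  if (!is.finite(bias) || bias <= 0 || bias >= 1)
    stop("bias must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(drift))
    stop("drift must be finite", call. = FALSE)
  structure(list(boundary_sep = boundary_sep, non_decision = non_decision,
                 bias = bias, drift = drift),
            class = "ddm_params")
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  ddm_params(x[["boundary_sep"]], x[["non_decision"]], x[["bias"]],
             x[["drift"]])
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: alpha = %.3f, tau = %.3f s, beta = %.3f, delta = %.3f\n",
    x$boundary_sep, x$non_decision, x$bias, x$drift))
  invisible(x)
}

#' Wiener first-passage-time density
#'
#' Density of the decision time at the upper or lower boundary of the
#' drift-diffusion process, evaluated with the classic dual-series expansion
#' (small-time and large-time forms, with the cheaper branch selected per
#' evaluation; absolute truncation tolerance `1e-10`). Times at or below the
#' non-decision time have density zero.
#'
#' @param t Numeric vector of response times in seconds (including the
#'   non-decision component).
#' @param boundary `"upper"` (healthy choice) or `"lower"`.
#' @param params A [ddm_params()] object.
#' @param log Return the log-density?
#' @return Numeric vector of densities (1/s).
#' @examples
#' p <- ddm_params(1.5, 0.3, 0.5, 1)
#' wiener_pdf(seq(0.4, 2, by = 0.4), "upper", p)
#' @export
wiener_pdf <- function(t, boundary = c("upper", "lower"), params, log = FALSE) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  stopifnot(is.numeric(t))
  dwiener_cpp(as.numeric(t), params$boundary_sep, params$non_decision,
              params$bias, params$drift, boundary == "upper", log)
}

#' Probability of absorption at the healthy (upper) boundary
#'
#' Closed-form hit probability of the drift-diffusion process with unit
#' diffusion: \eqn{(1 - e^{-2\delta\alpha\beta})/(1 - e^{-2\delta\alpha})}
#' for \eqn{\delta \neq 0}, and \eqn{\beta} in the zero-drift limit.
#'
#' @param params A [ddm_params()] object.
#' @return Probability of an upper-boundary (healthy) response.
#' @examples
#' hit_probability(ddm_params(1.5, 0.3, 0.62, 1))
#' @export
hit_probability <- function(params) {
  params <- as_ddm_params(params)
  d <- params$drift
  a <- params$boundary_sep
  b <- params$bias
  if (abs(d * a) < 1e-9) return(b)
  num <- -expm1(-2 * d * a * b)
  den <- -expm1(-2 * d * a)
  p <- num / den
  min(max(p, 0), 1)
}

#' Joint log-likelihood of choice/response-time pairs
#'
#' Sum of log Wiener first-passage densities over trials. Any response time
#' at or below the candidate non-decision time makes the likelihood zero;
#' this is guarded as a large negative number (`-1e10`) so optimizers can
#' traverse the region.
#'
#' @param rt Numeric vector of response times (s), all positive.
#' @param upper Logical vector: `TRUE` where the healthy (upper) boundary
#'   was hit.
#' @param params A [ddm_params()] object.
#' @return Log-likelihood in nats.
#' @export
wiener_loglik <- function(rt, upper, params) {
  params <- as_ddm_params(params)
  if (length(rt) == 0L) stop("empty trial list", call. = FALSE)
  if (length(rt) != length(upper))
    stop("rt and upper must have the same length", call. = FALSE)
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("all response times must be finite and positive", call. = FALSE)
  -wiener_negloglik_cpp(as.numeric(rt), as.logical(upper),
                        params$boundary_sep, params$non_decision,
                        params$bias, params$drift)
}

#' Simulate choice/response-time pairs from the drift-diffusion model
#'
#' Euler--Maruyama simulation (default step 1 ms) with Brownian-bridge
#' within-step crossing correction, so the discretization bias in the
#' response-time distribution is of order `dt` rather than `sqrt(dt)`.
#'
#' @param n Number of trials.
#' @param params A [ddm_params()] object.
#' @param dt Integration step (s).
#' @param tmax Cap on simulated decision time (s); runs exceeding it are
#'   returned as `NA`.
#' @return A data frame with columns `rt` (s) and `upper` (logical).
#' @export
rwiener <- function(n, params, dt = 1e-3, tmax = 60) {
  params <- as_ddm_params(params)
  stopifnot(n >= 0, dt > 0, tmax > 0)
  sim <- rwiener_cpp(as.integer(n), params$boundary_sep, params$non_decision,
                     params$bias, params$drift, dt, tmax)
  data.frame(rt = sim$rt, upper = sim$upper)
}

#' Fitting settings for [fit_ddm()]
#'
#' @param restarts Number of dispersed simplex restarts (default 5).
#' @param min_trials Minimum number of usable trials per fit (default 20).
#' @param bounds Named list of length-2 numeric bounds for `alpha`, `tau`
#'   (as a fraction of the minimum observed response time), `beta`, `delta`.
#' @param maxit Maximum simplex iterations per restart.
#' @param jitter_sd Standard deviation of the seed-controlled jitter applied
#'   to the dispersed starting points (on the unconstrained scale).
#' @return A list of settings.
#' @export
ddm_fit_settings <- function(restarts = 5L, min_trials = 20L,
                             bounds = list(alpha = c(0.1, 10),
                                           tau = c(0, 1),
                                           beta = c(0.01, 0.99),
                                           delta = c(-10, 10)),
                             maxit = 800L, jitter_sd = 0.3) {
  stopifnot(restarts >= 1, min_trials >= 1, maxit >= 50)
  list(restarts = as.integer(restarts), min_trials = as.integer(min_trials),
       bounds = bounds, maxit = as.integer(maxit), jitter_sd = jitter_sd)
}

# scaled-logit transform pair used to turn the box-constrained likelihood
# into an unconstrained simplex problem
.to_unc <- function(x, lo, hi) qlogis((x - lo) / (hi - lo))
.to_box <- function(z, lo, hi) lo + (hi - lo) * plogis(z)

#' Maximum-likelihood fit of the drift-diffusion model
#'
#' Bounded maximization of the Wiener likelihood over
#' \eqn{(\alpha, \tau, \beta, \delta)} by Nelder--Mead simplex on a
#' scaled-logit-transformed parameter space, with dispersed multi-start.
#' The non-decision time is bounded above by the minimum observed response
#' time (scaled by `bounds$tau[2]`, slightly below 1 by default through the
#' transform), which keeps the likelihood finite at the optimum.
#'
#' @param rt Response times in seconds.
#' @param upper Logical; `TRUE` for healthy (upper-boundary) choices.
#' @param settings A [ddm_fit_settings()] list.
#' @return A `ddm_fit` list: `params` ([ddm_params()]), `log_likelihood`,
#'   `n_trials`, `converged`, `n_restarts_used`.
#' @examples
#' set.seed(1)
#' sim <- rwiener(300, ddm_params(1.5, 0.3, 0.6, 0.8))
#' fit <- fit_ddm(sim$rt, sim$upper)
#' fit$params
#' @export
fit_ddm <- function(rt, upper, settings = ddm_fit_settings()) {
  ok <- is.finite(rt) & !is.na(upper)
  rt <- as.numeric(rt[ok]); upper <- as.logical(upper[ok])
  n <- length(rt)
  if (n < settings$min_trials)
    stop(sprintf("fit_ddm needs at least %d trials, got %d",
                 settings$min_trials, n), call. = FALSE)
  if (any(rt <= 0)) stop("response times must be positive", call. = FALSE)

  b <- settings$bounds
  min_rt <- min(rt)
  tau_hi <- b$tau[2] * min_rt   # hard upper bound for non-decision time
  tau_lo <- b$tau[1]

  nll <- function(z) {
    a  <- .to_box(z[1], b$alpha[1], b$alpha[2])
    tu <- .to_box(z[2], tau_lo, tau_hi)
    be <- .to_box(z[3], b$beta[1], b$beta[2])
    de <- .to_box(z[4], b$delta[1], b$delta[2])
    wiener_negloglik_cpp(rt, upper, a, tu, be, de)
  }

  # dispersed starting points: spread over plausible boundary separations,
  # non-decision fractions and biases; drift seeded from the choice fraction
  p_up <- mean(upper)
  d0 <- qlogis(min(max(p_up, 0.05), 0.95)) / 2
  starts <- list(
    c(1.2, 0.85 * min_rt, 0.5, d0),
    c(0.8, 0.50 * min_rt, 0.4, 0),
    c(2.0, 0.70 * min_rt, 0.6, d0),
    c(1.5, 0.90 * min_rt, 0.5, 2 * d0),
    c(3.0, 0.30 * min_rt, 0.5, -d0)
  )
  clamp <- function(x, lo, hi) pmin(pmax(x, lo + 1e-6 * (hi - lo)),
                                    hi - 1e-6 * (hi - lo))
  best <- NULL
  used <- 0L
  for (i in seq_len(settings$restarts)) {
    s <- starts[[((i - 1L) %% length(starts)) + 1L]]
    z0 <- c(.to_unc(clamp(s[1], b$alpha[1], b$alpha[2]), b$alpha[1], b$alpha[2]),
            .to_unc(clamp(s[2], tau_lo, tau_hi), tau_lo, tau_hi),
            .to_unc(clamp(s[3], b$beta[1], b$beta[2]), b$beta[1], b$beta[2]),
            .to_unc(clamp(s[4], b$delta[1], b$delta[2]), b$delta[1], b$delta[2]))
    if (i > 1L) z0 <- z0 + rnorm(4, 0, settings$jitter_sd)
    opt <- tryCatch(
      optim(z0, nll, method = "Nelder-Mead",
            control = list(maxit = settings$maxit, reltol = 1e-9)),
      error = function(e) NULL)
    used <- used + 1L
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) {
    return(structure(list(params = NULL, log_likelihood = NA_real_,
                          n_trials = n, converged = FALSE,
                          n_restarts_used = used), class = "ddm_fit"))
  }
  z <- best$par
  pars <- ddm_params(
    boundary_sep = .to_box(z[1], b$alpha[1], b$alpha[2]),
    non_decision = .to_box(z[2], tau_lo, tau_hi),
    bias         = .to_box(z[3], b$beta[1], b$beta[2]),
    drift        = .to_box(z[4], b$delta[1], b$delta[2]))
  structure(list(params = pars, log_likelihood = -best$value, n_trials = n,
                 converged = best$convergence == 0L, n_restarts_used = used),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("DDM fit: FAILED (no restart converged)\n")
  } else {
    cat(sprintf("DDM fit (n = %d, logLik = %.2f, converged = %s)\n",
                x$n_trials, x$log_likelihood, x$converged))
    print(x$params)
  }
  invisible(x)
}

#' Fit the drift-diffusion model per participant and condition
#'
#' One fit per participant x context x label-condition cell, pooling all
#' NWL-count combinations within the cell. Healthy choices map to the upper
#' boundary. Timeout-censored trials are excluded from the likelihood with a
#' logged count; cells with fewer usable trials than `settings$min_trials`
#' are returned flagged (`converged = NA`), never silently dropped.
#'
#' @param trials Data frame with columns `participant_id`, `context`,
#'   `nwl_shown`, `rt_s`, `healthy_choice`, and optionally `censored`.
#' @param settings A [ddm_fit_settings()] list.
#' @return Data frame `fits` with one row per condition: parameter columns
#'   `alpha`, `tau`, `beta`, `delta`, plus `loglik`, `n_trials`,
#'   `n_censored`, `converged`.
#' @export
fit_all_conditions <- function(trials, settings = ddm_fit_settings()) {
  need <- c("participant_id", "context", "nwl_shown", "rt_s", "healthy_choice")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cens <- if ("censored" %in% names(trials)) trials$censored else FALSE
  key <- interaction(trials$participant_id, trials$context, trials$nwl_shown,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    tr <- trials[idx, ]
    is_cens <- if (length(cens) > 1L) cens[idx] else rep(cens, length(idx))
    use <- !is_cens & is.finite(tr$rt_s) & tr$rt_s > 0
    out <- data.frame(participant_id = tr$participant_id[1],
                      context = tr$context[1], nwl_shown = tr$nwl_shown[1],
                      alpha = NA_real_, tau = NA_real_, beta = NA_real_,
                      delta = NA_real_, loglik = NA_real_,
                      n_trials = sum(use), n_censored = sum(is_cens),
                      converged = NA, stringsAsFactors = FALSE)
    if (sum(use) < settings$min_trials) return(out)  # flagged, kept
    fit <- fit_ddm(tr$rt_s[use], tr$healthy_choice[use], settings)
    if (!is.null(fit$params)) {
      out$alpha <- fit$params$boundary_sep
      out$tau <- fit$params$non_decision
      out$beta <- fit$params$bias
      out$delta <- fit$params$drift
      out$loglik <- fit$log_likelihood
    }
    out$converged <- isTRUE(fit$converged)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
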