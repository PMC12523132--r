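#' Piecewise-exponential hazard for the dropout process
#'
#' The dropout (composite event) time has hazard `z_i * h(s)` with a step
#' baseline `h(s) = exp(lambda_k)` on `[t_k, t_{k+1})` and a subject frailty
#' `z_i = exp(lambda0 * trt + eta1 * alpha_i + eta2 * gamma_i)` shared with
#' the longitudinal random effects (the shared-parameter link). The acute
#' random effect `beta_i` is deliberately excluded: the handful of acute-phase
#' visits carry almost no information about it.
#'
#' @param knots Increasing vector of K+1 interval boundaries starting at 0;
#'   the final interval extends to infinity (the last level is used beyond the
#'   last finite knot).
#' @param log_levels Numeric vector of K log baseline-hazard levels
#'   `lambda_1..lambda_K`.
#' @param lambda0 Log hazard ratio of treatment.
#' @param eta1,eta2 Connecting coefficients on `(alpha_i, gamma_i)`.
#' @return An object of class `piecewise_hazard`.
#' @export
piecewise_hazard <- function(knots, log_levels, lambda0 = 0, eta1 = 0, eta2 = 0) {
  knots <- as.numeric(knots)
  log_levels <- as.numeric(log_levels)
  stopifnot(length(knots) == length(log_levels) + 1L,
            knots[1L] == 0, all(diff(knots[is.finite(knots)]) > 0),
            all(is.finite(log_levels)))
  structure(
    list(knots = knots, log_levels = log_levels,
         lambda0 = lambda0, eta1 = eta1, eta2 = eta2,
         K = length(log_levels)),
    class = "piecewise_hazard"
  )
}

#' Place hazard knots at quantiles of the observed event times
#'
#' Interior knots sit at the k/K sample quantiles (k = 1..K-1, linear
#' interpolation, `type = 7`) of the uncensored event times; the first knot is
#' 0 and the last is `Inf`.
#'
#' @param event_times Observed (uncensored) event times.
#' @param K Number of hazard steps (default 5).
#' @return Numeric vector of K+1 knots.
#' @export
place_knots <- function(event_times, K = 5) {
  event_times <- event_times[is.finite(event_times)]
  if (length(event_times) == 0L) {
    stop("no observed events: supply a fixed knot grid instead")
  }
  if (K == 1L) return(c(0, Inf))
  qs <- stats::quantile(event_times, probs = seq_len(K - 1L) / K,
                        names = FALSE, type = 7)
  if (any(diff(qs) <= 0)) {
    stop("degenerate knots: observed event times have too few distinct values")
  }
  c(0, qs, Inf)
}

#' Subject frailty multiplying the baseline hazard
#'
#' @param trt Binary treatment indicator.
#' @param alpha_i,gamma_i Subject intercept and chronic-slope random effects.
#' @param hz A [piecewise_hazard()].
#' @return Positive frailty `z_i`.
#' @export
frailty <- function(trt, alpha_i, gamma_i, hz) {
  stopifnot(inherits(hz, "piecewise_hazard"))
  exp(hz$lambda0 * trt + hz$eta1 * alpha_i + hz$eta2 * gamma_i)
}

## Cumulative baseline hazard Lambda0(t) (vectorized in t). Beyond the last
## finite knot the final level is extended.
cum_base_hazard <- function(t, hz) {
  stopifnot(all(t >= 0))
  K <- hz$K
  lev <- exp(hz$log_levels)
  lower <- hz$knots[seq_len(K)]
  upper <- hz$knots[seq_len(K) + 1L]
  upper[K] <- Inf
  out <- numeric(length(t))
  for (k in seq_len(K)) {
    width <- pmin(t, upper[k]) - lower[k]
    out <- out + lev[k] * pmax(width, 0)
  }
  out
}

## Log baseline hazard at time t (last level extended beyond final knot).
log_base_hazard <- function(t, hz) {
  idx <- findInterval(t, hz$knots, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), hz$K)
  hz$log_levels[idx]
}

#' Survival probability under the frailty-scaled piecewise hazard
#'
#' `S(t) = exp(-z * Lambda0(t))` with `Lambda0` the piecewise-linear
#' cumulative baseline hazard.
#'
#' @param t Non-negative time(s) in years.
#' @param z Frailty (positive scalar or vector matching `t`).
#' @param hz A [piecewise_hazard()].
#' @return Survival probabilities in (0, 1].
#' @export
survival_prob <- function(t, z, hz) {
  if (any(t < 0)) stop("'t' must be non-negative")
  exp(-z * cum_base_hazard(t, hz))
}

#' Log-likelihood of one event/censoring record
#'
#' Events contribute `log(z * h(time)) + log S(time)`; censored records
#' contribute `log S(time)` only.
#'
#' @param time Event or censoring time (> 0).
#' @param event Binary indicator, 1 if the composite event was observed.
#' @param z Frailty.
#' @param hz A [piecewise_hazard()].
#' @return Scalar (or vector) log-likelihood.
#' @export
survival_loglik <- function(time, event, z, hz) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  ll <- -z * cum_base_hazard(time, hz)
  ev <- event == 1
  if (any(ev)) {
    ll[ev] <- ll[ev] + log(z)[if (length(z) > 1L) ev else 1L] +
      log_base_hazard(time[ev], hz)
  }
  ll
}

#' Sample event times by inverting the cumulative hazard
#'
#' Draws `U ~ Unif(0,1)` and returns `Lambda0^{-1}(-log U / z)`, so the draws
#' follow [survival_prob()] exactly.
#'
#' @param n Number of draws.
#' @param z Frailty (scalar or length-n vector).
#' @param hz A [piecewise_hazard()].
#' @return Numeric vector of event times.
#' @export
sample_event_time <- function(n, z, hz) {
  stopifnot(all(z > 0))
  target <- -log(stats::runif(n)) / z
  inv_cum_base_hazard(target, hz)
}

## Inverse of Lambda0 (vectorized); the last hazard level extends to Inf so
## the inverse is always defined.
inv_cum_base_hazard <- function(H, hz) {
  K <- hz$K
  lev <- exp(hz$log_levels)
  lower <- hz$knots[seq_len(K)]
  upper <- hz$knots[seq_len(K) + 1L]
  upper[K] <- Inf
  width <- upper - lower
  cumH <- c(0, cumsum(lev * width))  # cumulative hazard at each knot
  out <- numeric(length(H))
  remaining <- rep(TRUE, length(H))
  for (k in seq_len(K)) {
    in_k <- remaining & (H < cumH[k + 1L] | k == K)
    out[in_k] <- lower[k] + (H[in_k] - cumH[k]) / lev[k]
    remaining <- remaining & !in_k
  }
  out
}
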