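#' Acute/chronic spline time basis
#'
#' Decomposes follow-up time into the acute basis `A = yrs - d * (yrs - t_star)`
#' and the chronic basis `C = d * (yrs - t_star)`, where `d = 1(yrs > t_star)`
#' flags the chronic period. The two bases always sum to `yrs`, so the mean
#' trajectory is continuous at the change point.
#'
#' @param yrs Numeric vector of visit times since baseline, in years (>= 0).
#' @param t_star Change point between acute and chronic periods, in years
#'   (default 1/3, the fourth month after intervention).
#' @return A list with numeric components `acute`, `chronic` and the indicator
#'   `d` (0/1), each the length of `yrs`.
#' @examples
#' time_basis(c(0, 1/3, 2), t_star = 1/3)
#' @export
time_basis <- function(yrs, t_star = 1 / 3) {
  stopifnot(is.numeric(yrs), is.numeric(t_star), length(t_star) == 1L, t_star > 0)
  if (any(!is.finite(yrs)) || any(yrs < 0)) {
    stop("'yrs' must be finite and non-negative")
  }
  d <- as.numeric(yrs > t_star)
  chronic <- d * (yrs - t_star)
  list(acute = yrs - chronic, chronic = chronic, d = d)
}

#' Total-effect weight between acute and chronic slopes
#'
#' The total treatment effect over horizon `T_star` is the weighted average
#' `tau0 = w * zeta0 + (1 - w) * nu0` with `w = t_star / T_star`: the acute
#' slope acts for `t_star` years and the chronic slope for the remaining
#' `T_star - t_star`.
#'
#' @param t_star Change point in years.
#' @param T_star Evaluation horizon in years (default 3, the usual surrogate
#'   window for CKD trials).
#' @return A list with `t_star`, `T_star` and the weight `w` in (0, 1).
#' @export
effect_weight <- function(t_star = 1 / 3, T_star = 3) {
  stopifnot(is.numeric(t_star), is.numeric(T_star),
            length(t_star) == 1L, length(T_star) == 1L)
  if (!(t_star > 0 && T_star > t_star)) {
    stop("require 0 < t_star < T_star")
  }
  list(t_star = t_star, T_star = T_star, w = t_star / T_star)
}

#' Convert between chronic-effect and total-effect parameterizations
#'
#' `nu_from_tau()` solves `tau0 = w * zeta0 + (1 - w) * nu0` for the chronic
#' treatment effect `nu0`; `tau_from_nu()` is its inverse. The sampler and all
#' reporting work on the total-effect (`tau0`) scale, while the generating
#' spline is naturally written with the chronic effect `nu0`.
#'
#' @param tau0 Total treatment effect(s) on the `T_star`-year slope.
#' @param nu0 Chronic treatment effect(s).
#' @param zeta0 Acute treatment effect(s).
#' @param w Weight `t_star / T_star` in (0, 1).
#' @return Numeric vector of `nu0` (respectively `tau0`).
#' @export
nu_from_tau <- function(tau0, zeta0, w) {
  stopifnot(is.numeric(w), all(w > 0 & w < 1))
  (tau0 - w * zeta0) / (1 - w)
}

#' @rdname nu_from_tau
#' @export
tau_from_nu <- function(nu0, zeta0, w) {
  stopifnot(is.numeric(w), all(w > 0 & w < 1))
  w * zeta0 + (1 - w) * nu0
}

#' Expected eGFR trajectory under the two-slope model
#'
#' Evaluates the subject-level mean
#' \deqn{\mu(t) = (\alpha_0(x)+\alpha_i) + (\beta_0(x)+\beta_i) A(t) +
#'   (\gamma_0(x)+\gamma_i) C(t) + \tau_0(x)\,trt\,C(t)/(1-w) +
#'   \zeta_0(x)\,trt\,(t - C(t)/(1-w)),}
#' the total-effect parameterization of the concatenated spline. Setting
#' `nu0 = nu_from_tau(tau0, zeta0, w)` recovers the chronic-effect form in
#' which the treatment adds `zeta0 * A + nu0 * C`.
#'
#' @param yrs Visit times in years.
#' @param trt Binary treatment indicator (scalar).
#' @param alpha0,beta0,gamma0,tau0,zeta0 Surface values at the subject's
#'   covariates (scalars).
#' @param re Numeric length-3 vector of subject random effects
#'   `(alpha_i, beta_i, gamma_i)`; default zero.
#' @param weights Output of [effect_weight()].
#' @return Numeric vector of expected eGFR at each `yrs`.
#' @export
mean_trajectory <- function(yrs, trt, alpha0, beta0, gamma0, tau0, zeta0,
                            re = c(0, 0, 0), weights = effect_weight()) {
  stopifnot(length(re) == 3L, trt %in% c(0, 1))
  tb <- time_basis(yrs, weights$t_star)
  w <- weights$w
  (alpha0 + re[1L]) +
    (beta0 + re[2L]) * tb$acute +
    (gamma0 + re[3L]) * tb$chronic +
    tau0 * trt * tb$chronic / (1 - w) +
    zeta0 * trt * (yrs - tb$chronic / (1 - w))
}

## Random-effect design at the subject's visit times: columns (1, A, C).
re_design <- function(yrs, t_star) {
  tb <- time_basis(yrs, t_star)
  cbind(1, tb$acute, tb$chronic, deparse.level = 0)
}

#' Marginal Gaussian log-likelihood of one subject's eGFR records
#'
#' Integrates the random effects `(alpha_i, beta_i, gamma_i) ~ N(0, sigma2 *
#' Sigma)` out of the longitudinal likelihood in closed form:
#' `Y_i ~ N(mu_fixed, sigma2 * (I + Z Sigma Z'))` with `Z = (1, A, C)` at the
#' subject's visit times.
#'
#' @param yrs Visit times (years) for one subject.
#' @param y Observed eGFR values at those times.
#' @param mu_fixed Fixed-effect mean at those times (surfaces evaluated at the
#'   subject's covariates; see [mean_trajectory()] with `re = 0`).
#' @param sigma2 Residual variance.
#' @param Sigma Standardized 3x3 random-effect covariance (the random-effect
#'   covariance is `sigma2 * Sigma`).
#' @param t_star Change point in years.
#' @return Scalar log-density.
#' @export
marginal_subject_loglik <- function(yrs, y, mu_fixed, sigma2, Sigma,
                                    t_star = 1 / 3) {
  stopifnot(length(yrs) >= 1L, length(y) == length(yrs),
            length(mu_fixed) == length(yrs), sigma2 > 0,
            is.matrix(Sigma), all(dim(Sigma) == 3L))
  Z <- re_design(yrs, t_star)
  V <- sigma2 * (diag(length(y)) + Z %*% Sigma %*% t(Z))
  dmvnorm_log(y, mu_fixed, V)
}

#' Joint log-likelihood of the longitudinal data given random effects
#'
#' Sum over subjects and visits of the Gaussian log-density of the eGFR
#' records at their conditional means, plus the random-effect log prior
#' `N(0, sigma2 * Sigma)`. Used mostly for diagnostics and testing; the
#' sampler works with the collapsed form ([marginal_subject_loglik()]).
#'
#' @param y,mu Stacked observations and conditional means (random effects
#'   included in `mu`).
#' @param re Matrix (n x 3) of subject random effects.
#' @param sigma2,Sigma Variance components as in [marginal_subject_loglik()].
#' @return Scalar log-density.
#' @export
longitudinal_loglik <- function(y, mu, re, sigma2, Sigma) {
  stopifnot(length(y) == length(mu), sigma2 > 0, ncol(re) == 3L)
  Sig_chol <- chol(sigma2 * Sigma)  # errors if not positive definite
  quad <- rowSums((re %*% chol2inv(Sig_chol)) * re)
  ll_obs <- sum(stats::dnorm(y, mu, sqrt(sigma2), log = TRUE))
  ll_re <- -0.5 * nrow(re) * (3 * log(2 * pi) + 2 * sum(log(diag(Sig_chol)))) -
    0.5 * sum(quad)
  ll_obs + ll_re
}

## Dense multivariate-normal log-density (small dimensions only).
dmvnorm_log <- function(y, mu, V) {
  ch <- chol(V)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}
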