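## Independent oracles used across the suite. These deliberately avoid the
## package's own computational paths: dense matrix algebra, numeric
## quadrature and brute-force enumeration at tiny sizes.

ns <- asNamespace("slopehte")

## Dense multivariate-normal log density.
oracle_dmvnorm <- function(y, mu, V) {
  ch <- chol(V)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

## Numeric-quadrature marginal of one subject's longitudinal + survival
## contribution over the random effects (alpha, beta, gamma). beta is
## integrated analytically (the frailty does not involve it); (alpha, gamma)
## by 2-d adaptive quadrature on a wide box.
oracle_subject_marginal <- function(yrs, y, mu_fixed, trt, time, event,
                                    sigma2, Sigma, hz, t_star = 1 / 3,
                                    half_width = 8) {
  Q <- sigma2 * Sigma
  Z <- cbind(1, yrs - pmax(yrs - t_star, 0) * (yrs > t_star),
             pmax(yrs - t_star, 0) * (yrs > t_star))
  ## conditional distribution of beta given (alpha, gamma) under the prior
  idx_s <- c(1L, 3L)
  Qss <- Q[idx_s, idx_s]
  Qsb <- Q[idx_s, 2L]
  gvec <- solve(Qss, Qsb)
  s_b <- Q[2L, 2L] - sum(Qsb * gvec)

  log_f <- function(a, g) {
    mu_b <- gvec[1L] * a + gvec[2L] * g
    mean_y <- mu_fixed + a * Z[, 1L] + g * Z[, 3L] + mu_b * Z[, 2L]
    Vy <- sigma2 * diag(length(y)) + s_b * tcrossprod(Z[, 2L])
    ll_long <- oracle_dmvnorm(y, mean_y, Vy)
    zi <- exp(hz$lambda0 * trt + hz$eta1 * a + hz$eta2 * g)
    H0 <- -log(slopehte::survival_prob(time, 1, hz))
    ll_surv <- -zi * H0
    if (event == 1) {
      ll_surv <- ll_surv + log(zi) + ns$log_base_hazard(time, hz)
    }
    ll_prior <- oracle_dmvnorm(c(a, g), c(0, 0), Qss)
    ll_long + ll_surv + ll_prior
  }
  ## adaptive Gauss-Hermite: center and scale from an independent numeric
  ## optimization of the integrand, then a 40x40 product rule
  opt <- stats::optim(c(0, 0), function(v) -log_f(v[1L], v[2L]),
                      method = "BFGS")
  Hn <- pracma::hessian(function(v) -log_f(v[1L], v[2L]), opt$par)
  L <- t(chol(solve((Hn + t(Hn)) / 2)))
  gh <- pracma::gaussHermite(40)
  peak <- -opt$value
  total <- 0
  for (i in seq_along(gh$x)) {
    for (j in seq_along(gh$x)) {
      v <- opt$par + sqrt(2) * drop(L %*% c(gh$x[i], gh$x[j]))
      total <- total + gh$w[i] * gh$w[j] * exp(gh$x[i]^2 + gh$x[j]^2) *
        exp(log_f(v[1L], v[2L]) - peak)
    }
  }
  peak + log(total) + log(2) + determinant(L)$modulus
}

## Small simulated dataset shared by sampler-level tests.
tiny_trial <- function(n = 40, scenario_name = "setting13", seed = 42, ...) {
  slopehte::gen_trial(slopehte::scenario(scenario_name, n = n, ...), seed = seed)
}

## Chi-square goodness-of-fit p-value for observed counts vs probabilities.
oracle_chisq_p <- function(obs, probs) {
  stats::chisq.test(obs, p = probs / sum(probs))$p.value
}
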