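test_that("time basis decomposes follow-up time and is continuous at the knot", {
  tb <- time_basis(c(0, 1 / 3, 2), t_star = 1 / 3)
  expect_equal(tb$acute + tb$chronic, c(0, 1 / 3, 2))
  expect_equal(tb$acute, c(0, 1 / 3, 1 / 3))
  expect_equal(tb$chronic, c(0, 0, 5 / 3))
  expect_equal(tb$d, c(0, 0, 1))
  expect_error(time_basis(-0.1), "non-negative")

  ## acute basis is capped at t_star, chronic is nonnegative, for random times
  set.seed(1)
  yrs <- runif(200, 0, 4)
  tb <- time_basis(yrs, 0.5)
  expect_true(all(tb$acute >= 0 & tb$acute <= 0.5 + 1e-12))
  expect_true(all(tb$chronic >= 0))
})

test_that("total-effect weight and parameterization conversions are exact", {
  w <- effect_weight(1 / 3, 3)
  expect_equal(w$w, 1 / 9)
  expect_equal(effect_weight(1, 2)$w, 0.5)
  expect_error(effect_weight(0.5, 0.5))

  expect_equal(nu_from_tau(0.9, 0, 1 / 9), 1.0125)
  expect_equal(nu_from_tau(3, 3, 0.4), 3)  # fixed point when tau = zeta
  set.seed(2)
  for (i in 1:20) {
    tau <- rnorm(1); zeta <- rnorm(1); ww <- runif(1, 0.05, 0.95)
    expect_equal(tau_from_nu(nu_from_tau(tau, zeta, ww), zeta, ww), tau)
  }
})

test_that("total-effect and chronic-effect mean parameterizations coincide", {
  ## Derived identity: the mean written with tau0 * trt * C/(1-w) +
  ## zeta0 * trt * (yrs - C/(1-w)) equals the spline with chronic effect
  ## nu0 = (tau0 - w * zeta0) / (1 - w) and acute effect zeta0.
  set.seed(3)
  for (i in 1:100) {
    wts <- effect_weight(runif(1, 0.1, 1), 3)
    yrs <- runif(7, 0, 3.5)
    pars <- rnorm(5)
    re <- rnorm(3)
    tau0 <- rnorm(1); zeta0 <- rnorm(1)
    mu_tau <- mean_trajectory(yrs, 1, pars[1], pars[2], pars[3], tau0, zeta0,
                              re = re, weights = wts)
    nu0 <- nu_from_tau(tau0, zeta0, wts$w)
    tb <- time_basis(yrs, wts$t_star)
    mu_nu <- (pars[1] + re[1]) + (pars[2] + re[2]) * tb$acute +
      (pars[3] + re[3]) * tb$chronic + zeta0 * tb$acute + nu0 * tb$chronic
    expect_equal(mu_tau, mu_nu, tolerance = 1e-12)
  }
})

test_that("mean trajectory is continuous at the change point", {
  set.seed(4)
  for (i in 1:50) {
    wts <- effect_weight(runif(1, 0.2, 0.8), 3)
    pars <- rnorm(5); re <- rnorm(3); trt <- rbinom(1, 1, 0.5)
    eps <- 1e-9
    mu <- mean_trajectory(wts$t_star + c(-eps, eps), trt, pars[1], pars[2],
                          pars[3], pars[4], pars[5], re = re, weights = wts)
    expect_lt(abs(diff(mu)), 1e-6)
  }
  ## baseline value is the intercept only
  expect_equal(mean_trajectory(0, 1, 42, -2, -3, 1, 0.5, re = c(1.5, 0, 0)),
               43.5)
})

test_that("subject marginal likelihood matches a dense MVN oracle", {
  set.seed(5)
  yrs <- c(0, 1 / 3, 1, 2, 3)
  Sigma <- crossprod(matrix(rnorm(9, sd = 0.4), 3)) + diag(0.05, 3)
  sigma2 <- 7
  mu <- 40 - 2 * yrs
  y <- mu + rnorm(5, 0, 2)
  Z <- cbind(1, yrs - pmax(yrs - 1 / 3, 0), pmax(yrs - 1 / 3, 0))
  V <- sigma2 * (diag(5) + Z %*% Sigma %*% t(Z))
  expect_equal(marginal_subject_loglik(yrs, y, mu, sigma2, Sigma),
               oracle_dmvnorm(y, mu, V))

  ## Sigma -> 0 reduces to independent Gaussians
  expect_equal(
    marginal_subject_loglik(yrs, y, mu, sigma2, diag(1e-14, 3)),
    sum(dnorm(y, mu, sqrt(sigma2), log = TRUE)),
    tolerance = 1e-6)
})

test_that("subject marginal matches Monte-Carlo integration over random effects", {
  set.seed(6)
  yrs <- c(0, 1 / 3, 1)
  Sigma <- diag(c(0.3, 0.1, 0.1))
  sigma2 <- 4
  mu <- c(35, 34, 32)
  y <- c(36.1, 33.0, 30.5)
  B <- 2e5
  re <- MASS::mvrnorm(B, rep(0, 3), sigma2 * Sigma)
  Z <- cbind(1, yrs - pmax(yrs - 1 / 3, 0), pmax(yrs - 1 / 3, 0))
  ll <- sapply(seq_len(3), function(j) {
    dnorm(y[j], mu[j] + re %*% Z[j, ], sqrt(sigma2), log = TRUE)
  })
  lw <- rowSums(ll)
  mc <- log(mean(exp(lw - max(lw)))) + max(lw)
  se <- sd(exp(lw - max(lw))) / sqrt(B) / mean(exp(lw - max(lw)))
  expect_lt(abs(marginal_subject_loglik(yrs, y, mu, sigma2, Sigma) - mc),
            3 * se)
})

test_that("joint longitudinal log-likelihood has Gaussian scale behaviour", {
  y <- c(30, 31)
  re <- matrix(0, 1, 3)
  Sigma <- diag(3) * 0.2
  l1 <- longitudinal_loglik(y, y, re, sigma2 = 1, Sigma = Sigma)
  l2 <- longitudinal_loglik(y, y, re, sigma2 = 4, Sigma = Sigma)
  direct <- function(s2) {
    sum(dnorm(y, y, sqrt(s2), log = TRUE)) +
      oracle_dmvnorm(c(0, 0, 0), c(0, 0, 0), s2 * Sigma)
  }
  expect_equal(l1, direct(1))
  expect_equal(l2, direct(4))
  expect_error(longitudinal_loglik(y, y, re, 1, matrix(0, 3, 3)))
})

test_that("control-arm fit recovers two-slope fixed effects (lme4 oracle)", {
  skip_if_not_installed("lme4")
  ## constant surfaces, no treatment arm: the model collapses to a standard
  ## two-slope linear mixed model
  sc <- scenario_config(n = 250, tau0 = surface_const(0),
                        alpha0 = surface_const(42),
                        gamma0 = surface_const(-3.5),
                        beta0 = -2, zeta0 = 0, eta = c(0, 0))
  d <- gen_trial(sc, seed = 9)
  tb <- time_basis(d$records$yrs)
  df <- data.frame(y = d$records$egfr, A = tb$acute, C = tb$chronic,
                   id = d$records$subject_id)
  fit <- lme4::lmer(y ~ A + C + (1 + A + C | id), data = df,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  expect_equal(unname(fe["(Intercept)"]), 42, tolerance = 0.02)
  expect_equal(unname(fe["A"]), -2, tolerance = 0.6)
  expect_equal(unname(fe["C"]), -3.5, tolerance = 0.1)
})
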