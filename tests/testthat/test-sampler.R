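test_that("Laplace subject marginal is exact when the frailty link is off", {
  set.seed(1)
  sigma2 <- 9; Sigma <- diag(c(0.44, 0.25, 0.25))
  hz <- piecewise_hazard(c(0, 1, Inf), log(c(0.2, 0.1)), lambda0 = 0.3,
                         eta1 = 0, eta2 = 0)
  for (i in 1:10) {
    tm <- runif(1, 0.5, 3); ev <- rbinom(1, 1, 0.5)
    yrs <- seq(0, 3, by = 1 / 3); yrs <- yrs[yrs <= tm]
    mu <- 40 - 2 * yrs
    y <- mu + rnorm(length(yrs), 0, 3)
    trt <- rbinom(1, 1, 0.5)
    exact <- marginal_subject_loglik(yrs, y, mu, sigma2, Sigma) +
      survival_loglik(tm, ev, frailty(trt, 0, 0, hz), hz)
    expect_equal(laplace_subject_marginal(yrs, y, mu, trt, tm, ev,
                                          sigma2, Sigma, hz),
                 exact, tolerance = 1e-10)
  }
})

test_that("Laplace subject marginal tracks quadrature at study conditions", {
  skip_if_not_installed("pracma")
  set.seed(2)
  err <- numeric(25)
  sigma2 <- 9; Sigma <- diag(c((2 / 3)^2, 0.25, 0.25))
  hz <- piecewise_hazard(c(0, 0.6, 1.2, 1.8, 2.4, Inf), rep(log(0.119), 5),
                         lambda0 = 0, eta1 = -0.5, eta2 = -0.5)
  for (i in seq_along(err)) {
    re <- MASS::mvrnorm(1, rep(0, 3), sigma2 * Sigma)
    tm <- min(sample_event_time(1, frailty(0, re[1], re[3], hz), hz), 3)
    ev <- as.numeric(tm < 3)
    yrs <- seq(0, 3, by = 1 / 3); yrs <- yrs[yrs <= tm]
    mu <- 40 - 1.5 * yrs
    y <- mu + re[1] + re[2] * pmin(yrs, 1 / 3) + re[3] * pmax(yrs - 1 / 3, 0) +
      rnorm(length(yrs), 0, 3)
    err[i] <- laplace_subject_marginal(yrs, y, mu, 0, tm, ev, sigma2, Sigma, hz) -
      oracle_subject_marginal(yrs, y, mu, 0, tm, ev, sigma2, Sigma, hz)
  }
  ## the Gaussianization of the frailty factor carries a third-order error in
  ## the frailty direction; at these settings it stays below 0.05 log units
  expect_lt(max(abs(err)), 0.05)
})

test_that("Laplace marginal decreases as data move away from the mean", {
  sigma2 <- 9; Sigma <- diag(c(0.44, 0.25, 0.25))
  hz <- piecewise_hazard(c(0, Inf), log(0.2), eta1 = -0.5, eta2 = -0.5)
  yrs <- c(0, 1 / 3, 1, 2)
  mu <- rep(40, 4)
  vals <- sapply(c(0, 5, 15), function(shift) {
    laplace_subject_marginal(yrs, mu + shift, mu, 1, 2.5, 0, sigma2, Sigma, hz)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("collapsed tree-move marginal matches a dense matrix oracle", {
  d <- tiny_trial(n = 30, "setting3", seed = 7)
  cfg <- sampler_config(B1 = 10, B2 = 2, seed = 2, min_leaf = 4)
  fit <- ns$prepare_fit(d, cfg)
  set.seed(2)
  state <- ns$init_state(fit)
  state <- update_sp_params(fit, state)
  lap <- ns$laplace_stats(fit, state)
  ztz <- ns$ztz_entries(fit)
  kap <- ns$marginal_kappa(fit, state, lap, ztz)

  dense_con <- function(state) {
    D <- ns$build_F(fit, state)
    q <- ncol(D)
    A <- diag(q) / fit$tau0sq
    bv <- numeric(q)
    eta <- lap$eta
    for (i in seq_len(fit$n)) {
      rows <- which(fit$subj == i)
      Z <- cbind(1, fit$A[rows], fit$C[rows])
      Cinv <- solve(state$sigma2 * state$Sigma) +
        lap$czstar[i] * tcrossprod(eta)
      V <- state$sigma2 * diag(length(rows)) + Z %*% solve(Cinv) %*% t(Z)
      ri <- fit$y[rows] - drop(Z %*% lap$m[i, ])
      Vi <- solve(V)
      Drows <- D[rows, , drop = FALSE]
      A <- A + t(Drows) %*% Vi %*% Drows
      bv <- bv + drop(t(Drows) %*% Vi %*% ri)
    }
    as.numeric(-0.5 * (q * log(fit$tau0sq) + determinant(A)$modulus) +
                 0.5 * sum(bv * solve(A, bv)))
  }
  sweep_con <- function(state) {
    ns$cpp_tree_sweep(unclass(state$trees[[3]]), fit$Xsplit, fit$grids,
                      fit$Xa, fit$Xs, kap, fit$trt,
                      fit$w / (1 - fit$w), 1 / (1 - fit$w),
                      state$assigns[[1]], state$assigns[[2]], state$assigns[[3]],
                      2L, num_leaves(state$trees[[1]]),
                      num_leaves(state$trees[[2]]), num_leaves(state$trees[[3]]),
                      fit$tau0sq, cfg$c0, cfg$d0, fit$min_leaf, FALSE, 0L,
                      FALSE)$log_marginal_part
  }
  expect_equal(sweep_con(state), dense_con(state), tolerance = 1e-8)

  st2 <- state
  st2$trees[[3]] <- ns$grow_leaf(state$trees[[3]], 1L, 1L, fit$grids$x1[5])
  attr(st2$trees[[3]], "var_names") <- names(fit$grids)
  st2$assigns[[3]] <- leaf_assign(st2$trees[[3]], as.data.frame(fit$Xsplit))
  st2$coefs$theta2 <- c(0, 0)
  expect_equal(sweep_con(st2), dense_con(st2), tolerance = 1e-8)
})

test_that("collapsed marginal is invariant to subject relabeling", {
  d <- tiny_trial(n = 25, "setting13", seed = 8)
  cfg <- sampler_config(B1 = 5, B2 = 1, seed = 3, min_leaf = 3)
  con_of <- function(data) {
    fit <- ns$prepare_fit(data, cfg,
                          grids = build_cutpoint_grid(
                            d$covariates[, d$spec$split_vars]))
    set.seed(9)
    state <- ns$init_state(fit)
    lap <- ns$laplace_stats(fit, state)
    kap <- ns$marginal_kappa(fit, state, lap, ns$ztz_entries(fit))
    ns$cpp_tree_sweep(unclass(state$trees[[3]]), fit$Xsplit, fit$grids,
                      fit$Xa, fit$Xs, kap, fit$trt,
                      fit$w / (1 - fit$w), 1 / (1 - fit$w),
                      state$assigns[[1]], state$assigns[[2]], state$assigns[[3]],
                      2L, 1L, 1L, 1L, fit$tau0sq, cfg$c0, cfg$d0,
                      fit$min_leaf, FALSE, 0L, FALSE)$log_marginal_part
  }
  base <- con_of(d)
  ## relabel subjects in reverse order
  d2 <- d
  remap <- setNames(sprintf("T%05d", rev(seq_len(d$n))), d$covariates$subject_id)
  d2$records$subject_id <- unname(remap[d$records$subject_id])
  d2$survival$subject_id <- unname(remap[d$survival$subject_id])
  d2$covariates$subject_id <- unname(remap[d$covariates$subject_id])
  d2 <- trial_dataset(d2$records, d2$survival, d2$covariates, d$spec)
  expect_equal(con_of(d2), base, tolerance = 1e-10)
})

test_that("variance components and hazard parameters are recovered", {
  sc <- scenario_config(n = 500, tau0 = surface_const(0.5),
                        alpha0 = surface_const(40),
                        gamma0 = surface_const(-3), beta0 = -2, zeta0 = 0.3,
                        eta = c(-0.5, -0.5), sigma = 3,
                        re_sd = c(2, 1.5, 1.5))
  d <- gen_trial(sc, seed = 10)
  cfg <- sampler_config(B1 = 40, B2 = 30, seed = 4)
  ch <- run_chain(d, cfg, freeze_trees = TRUE,
                  init = NULL)
  keep <- 15:30
  sig_draws <- sapply(ch$draws[keep], `[[`, "sigma2")
  expect_lt(abs(mean(sig_draws) - 9), 1.5)
  psi_draws <- sapply(ch$draws[keep], `[[`, "psi")
  eta_mean <- rowMeans(psi_draws)[7:8]
  ## connecting parameters pull toward their true negative values
  expect_lt(eta_mean[1], 0.1)
  expect_lt(eta_mean[2], 0.1)
  ## constant baseline hazard log(0.119) recovered within a wide band
  lam_mean <- mean(rowMeans(psi_draws)[2:6])
  expect_lt(abs(lam_mean - log(-log(0.7) / 3)), 0.5)
  ## theta2 (single leaf) recovers the constant effect
  th <- sapply(ch$draws[keep], function(dd) dd$coefs$theta2)
  expect_lt(abs(mean(th) - 0.5), 0.35)
})

test_that("run_chain honours B2 and keeps legal states", {
  d <- tiny_trial(n = 40, "setting13", seed = 11)
  cfg <- sampler_config(B1 = 10, B2 = 1, seed = 5, min_leaf = 5)
  ch <- run_chain(d, cfg)
  expect_length(ch$draws, 1L)
  cfg2 <- sampler_config(B1 = 10, B2 = 8, seed = 5, min_leaf = 5)
  ch2 <- run_chain(d, cfg2)
  expect_length(ch2$draws, 8L)
  expect_true(all(vapply(ch2$draws, function(dd) num_leaves(dd$trees[[3]]), 0L) >= 1L))
  expect_true(all(is.finite(sapply(ch2$draws, `[[`, "sigma2"))))
  expect_true(all(is.finite(unlist(lapply(ch2$draws, `[[`, "psi")))))
  ## fixed seed reproduces the trajectory
  ch3 <- run_chain(d, cfg2)
  expect_identical(sapply(ch2$draws, `[[`, "sigma2"),
                   sapply(ch3$draws, `[[`, "sigma2"))
})

test_that("null data keep the effect tree at the root", {
  d <- gen_trial(scenario("setting13", n = 300), seed = 12)
  cfg <- sampler_config(B1 = 30, B2 = 15, seed = 6)
  ch <- run_chain(split_dataset(d, 0.6, 1)$discovery, cfg)
  J2 <- vapply(ch$draws, function(dd) num_leaves(dd$trees[[3]]), 0L)
  expect_gte(mean(J2 == 1L), 0.9)
})

test_that("strong two-group signal is recovered by the tree chain", {
  d <- gen_trial(scenario("setting1", n = 800), seed = 13)
  cfg <- sampler_config(B1 = 40, B2 = 20, seed = 7)
  ch <- run_chain(split_dataset(d, 0.6, 2)$discovery, cfg)
  split_var <- vapply(ch$draws[-(1:5)], function(dd) {
    tr <- dd$trees[[3]]
    if (num_leaves(tr) < 2L) NA_character_ else attr(tr, "var_names")[tr$var[1]]
  }, "")
  expect_gte(mean(split_var == "x1", na.rm = TRUE), 0.95)
  expect_lte(mean(is.na(split_var)), 0.05)
})
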