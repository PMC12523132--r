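#' Sampler configuration
#'
#' Chain-length and model settings for the round-trip Gibbs sampler. One
#' round-trip is: `B1` inner iterations for the shared-parameter block
#' conditional on the trees (the first half is warmup for the adaptive
#' random-walk scales), then `B1` birth/death Metropolis-Hastings moves for
#' each of the three decision trees with random effects marginalized out via
#' Laplace's approximation; only the final state of each conditional step is
#' kept, and `B2` round-trips give `B2` retained posterior draws.
#'
#' @param B1 Inner-chain length per conditional step (default 100).
#' @param B2 Number of round-trips / retained draws (default 100).
#' @param seed Integer seed.
#' @param t_star,T_star Change point and total-slope horizon in years.
#' @param K Number of baseline-hazard steps (default 5).
#' @param prior_scale Prior SD of all regression/hazard coefficients
#'   (default 1000, a deliberately vague prior).
#' @param a0,b0 Gamma/Wishart hyper-parameters (default 0.01).
#' @param c0,d0 Tree-prior base and power parameters (defaults 0.95, 2).
#' @param min_leaf Minimum discovery subjects per leaf; `NULL` means
#'   `max(25, ceiling(0.02 n))`.
#' @param n_cuts Quantile bins for continuous cutpoint grids (default 10).
#' @param require_both_arms Require both arms in every leaf (default `TRUE`).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(B1 = 100, B2 = 100, seed = 1L,
                           t_star = 1 / 3, T_star = 3, K = 5,
                           prior_scale = 1000, a0 = 0.01, b0 = 0.01,
                           c0 = 0.95, d0 = 2, min_leaf = NULL, n_cuts = 10,
                           require_both_arms = TRUE) {
  stopifnot(B1 >= 1, B2 >= 1, K >= 1)
  structure(
    list(B1 = as.integer(B1), B2 = as.integer(B2), seed = as.integer(seed),
         weights = effect_weight(t_star, T_star), K = as.integer(K),
         prior_scale = prior_scale, a0 = a0, b0 = b0, c0 = c0, d0 = d0,
         min_leaf = min_leaf, n_cuts = n_cuts,
         require_both_arms = require_both_arms),
    class = "sampler_config"
  )
}

## Standardization moments for design columns (continuous covariates only).
design_scaling <- function(data) {
  spec <- data$spec
  vars <- intersect(union(spec$alpha_design, spec$slope_design), spec$continuous)
  if (!spec$standardize || !length(vars)) return(NULL)
  list(vars = vars,
       center = vapply(vars, function(v) mean(data$covariates[[v]]), 0),
       scale = vapply(vars, function(v) {
         s <- stats::sd(data$covariates[[v]])
         if (!is.finite(s) || s < 1e-12) 1 else s
       }, 0))
}

scaled_design <- function(data, vars, scaling) {
  X <- design_matrix(data, vars)
  if (!is.null(scaling)) {
    for (v in intersect(vars, scaling$vars)) {
      X[, v] <- (X[, v] - scaling$center[v]) / scaling$scale[v]
    }
  }
  X
}

## Assemble everything the sampler needs from a trial_dataset. `grids` and
## `scaling` can be supplied to freeze the discovery-set cutpoints and design
## standardization when refitting on validation data.
prepare_fit <- function(data, config, grids = NULL, scaling = NULL) {
  stopifnot(inherits(data, "trial_dataset"), inherits(config, "sampler_config"))
  spec <- data$spec
  ids <- data$covariates$subject_id
  n <- data$n
  w <- config$weights$w
  t_star <- config$weights$t_star

  Xsplit_df <- data$covariates[, spec$split_vars, drop = FALSE]
  if (is.null(grids)) grids <- build_cutpoint_grid(Xsplit_df, n_cuts = config$n_cuts)
  Xsplit <- as.matrix(Xsplit_df[, names(grids), drop = FALSE])
  if (is.null(scaling)) scaling <- design_scaling(data)
  Xa <- scaled_design(data, spec$alpha_design, scaling)
  Xs <- scaled_design(data, spec$slope_design, scaling)

  subj <- match(data$records$subject_id, ids)
  stopifnot(!is.unsorted(subj))
  y <- data$records$egfr
  tb <- time_basis(data$records$yrs, t_star)
  A <- tb$acute
  C <- tb$chronic
  trt <- data$covariates$trt
  u_tau <- trt[subj] * C / (1 - w)
  ztr <- trt[subj] * (A - C * w / (1 - w))
  starts <- c(0L, cumsum(tabulate(subj, n)))

  time <- data$survival$time
  event <- data$survival$event
  knots <- tryCatch(place_knots(time[event == 1], config$K),
                    error = function(e) {
                      ## fixed grid fallback when events are too few/degenerate
                      c(seq(0, max(time), length.out = config$K + 1L)[seq_len(config$K)], Inf)
                    })
  K <- length(knots) - 1L
  lower <- knots[seq_len(K)]
  upper <- knots[seq_len(K) + 1L]
  upper[K] <- Inf
  Delta <- vapply(seq_len(K), function(k) {
    pmax(pmin(time, upper[k]) - lower[k], 0)
  }, numeric(n))
  Delta <- matrix(Delta, nrow = n)
  tidx <- pmin(pmax(findInterval(time, knots), 1L), K) - 1L  # 0-based

  min_leaf <- config$min_leaf
  if (is.null(min_leaf)) min_leaf <- max(25L, ceiling(0.02 * n))

  list(data = data, config = config, ids = ids, n = n, N = length(y),
       y = y, subj = subj, starts = as.integer(starts), A = A, C = C,
       u_tau = u_tau, ztr = ztr, trt = trt,
       Xa = Xa, Xs = Xs, Xsplit = Xsplit, grids = grids, scaling = scaling,
       time = time, event = event, knots = knots, K = K,
       Delta = Delta, tidx = as.integer(tidx),
       min_leaf = as.integer(min_leaf),
       tau0sq = config$prior_scale^2, w = w, t_star = t_star)
}

## Root-tree initialization: OLS coefficients, residual-moment variance
## components, constant-hazard levels, eta = 0.
init_state <- function(fit) {
  pa <- ncol(fit$Xa)
  ps <- ncol(fit$Xs)
  trees <- replicate(3, {
    tr <- root_tree()
    attr(tr, "var_names") <- names(fit$grids)
    tr
  }, simplify = FALSE)
  assigns <- replicate(3, rep(1L, fit$n), simplify = FALSE)
  coefs <- list(mu0 = matrix(0, pa, 1), mu1 = matrix(0, ps, 1),
                theta2 = 0, mu3 = numeric(ps), mu4 = numeric(ps))
  state <- list(trees = trees, assigns = assigns, coefs = coefs,
                b = matrix(0, fit$n, 3), sigma2 = 1,
                Sigma = diag(c(0.25, 0.1, 0.1)),
                psi = numeric(fit$K + 3L),
                rw_scale = rep(0.25, fit$K + 3L))

  F <- build_F(fit, state)
  ridge <- diag(1e-8, ncol(F))
  theta <- tryCatch(
    drop(solve(crossprod(F) + ridge, crossprod(F, fit$y))),
    error = function(e) numeric(ncol(F)))
  state$coefs <- unpack_theta(fit, state, theta)
  resid <- fit$y - drop(F %*% theta)
  state$sigma2 <- max(stats::var(resid), 1e-4)
  a_proxy <- tapply(resid, fit$subj, mean)
  s11 <- stats::var(a_proxy) / state$sigma2
  state$Sigma <- diag(c(max(min(s11, 5), 0.05), 0.05, 0.05))
  rate <- sum(fit$event) / sum(fit$time)
  lam <- log(max(rate, 1e-4))
  state$psi <- c(0, rep(lam, fit$K), 0, 0)
  state
}

## Fixed design matrix (N x q) under the current tree structures. Column
## blocks: [alpha leaves (pa each)] [gamma leaves (ps each)] [tau leaves (1
## each)] [beta0 (ps)] [zeta0 (ps)].
build_F <- function(fit, state) {
  pa <- ncol(fit$Xa); ps <- ncol(fit$Xs)
  J0 <- num_leaves(state$trees[[1L]])
  J1 <- num_leaves(state$trees[[2L]])
  J2 <- num_leaves(state$trees[[3L]])
  q <- pa * J0 + ps * J1 + J2 + 2L * ps
  F <- matrix(0, fit$N, q)
  a0i <- state$assigns[[1L]][fit$subj]
  a1i <- state$assigns[[2L]][fit$subj]
  a2i <- state$assigns[[3L]][fit$subj]
  Xa_obs <- fit$Xa[fit$subj, , drop = FALSE]
  Xs_obs <- fit$Xs[fit$subj, , drop = FALSE]
  off <- 0L
  for (j in seq_len(J0)) {
    sel <- a0i == j
    F[sel, off + seq_len(pa)] <- Xa_obs[sel, , drop = FALSE]
    off <- off + pa
  }
  for (j in seq_len(J1)) {
    sel <- a1i == j
    F[sel, off + seq_len(ps)] <- Xs_obs[sel, , drop = FALSE] * fit$C[sel]
    off <- off + ps
  }
  for (j in seq_len(J2)) {
    sel <- a2i == j
    F[sel, off + 1L] <- fit$u_tau[sel]
    off <- off + 1L
  }
  F[, off + seq_len(ps)] <- Xs_obs * fit$A
  off <- off + ps
  F[, off + seq_len(ps)] <- Xs_obs * fit$ztr
  F
}

pack_theta <- function(state) {
  c(as.numeric(state$coefs$mu0), as.numeric(state$coefs$mu1),
    state$coefs$theta2, state$coefs$mu3, state$coefs$mu4)
}

unpack_theta <- function(fit, state, theta) {
  pa <- ncol(fit$Xa); ps <- ncol(fit$Xs)
  J0 <- num_leaves(state$trees[[1L]])
  J1 <- num_leaves(state$trees[[2L]])
  J2 <- num_leaves(state$trees[[3L]])
  off <- 0L
  mu0 <- matrix(theta[off + seq_len(pa * J0)], pa, J0); off <- off + pa * J0
  mu1 <- matrix(theta[off + seq_len(ps * J1)], ps, J1); off <- off + ps * J1
  theta2 <- theta[off + seq_len(J2)]; off <- off + J2
  mu3 <- theta[off + seq_len(ps)]; off <- off + ps
  mu4 <- theta[off + seq_len(ps)]
  list(mu0 = mu0, mu1 = mu1, theta2 = theta2, mu3 = mu3, mu4 = mu4)
}

## Laplace approximation of [survival likelihood x random-effect prior] for
## every subject: mode m_i and the ingredients of the tilted covariance.
## Because the frailty depends on (alpha_i, gamma_i) only through the linear
## form eta1*alpha + eta2*gamma, the mode lies on a fixed direction and is
## found by a one-dimensional Newton iteration, vectorized over subjects.
laplace_stats <- function(fit, state) {
  K <- fit$K
  psi <- state$psi
  lam0 <- psi[1L]
  eta <- c(psi[K + 2L], 0, psi[K + 3L])
  Q <- state$sigma2 * state$Sigma
  Lam0 <- drop(fit$Delta %*% exp(psi[1L + seq_len(K)]))
  ci <- exp(lam0 * fit$trt) * Lam0
  Qeta <- drop(Q %*% eta)
  g <- sum(eta * Qeta)

  tvec <- numeric(fit$n)
  if (g > 0) {
    for (iter in 1:50) {
      egt <- ci * exp(tvec * g)
      phi <- tvec - fit$event + egt
      tvec_new <- tvec - phi / (1 + g * egt)
      if (max(abs(tvec_new - tvec)) < 1e-10) { tvec <- tvec_new; break }
      tvec <- tvec_new
    }
  }
  m <- outer(tvec, Qeta)                      # n x 3 mode
  czstar <- ci * exp(tvec * g)                # curvature weight
  Siginv <- solve(state$Sigma)
  list(m = m, czstar = czstar, eta = eta, Siginv = Siginv,
       ci = ci, tvec = tvec, Q = Q, g = g)
}

## Batch inverse of symmetric 3x3 matrices stored as columns
## (m11, m12, m13, m22, m23, m33); returns the same layout.
batch_inv3 <- function(M) {
  a <- M[, 1L]; b <- M[, 2L]; c <- M[, 3L]
  d <- M[, 4L]; e <- M[, 5L]; f <- M[, 6L]
  co11 <- d * f - e * e
  co12 <- c * e - b * f
  co13 <- b * e - c * d
  det <- a * co11 + b * co12 + c * co13
  cbind(co11, co12, co13, a * f - c * c, b * c - a * e, a * d - b * b) / det
}

## Per-subject Z'Z entries (1, A, C basis), layout (z11,z12,z13,z22,z23,z33).
ztz_entries <- function(fit) {
  cbind(
    tabulate(fit$subj, fit$n),
    rowsum_by(fit$A, fit$subj, fit$n),
    rowsum_by(fit$C, fit$subj, fit$n),
    rowsum_by(fit$A^2, fit$subj, fit$n),
    rowsum_by(fit$A * fit$C, fit$subj, fit$n),
    rowsum_by(fit$C^2, fit$subj, fit$n)
  )
}

rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

## Quadratic form u' G v for batches of 3-vectors and symmetric G (n x 6).
batch_qf3 <- function(G, u, v) {
  G[, 1L] * u[, 1L] * v[, 1L] + G[, 4L] * u[, 2L] * v[, 2L] +
    G[, 6L] * u[, 3L] * v[, 3L] +
    G[, 2L] * (u[, 1L] * v[, 2L] + u[, 2L] * v[, 1L]) +
    G[, 3L] * (u[, 1L] * v[, 3L] + u[, 3L] * v[, 1L]) +
    G[, 5L] * (u[, 2L] * v[, 3L] + u[, 3L] * v[, 2L])
}

## Per-subject time-basis Gram scalars feeding the collapsed marginal
## likelihood of the tree moves: kPQ = P' V^-1 Q for bases P, Q in {1, A, C}
## plus products with r, the data minus the Laplace mean shift. V is the
## Laplace-tilted random-effect-marginal covariance
## sigma^2 I + Z C_laplace Z'. These do not depend on any regression
## coefficients, so they are computed once per round-trip and shared by the
## three tree sweeps.
marginal_kappa <- function(fit, state, lap, ztz) {
  sigma2 <- state$sigma2
  ## G_i = (sigma^2 C_i^{-1} + Z'Z_i)^{-1}; sigma^2 C^{-1} = Sigma^{-1} +
  ## sigma^2 czstar * eta eta'
  eta <- lap$eta
  Sg <- lap$Siginv
  outer_eta <- c(eta[1L]^2, eta[1L] * eta[2L], eta[1L] * eta[3L],
                 eta[2L]^2, eta[2L] * eta[3L], eta[3L]^2)
  base <- c(Sg[1L, 1L], Sg[1L, 2L], Sg[1L, 3L], Sg[2L, 2L], Sg[2L, 3L], Sg[3L, 3L])
  Mpre <- matrix(rep(base, each = fit$n), fit$n, 6L) +
    sigma2 * lap$czstar * matrix(rep(outer_eta, each = fit$n), fit$n, 6L) + ztz
  G <- batch_inv3(Mpre)

  mshift <- lap$m[fit$subj, 1L] + lap$m[fit$subj, 2L] * fit$A +
    lap$m[fit$subj, 3L] * fit$C
  r <- fit$y - mshift
  Zr <- cbind(rowsum_by(r, fit$subj, fit$n),
              rowsum_by(fit$A * r, fit$subj, fit$n),
              rowsum_by(fit$C * r, fit$subj, fit$n))
  Z1 <- ztz[, c(1L, 2L, 3L), drop = FALSE]
  ZA <- ztz[, c(2L, 4L, 5L), drop = FALSE]
  ZC <- ztz[, c(3L, 5L, 6L), drop = FALSE]
  kap <- cbind(
    k11 = ztz[, 1L] - batch_qf3(G, Z1, Z1),
    k1A = ztz[, 2L] - batch_qf3(G, Z1, ZA),
    k1C = ztz[, 3L] - batch_qf3(G, Z1, ZC),
    kAA = ztz[, 4L] - batch_qf3(G, ZA, ZA),
    kAC = ztz[, 5L] - batch_qf3(G, ZA, ZC),
    kCC = ztz[, 6L] - batch_qf3(G, ZC, ZC),
    k1r = Zr[, 1L] - batch_qf3(G, Z1, Zr),
    kAr = Zr[, 2L] - batch_qf3(G, ZA, Zr),
    kCr = Zr[, 3L] - batch_qf3(G, ZC, Zr)
  ) / sigma2
  kap
}

#' One tree-update step of the round-trip sampler
#'
#' For each of the three decision trees in turn, runs `B1` birth/death
#' Metropolis-Hastings moves whose acceptance ratio combines the tree prior
#' with the marginal likelihood of the discovery data, random effects
#' integrated out using Laplace's approximation of the survival-likelihood x
#' random-effect-prior factor; the leaf coefficients are then redrawn from
#' their conjugate Gaussian full conditionals.
#'
#' @param fit Internal fit context from `prepare_fit()` (see [run_chain()]).
#' @param state Current sampler state.
#' @param B1 Number of moves per tree (defaults to the config value).
#' @return Updated state; acceptance counts in `attr(, "tree_accept")`.
#' @export
update_trees <- function(fit, state, B1 = fit$config$B1) {
  lap <- laplace_stats(fit, state)
  ztz <- ztz_entries(fit)
  kap <- marginal_kappa(fit, state, lap, ztz)
  accept <- integer(3)
  for (k in 0:2) {
    res <- cpp_tree_sweep(
      unclass(state$trees[[k + 1L]]), fit$Xsplit, fit$grids,
      fit$Xa, fit$Xs, kap, fit$trt,
      fit$w / (1 - fit$w), 1 / (1 - fit$w),
      state$assigns[[1L]], state$assigns[[2L]], state$assigns[[3L]],
      as.integer(k),
      num_leaves(state$trees[[1L]]), num_leaves(state$trees[[2L]]),
      num_leaves(state$trees[[3L]]),
      fit$tau0sq, fit$config$c0, fit$config$d0, fit$min_leaf,
      fit$config$require_both_arms, as.integer(B1), FALSE)
    tr <- structure(res$tree, class = "bdt_tree")
    attr(tr, "var_names") <- names(fit$grids)
    state$trees[[k + 1L]] <- tr
    state$assigns[[k + 1L]] <- as.integer(res$assign)
    state$coefs <- unpack_theta(fit, state, drop(res$theta))
    accept[k + 1L] <- res$accepted
  }
  attr(state, "tree_accept") <- accept
  state
}

#' One shared-parameter update step of the round-trip sampler
#'
#' Runs `B1` inner Gibbs iterations for all non-tree parameters conditional
#' on the trees: random effects (conjugate Gaussian proposal with a
#' Metropolis correction for the survival factor), all regression
#' coefficients (joint conjugate Gaussian), `sigma2` (inverse gamma),
#' `Sigma` (inverse Wishart) and the survival parameters (adaptive
#' random-walk Metropolis). Only the last iteration's state is returned.
#'
#' @inheritParams update_trees
#' @param keep Number of trailing iterations whose coefficient draws are
#'   returned (used by the honest refit); 0 keeps none.
#' @param adapt Adapt the random-walk scales during the first half of the
#'   inner chain (turn off when sampling after warmup).
#' @return Updated state; kept draws, acceptance rates in attributes.
#' @export
update_sp_params <- function(fit, state, B1 = fit$config$B1, keep = 0L,
                             adapt = TRUE) {
  F <- build_F(fit, state)
  res <- cpp_sp_inner(
    fit$y, fit$subj - 1L, fit$A, fit$C, F, fit$starts,
    fit$event, fit$Delta, fit$tidx, fit$trt,
    list(theta = pack_theta(state), b = state$b, sigma2 = state$sigma2,
         Sigma = state$Sigma, psi = state$psi, rw_scale = state$rw_scale),
    fit$tau0sq, fit$config$a0, fit$config$b0, 3 + fit$config$a0,
    as.integer(B1), as.integer(keep), adapt)
  state$coefs <- unpack_theta(fit, state, drop(res$theta))
  state$b <- res$b
  state$sigma2 <- res$sigma2
  state$Sigma <- res$Sigma
  state$psi <- drop(res$psi)
  state$rw_scale <- drop(res$rw_scale)
  attr(state, "re_accept") <- res$re_accept
  attr(state, "psi_accept") <- drop(res$psi_accept)
  if (keep > 0L) {
    attr(state, "kept") <- list(theta = res$keep_theta,
                                sigma2 = drop(res$keep_sigma2),
                                psi = res$keep_psi)
  }
  state
}

#' Run the round-trip Gibbs sampler
#'
#' Alternates [update_sp_params()] and [update_trees()] for `B2` round-trips
#' and retains one joint draw per round-trip: the three trees, all
#' coefficients, variance components, survival parameters and the implied
#' total-effect surface at the fitted subjects.
#'
#' @param data A [trial_dataset()] (typically the discovery split).
#' @param config A [sampler_config()].
#' @param grids Optional frozen cutpoint grids (see [build_cutpoint_grid()]);
#'   computed from `data` when `NULL`.
#' @param scaling Optional frozen design standardization moments.
#' @param freeze_trees Keep the tree structures of `init` fixed and update
#'   only the shared parameters (the honest-refit mode).
#' @param init Optional initial state (required when `freeze_trees = TRUE`).
#' @return An object of class `slopehte_chain`: list with `draws` (length
#'   `B2`), the final `state`, the `fit` context and a `diagnostics`
#'   data.frame (tree sizes, acceptance rates).
#' @export
run_chain <- function(data, config = sampler_config(), grids = NULL,
                      scaling = NULL, freeze_trees = FALSE, init = NULL) {
  set.seed(config$seed)
  fit <- prepare_fit(data, config, grids = grids, scaling = scaling)
  state <- if (is.null(init)) init_state(fit) else reindex_state(fit, init)
  draws <- vector("list", config$B2)
  diag_rows <- vector("list", config$B2)
  for (bb in seq_len(config$B2)) {
    state <- update_sp_params(fit, state)
    ## with frozen trees, a zero-move sweep still redraws all coefficients
    ## from their collapsed (random-effects-marginalized) conditional, which
    ## mixes far better than the theta | b alternation alone
    state <- update_trees(fit, state, B1 = if (freeze_trees) 0L else fit$config$B1)
    draws[[bb]] <- list(
      trees = state$trees, coefs = state$coefs,
      tau_surface = state$coefs$theta2[state$assigns[[3L]]],
      assigns = state$assigns,
      sigma2 = state$sigma2, Sigma = state$Sigma, psi = state$psi)
    diag_rows[[bb]] <- data.frame(
      iter = bb,
      J0 = num_leaves(state$trees[[1L]]),
      J1 = num_leaves(state$trees[[2L]]),
      J2 = num_leaves(state$trees[[3L]]),
      re_accept = attr(state, "re_accept") %||% NA_real_,
      tree_accept = sum(attr(state, "tree_accept") %||% NA_integer_))
  }
  structure(list(draws = draws, state = state, fit = fit,
                 diagnostics = do.call(rbind, diag_rows)),
            class = "slopehte_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.slopehte_chain <- function(x, ...) {
  J2 <- vapply(x$draws, function(d) num_leaves(d$trees[[3L]]), 0L)
  cat(sprintf(
    "<slopehte_chain> %d retained draws; tau0-tree leaves: min %d / median %g / max %d\n",
    length(x$draws), min(J2), stats::median(J2), max(J2)))
  invisible(x)
}

## Recompute leaf assignments of a carried-over state on a new dataset
## (used when refitting validation data with frozen discovery trees).
reindex_state <- function(fit, state) {
  Xs_df <- as.data.frame(fit$Xsplit)
  state$assigns <- lapply(state$trees, function(tr) leaf_assign(tr, Xs_df))
  state$b <- matrix(0, fit$n, 3)
  if (is.null(state$coefs)) {
    pa <- ncol(fit$Xa); ps <- ncol(fit$Xs)
    state$coefs <- list(
      mu0 = matrix(0, pa, num_leaves(state$trees[[1L]])),
      mu1 = matrix(0, ps, num_leaves(state$trees[[2L]])),
      theta2 = numeric(num_leaves(state$trees[[3L]])),
      mu3 = numeric(ps), mu4 = numeric(ps))
  }
  if (is.null(state$sigma2)) state$sigma2 <- 1
  if (is.null(state$Sigma)) state$Sigma <- diag(c(0.25, 0.1, 0.1))
  if (is.null(state$psi)) {
    rate <- sum(fit$event) / sum(fit$time)
    state$psi <- c(0, rep(log(max(rate, 1e-4)), fit$K), 0, 0)
  }
  if (length(state$psi) != fit$K + 3L) {
    state$psi <- c(state$psi[1L], rep(mean(state$psi[-1L]), fit$K), 0, 0)[seq_len(fit$K + 3L)]
  }
  if (length(state$rw_scale) != fit$K + 3L) state$rw_scale <- rep(0.25, fit$K + 3L)
  state
}

#' Laplace-approximate marginal log-likelihood of one subject
#'
#' Approximates the joint contribution of one subject's eGFR records and
#' event/censoring record with the subject random effects integrated out:
#' the survival-likelihood x random-effect-prior factor is replaced by a
#' Gaussian matched at its mode (exact in the beta_i direction, which the
#' frailty does not involve), after which the Gaussian longitudinal
#' likelihood integrates in closed form. With `eta1 = eta2 = 0` the result
#' is exactly [marginal_subject_loglik()] plus the survival log-likelihood.
#'
#' @param yrs,y Visit times and eGFR values of the subject.
#' @param mu_fixed Fixed-effect mean at the visit times.
#' @param trt Arm indicator.
#' @param time,event Event/censoring time and indicator.
#' @param sigma2,Sigma Variance components.
#' @param hz A [piecewise_hazard()] carrying `lambda0`, `eta1`, `eta2`.
#' @param t_star Change point in years.
#' @return Scalar approximate log marginal likelihood.
#' @export
laplace_subject_marginal <- function(yrs, y, mu_fixed, trt, time, event,
                                     sigma2, Sigma, hz, t_star = 1 / 3,
                                     tol = 1e-8, max_iter = 50) {
  stopifnot(inherits(hz, "piecewise_hazard"), length(time) == 1L)
  Q <- sigma2 * Sigma
  Qinv <- solve(Q)
  eta <- c(hz$eta1, 0, hz$eta2)
  ci <- exp(hz$lambda0 * trt) * cum_base_hazard(time, hz)
  Z <- re_design(yrs, t_star)
  ZtZ <- crossprod(Z)
  r0 <- y - mu_fixed
  Ztr <- drop(crossprod(Z, r0))

  ## joint posterior mode of the random effects (Newton; the objective is
  ## strictly concave). Expanding the survival x prior factor here, rather
  ## than at its own mode, keeps the Gaussianization accurate where the
  ## longitudinal likelihood concentrates the integral.
  bhat <- c(0, 0, 0)
  conv <- FALSE
  for (i in seq_len(max_iter)) {
    es <- ci * exp(sum(eta * bhat))
    grad <- (Ztr - drop(ZtZ %*% bhat)) / sigma2 + event * eta - es * eta -
      drop(Qinv %*% bhat)
    H <- ZtZ / sigma2 + es * tcrossprod(eta) + Qinv
    step <- solve(H, grad)
    bhat <- bhat + step
    if (max(abs(step)) < tol) { conv <- TRUE; break }
  }
  if (!conv) bhat <- c(0, 0, 0)  # fall back to the prior-mode expansion

  ## Gaussianize phi(b) = log surv + log prior around bhat with matched
  ## value, gradient and curvature, then integrate the Gaussian longitudinal
  ## likelihood against it in closed form.
  es <- ci * exp(sum(eta * bhat))
  g_phi <- event * eta - es * eta - drop(Qinv %*% bhat)
  H_phi <- Qinv + es * tcrossprod(eta)
  Cmat <- solve(H_phi)
  m <- bhat + drop(Cmat %*% g_phi)

  lin <- hz$lambda0 * trt + sum(eta * bhat)
  ll_surv <- -exp(lin) * cum_base_hazard(time, hz)
  if (event == 1) ll_surv <- ll_surv + lin + log_base_hazard(time, hz)
  phi_hat <- ll_surv + dmvnorm_log(bhat, rep(0, 3), Q)
  log_kappa <- phi_hat + 0.5 * sum(g_phi * drop(Cmat %*% g_phi)) +
    1.5 * log(2 * pi) + 0.5 * determinant(Cmat)$modulus

  V <- sigma2 * diag(length(y)) + Z %*% Cmat %*% t(Z)
  as.numeric(log_kappa + dmvnorm_log(y, mu_fixed + drop(Z %*% m), V))
}
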