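#' Most representative tree of a chain
#'
#' Among the retained draws, selects the one whose total-effect surface at
#' the discovery subjects is closest (smallest sum of squared differences) to
#' the posterior-mean surface. Ties are broken by fewer leaves, then by
#' canonical serialization order.
#'
#' @param draws List of retained draws from [run_chain()] (each carries
#'   `tau_surface`, the total-effect surface at the fitted subjects).
#' @return List with `index`, `tree` (the tau0 tree), `draw` and `distance`.
#' @export
most_representative_tree <- function(draws) {
  stopifnot(length(draws) >= 1L)
  surf <- do.call(rbind, lapply(draws, `[[`, "tau_surface"))
  tau_bar <- colMeans(surf)
  dist <- rowSums((surf - rep(tau_bar, each = nrow(surf)))^2)
  nl <- vapply(draws, function(d) num_leaves(d$trees[[3L]]), 0L)
  str <- vapply(draws, function(d) tree_string(d$trees[[3L]]), "")
  ord <- order(dist, nl, str)
  idx <- ord[1L]
  list(index = idx, tree = draws[[idx]]$trees[[3L]], draw = draws[[idx]],
       distance = dist[idx])
}

#' Super-representative tree across repeated data splits
#'
#' The modal tree (by canonical serialization) among the representative trees
#' of the `B3` discovery/validation splits; frozen cutpoint grids make the
#' tree space finite so frequencies are well defined. Ties are broken by
#' fewer leaves, then serialization order.
#'
#' @param rep_trees List of `bdt_tree` objects (one per split).
#' @return List with `tree`, `frequency` (proportion of splits), `counts`
#'   (named frequency table) and `matches` (indices of splits that produced
#'   the modal tree).
#' @export
super_representative_tree <- function(rep_trees) {
  stopifnot(length(rep_trees) >= 1L)
  keys <- vapply(rep_trees, tree_string, "")
  tab <- table(keys)
  top <- max(tab)
  cand <- names(tab)[tab == top]
  if (length(cand) > 1L) {
    nl <- vapply(cand, function(k) num_leaves(rep_trees[[match(k, keys)]]), 0L)
    cand <- cand[order(nl, cand)]
  }
  key <- cand[1L]
  idx <- which(keys == key)
  list(tree = rep_trees[[idx[1L]]], frequency = top / length(rep_trees),
       counts = sort(tab, decreasing = TRUE), matches = idx)
}

#' Intersection partition of the three fitted trees
#'
#' Cells are the nonempty intersections of the leaf regions of the baseline,
#' chronic-slope and total-effect trees (nonemptiness judged on the supplied
#' covariate sample). The partition refines each tree's own partition; a
#' conventional SP model fitted within these cells is free of the
#' control-surface misspecification that pooling leaves would induce.
#'
#' @param bt0,bt1,bt2 The three `bdt_tree` objects.
#' @param X Covariate data.frame (split variables present).
#' @return List with `cell` (integer cell id per row of `X`) and `cells`
#'   (data.frame of leaf-index triples defining each occupied cell).
#' @export
intersection_tree <- function(bt0, bt1, bt2, X) {
  a0 <- leaf_assign(bt0, X)
  a1 <- leaf_assign(bt1, X)
  a2 <- leaf_assign(bt2, X)
  key <- paste(a0, a1, a2, sep = "/")
  cells <- unique(data.frame(leaf0 = a0, leaf1 = a1, leaf2 = a2, key = key,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$leaf0, cells$leaf1, cells$leaf2), , drop = FALSE]
  rownames(cells) <- NULL
  list(cell = match(key, cells$key), cells = cells[, 1:3])
}

#' Honest refit on the validation split with frozen trees
#'
#' Re-runs the shared-parameter sampler on the validation data with all three
#' tree structures fixed (only parameters update), yielding honest per-leaf
#' posteriors of the total treatment effect and per-leaf slope summaries.
#' Leaves without validation subjects from both arms are flagged
#' non-estimable.
#'
#' @param validation A [trial_dataset()] (the held-out 40%).
#' @param draw A retained draw from the discovery chain (provides the trees
#'   and initial parameter values).
#' @param config A [sampler_config()].
#' @param grids,scaling Frozen discovery-set cutpoint grids and design
#'   scaling.
#' @param n_warm,n_draws Warmup iterations and retained (thinned) draws;
#'   defaults `2 * B1` and `10 * B1`.
#' @return List with `theta_draws` (`n_draws x J2`), `leaf_n`, `leaf_p`
#'   (uncensored proportion), `control_slope`, `treatment_slope`, `estimable`
#'   and the validation `cate` estimates (posterior-mean effect per subject).
#' @export
honest_refit <- function(validation, draw, config, grids, scaling,
                         n_warm = NULL, n_draws = NULL) {
  if (is.null(n_warm)) n_warm <- 2L * config$B1
  if (is.null(n_draws)) n_draws <- 10L * config$B1
  fit <- prepare_fit(validation, config, grids = grids, scaling = scaling)
  state <- reindex_state(fit, list(
    trees = draw$trees, coefs = draw$coefs, sigma2 = draw$sigma2,
    Sigma = draw$Sigma, psi = draw$psi,
    rw_scale = rep(0.25, fit$K + 3L)))

  a2 <- state$assigns[[3L]]
  J2 <- num_leaves(state$trees[[3L]])
  estimable <- vapply(seq_len(J2), function(j) {
    arms <- fit$trt[a2 == j]
    length(arms) > 0L && length(unique(arms)) == 2L
  }, logical(1))

  ## warmup (adaptive), then thinned draws; a zero-move tree sweep after each
  ## shared-parameter batch redraws all coefficients from their collapsed
  ## conditional, which mixes the leaf effects well even from a cold start
  thin <- 2L
  state <- update_sp_params(fit, state, B1 = max(n_warm, 20L), adapt = TRUE)
  state <- update_trees(fit, state, B1 = 0L)
  nd <- as.integer(n_draws)
  w <- fit$w
  a1 <- state$assigns[[2L]]
  theta_draws <- matrix(NA_real_, nd, J2)
  ctrl <- matrix(0, nd, J2)
  for (d in seq_len(nd)) {
    state <- update_sp_params(fit, state, B1 = thin, adapt = FALSE)
    state <- update_trees(fit, state, B1 = 0L)
    theta_draws[d, ] <- state$coefs$theta2
    slope_i <- w * drop(fit$Xs %*% state$coefs$mu3) +
      (1 - w) * rowSums(fit$Xs * t(state$coefs$mu1)[a1, , drop = FALSE])
    ctrl[d, ] <- vapply(seq_len(J2), function(j) mean(slope_i[a2 == j]), 0)
  }
  control_slope <- colMeans(ctrl)
  effect_mean <- colMeans(theta_draws)
  list(theta_draws = theta_draws,
       leaf_n = tabulate(a2, J2),
       leaf_p = vapply(seq_len(J2), function(j) mean(fit$event[a2 == j]), 0),
       control_slope = control_slope,
       treatment_slope = control_slope + effect_mean,
       estimable = estimable,
       cate = effect_mean[a2],
       assign = a2)
}

#' Posterior probability that one subgroup benefits more than another
#'
#' Fraction of posterior draws in which the total treatment effect of leaf A
#' strictly exceeds that of leaf B. Draws are compared pairwise by index
#' (they arise from the same posterior samples).
#'
#' @param leafA_draws,leafB_draws Numeric vectors of posterior draws.
#' @return Probability in `[0, 1]`.
#' @export
ordering_probability <- function(leafA_draws, leafB_draws) {
  if (!length(leafA_draws) || !length(leafB_draws)) stop("no posterior draws")
  m <- max(length(leafA_draws), length(leafB_draws))
  mean(rep_len(leafA_draws, m) > rep_len(leafB_draws, m))
}

#' Discovery/validation concordance of effect estimates
#'
#' For each split, validation subjects are ranked into tertiles by their
#' discovery-tree effect estimates; the honest validation estimates are then
#' averaged within tertile. Concordant fits show nondecreasing tertile means.
#'
#' @param split_results List (one element per split) of lists with numeric
#'   `disc_cate` and `valid_cate` over the same validation subjects.
#' @return Matrix (`B3 x 3`) of tertile means of the validation estimates.
#' @export
concordance_summary <- function(split_results) {
  out <- t(vapply(split_results, function(sr) {
    stopifnot(length(sr$disc_cate) == length(sr$valid_cate))
    rk <- rank(sr$disc_cate, ties.method = "random")
    ter <- cut(rk, breaks = stats::quantile(rk, probs = seq(0, 1, 1 / 3)),
               include.lowest = TRUE, labels = FALSE)
    vapply(1:3, function(g) mean(sr$valid_cate[ter == g]), 0)
  }, numeric(3)))
  colnames(out) <- c("tertile1", "tertile2", "tertile3")
  out
}

#' Honest heterogeneous-treatment-effect pipeline
#'
#' The full workflow: `B3` stratified 60/40 splits; on each discovery set a
#' round-trip chain, its most representative total-effect tree; the modal
#' ("super-representative") tree across splits; honest refits on the
#' validation sets of the splits that produced the modal tree; pooled
#' per-leaf effect posteriors, ordering probabilities and concordance
#' summaries.
#'
#' @param data A [trial_dataset()].
#' @param config A [sampler_config()]; `config$seed` drives the split and
#'   chain seeds.
#' @param B3 Number of repeated splits (default 100).
#' @param frac_discovery Discovery proportion (default 0.6).
#' @param refit Run the honest validation refits (default `TRUE`). When
#'   `FALSE` (structure-only use, e.g. heterogeneity classification), leaf
#'   effect estimates are taken from the discovery draws of the matching
#'   splits instead.
#' @param refit_warm,refit_draws Warmup iterations and retained draws per
#'   refit (defaults `2 * B1` and `10 * B1`).
#' @return An object of class `hte_result`.
#' @export
hte_pipeline <- function(data, config = sampler_config(), B3 = 100,
                         frac_discovery = 0.6, refit = TRUE,
                         refit_warm = NULL, refit_draws = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  set.seed(config$seed)
  split_seeds <- sample.int(.Machine$integer.max %/% 2L, B3)
  chain_seeds <- sample.int(.Machine$integer.max %/% 2L, B3)
  if (is.null(refit_warm)) refit_warm <- 2L * config$B1
  if (is.null(refit_draws)) refit_draws <- 10L * config$B1

  ## cutpoint grids and design scaling are frozen once per run from the
  ## covariate table (no outcome data involved, so honesty is preserved);
  ## frozen grids make the tree space finite and shared across splits, which
  ## is what allows representative trees from different splits to coincide.
  grids <- build_cutpoint_grid(
    data$covariates[, data$spec$split_vars, drop = FALSE],
    n_cuts = config$n_cuts)
  scaling <- design_scaling(data)

  splits <- vector("list", B3)
  for (b in seq_len(B3)) {
    sp <- split_dataset(data, frac_discovery, seed = split_seeds[b])
    cfg_b <- config
    cfg_b$seed <- chain_seeds[b]
    chain <- run_chain(sp$discovery, cfg_b, grids = grids, scaling = scaling)
    rep <- most_representative_tree(chain$draws)
    splits[[b]] <- list(
      seed = split_seeds[b], grids = grids, scaling = scaling,
      discovery_ids = sp$discovery$covariates$subject_id,
      validation = sp$validation,
      rep = rep, J2 = vapply(chain$draws, function(d) num_leaves(d$trees[[3L]]), 0L))
  }

  rep_trees <- lapply(splits, function(s) s$rep$tree)
  super <- super_representative_tree(rep_trees)
  J2 <- num_leaves(super$tree)

  theta_draws <- NULL
  refits <- list()
  split_concord <- list()
  for (b in super$matches) {
    s <- splits[[b]]
    if (refit) {
      rf <- honest_refit(s$validation, s$rep$draw, config, s$grids, s$scaling,
                         n_warm = refit_warm, n_draws = refit_draws)
      refits[[length(refits) + 1L]] <- rf
      theta_draws <- rbind(theta_draws, rf$theta_draws)
      disc_cate <- predict_surface(
        s$rep$tree, s$rep$draw$coefs$theta2,
        s$validation$covariates[, data$spec$split_vars, drop = FALSE])
      split_concord[[length(split_concord) + 1L]] <-
        list(disc_cate = disc_cate, valid_cate = rf$cate)
    } else {
      va <- leaf_assign(super$tree,
                        s$validation$covariates[, data$spec$split_vars, drop = FALSE])
      refits[[length(refits) + 1L]] <- list(
        theta_draws = matrix(s$rep$draw$coefs$theta2, 1L, J2),
        leaf_n = tabulate(va, J2),
        leaf_p = vapply(seq_len(J2), function(j) {
          mean(s$validation$survival$event[va == j])
        }, 0),
        control_slope = rep(NA_real_, J2),
        treatment_slope = rep(NA_real_, J2),
        estimable = rep(TRUE, J2))
      theta_draws <- rbind(theta_draws, refits[[length(refits)]]$theta_draws)
    }
  }

  effect_mean <- colMeans(theta_draws)
  ci <- apply(theta_draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  leaf_summary <- data.frame(
    leaf = seq_len(J2),
    E_n = colMeans(do.call(rbind, lapply(refits, `[[`, "leaf_n"))),
    E_p = colMeans(do.call(rbind, lapply(refits, `[[`, "leaf_p"))),
    control_slope = colMeans(do.call(rbind, lapply(refits, `[[`, "control_slope"))),
    treatment_slope = colMeans(do.call(rbind, lapply(refits, `[[`, "treatment_slope"))),
    effect = effect_mean,
    lower95 = ci[1L, ],
    upper95 = ci[2L, ],
    estimable = apply(do.call(rbind, lapply(refits, `[[`, "estimable")), 2L, all)
  )
  ordering <- outer(seq_len(J2), seq_len(J2), Vectorize(function(a, bb) {
    if (a == bb) return(NA_real_)
    ordering_probability(theta_draws[, a], theta_draws[, bb])
  }))

  structure(
    list(super_tree = super$tree, frequency = super$frequency,
         tree_counts = super$counts, matches = super$matches,
         rep_trees = vapply(rep_trees, tree_string, ""),
         splits = splits, leaf_summary = leaf_summary,
         theta_draws = theta_draws, ordering = ordering,
         concordance = if (length(split_concord)) concordance_summary(split_concord) else NULL,
         effect_mean = effect_mean, split_vars = data$spec$split_vars,
         refit = refit),
    class = "hte_result"
  )
}

#' Predict the pipeline's conditional average treatment effect
#'
#' Routes covariates through the super-representative tree and returns the
#' pooled honest posterior-mean effect of the landing leaf.
#'
#' @param object An `hte_result`.
#' @param newdata Covariate data.frame (split variables present).
#' @param ... Unused.
#' @return Numeric vector of effect estimates.
#' @export
predict.hte_result <- function(object, newdata, ...) {
  j <- leaf_assign(object$super_tree, newdata)
  object$effect_mean[j]
}

#' @export
print.hte_result <- function(x, ...) {
  cat(sprintf("<hte_result> super-representative tree (frequency %.0f%%): %s\n",
              100 * x$frequency, tree_string(x$super_tree)))
  print(x$leaf_summary, digits = 3)
  invisible(x)
}
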