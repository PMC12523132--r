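#' Simulation metrics for subgroup recovery
#'
#' The three validation-set metrics of the simulation study: `l1_error()` is
#' the mean absolute error of the estimated total-effect surface;
#' `r1_regret()` is the mean of `|tau0|` over subjects whose treatment
#' recommendation (sign of the estimate) disagrees with the oracle sign;
#' `htr_indicator()` flags misclassification of heterogeneity — it is 0 when
#' the estimate and the truth agree on whether the effect surface is constant
#' across the validation subjects, 1 otherwise.
#'
#' @param cate_hat Estimated conditional average treatment effects over the
#'   validation subjects.
#' @param cate_true True effects for the same subjects.
#' @return A scalar metric value.
#' @export
l1_error <- function(cate_hat, cate_true) {
  stopifnot(length(cate_hat) == length(cate_true), length(cate_hat) > 0L)
  mean(abs(cate_hat - cate_true))
}

#' @rdname l1_error
#' @export
r1_regret <- function(cate_hat, cate_true) {
  stopifnot(length(cate_hat) == length(cate_true), length(cate_hat) > 0L)
  mean(abs(cate_true) * (as.numeric(cate_hat > 0) != as.numeric(cate_true > 0)))
}

#' @rdname l1_error
#' @export
htr_indicator <- function(cate_hat, cate_true) {
  stopifnot(length(cate_hat) == length(cate_true), length(cate_hat) > 0L)
  const_hat <- length(unique(cate_hat)) == 1L
  const_true <- length(unique(cate_true)) == 1L
  abs(as.numeric(const_hat) - as.numeric(const_true))
}

## Treat-all baseline: recommend treatment for everyone.
r1_naive <- function(cate_true) {
  mean(abs(cate_true) * (1 != as.numeric(cate_true > 0)))
}

#' Bayesian empirical power of a scenario
#'
#' Oracle signal measure: conventional (root-tree) shared-parameter models
#' are fitted separately on the subjects with truly positive and truly
#' non-positive effects, and the posterior probability that the positive
#' subgroup's effect exceeds the other's is reported. When no subject has a
#' non-positive true effect, that subgroup's estimate is fixed at 0.
#'
#' @param data A simulated [trial_dataset()] with `truth` bookkeeping.
#' @param config A [sampler_config()].
#' @param n_warm,n_draws Warmup/retained iterations per subset fit.
#' @return Probability in `[0, 1]`.
#' @export
bep <- function(data, config = sampler_config(), n_warm = 500, n_draws = 500) {
  stopifnot(!is.null(data$truth))
  pos_ids <- data$truth$subject_id[data$truth$true_cate > 0]
  neg_ids <- data$truth$subject_id[data$truth$true_cate <= 0]

  subset_draws <- function(ids) {
    if (length(ids) < 10L) return(NULL)
    sub <- subset_trial(data, ids)
    fit <- prepare_fit(sub, config)
    state <- init_state(fit)
    state <- update_sp_params(fit, state, B1 = n_warm + n_draws, keep = n_draws)
    kept <- attr(state, "kept")
    tau_row <- ncol(fit$Xa) + ncol(fit$Xs) + 1L  # root trees: J0 = J1 = J2 = 1
    kept$theta[tau_row, ]
  }
  dpos <- subset_draws(pos_ids)
  dneg <- subset_draws(neg_ids)
  if (is.null(dpos)) stop("no subjects with positive true effect")
  if (is.null(dneg)) dneg <- 0
  ordering_probability(dpos, dneg)
}

#' Evaluate the honest pipeline on one replicate's validation sets
#'
#' Computes the validation-set metrics for a fitted [hte_pipeline()] result,
#' averaging over the pipeline's splits: the estimator is the (piecewise
#' constant) super-representative-tree surface with pooled honest leaf
#' estimates, evaluated against the generator's true effects.
#'
#' @param result An `hte_result`.
#' @param data The simulated [trial_dataset()] the pipeline was run on
#'   (supplies `truth`).
#' @return One-row data.frame with `l1`, `r1_propose`, `r1_naive`, `htr`,
#'   `J_super`, `frequency`.
#' @export
pipeline_metrics <- function(result, data) {
  stopifnot(inherits(result, "hte_result"), !is.null(data$truth))
  per_split <- lapply(result$splits, function(s) {
    v <- s$validation
    truth <- v$truth$true_cate[match(v$covariates$subject_id, v$truth$subject_id)]
    est <- predict(result, v$covariates[, result$split_vars, drop = FALSE])
    c(l1 = l1_error(est, truth),
      r1_propose = r1_regret(est, truth),
      r1_naive = r1_naive(truth),
      htr = htr_indicator(est, truth))
  })
  m <- colMeans(do.call(rbind, per_split))
  data.frame(l1 = m[["l1"]], r1_propose = m[["r1_propose"]],
             r1_naive = m[["r1_naive"]], htr = m[["htr"]],
             J_super = num_leaves(result$super_tree),
             frequency = result$frequency)
}

#' Monte-Carlo study over simulated trials
#'
#' Repeatedly simulates a scenario, runs the honest pipeline and aggregates
#' the validation metrics as mean (SD) over replicates, mirroring the layout
#' of the simulation-study tables.
#'
#' @param sc A [scenario_config()] (or scenario name for [scenario()]).
#' @param reps Number of Monte-Carlo replicates.
#' @param config A [sampler_config()]; per-replicate seeds are derived from
#'   `config$seed`.
#' @param B3 Splits per replicate.
#' @param refit Run honest refits (see [hte_pipeline()]).
#' @param compute_bep Also compute the oracle [bep()] per replicate.
#' @return List with `per_rep` (one row per replicate) and `summary`
#'   (mean and SD per metric); replicate failures are counted, not dropped
#'   silently.
#' @export
monte_carlo_study <- function(sc, reps = 10, config = sampler_config(),
                              B3 = 10, refit = TRUE, compute_bep = FALSE) {
  if (is.character(sc)) sc <- scenario(sc)
  set.seed(config$seed)
  data_seeds <- sample.int(.Machine$integer.max %/% 2L, reps)
  pipe_seeds <- sample.int(.Machine$integer.max %/% 2L, reps)
  rows <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      dat <- gen_trial(sc, seed = data_seeds[r])
      cfg <- config
      cfg$seed <- pipe_seeds[r]
      pipe <- hte_pipeline(dat, cfg, B3 = B3, refit = refit)
      row <- pipeline_metrics(pipe, dat)
      if (compute_bep) row$bep <- bep(dat, config)
      row$rep <- r
      row
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[r]] <- res
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), "rep")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_rep[[m]]), 0),
    sd = vapply(metrics, function(m) {
      if (nrow(per_rep) < 2L) NA_real_ else stats::sd(per_rep[[m]])
    }, 0)
  )
  if (reps == 1L) warning("single replicate: SDs reported as NA")
  rownames(summary) <- NULL
  list(per_rep = per_rep, summary = summary, failures = failures)
}
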