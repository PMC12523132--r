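#' Covariate specification for a trial dataset
#'
#' Describes the baseline covariate table: column names, which columns are
#' continuous (and therefore receive the heavy-tail-mitigating `log(1+x)`
#' transform and optional standardization), and which columns enter each
#' design: the baseline-level surface `alpha0`, the slope/effect surfaces
#' (`gamma0`, `tau0`) and the tree split set.
#'
#' @param names Character vector of covariate column names (excluding
#'   `subject_id` and `trt`).
#' @param continuous Character vector (subset of `names`) of continuous
#'   columns; these get `log1p` at read time.
#' @param split_vars Covariates eligible as tree split variables.
#' @param alpha_design,slope_design Covariates entering the within-leaf linear
#'   designs for the baseline surface and for the slope/effect surfaces. The
#'   intercept is always included implicitly.
#' @param standardize Standardize continuous design columns (post-transform)
#'   to mean 0 / SD 1 using discovery-sample moments. Default `TRUE`.
#' @param log1p_transform Apply `log(1+x)` to continuous columns at read time.
#'   Default `TRUE` (matches the heavy-tailed lab measurements these trials
#'   collect); the simulator's uniform covariates use `FALSE`.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(names,
                           continuous = character(),
                           split_vars = names,
                           alpha_design = names,
                           slope_design = names,
                           standardize = TRUE,
                           log1p_transform = TRUE) {
  stopifnot(is.character(names), !anyDuplicated(names))
  for (role in list(continuous, split_vars, alpha_design, slope_design)) {
    if (!all(role %in% names)) stop("covariate roles must reference existing names")
  }
  structure(
    list(names = names, continuous = continuous, split_vars = split_vars,
         alpha_design = alpha_design, slope_design = slope_design,
         standardize = standardize, log1p_transform = log1p_transform),
    class = "covariate_spec"
  )
}

#' Heavy-tail-mitigating log transform
#'
#' Natural log of `1 + x`, applied to continuous baseline covariates such as
#' UACR and triglycerides whose distributions are strongly right-skewed.
#'
#' @param x Numeric values greater than -1.
#' @return `log(1 + x)`.
#' @export
apply_log1p <- function(x) {
  if (any(x <= -1, na.rm = TRUE)) stop("log(1+x) requires x > -1")
  log1p(x)
}

#' Assemble and validate a trial dataset
#'
#' Bundles the three aligned tables of a CKD trial: long-format eGFR records,
#' one-row-per-subject event/censoring times and the baseline covariate table.
#' Validation enforces: identical subject sets across tables; a baseline
#' (`yrs = 0`) record for every subject; records sorted by time within
#' subject; no eGFR record after the subject's event/censoring time; binary
#' `trt` and `event`.
#'
#' @param records `data.frame` with columns `subject_id`, `yrs`, `egfr`.
#' @param survival `data.frame` with columns `subject_id`, `time`, `event`.
#' @param covariates `data.frame` with `subject_id`, one column per covariate
#'   in `spec$names`, and `trt`.
#' @param spec A [covariate_spec()]. Transforms are assumed already applied.
#' @param truth Optional `data.frame` of generator bookkeeping (true CATEs).
#' @return An object of class `trial_dataset` with elements `records`,
#'   `survival`, `covariates`, `spec`, `n` and optionally `truth`.
#' @export
trial_dataset <- function(records, survival, covariates, spec, truth = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(survival),
            is.data.frame(covariates), inherits(spec, "covariate_spec"))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
    }
  }
  need(records, c("subject_id", "yrs", "egfr"), "longitudinal")
  need(survival, c("subject_id", "time", "event"), "survival")
  need(covariates, c("subject_id", spec$names, "trt"), "covariate")

  ids <- sort(unique(covariates$subject_id))
  if (anyDuplicated(covariates$subject_id)) stop("duplicated subject_id in covariates")
  if (!setequal(ids, unique(records$subject_id)) ||
      !setequal(ids, survival$subject_id)) {
    stop("the three tables must reference identical subject-id sets")
  }
  if (!all(covariates$trt %in% c(0, 1))) stop("'trt' must be binary 0/1")
  if (!all(survival$event %in% c(0, 1))) stop("'event' must be binary 0/1")
  if (any(survival$time <= 0)) stop("event/censoring times must be positive")
  if (any(records$yrs < 0) || any(!is.finite(records$egfr))) {
    stop("longitudinal records must have yrs >= 0 and finite egfr")
  }

  ord <- order(match(records$subject_id, ids), records$yrs)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  survival <- survival[match(ids, survival$subject_id), , drop = FALSE]
  rownames(survival) <- NULL
  covariates <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  rownames(covariates) <- NULL

  base_count <- tapply(records$yrs == 0, records$subject_id, any)
  if (!all(base_count[as.character(ids)])) {
    stop("every subject needs a baseline (yrs = 0) record")
  }
  tmax <- tapply(records$yrs, records$subject_id, max)[as.character(ids)]
  if (any(tmax > survival$time + 1e-12)) {
    stop("longitudinal records extend beyond the event/censoring time")
  }

  structure(
    list(records = records, survival = survival, covariates = covariates,
         spec = spec, n = length(ids), truth = truth),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> n = %d subjects, %d eGFR records, %d events (%.0f%%)\n",
    x$n, nrow(x$records), sum(x$survival$event),
    100 * mean(x$survival$event)))
  cat(sprintf("  covariates: %s\n", paste(x$spec$names, collapse = ", ")))
  invisible(x)
}

#' Read a trial dataset from three delimited text files
#'
#' Reads comma- (default) or tab-delimited files with header rows, applies the
#' covariate transforms declared in `spec`, drops subjects with any missing
#' covariate (counting them), drops eGFR records after the subject's
#' event/censoring time, and validates the result.
#'
#' @param longitudinal_path,survival_path,covariate_path File paths.
#' @param spec A [covariate_spec()].
#' @param sep Field separator, `","` or `"\t"`.
#' @return A validated [trial_dataset()]; the number of subjects dropped for
#'   missing covariates is in `attr(, "dropped")`.
#' @export
read_trial <- function(longitudinal_path, survival_path, covariate_path, spec,
                       sep = ",") {
  rd <- function(p) utils::read.table(p, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE)
  records <- rd(longitudinal_path)
  survival <- rd(survival_path)
  covariates <- rd(covariate_path)
  if (!all(c("subject_id", "yrs", "egfr") %in% names(records)))
    stop("longitudinal file: expected columns subject_id, yrs, egfr")
  if (!all(c("subject_id", "time", "event") %in% names(survival)))
    stop("survival file: expected columns subject_id, time, event")
  if (!all(c("subject_id", spec$names, "trt") %in% names(covariates)))
    stop("covariate file: expected subject_id, declared covariates, trt")

  if (spec$log1p_transform) {
    for (v in spec$continuous) covariates[[v]] <- apply_log1p(covariates[[v]])
  }
  complete <- stats::complete.cases(covariates[, c(spec$names, "trt")])
  dropped <- sum(!complete)
  keep_ids <- covariates$subject_id[complete]
  covariates <- covariates[complete, , drop = FALSE]
  records <- records[records$subject_id %in% keep_ids, , drop = FALSE]
  survival <- survival[survival$subject_id %in% keep_ids, , drop = FALSE]

  ## visits after the event/censoring time are excluded at read time
  tmap <- survival$time[match(records$subject_id, survival$subject_id)]
  records <- records[records$yrs <= tmap + 1e-12, , drop = FALSE]

  out <- trial_dataset(records, survival, covariates, spec)
  attr(out, "dropped") <- dropped
  out
}

#' Write a trial dataset to three delimited text files
#'
#' Inverse of [read_trial()] (with `log1p_transform = FALSE` on re-read, since
#' stored covariates are already transformed). Values are written at full
#' precision.
#'
#' @param data A [trial_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_trial <- function(data, dir, prefix = "trial") {
  stopifnot(inherits(data, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("longitudinal", "survival", "covariates"),
                                 ".csv"))
  wr <- function(df, p) utils::write.table(
    format(df, digits = 17, trim = TRUE, scientific = FALSE), p,
    sep = ",", row.names = FALSE, quote = FALSE)
  wr(data$records, paths[1L])
  wr(data$survival, paths[2L])
  wr(data$covariates, paths[3L])
  invisible(paths)
}

#' Subject-level discovery/validation split
#'
#' Partitions subjects (never individual records) into a discovery set used
#' for tree-structure search and a validation set reserved for honest effect
#' estimation. The split is stratified by treatment arm so small leaves keep
#' both arms represented.
#'
#' @param data A [trial_dataset()].
#' @param frac_discovery Proportion of subjects assigned to discovery
#'   (default 0.6).
#' @param seed Integer seed making the split reproducible.
#' @return List with `trial_dataset` elements `discovery` and `validation`.
#' @export
split_dataset <- function(data, frac_discovery = 0.6, seed = 1L) {
  stopifnot(inherits(data, "trial_dataset"),
            frac_discovery > 0, frac_discovery < 1)
  if (data$n < 2L) stop("need at least 2 subjects to split")
  ids <- data$covariates$subject_id
  trt <- data$covariates$trt
  n_disc <- floor(data$n * frac_discovery)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  disc_ids <- character(0)
  for (arm in c(0, 1)) {
    arm_ids <- ids[trt == arm]
    k <- round(length(arm_ids) * frac_discovery)
    disc_ids <- c(disc_ids, as.character(sample(arm_ids, k)))
  }
  ## adjust to exact floor(n * frac) by moving subjects between sets
  disc <- ids %in% disc_ids
  excess <- sum(disc) - n_disc
  if (excess > 0) disc[sample(which(disc), excess)] <- FALSE
  if (excess < 0) disc[sample(which(!disc), -excess)] <- TRUE

  list(discovery = subset_trial(data, ids[disc]),
       validation = subset_trial(data, ids[!disc]))
}

## Restrict a trial_dataset to a subject-id subset (keeps truth rows aligned).
subset_trial <- function(data, keep_ids) {
  truth <- data$truth
  if (!is.null(truth)) {
    truth <- truth[truth$subject_id %in% keep_ids, , drop = FALSE]
    rownames(truth) <- NULL
  }
  trial_dataset(
    records = data$records[data$records$subject_id %in% keep_ids, , drop = FALSE],
    survival = data$survival[data$survival$subject_id %in% keep_ids, , drop = FALSE],
    covariates = data$covariates[data$covariates$subject_id %in% keep_ids, , drop = FALSE],
    spec = data$spec, truth = truth
  )
}

## Design matrix (n x p, leading intercept column) for a given role.
design_matrix <- function(data, vars) {
  X <- as.matrix(data$covariates[, vars, drop = FALSE])
  storage.mode(X) <- "double"
  cbind(`(Intercept)` = 1, X)
}
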