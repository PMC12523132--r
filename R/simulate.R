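#' Effect-surface constructors for the trial simulator
#'
#' Three families cover the simulation catalog: `surface_step()` is a step
#' (ST) function of the first (continuous) and sixth (binary) covariates,
#' taking at most four distinct values; `surface_con()` is continuous (CON) in
#' the first covariate; `surface_const()` is constant (CST).
#'
#' @param base Value in the reference cell (`x1 <= threshold`, `x6 = 0`).
#' @param step_x1 Added when `x1 > threshold`.
#' @param step_x6 Added when `x6 = 1`.
#' @param slope_x1 Linear coefficient on `x1` for the continuous family.
#' @param threshold Step location on `x1` (default 0).
#' @param value Constant value.
#' @return A function mapping a covariate data.frame to a numeric vector,
#'   tagged with a `family` attribute.
#' @export
surface_step <- function(base, step_x1, step_x6 = 0, threshold = 0) {
  f <- function(x) base + step_x1 * (x$x1 > threshold) + step_x6 * x$x6
  structure(f, family = "ST")
}

#' @rdname surface_step
#' @export
surface_con <- function(base, slope_x1, step_x6 = 0) {
  f <- function(x) base + slope_x1 * x$x1 + step_x6 * x$x6
  structure(f, family = "CON")
}

#' @rdname surface_step
#' @export
surface_const <- function(value) {
  f <- function(x) rep(value, nrow(x))
  structure(f, family = "CST")
}

#' Simulation scenario configuration
#'
#' Fully specifies a synthetic CKD trial: sample size, effect surfaces for
#' the baseline level, slopes and treatment effects, the informative-censoring
#' switch (`eta`), variance components, the visit schedule and the dropout
#' hazard. Defaults emulate a 3-year trial with visits every 4 months,
#' residual SD around 3 eGFR units, slope random-effect SDs around 1.5
#' units/yr, and roughly 30% of control subjects reaching the composite event
#' by year 3.
#'
#' @param n Number of subjects.
#' @param tau0,alpha0,gamma0 Surfaces (functions from [surface_step()] and
#'   friends) for the total treatment effect, expected baseline eGFR and
#'   control chronic slope.
#' @param beta0,zeta0 Constant control acute slope and acute treatment effect
#'   (units/yr).
#' @param eta Length-2 vector `(eta1, eta2)`; `c(-0.5, -0.5)` makes subjects
#'   with lower baseline and faster decline drop out earlier.
#' @param lambda0 Treatment log hazard ratio for dropout.
#' @param sigma Residual SD in eGFR units.
#' @param re_sd Length-3 SDs of the subject random effects
#'   `(alpha_i, beta_i, gamma_i)`.
#' @param base_event_rate Constant baseline hazard (events/yr) for controls.
#' @param visit_schedule Visit times in years.
#' @param horizon Administrative censoring time in years.
#' @param t_star,T_star Change point and total-slope horizon in years.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n = 800,
                            tau0 = surface_const(0.1),
                            alpha0 = surface_const(40),
                            gamma0 = surface_const(-3),
                            beta0 = -2,
                            zeta0 = 0.5,
                            eta = c(0, 0),
                            lambda0 = 0,
                            sigma = 3,
                            re_sd = c(2, 1.5, 1.5),
                            base_event_rate = -log(0.7) / 3,
                            visit_schedule = seq(0, 3, by = 1 / 3),
                            horizon = 3,
                            t_star = 1 / 3,
                            T_star = 3) {
  stopifnot(n >= 1, length(eta) == 2L, length(re_sd) == 3L, sigma > 0,
            all(visit_schedule >= 0), visit_schedule[1L] == 0)
  sigma2 <- sigma^2
  Sigma <- diag((re_sd / sigma)^2)
  hz <- piecewise_hazard(
    knots = c(seq(0, horizon, length.out = 6L)[1:5], Inf),
    log_levels = rep(log(base_event_rate), 5L),
    lambda0 = lambda0, eta1 = eta[1L], eta2 = eta[2L]
  )
  structure(
    list(n = n, tau0 = tau0, alpha0 = alpha0, gamma0 = gamma0,
         beta0 = beta0, zeta0 = zeta0, eta = eta, hz = hz,
         sigma2 = sigma2, Sigma = Sigma,
         visit_schedule = sort(unique(visit_schedule)), horizon = horizon,
         weights = effect_weight(t_star, T_star)),
    class = "scenario_config"
  )
}

#' Named scenarios from the simulation catalog
#'
#' Presets mirroring the main-text constraints of the study settings:
#' step/continuous/constant surface families on `(x1, x6)`, between-subgroup
#' total-effect contrasts of 2 (strong), 0.4 (subtle) or 0 (null with
#' `tau0 = 0.1` everywhere), and informative censoring toggled via
#' `eta = -0.5`.
#'
#' * `setting1` — strong step heterogeneity (harmed subgroup, contrast 2),
#'   step baseline/chronic surfaces, no informative censoring.
#' * `setting3` — as `setting1` with informative censoring.
#' * `setting5` — continuous tau0 (model mis-specified), step nuisance
#'   surfaces, no informative censoring.
#' * `setting9` — subtle step heterogeneity (contrast 0.4, harmed subgroup),
#'   constant nuisance surfaces.
#' * `setting13` — null: constant `tau0 = 0.1`, constant surfaces, no
#'   informative censoring.
#' * `setting15` — as `setting13` with informative censoring.
#'
#' @param name Scenario name.
#' @param n Number of subjects.
#' @param ... Overrides passed on to [scenario_config()].
#' @return A [scenario_config()].
#' @export
scenario <- function(name, n = 800, ...) {
  strong_tau <- surface_step(base = -1, step_x1 = 2)
  step_alpha <- surface_step(base = 40, step_x1 = 5, step_x6 = -5)
  step_gamma <- surface_step(base = -3, step_x1 = -1, step_x6 = 0.5)
  args <- switch(
    name,
    setting1 = list(tau0 = strong_tau, alpha0 = step_alpha, gamma0 = step_gamma),
    setting3 = list(tau0 = strong_tau, alpha0 = step_alpha, gamma0 = step_gamma,
                    eta = c(-0.5, -0.5)),
    setting5 = list(tau0 = surface_con(base = 0, slope_x1 = 0.75),
                    alpha0 = step_alpha, gamma0 = step_gamma),
    setting9 = list(tau0 = surface_step(base = -0.1, step_x1 = 0.4)),
    setting13 = list(tau0 = surface_const(0.1)),
    setting15 = list(tau0 = surface_const(0.1), eta = c(-0.5, -0.5)),
    stop(sprintf("unknown scenario '%s'", name))
  )
  do.call(scenario_config, c(list(n = n), args, list(...)))
}

#' Draw the baseline covariate matrix
#'
#' Five continuous covariates from Unif(-2, 2) and one binary from
#' Bernoulli(0.5); only `x1` and `x6` ever drive heterogeneity, the rest are
#' nuisance predictors.
#'
#' @param n Number of subjects.
#' @return Data.frame with columns `x1..x6`.
#' @export
gen_covariates <- function(n) {
  out <- as.data.frame(matrix(stats::runif(5 * n, -2, 2), nrow = n))
  names(out) <- paste0("x", 1:5)
  out$x6 <- stats::rbinom(n, 1L, 0.5)
  out
}

#' Simulate one subject's records
#'
#' Draws the random effects, samples the dropout time from the frailty-scaled
#' piecewise-exponential model, truncates the visit schedule at
#' `min(event time, horizon)` and adds residual noise around the two-slope
#' mean.
#'
#' @param x One-row covariate data.frame.
#' @param trt Arm indicator.
#' @param sc A [scenario_config()].
#' @return List with `yrs`, `egfr`, `time`, `event`, `re`, `true_cate`.
#' @export
gen_subject <- function(x, trt, sc) {
  re <- drop(MASS::mvrnorm(1L, mu = rep(0, 3), Sigma = sc$sigma2 * sc$Sigma))
  z <- frailty(trt, re[1L], re[3L], sc$hz)
  t_event <- sample_event_time(1L, z, sc$hz)
  time <- min(t_event, sc$horizon)
  event <- as.numeric(t_event <= sc$horizon)
  yrs <- sc$visit_schedule[sc$visit_schedule <= time]
  mu <- mean_trajectory(yrs, trt,
                        alpha0 = sc$alpha0(x), beta0 = sc$beta0,
                        gamma0 = sc$gamma0(x), tau0 = sc$tau0(x),
                        zeta0 = sc$zeta0, re = re, weights = sc$weights)
  list(yrs = yrs, egfr = mu + stats::rnorm(length(yrs), 0, sqrt(sc$sigma2)),
       time = time, event = event, re = re, true_cate = sc$tau0(x))
}

#' Simulate a complete trial
#'
#' 1:1 Bernoulli randomization, subject-wise generation via [gen_subject()],
#' and per-subject bookkeeping of the true conditional average treatment
#' effect for later evaluation.
#'
#' @param sc A [scenario_config()].
#' @param seed Integer seed.
#' @return A [trial_dataset()] whose `truth` element holds `subject_id`,
#'   `true_cate` and `true_leaf` (grouping by distinct true effect values).
#' @export
gen_trial <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "scenario_config"))
  set.seed(seed)
  n <- sc$n
  ids <- sprintf("S%05d", seq_len(n))
  X <- gen_covariates(n)
  trt <- stats::rbinom(n, 1L, 0.5)

  rec_list <- vector("list", n)
  surv <- data.frame(subject_id = ids, time = NA_real_, event = NA_real_)
  true_cate <- numeric(n)
  for (i in seq_len(n)) {
    s <- gen_subject(X[i, , drop = FALSE], trt[i], sc)
    rec_list[[i]] <- data.frame(subject_id = ids[i], yrs = s$yrs, egfr = s$egfr)
    surv$time[i] <- s$time
    surv$event[i] <- s$event
    true_cate[i] <- s$true_cate
  }
  records <- do.call(rbind, rec_list)
  covs <- cbind(data.frame(subject_id = ids), X, data.frame(trt = trt))
  spec <- covariate_spec(names = paste0("x", 1:6),
                         continuous = paste0("x", 1:5),
                         standardize = FALSE, log1p_transform = FALSE)
  truth <- data.frame(subject_id = ids, true_cate = true_cate,
                      true_leaf = match(true_cate, sort(unique(true_cate))))
  trial_dataset(records, surv, covs, spec, truth = truth)
}

#' Synthetic MDRD-like fixture
#'
#' A synthetic dataset emulating the schema of a moderate-size CKD trial:
#' the standard covariate panel (eGFR, AGE, UACR, PHOS, ALB, BICARB, BMI,
#' CAL, DBP_sit, SBP_sit, LDL, HDL, TG plus Sex, Smoke and one-hot race
#' indicators), heavy-tailed UACR/TG, roughly monthly visits over 3 years,
#' composite dropout events, and a planted total-effect split on baseline
#' eGFR near 34 ml/min/1.73m2 (benefit 1.5 vs 0.2 eGFR units/yr, a contrast
#' chosen to be decisively detectable at the fixture's size so end-to-end
#' recovery tests exercise the pipeline rather than borderline posterior
#' mass). Covariates are stored already log(1+x)
#' transformed (the returned spec has `log1p_transform = FALSE`). This is a
#' synthetic stand-in for testing the full pipeline end to end; it is not
#' the restricted trial data.
#'
#' @param n Number of subjects (default 815).
#' @param seed Integer seed.
#' @param egfr_threshold Planted split location on the raw eGFR scale.
#' @return A [trial_dataset()] with `truth` bookkeeping.
#' @export
mdrd_like_fixture <- function(n = 815, seed = 1L, egfr_threshold = 34) {
  set.seed(seed)
  ids <- sprintf("M%05d", seq_len(n))
  egfr <- exp(stats::rnorm(n, log(33), 0.35))
  covs <- data.frame(
    subject_id = ids,
    eGFR = egfr,
    AGE = round(pmin(pmax(stats::rnorm(n, 52, 12), 18), 75)),
    UACR = exp(stats::rnorm(n, log(120), 1.1)),
    PHOS = stats::rnorm(n, 3.8, 0.7),
    ALB = stats::rnorm(n, 4.0, 0.35),
    BICARB = stats::rnorm(n, 23, 3),
    BMI = exp(stats::rnorm(n, log(26.5), 0.18)),
    CAL = stats::rnorm(n, 9.1, 0.5),
    DBP_sit = stats::rnorm(n, 81, 9),
    SBP_sit = stats::rnorm(n, 130, 16),
    LDL = stats::rnorm(n, 145, 40),
    HDL = exp(stats::rnorm(n, log(37), 0.3)),
    TG = exp(stats::rnorm(n, log(140), 0.55)),
    Sex = stats::rbinom(n, 1L, 0.39),
    Smoke = stats::rbinom(n, 1L, 0.2)
  )
  race <- sample(c("hisp", "black", "white", "other"), n, replace = TRUE,
                 prob = c(0.05, 0.08, 0.85, 0.02))
  covs$race_black <- as.numeric(race == "black")
  covs$race_white <- as.numeric(race == "white")
  covs$race_other <- as.numeric(race == "other")
  trt <- stats::rbinom(n, 1L, 0.5)

  weights <- effect_weight(1 / 3, 3)
  hz <- piecewise_hazard(knots = c(0, 0.6, 1.2, 1.8, 2.4, Inf),
                         log_levels = rep(log(0.12), 5L),
                         lambda0 = log(0.9), eta1 = -0.05, eta2 = -0.3)
  sigma2 <- 9
  Sigma <- diag(c((4 / 3)^2, 0.25, 0.25))
  visit <- seq(0, 3, by = 1 / 12)

  tau0 <- 0.2 + 1.3 * (egfr > egfr_threshold)
  alpha0 <- egfr
  gamma0 <- -4 + 0.03 * (egfr - 33)
  beta0 <- -2
  zeta0 <- 0.3

  rec_list <- vector("list", n)
  surv <- data.frame(subject_id = ids, time = NA_real_, event = NA_real_)
  for (i in seq_len(n)) {
    re <- drop(MASS::mvrnorm(1L, rep(0, 3), sigma2 * Sigma))
    z <- frailty(trt[i], re[1L], re[3L], hz)
    t_event <- sample_event_time(1L, z, hz)
    time <- min(t_event, 3)
    surv$time[i] <- time
    surv$event[i] <- as.numeric(t_event <= 3)
    yrs <- visit[visit <= time]
    mu <- mean_trajectory(yrs, trt[i], alpha0[i], beta0, gamma0[i],
                          tau0[i], zeta0, re = re, weights = weights)
    rec_list[[i]] <- data.frame(subject_id = ids[i], yrs = yrs,
                                egfr = mu + stats::rnorm(length(yrs), 0, sqrt(sigma2)))
  }
  cont <- c("eGFR", "AGE", "UACR", "PHOS", "ALB", "BICARB", "BMI", "CAL",
            "DBP_sit", "SBP_sit", "LDL", "HDL", "TG")
  for (v in cont) covs[[v]] <- apply_log1p(covs[[v]])
  spec <- covariate_spec(
    names = c(cont, "Sex", "Smoke", "race_black", "race_white", "race_other"),
    continuous = cont,
    split_vars = c("eGFR", "AGE", "UACR", "PHOS"),
    alpha_design = c("AGE", "UACR", "PHOS"),
    slope_design = c("eGFR", "AGE", "UACR", "PHOS"),
    standardize = TRUE, log1p_transform = FALSE
  )
  covs <- cbind(covs, data.frame(trt = trt))
  truth <- data.frame(subject_id = ids, true_cate = tau0,
                      true_leaf = 1L + (egfr > egfr_threshold),
                      planted_var = "eGFR",
                      planted_cut = apply_log1p(egfr_threshold))
  trial_dataset(do.call(rbind, rec_list), surv, covs, spec, truth = truth)
}
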