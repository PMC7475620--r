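#' Default SREM generating parameters
#'
#' Illustrative parameter set for simulation: fixed effects, covariate
#' hazard ratios and association loadings typical of registry HIV/CD4
#' analyses on the fourth-root scale (marker declining ~0.08 units/year,
#' strongly protective random intercept and slope). The random-effect
#' variances (0.466 intercept, 0.009 slope, correlation -0.2), residual
#' variance 0.25 and Weibull baseline (shape 1.2, scale calibrated so the
#' default cohort's event proportion is near 24%) complete the set.
#'
#' @return an `srem_params`.
#' @export
default_srem_params <- function() {
  srem_params(
    beta = c(intercept = 4.825, time = -0.079, sex = 0.263,
             addiction = -0.197, age = -0.010),
    re_cov = matrix(c(0.466, -0.2 * sqrt(0.466 * 0.009),
                      -0.2 * sqrt(0.466 * 0.009), 0.009), 2, 2),
    resid_var = 0.25,
    shape = 1.2, scale = 10,
    alpha = c(-1.243, -0.944, -0.045),
    assoc = c(-1.013, -6.410))
}

#' Default 3-class JLCM generating parameters
#'
#' Illustrative parameter set for simulation: a small high-risk class with a
#' steep marker decline, a moderate class, and a large low-risk class with a
#' nearly flat trajectory; membership depends on sex, addiction and age.
#' Random-effect and residual variances as in [default_srem_params()];
#' class log-hazard factors (2.8, 1.2, 0) and Weibull baseline (shape 1.2,
#' scale calibrated so the default cohort's event proportion is near 24%).
#'
#' @return a `jlcm_params`.
#' @export
default_jlcm_params <- function() {
  jlcm_params(
    n_classes = 3L,
    membership = matrix(c(1.211, -1.495, 0.819, -0.070,
                          4.563, -2.186, 0.300, -0.118),
                        nrow = 2, byrow = TRUE),
    traj_intercepts = c(4.370, 5.263, 5.107),
    traj_slopes = c(-0.388, -0.163, -0.016),
    traj_common = c(0.204, -0.176, -0.016),
    re_cov = matrix(c(0.466, -0.2 * sqrt(0.466 * 0.009),
                      -0.2 * sqrt(0.466 * 0.009), 0.009), 2, 2),
    resid_var = 0.25,
    shape = 1.2, scale = 180,
    alpha = c(-2.375, -0.341, 0.021),
    class_log_hazard = c(2.8, 1.2, 0))
}

#' Well-separated JLCM parameters for method checks
#'
#' A deliberately clean mixture (distant class trajectories, widely spaced
#' class hazards, modest noise) used to study parameter recovery, class
#' enumeration and classification accuracy under near-ideal conditions.
#'
#' @param G 2 or 3 classes.
#' @return a `jlcm_params`.
#' @export
separated_jlcm_params <- function(G = 3L) {
  G <- as.integer(G)
  if (G == 2L) {
    jlcm_params(
      n_classes = 2L,
      membership = matrix(c(-0.8, 0.4, -0.3, 0), nrow = 1),
      traj_intercepts = c(3.4, 5.6),
      traj_slopes = c(-0.45, -0.04),
      traj_common = c(0.2, -0.2, -0.01),
      re_cov = diag(c(0.25, 0.004)),
      resid_var = 0.16,
      shape = 1.2, scale = 60,
      alpha = c(-0.5, -0.3, 0.01),
      class_log_hazard = c(2.2, 0))
  } else if (G == 3L) {
    jlcm_params(
      n_classes = 3L,
      membership = matrix(c(-1.2, 0.3, -0.2, 0,
                            -0.2, -0.3, 0.2, 0), nrow = 2, byrow = TRUE),
      traj_intercepts = c(3.0, 4.6, 6.0),
      traj_slopes = c(-0.5, -0.22, -0.02),
      traj_common = c(0.2, -0.2, -0.01),
      re_cov = diag(c(0.25, 0.004)),
      resid_var = 0.16,
      shape = 1.2, scale = 110,
      alpha = c(-0.5, -0.3, 0.01),
      class_log_hazard = c(3.0, 1.4, 0))
  } else {
    stop("separated presets exist for G = 2 or 3")
  }
}

#' Simulation configuration for synthetic joint cohorts
#'
#' Defaults emulate a registry HIV cohort: 213 subjects, ~18% female,
#' age ~ N(38, 8^2) truncated above 18, roughly twice-yearly visits with
#' jitter, administrative follow-up horizon of 25 years plus independent
#' exponential censoring.
#'
#' @param n_subjects cohort size.
#' @param generator `"JLCM"` or `"SREM"`.
#' @param params true parameters (`jlcm_params` / `srem_params`); defaults
#'   to [default_jlcm_params()] or [default_srem_params()].
#' @param sex_prob P(sex = 1, female).
#' @param addiction_prob P(addiction = 1, no history of addiction).
#' @param age_mean,age_sd,age_min Gaussian age distribution truncated at
#'   `age_min`.
#' @param visit_interval,visit_jitter_sd visit schedule (years): visits at
#'   `j * visit_interval + N(0, visit_jitter_sd^2)`, j = 0, 1, ...
#' @param max_follow_up administrative censoring horizon (years).
#' @param censor_rate rate of the independent exponential censoring time.
#' @param guarantee_two_visits when a subject's follow-up ends before the
#'   second scheduled visit, insert a confirmatory visit at half the
#'   follow-up time. The generator then emulates the eligible cohort
#'   directly (every subject has >= 2 measurements), avoiding the
#'   short-survivor selection a post-hoc eligibility filter would induce.
#' @param seed integer seed used by the simulators.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 213L,
                              generator = c("JLCM", "SREM"),
                              params = NULL,
                              sex_prob = 0.183, addiction_prob = 0.35,
                              age_mean = 38, age_sd = 8, age_min = 18,
                              visit_interval = 0.5, visit_jitter_sd = 0.08,
                              max_follow_up = 25, censor_rate = 0.03,
                              guarantee_two_visits = TRUE, seed = 1L) {
  generator <- match.arg(generator)
  if (is.null(params)) {
    params <- if (generator == "JLCM") default_jlcm_params() else default_srem_params()
  }
  stopifnot(n_subjects >= 1L, sex_prob >= 0, sex_prob <= 1,
            addiction_prob >= 0, addiction_prob <= 1, max_follow_up > 0,
            visit_interval > 0, censor_rate >= 0)
  structure(list(n_subjects = as.integer(n_subjects), generator = generator,
                 params = params, sex_prob = sex_prob,
                 addiction_prob = addiction_prob, age_mean = age_mean,
                 age_sd = age_sd, age_min = age_min,
                 visit_interval = visit_interval,
                 visit_jitter_sd = visit_jitter_sd,
                 max_follow_up = max_follow_up, censor_rate = censor_rate,
                 guarantee_two_visits = guarantee_two_visits, seed = seed),
            class = "simulation_config")
}

#' Draw baseline covariates
#'
#' @param config a `simulation_config`.
#' @param seed overrides `config$seed` when given.
#' @return data.frame: `subject_id`, `sex`, `addiction`, `age`.
#' @export
simulate_covariates <- function(config, seed = NULL) {
  set.seed(seed %||% config$seed)
  n <- config$n_subjects
  age <- config$age_mean + config$age_sd * stats::rnorm(n)
  while (any(bad <- age <= config$age_min)) {
    age[bad] <- config$age_mean + config$age_sd * stats::rnorm(sum(bad))
  }
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             sex = stats::rbinom(n, 1L, config$sex_prob),
             addiction = stats::rbinom(n, 1L, config$addiction_prob),
             age = age)
}

#' Inverse-transform sampling of a Weibull PH event time
#'
#' Solves `S(T) = u` for the Weibull PH model with log-hazard offset
#' `offset`: `T = scale * (-log(u) / exp(offset))^(1/shape)`.
#'
#' @param offset log-hazard offset(s) (covariates, random effects, class
#'   factor - constant in time for both model families).
#' @param shape,scale Weibull baseline parameters.
#' @param u uniform draw(s) in (0, 1).
#' @return event time(s).
#' @export
simulate_event_time <- function(offset, shape, scale, u) {
  stopifnot(all(u > 0), all(u < 1))
  scale * (-log(u) / exp(offset))^(1 / shape)
}

# shared mechanics: given latent times and per-subject mean functions, build
# the observed dataset (visit schedule, censoring, marker noise)
assemble_cohort <- function(config, cov, latent_time, mean_fun, truth) {
  n <- config$n_subjects
  cens <- pmin(stats::rexp(n, max(config$censor_rate, 1e-12)),
               config$max_follow_up)
  obs_time <- pmin(latent_time, cens)
  event <- as.integer(latent_time <= cens)
  sd_eps <- sqrt(config$params$resid_var)
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    jmax <- floor(obs_time[i] / config$visit_interval)
    tij <- seq(0, by = config$visit_interval, length.out = jmax + 1L)
    if (config$visit_jitter_sd > 0 && length(tij) > 1L) {
      tij[-1L] <- tij[-1L] + stats::rnorm(jmax, 0, config$visit_jitter_sd)
    }
    if (length(tij) < 2L && isTRUE(config$guarantee_two_visits)) {
      tij <- c(0, obs_time[i] / 2)
    }
    tij <- sort(unique(pmin(pmax(tij, 0), obs_time[i])))
    y <- mean_fun(i, tij) + stats::rnorm(length(tij), 0, sd_eps)
    meas[[i]] <- data.frame(subject_id = cov$subject_id[i], time = tij,
                            marker = y)
  }
  measurements <- do.call(rbind, meas)
  subjects <- data.frame(subject_id = cov$subject_id,
                         event_time = obs_time, event = event,
                         sex = cov$sex, addiction = cov$addiction,
                         age = cov$age)
  dataset <- joint_dataset(subjects, measurements, transform = "fourth_root")
  truth$latent_time <- latent_time
  truth$censor_time <- cens
  structure(list(dataset = dataset, truth = truth),
            class = "simulated_cohort")
}

#' Simulate a cohort from a joint latent class model
#'
#' Classes are drawn from the membership model, random effects from
#' `N(0, B)`, event times by inverse-transform sampling from the class
#' hazard, and markers at jittered scheduled visits truncated at the
#' observed time.
#'
#' @param config a `simulation_config` with `generator = "JLCM"`.
#' @param seed overrides `config$seed`.
#' @return `simulated_cohort`: `dataset` (a `joint_dataset`) and `truth`
#'   (data.frame with `subject_id`, `class`, `b0`, `b1`, `latent_time`,
#'   `censor_time`).
#' @export
simulate_jlcm_cohort <- function(config, seed = NULL) {
  stopifnot(config$generator == "JLCM", inherits(config$params, "jlcm_params"))
  cov <- simulate_covariates(config, seed)
  p <- config$params
  n <- config$n_subjects
  pi_ <- class_membership_probs(p, cov)
  cl <- vapply(seq_len(n), function(i) {
    sample.int(p$n_classes, 1L, prob = pi_[i, ])
  }, integer(1L))
  L <- t(chol(p$re_cov))
  b <- t(L %*% matrix(stats::rnorm(2L * n), 2L, n))
  lp <- covariate_lp(p$alpha, cov$sex, cov$addiction, cov$age) +
    p$class_log_hazard[cl]
  latent <- simulate_event_time(lp, p$shape, p$scale, stats::runif(n))
  common <- covariate_lp(p$traj_common, cov$sex, cov$addiction, cov$age)
  mean_fun <- function(i, tij) {
    p$traj_intercepts[cl[i]] + common[i] + b[i, 1L] +
      (p$traj_slopes[cl[i]] + b[i, 2L]) * tij
  }
  truth <- data.frame(subject_id = cov$subject_id, class = cl,
                      b0 = b[, 1L], b1 = b[, 2L])
  assemble_cohort(config, cov, latent, mean_fun, truth)
}

#' Simulate a cohort from a shared random-effect model
#'
#' The same random intercept and slope drive the marker trajectory and the
#' hazard (log-hazard offset `assoc[1] b0 + assoc[2] b1`).
#'
#' @param config a `simulation_config` with `generator = "SREM"`.
#' @param seed overrides `config$seed`.
#' @return `simulated_cohort` with truth columns `b0`, `b1`.
#' @export
simulate_srem_cohort <- function(config, seed = NULL) {
  stopifnot(config$generator == "SREM", inherits(config$params, "srem_params"))
  cov <- simulate_covariates(config, seed)
  p <- config$params
  n <- config$n_subjects
  L <- t(chol(p$re_cov))
  b <- t(L %*% matrix(stats::rnorm(2L * n), 2L, n))
  lp <- covariate_lp(p$alpha, cov$sex, cov$addiction, cov$age) +
    p$assoc[1L] * b[, 1L] + p$assoc[2L] * b[, 2L]
  latent <- simulate_event_time(lp, p$shape, p$scale, stats::runif(n))
  mean_fun <- function(i, tij) {
    trajectory_mean(p, cov[i, ], b[i, ], tij)
  }
  truth <- data.frame(subject_id = cov$subject_id, b0 = b[, 1L], b1 = b[, 2L])
  assemble_cohort(config, cov, latent, mean_fun, truth)
}

#' Write a simulated cohort to CSV files
#'
#' The standard two-file input format plus `truth.csv`.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_simulated_cohort <- function(cohort, dir) {
  paths <- write_joint_data(cohort$dataset, dir)
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(cohort$truth, tp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, truth = tp))
}
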