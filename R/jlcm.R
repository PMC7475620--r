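#' Joint latent class model parameters
#'
#' The population is a finite mixture of `n_classes` latent classes. Class
#' membership follows a multinomial logistic model on baseline covariates
#' (last class = reference). Within class g the marker follows a linear
#' mixed model with class-specific intercept and slope, covariate effects
#' and random-effect covariance common to all classes; the hazard is Weibull
#' PH with a class-specific proportional factor `exp(xi_g)` (reference class
#' has xi = 0). Marker and event are conditionally independent given class.
#'
#' @param n_classes G >= 1.
#' @param membership (G-1) x 4 matrix, rows = non-reference classes, columns
#'   `(intercept, sex, addiction, age)`.
#' @param traj_intercepts,traj_slopes length-G class-specific trajectory
#'   intercepts and time slopes (transformed marker scale).
#' @param traj_common length-3 common covariate effects (sex, addiction,
#'   age) on the marker.
#' @param re_cov,resid_var random-effect covariance (2x2 pd) and residual
#'   variance, common across classes.
#' @param shape,scale,alpha Weibull baseline and covariate log hazard ratios
#'   (sex, addiction, age), common across classes.
#' @param class_log_hazard length-G log proportional hazard factors xi_g,
#'   last entry must be 0.
#' @return an object of class `jlcm_params`.
#' @export
jlcm_params <- function(n_classes, membership, traj_intercepts, traj_slopes,
                        traj_common, re_cov, resid_var, shape, scale, alpha,
                        class_log_hazard) {
  G <- as.integer(n_classes)
  stopifnot(G >= 1L)
  membership <- matrix(as.numeric(membership), nrow = G - 1L, ncol = 4L)
  stopifnot(length(traj_intercepts) == G, length(traj_slopes) == G,
            length(traj_common) == 3L, length(alpha) == 3L,
            length(class_log_hazard) == G, resid_var > 0, shape > 0,
            scale > 0)
  if (abs(class_log_hazard[G]) > 1e-12) {
    stop("class_log_hazard must be 0 for the reference (last) class")
  }
  re_cov <- (re_cov + t(re_cov)) / 2
  if (min(eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("re_cov must be positive definite")
  }
  structure(list(n_classes = G, membership = membership,
                 traj_intercepts = as.numeric(traj_intercepts),
                 traj_slopes = as.numeric(traj_slopes),
                 traj_common = as.numeric(traj_common), re_cov = re_cov,
                 resid_var = resid_var, shape = shape, scale = scale,
                 alpha = as.numeric(alpha),
                 class_log_hazard = as.numeric(class_log_hazard)),
            class = "jlcm_params")
}

jlcm_theta_names <- function(G) {
  nm <- character(0)
  if (G > 1L) {
    nm <- paste0(rep(paste0("memb", seq_len(G - 1L)), each = 4L), "_",
                 c("intercept", "sex", "addiction", "age"))
  }
  c(nm,
    paste0("traj_intercept", seq_len(G)), paste0("traj_slope", seq_len(G)),
    c("traj_sex", "traj_addiction", "traj_age"),
    c("re_lchol1", "re_lchol2", "re_lchol3"), "log_resid_var",
    c("alpha_sex", "alpha_addiction", "alpha_age"),
    c("log_shape", "log_scale"),
    if (G > 1L) paste0("xi", seq_len(G - 1L)))
}

jlcm_to_theta <- function(p) {
  G <- p$n_classes
  stats::setNames(
    c(if (G > 1L) as.vector(t(p$membership)),
      p$traj_intercepts, p$traj_slopes, p$traj_common,
      cov_to_logchol(p$re_cov), log(p$resid_var), p$alpha,
      log(p$shape), log(p$scale),
      if (G > 1L) p$class_log_hazard[seq_len(G - 1L)]),
    jlcm_theta_names(G))
}

theta_to_jlcm <- function(theta, G) {
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  membership <- if (G > 1L) {
    matrix(take(4L * (G - 1L)), nrow = G - 1L, ncol = 4L, byrow = TRUE)
  } else matrix(numeric(0), 0L, 4L)
  ti <- take(G); tsl <- take(G); tc <- take(3L)
  lch <- take(3L); lv <- take(1L); al <- take(3L)
  lsh <- take(1L); lsc <- take(1L)
  xi <- if (G > 1L) c(take(G - 1L), 0) else 0
  jlcm_params(G, membership, ti, tsl, tc, logchol_to_cov(lch), exp(lv),
              exp(lsh), exp(lsc), al, xi)
}

#' Prior class-membership probabilities
#'
#' Multinomial logistic model: `pi_g = softmax(eta_g)` with
#' `eta_g = e0g + e1g sex + e2g addiction + e3g age` for non-reference
#' classes and `eta_G = 0`.
#'
#' @param params a `jlcm_params`.
#' @param covariates list or data.frame with `sex`, `addiction`, `age`
#'   (vectors allowed).
#' @return matrix (subjects x G) of probabilities, rows summing to 1.
#' @export
class_membership_probs <- function(params, covariates) {
  G <- params$n_classes
  n <- length(covariates$sex)
  eta <- matrix(0, n, G)
  if (G > 1L) {
    for (g in seq_len(G - 1L)) {
      e <- params$membership[g, ]
      eta[, g] <- e[1L] + e[2L] * covariates$sex + e[3L] * covariates$addiction +
        e[4L] * covariates$age
    }
  }
  p <- exp(eta - apply(eta, 1L, max))
  p / rowSums(p)
}

# per-subject marginal Gaussian log-likelihood of the measurement vector in
# each class (random effects integrated in closed form); returns n x G
jlcm_lly <- function(params, ss) {
  B <- params$re_cov
  s2 <- params$resid_var
  detB <- B[1L, 1L] * B[2L, 2L] - B[1L, 2L]^2
  m11 <- s2 * B[2L, 2L] / detB + ss$ni
  m12 <- -s2 * B[1L, 2L] / detB + ss$St
  m22 <- s2 * B[1L, 1L] / detB + ss$Stt
  detM <- m11 * m22 - m12^2
  common <- covariate_lp(params$traj_common, ss$sex, ss$addiction, ss$age)
  G <- params$n_classes
  out <- matrix(0, ss$n, G)
  for (g in seq_len(G)) {
    d <- params$traj_intercepts[g] + common
    bt <- params$traj_slopes[g]
    Sr <- ss$Sy - ss$ni * d - bt * ss$St
    Srt <- ss$Syt - d * ss$St - bt * ss$Stt
    Srr <- ss$Syy - 2 * d * ss$Sy - 2 * bt * ss$Syt + ss$ni * d^2 +
      2 * d * bt * ss$St + bt^2 * ss$Stt
    qMq <- (m22 * Sr^2 - 2 * m12 * Sr * Srt + m11 * Srt^2) / detM
    out[, g] <- -0.5 * (ss$ni * log(2 * pi * s2) +
                          log(detB * detM / s2^2) + (Srr - qMq) / s2)
  }
  out
}

# per-subject survival log-likelihood in each class (n x G)
jlcm_llt <- function(params, ss) {
  lp <- covariate_lp(params$alpha, ss$sex, ss$addiction, ss$age)
  log_haz <- log(params$shape / params$scale) +
    (params$shape - 1) * log(ss$T / params$scale)
  cumhaz <- (ss$T / params$scale)^params$shape
  matrix(vapply(seq_len(params$n_classes), function(g) {
    xi <- params$class_log_hazard[g]
    ss$delta * (log_haz + lp + xi) - cumhaz * exp(lp + xi)
  }, numeric(ss$n)), nrow = ss$n)
}

#' Class-conditional longitudinal log-likelihood of one subject
#'
#' Log-density of the subject's measurement vector under class `g`:
#' multivariate normal with mean from the class-g fixed trajectory and
#' covariance `Z B Z' + sigma^2 I` (random effects integrated out in closed
#' form).
#'
#' @param params a `jlcm_params`.
#' @param measurements subject rows (`time`, `marker`).
#' @param covariates list/row with `sex`, `addiction`, `age`.
#' @param g class index.
#' @return scalar log-density.
#' @export
class_longitudinal_loglik <- function(params, measurements, covariates, g) {
  ss <- list(n = 1L, ni = nrow(measurements),
             St = sum(measurements$time), Stt = sum(measurements$time^2),
             Sy = sum(measurements$marker),
             Syt = sum(measurements$marker * measurements$time),
             Syy = sum(measurements$marker^2),
             sex = covariates$sex, addiction = covariates$addiction,
             age = covariates$age)
  jlcm_lly(params, ss)[1L, g]
}

#' Class-conditional survival log-likelihood of one subject
#'
#' [event_loglik()] under the class-g hazard (extra log factor `xi_g`).
#'
#' @inheritParams class_longitudinal_loglik
#' @param survival_record list/row with `event_time`, `event`.
#' @return scalar log-likelihood.
#' @export
class_survival_loglik <- function(params, survival_record, covariates, g) {
  haz <- weibull_ph(params$shape, params$scale, params$alpha,
                    extra_log_factor = params$class_log_hazard[g])
  event_loglik(haz, covariates, survival_record$event_time,
               survival_record$event)
}

#' Marginal log-likelihood of the JLCM
#'
#' `sum_i log sum_g pi_ig exp(ll_Y,ig + ll_T,ig)`, computed with log-sum-exp
#' stabilization; exact (the class-conditional terms are closed-form).
#'
#' @param params a `jlcm_params`.
#' @param dataset a `joint_dataset`.
#' @param per_subject return per-subject contributions.
#' @return scalar log-likelihood (or per-subject vector).
#' @export
jlcm_marginal_loglik <- function(params, dataset, per_subject = FALSE) {
  ss <- if (inherits(dataset, "joint_suffstats")) dataset else joint_suffstats(dataset)
  lpi <- log(class_membership_probs(params, ss))
  ll <- logsumexp_rows(lpi + jlcm_lly(params, ss) + jlcm_llt(params, ss))
  if (per_subject) ll else sum(ll)
}

# JLCM likelihood augmented with hazard loadings gamma on the within-class
# random effects (H0: gamma = 0). Used by the conditional-independence score
# test; reduces exactly to jlcm_marginal_loglik at gamma = 0.
jlcm_augmented_loglik <- function(params, gamma, dataset, nodes = 9L,
                                  per_subject = FALSE) {
  ss <- if (inherits(dataset, "joint_suffstats")) dataset else joint_suffstats(dataset)
  B <- params$re_cov
  s2 <- params$resid_var
  detB <- B[1L, 1L] * B[2L, 2L] - B[1L, 2L]^2
  m11 <- s2 * B[2L, 2L] / detB + ss$ni
  m12 <- -s2 * B[1L, 2L] / detB + ss$St
  m22 <- s2 * B[1L, 1L] / detB + ss$Stt
  detM <- m11 * m22 - m12^2
  s2_v <- s2 * (m22 * gamma[1L]^2 - 2 * m12 * gamma[1L] * gamma[2L] +
                  m11 * gamma[2L]^2) / detM
  common <- covariate_lp(params$traj_common, ss$sex, ss$addiction, ss$age)
  lp <- covariate_lp(params$alpha, ss$sex, ss$addiction, ss$age)
  log_haz <- log(params$shape / params$scale) +
    (params$shape - 1) * log(ss$T / params$scale)
  cumhaz <- (ss$T / params$scale)^params$shape
  lly <- jlcm_lly(params, ss)
  G <- params$n_classes
  lljoint <- matrix(0, ss$n, G)
  for (g in seq_len(G)) {
    d <- params$traj_intercepts[g] + common
    bt <- params$traj_slopes[g]
    Sr <- ss$Sy - ss$ni * d - bt * ss$St
    Srt <- ss$Syt - d * ss$St - bt * ss$Stt
    mu0 <- (m22 * Sr - m12 * Srt) / detM
    mu1 <- (-m12 * Sr + m11 * Srt) / detM
    m_v <- gamma[1L] * mu0 + gamma[2L] * mu1
    k <- cumhaz * exp(lp + params$class_log_hazard[g])
    li <- log_tilted_integral(m_v, pmax(s2_v, 0), ss$delta, k, nodes)
    lljoint[, g] <- lly[, g] +
      ss$delta * (log_haz + lp + params$class_log_hazard[g]) + li
  }
  lpi <- log(class_membership_probs(params, ss))
  ll <- logsumexp_rows(lpi + lljoint)
  if (per_subject) ll else sum(ll)
}

#' Posterior class-membership probabilities
#'
#' `P(c_i = g | data_i) ~ pi_ig L_Y,ig L_T,ig`, normalized per subject; each
#' subject is assigned to the class with the highest posterior probability.
#'
#' @inheritParams jlcm_marginal_loglik
#' @return data.frame: `subject_id`, `prob.1` ... `prob.G`,
#'   `assigned_class`.
#' @export
posterior_class_probs <- function(params, dataset) {
  ss <- joint_suffstats(dataset)
  lw <- log(class_membership_probs(params, ss)) + jlcm_lly(params, ss) +
    jlcm_llt(params, ss)
  pr <- exp(lw - logsumexp_rows(lw))
  pr <- pr / rowSums(pr)
  out <- data.frame(subject_id = dataset$subjects$subject_id)
  for (g in seq_len(params$n_classes)) out[[paste0("prob.", g)]] <- pr[, g]
  out$assigned_class <- max.col(pr, ties.method = "first")
  out
}

#' Classification sharpness of a fitted JLCM
#'
#' For each class: the share of subjects assigned to it and the mean of
#' their maximal posterior probabilities (values near 1 indicate clear-cut
#' discrimination).
#'
#' @param posteriors output of [posterior_class_probs()].
#' @return data.frame: `class`, `n_assigned`, `proportion_pct`,
#'   `mean_max_posterior` (NA, with a warning, for empty classes).
#' @export
classification_quality <- function(posteriors) {
  stopifnot(nrow(posteriors) > 0L)
  G <- sum(grepl("^prob\\.", names(posteriors)))
  pmax_ <- do.call(pmax, posteriors[paste0("prob.", seq_len(G))])
  out <- data.frame(class = seq_len(G),
                    n_assigned = 0L, proportion_pct = 0,
                    mean_max_posterior = NA_real_)
  for (g in seq_len(G)) {
    in_g <- posteriors$assigned_class == g
    out$n_assigned[g] <- sum(in_g)
    out$proportion_pct[g] <- 100 * mean(in_g)
    if (any(in_g)) out$mean_max_posterior[g] <- mean(pmax_[in_g])
  }
  if (any(out$n_assigned == 0L)) {
    warning("empty class(es): ",
            paste(out$class[out$n_assigned == 0L], collapse = ", "))
  }
  out
}

#' Free-parameter count of the default JLCM specification
#'
#' Per non-reference class: a 4-coefficient membership vector, a trajectory
#' intercept and slope, and one proportional log-hazard factor; common
#' across classes: 3 longitudinal covariate effects, the reference-class
#' trajectory intercept and slope, 3 free entries of the random-effect
#' covariance, the residual variance, 2 Weibull parameters and 3 survival
#' covariate effects. Totals 14 + 7(G - 1).
#'
#' @param G number of latent classes (>= 1).
#' @return integer parameter count.
#' @export
count_parameters <- function(G) {
  G <- as.integer(G)
  stopifnot(G >= 1L)
  membership <- 4L * (G - 1L)
  trajectory <- 2L * G + 3L   # class intercepts + slopes, common covariates
  random <- 3L + 1L           # covariance (log-Cholesky) + residual variance
  survival <- 2L + 3L + (G - 1L)  # Weibull, covariates, class factors
  membership + trajectory + random + survival
}

#' Bayesian information criterion
#'
#' `-2 loglik + n_params log(n_subjects)`; lower is better.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params free-parameter count.
#' @param n_subjects number of subjects.
#' @return scalar BIC.
#' @export
bic <- function(loglik, n_params, n_subjects) {
  stopifnot(n_subjects >= 1)
  -2 * loglik + n_params * log(n_subjects)
}

# two-stage JLCM initialization: per-subject OLS intercept/slope, k-means
# into G groups for the class-specific parameters, pooled fits for the rest
jlcm_init <- function(dataset, G) {
  base <- srem_init(dataset)
  m <- dataset$measurements
  s <- dataset$subjects
  idx <- match(m$subject_id, s$subject_id)
  resid <- m$marker - (base$beta[["sex"]] * s$sex[idx] +
                         base$beta[["addiction"]] * s$addiction[idx] +
                         base$beta[["age"]] * s$age[idx])
  f <- factor(m$subject_id, levels = s$subject_id)
  ni <- as.vector(table(f))
  St <- as.vector(rowsum(m$time, f))
  Stt <- as.vector(rowsum(m$time^2, f))
  Sy <- as.vector(rowsum(resid, f))
  Syt <- as.vector(rowsum(resid * m$time, f))
  det_ <- ni * Stt - St^2
  ok <- det_ > 1e-8
  b0 <- ifelse(ok, (Stt * Sy - St * Syt) / det_, Sy / pmax(ni, 1))
  b1 <- ifelse(ok, (ni * Syt - St * Sy) / det_, 0)
  if (G == 1L) {
    return(jlcm_params(1L, matrix(numeric(0), 0, 4),
                       base$beta[["intercept"]], base$beta[["time"]],
                       c(base$beta[["sex"]], base$beta[["addiction"]],
                         base$beta[["age"]]),
                       base$re_cov, base$resid_var, base$shape, base$scale,
                       base$alpha, 0))
  }
  # candidate partitions of the subjects; per-subject OLS summaries are
  # noisy (2-visit subjects dominate the slope noise), so several cheap
  # splits are scored under the actual likelihood and the best is kept
  qsplit <- function(x) {
    cut(rank(x, ties.method = "first"), breaks = G, labels = FALSE)
  }
  cands <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(760451L)
    list(
      stats::kmeans(cbind(scale(b0), scale(b1)), G, nstart = 25L)$cluster,
      stats::kmeans(scale(b0), G, nstart = 25L)$cluster,
      qsplit(b0), qsplit(b1))
  })
  best <- NULL
  best_ll <- -Inf
  for (cl in cands) {
    if (min(table(factor(cl, levels = seq_len(G)))) < 3L) next
    cand <- tryCatch(init_from_partition(dataset, G, cl, base, m, s, idx),
                     error = function(e) NULL)
    if (is.null(cand)) next
    ll <- tryCatch(jlcm_marginal_loglik(cand, dataset),
                   error = function(e) -Inf)
    if (ll > best_ll) {
      best <- cand
      best_ll <- ll
    }
  }
  if (is.null(best)) stop("could not construct a JLCM starting point")
  best
}

# class-specific starting values given a hard partition of the subjects
init_from_partition <- function(dataset, G, cl, base, m, s, idx) {
  ev <- as.vector(tapply(s$event, factor(cl, levels = seq_len(G)), mean))
  ev[is.na(ev)] <- 0
  ord <- order(ev, decreasing = TRUE)
  cl <- match(cl, ord)
  ev <- ev[ord]
  # cluster-specific intercepts/slopes: a single-population mixed fit badly
  # inflates the slope variance on mixture data (a poor optimizer basin)
  dfm <- data.frame(y = m$marker, time = m$time, sex = s$sex[idx],
                    addiction = s$addiction[idx], age = s$age[idx],
                    id = m$subject_id, cl = factor(cl[idx], levels = seq_len(G)))
  mix <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ 0 + cl + cl:time + sex + addiction + age +
                   (1 + time | id), data = dfm, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )), error = function(e) NULL)
  if (is.null(mix)) return(NULL)
  fe <- lme4::fixef(mix)
  ints <- unname(fe[paste0("cl", seq_len(G))])
  slps <- unname(fe[paste0("cl", seq_len(G), ":time")])
  common <- unname(fe[c("sex", "addiction", "age")])
  vc <- lme4::VarCorr(mix)
  B <- matrix(as.numeric(vc$id), 2L, 2L)
  if (min(eigen(B, only.values = TRUE)$values) < 1e-6) {
    B <- B + diag(c(1e-3, 1e-4))
  }
  s2 <- attr(vc, "sc")^2
  prop <- pmax(as.vector(table(factor(cl, levels = seq_len(G)))), 0.5) /
    length(cl)
  xi <- log((ev + 0.05) / (ev[G] + 0.05))
  xi <- pmin(pmax(xi - xi[G], -3), 3)
  memb <- cbind(log(prop[seq_len(G - 1L)] / prop[G]), 0, 0, 0)
  jlcm_params(G, memb, ints, slps, common, B, max(s2, 1e-4),
              base$shape, base$scale, base$alpha, xi)
}

# relabel classes in canonical order (descending xi, i.e. highest-risk
# first); the multinomial-logit membership is re-referenced to the new last
# class, leaving all probabilities and the likelihood unchanged
canonicalize_jlcm <- function(params) {
  G <- params$n_classes
  if (G == 1L) return(params)
  ord <- order(params$class_log_hazard, decreasing = TRUE)
  eta <- rbind(params$membership, 0)[ord, , drop = FALSE]
  memb <- sweep(eta[seq_len(G - 1L), , drop = FALSE], 2L, eta[G, ])
  xi <- params$class_log_hazard[ord]
  shift <- xi[G]
  # re-referencing xi multiplies every hazard by exp(-shift); the Weibull
  # scale absorbs it so the model is unchanged
  scale <- params$scale * exp(-shift / params$shape)
  jlcm_params(G, memb, params$traj_intercepts[ord], params$traj_slopes[ord],
              params$traj_common, params$re_cov, params$resid_var,
              params$shape, scale, params$alpha, xi - shift)
}

#' Fit the joint latent class model by maximum likelihood
#'
#' Maximizes [jlcm_marginal_loglik()] from multiple starting points: a
#' deterministic two-stage start (per-subject least-squares trajectories
#' clustered by k-means, pooled mixed-model and survival fits) plus
#' `n_starts - 1` seeded random perturbations of it. The best local optimum
#' is returned with classes in canonical order (descending class log-hazard,
#' i.e. highest-risk class first; the last class is the reference).
#'
#' @param dataset a `joint_dataset` (should pass [filter_eligible()]).
#' @param G number of latent classes.
#' @param n_starts number of starting points (default 10; 1 = deterministic
#'   start only).
#' @param seed integer seed for the start perturbations.
#' @param init optional `jlcm_params` used as the deterministic start.
#' @param method,se,control as in [fit_srem()]; `control$collapse_retries`
#'   (default 1) caps the extra restarts taken when a fitted class share
#'   drops below 1% (an empty class usually signals a collapsed local
#'   optimum).
#' @return an object of classes `jlcm_fit`/`joint_fit`; fields as in
#'   [fit_srem()] plus `G`, `start_logliks`.
#' @export
fit_jlcm <- function(dataset, G, n_starts = 10L, seed = 1L, init = NULL,
                     method = c("bfgs", "marquardt"), se = FALSE,
                     control = list()) {
  method <- match.arg(method)
  maxit <- control$maxit %||% 400L
  reltol <- control$reltol %||% 1e-9
  collapse_retries <- control$collapse_retries %||% 1L
  if (is.null(init)) init <- jlcm_init(dataset, G)
  ss <- joint_suffstats(dataset)
  class(ss) <- "joint_suffstats"
  nll <- function(theta) {
    v <- tryCatch(suppressWarnings(
      -jlcm_marginal_loglik(theta_to_jlcm(theta, G), ss)),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  theta0 <- jlcm_to_theta(init)
  p <- length(theta0)
  starts <- list(theta0)
  if (n_starts > 1L) {
    rng <- local({
      set.seed(seed)
      lapply(seq_len(n_starts - 1L), function(i) stats::rnorm(p))
    })
    # perturb class-specific coordinates more than shared ones
    class_specific <- grepl("^(memb|traj_intercept|traj_slope|xi)",
                            names(theta0))
    sc <- ifelse(class_specific, 0.5, 0.05)
    starts <- c(starts, lapply(rng, function(z) theta0 + sc * z))
  }
  best <- NULL
  start_lls <- numeric(0)
  iters <- 0L
  conv <- FALSE
  for (st in starts) {
    if (method == "bfgs") {
      opt <- tryCatch(
        stats::optim(st, nll, method = "BFGS",
                     control = list(maxit = maxit, reltol = reltol,
                                    ndeps = rep(1e-5, p))),
        error = function(e) NULL)
      if (is.null(opt)) next
      ok <- opt$convergence == 0L
      it <- opt$counts[["function"]]
    } else {
      opt <- marquardt_optim(st, nll, maxit = maxit)
      ok <- opt$convergence == 0L
      it <- opt$iterations
    }
    start_lls <- c(start_lls, -opt$value)
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- ok
      iters <- it
    }
  }
  if (is.null(best)) stop("all starts failed")
  # empty-class safeguard: a vanishing class share signals a collapsed
  # local optimum (the mixture has degenerated to fewer classes); retry
  # from fresh seeded perturbations of the deterministic start
  class_shares <- function(theta) {
    p <- theta_to_jlcm(theta, G)
    lw <- log(class_membership_probs(p, ss)) + jlcm_lly(p, ss) +
      jlcm_llt(p, ss)
    colMeans(exp(lw - logsumexp_rows(lw)))
  }
  if (G > 1L) {
    attempt <- 0L
    while (min(class_shares(best$par)) < 0.01 && attempt < collapse_retries) {
      attempt <- attempt + 1L
      z <- local({
        set.seed(seed + 7919L * attempt)
        stats::rnorm(p)
      })
      class_specific <- grepl("^(memb|traj_intercept|traj_slope|xi)",
                              names(theta0))
      st <- theta0 + ifelse(class_specific, 1, 0.05) * z
      opt <- tryCatch(
        stats::optim(st, nll, method = "BFGS",
                     control = list(maxit = maxit, reltol = reltol,
                                    ndeps = rep(1e-5, p))),
        error = function(e) NULL)
      if (!is.null(opt)) {
        start_lls <- c(start_lls, -opt$value)
        if (opt$value < best$value) {
          best <- opt
          conv <- opt$convergence == 0L
          iters <- opt$counts[["function"]]
        }
      }
    }
  }
  params <- canonicalize_jlcm(theta_to_jlcm(best$par, G))
  theta <- jlcm_to_theta(params)
  out <- list(params = params, theta = theta, G = G, loglik = -best$value,
              n_params = count_parameters(G), n_subjects = dataset$n,
              converged = conv, iterations = iters,
              start_logliks = start_lls, method = method,
              standard_errors = NULL, vcov = NULL)
  if (se) {
    H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      out$vcov <- V
      out$standard_errors <- stats::setNames(sqrt(diag(V)), names(theta))
    }
  }
  structure(out, class = c("jlcm_fit", "joint_fit"))
}

#' Score test of the conditional-independence assumption
#'
#' Tests H0: within latent classes, the random effects carry no residual
#' information about the hazard. The hazard is augmented with loadings
#' `gamma = (gamma0, gamma1)` of (b0, b1); the efficient score of gamma at
#' the fitted JLCM (gamma = 0) is normalized by its estimated variance, with
#' nuisance-parameter uncertainty projected out through the empirical
#' (outer-product) information. Per-subject scores are obtained by central
#' differencing of the gamma-augmented likelihood. Under H0 the statistic is
#' asymptotically chi-squared with df = 2 (the number of random effects).
#'
#' @param fit a converged `jlcm_fit`.
#' @param dataset the `joint_dataset` the model was fitted to.
#' @param nodes quadrature nodes for the augmented likelihood.
#' @param eps relative step for the numeric scores.
#' @return list of class `ci_score_test`: `statistic`, `df`, `p_value`.
#' @export
conditional_independence_score_test <- function(fit, dataset, nodes = 9L,
                                                eps = 1e-4) {
  stopifnot(inherits(fit, "jlcm_fit"))
  G <- fit$G
  ss <- joint_suffstats(dataset)
  class(ss) <- "joint_suffstats"
  theta <- fit$theta
  P <- length(theta)
  per_subj <- function(th, gamma) {
    jlcm_augmented_loglik(theta_to_jlcm(th, G), gamma, ss, nodes = nodes,
                          per_subject = TRUE)
  }
  U <- matrix(0, ss$n, P + 2L)
  for (j in seq_len(P)) {
    h <- eps * max(abs(theta[j]), 1)
    up <- dn <- theta
    up[j] <- theta[j] + h
    dn[j] <- theta[j] - h
    U[, j] <- (per_subj(up, c(0, 0)) - per_subj(dn, c(0, 0))) / (2 * h)
  }
  for (j in 1:2) {
    gu <- gd <- c(0, 0)
    gu[j] <- eps
    gd[j] <- -eps
    U[, P + j] <- (per_subj(theta, gu) - per_subj(theta, gd)) / (2 * eps)
  }
  info <- crossprod(U)
  Itt <- info[seq_len(P), seq_len(P)]
  Igt <- info[P + 1:2, seq_len(P)]
  Igg <- info[P + 1:2, P + 1:2]
  # pseudo-inverse: the projection only needs the range of the nuisance
  # information, and near-boundary fits can make it numerically singular
  proj <- Igt %*% MASS::ginv(Itt)
  # n/(n - P) degrees-of-freedom correction: the projection estimates P
  # directions from n subjects and otherwise deflates the residual
  # covariance of the efficient score
  V <- (Igg - proj %*% t(Igt)) * ss$n / max(ss$n - P, 2L)
  # efficient (projected) score: insensitive to residual gradient in the
  # nuisance directions at the numerical optimum
  Sg <- colSums(U[, P + 1:2, drop = FALSE]) -
    drop(proj %*% colSums(U[, seq_len(P), drop = FALSE]))
  stat <- tryCatch(drop(t(Sg) %*% solve(V, Sg)), error = function(e) {
    stop("singular efficient-score variance in score test")
  })
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = 2L,
                 p_value = score_test_pvalue(stat, 2L)),
            class = "ci_score_test")
}

#' P-value of a score statistic
#'
#' Upper-tail chi-squared probability; the reference distribution of the
#' conditional-independence score statistic has df = number of random
#' effects (2 for a random intercept and slope).
#'
#' @param statistic non-negative score statistic.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
score_test_pvalue <- function(statistic, df = 2L) {
  stopifnot(statistic >= 0)
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' @export
print.ci_score_test <- function(x, ...) {
  cat("conditional-independence score test: statistic =",
      format(x$statistic, digits = 4), ", df =", x$df,
      ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Choose the number of latent classes
#'
#' Among candidate fits, selects the lowest-BIC model whose
#' conditional-independence test is not rejected at `alpha`; if every
#' candidate is rejected, the overall lowest-BIC model is returned with a
#' warning. The decision trace records every candidate's log-likelihood,
#' parameter count, BIC and score-test result.
#'
#' @param candidates list of lists with elements `G`, `fit` (`jlcm_fit`) and
#'   optionally `score` (`ci_score_test`).
#' @param alpha rejection level for the conditional-independence test.
#' @return list: `G` (chosen), `trace` (data.frame), `ci_rejected_everywhere`.
#' @export
select_num_classes <- function(candidates, alpha = 0.05) {
  stopifnot(length(candidates) >= 1L)
  trace <- do.call(rbind, lapply(candidates, function(cand) {
    data.frame(G = cand$G, loglik = cand$fit$loglik,
               n_params = cand$fit$n_params,
               bic = bic(cand$fit$loglik, cand$fit$n_params,
                         cand$fit$n_subjects),
               score_stat = if (is.null(cand$score)) NA_real_ else cand$score$statistic,
               score_p = if (is.null(cand$score)) NA_real_ else cand$score$p_value)
  }))
  trace$ci_ok <- is.na(trace$score_p) | trace$score_p >= alpha
  eligible <- which(trace$ci_ok)
  all_rejected <- length(eligible) == 0L
  if (all_rejected) {
    warning("conditional independence rejected for every candidate; ",
            "returning the lowest-BIC model")
    eligible <- seq_len(nrow(trace))
  }
  chosen <- eligible[which.min(trace$bic[eligible])]
  list(G = trace$G[chosen], trace = trace,
       ci_rejected_everywhere = all_rejected)
}

#' Class-specific predicted survival curves
#'
#' S_g(t) for each latent class at a covariate profile, on a time grid;
#' every curve starts at 1 and is non-increasing, and classes with larger
#' log-hazard factors lie uniformly lower.
#'
#' @param params a `jlcm_params`.
#' @param covariates list/row with `sex`, `addiction`, `age`.
#' @param times non-negative time grid (years).
#' @return data.frame: `time`, `class`, `survival`.
#' @export
class_survival_curves <- function(params, covariates, times) {
  out <- do.call(rbind, lapply(seq_len(params$n_classes), function(g) {
    haz <- weibull_ph(params$shape, params$scale, params$alpha,
                      extra_log_factor = params$class_log_hazard[g])
    data.frame(time = times, class = g,
               survival = survival_prob(haz, covariates, times))
  }))
  rownames(out) <- NULL
  out
}
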