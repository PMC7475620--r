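#' Shared random-effect joint model parameters
#'
#' The longitudinal submodel is a linear mixed model on the transformed
#' marker scale,
#' `Y_i(t) = b0_i + beta_int + beta_sex sex + beta_add addiction + beta_age age
#'  + (beta_time + b1_i) t + eps`,
#' with `(b0, b1) ~ N(0, B)` and `eps ~ N(0, resid_var)`. The survival
#' submodel is Weibull PH with log-hazard offset `assoc[1]*b0 + assoc[2]*b1`,
#' linking the two processes through the random intercept and slope.
#'
#' @param beta named numeric: `intercept`, `time`, `sex`, `addiction`, `age`
#'   (fixed effects on the transformed marker scale).
#' @param re_cov 2x2 symmetric positive-definite covariance of (b0, b1).
#' @param resid_var residual variance sigma^2 > 0.
#' @param shape,scale Weibull baseline parameters (see [weibull_ph()]).
#' @param alpha length-3 log hazard ratios for (sex, addiction, age).
#' @param assoc length-2 association loadings (alpha4, alpha5) of (b0, b1)
#'   in the log hazard.
#' @return an object of class `srem_params`.
#' @export
srem_params <- function(beta, re_cov, resid_var, shape, scale, alpha,
                        assoc = c(0, 0)) {
  beta <- beta[c("intercept", "time", "sex", "addiction", "age")]
  stopifnot(!anyNA(beta), resid_var > 0, shape > 0, scale > 0,
            length(alpha) == 3L, length(assoc) == 2L)
  re_cov <- (re_cov + t(re_cov)) / 2
  if (min(eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("re_cov must be positive definite")
  }
  structure(list(beta = beta, re_cov = re_cov, resid_var = resid_var,
                 shape = shape, scale = scale, alpha = as.numeric(alpha),
                 assoc = as.numeric(assoc)),
            class = "srem_params")
}

srem_theta_names <- c("beta_intercept", "beta_time", "beta_sex",
                      "beta_addiction", "beta_age",
                      "re_lchol1", "re_lchol2", "re_lchol3", "log_resid_var",
                      "alpha_sex", "alpha_addiction", "alpha_age",
                      "log_shape", "log_scale", "assoc_b0", "assoc_b1")

srem_to_theta <- function(p) {
  stats::setNames(
    c(p$beta, cov_to_logchol(p$re_cov), log(p$resid_var), p$alpha,
      log(p$shape), log(p$scale), p$assoc),
    srem_theta_names)
}

theta_to_srem <- function(theta) {
  srem_params(
    beta = stats::setNames(theta[1:5],
                           c("intercept", "time", "sex", "addiction", "age")),
    re_cov = logchol_to_cov(theta[6:8]),
    resid_var = exp(theta[9L]),
    alpha = theta[10:12],
    shape = exp(theta[13L]),
    scale = exp(theta[14L]),
    assoc = theta[15:16])
}

#' Mean marker trajectory for given random effects
#'
#' @param params an `srem_params`.
#' @param covariates list/row with `sex`, `addiction`, `age`.
#' @param b length-2 random effects (b0, b1).
#' @param t time(s) in years.
#' @return `beta_int + beta_sex sex + beta_add addiction + beta_age age + b0 +
#'   (beta_time + b1) t`.
#' @export
trajectory_mean <- function(params, covariates, b, t) {
  params$beta[["intercept"]] + params$beta[["sex"]] * covariates$sex +
    params$beta[["addiction"]] * covariates$addiction +
    params$beta[["age"]] * covariates$age + b[1L] +
    (params$beta[["time"]] + b[2L]) * t
}

#' Joint log-likelihood of one subject conditional on its random effects
#'
#' Gaussian measurement log-densities plus the survival contribution with
#' log-hazard offset `assoc' b`. This is the integrand of the marginal
#' likelihood; it is exposed for oracles, empirical-Bayes localization and
#' Monte-Carlo checks.
#'
#' @inheritParams trajectory_mean
#' @param measurements data.frame with `time`, `marker` for the subject.
#' @param survival_record list/row with `event_time`, `event`.
#' @return scalar log-likelihood.
#' @export
subject_loglik_given_b <- function(params, measurements, survival_record,
                                   covariates, b) {
  mu <- trajectory_mean(params, covariates, b, measurements$time)
  ll_y <- sum(stats::dnorm(measurements$marker, mu,
                           sqrt(params$resid_var), log = TRUE))
  haz <- weibull_ph(params$shape, params$scale, params$alpha,
                    extra_log_factor = sum(params$assoc * b))
  ll_y + event_loglik(haz, covariates, survival_record$event_time,
                      survival_record$event)
}

# Per-subject sufficient statistics; everything downstream is vectorized on
# these columns, which is what keeps full-cohort likelihood evaluations at
# O(n) with small constants.
joint_suffstats <- function(dataset) {
  m <- dataset$measurements
  s <- dataset$subjects
  f <- factor(m$subject_id, levels = s$subject_id)
  agg <- function(x) as.vector(rowsum(x, f))
  list(n = dataset$n,
       ni = as.vector(table(f)),
       St = agg(m$time), Stt = agg(m$time^2),
       Sy = agg(m$marker), Syt = agg(m$marker * m$time),
       Syy = agg(m$marker^2),
       sex = s$sex, addiction = s$addiction, age = s$age,
       T = s$event_time, delta = s$event)
}

# Core SREM machinery, vectorized across subjects. Returns per-subject:
#  ll_y     marginal Gaussian log-likelihood of the measurement vector
#  m_v,s2_v mean/variance of v = assoc' b under the posterior b | Y
#  plus survival ingredients (k = Lambda0(T) e^{alpha'w}, lp, etc).
srem_parts <- function(params, ss) {
  B <- params$re_cov
  s2 <- params$resid_var
  detB <- B[1L, 1L] * B[2L, 2L] - B[1L, 2L]^2
  d <- params$beta[["intercept"]] + params$beta[["sex"]] * ss$sex +
    params$beta[["addiction"]] * ss$addiction + params$beta[["age"]] * ss$age
  bt <- params$beta[["time"]]
  Sr <- ss$Sy - ss$ni * d - bt * ss$St
  Srt <- ss$Syt - d * ss$St - bt * ss$Stt
  Srr <- ss$Syy - 2 * d * ss$Sy - 2 * bt * ss$Syt + ss$ni * d^2 +
    2 * d * bt * ss$St + bt^2 * ss$Stt
  # M = s2 * B^-1 + Z'Z  (2x2 per subject, componentwise)
  m11 <- s2 * B[2L, 2L] / detB + ss$ni
  m12 <- -s2 * B[1L, 2L] / detB + ss$St
  m22 <- s2 * B[1L, 1L] / detB + ss$Stt
  detM <- m11 * m22 - m12^2
  qMq <- (m22 * Sr^2 - 2 * m12 * Sr * Srt + m11 * Srt^2) / detM
  ll_y <- -0.5 * (ss$ni * log(2 * pi * s2) + log(detB * detM / s2^2) +
                    (Srr - qMq) / s2)
  # posterior of b | Y: mean mu = M^-1 q, cov = s2 * M^-1
  mu0 <- (m22 * Sr - m12 * Srt) / detM
  mu1 <- (-m12 * Sr + m11 * Srt) / detM
  a <- params$assoc
  m_v <- a[1L] * mu0 + a[2L] * mu1
  s2_v <- s2 * (m22 * a[1L]^2 - 2 * m12 * a[1L] * a[2L] + m11 * a[2L]^2) / detM
  lp <- covariate_lp(params$alpha, ss$sex, ss$addiction, ss$age)
  list(ll_y = ll_y, m_v = m_v, s2_v = pmax(s2_v, 0), lp = lp,
       mu0 = mu0, mu1 = mu1)
}

# log integral(phi(v; m, s2) * exp(delta*v - k*e^v) dv), vectorized, by
# mode-centered (adaptive) Gauss-Hermite quadrature; exact when s2 = 0.
log_tilted_integral <- function(m_v, s2_v, delta, k, nodes = 9L) {
  degen <- s2_v < 1e-12
  out <- numeric(length(m_v))
  out[degen] <- delta[degen] * m_v[degen] - k[degen] * exp(m_v[degen])
  if (any(!degen)) {
    m <- m_v[!degen]; s2 <- s2_v[!degen]
    dl <- delta[!degen]; kk <- k[!degen]
    # Newton for the mode of h(v) = log phi + delta v - k e^v (concave)
    v <- m
    for (i in 1:40) {
      ev <- kk * exp(v)
      g <- -(v - m) / s2 + dl - ev
      hss <- -1 / s2 - ev
      step <- g / hss
      v <- v - step
      if (max(abs(step)) < 1e-12) break
    }
    sig <- 1 / sqrt(1 / s2 + kk * exp(v))
    gh <- gh_rule(nodes)
    # nodes matrix: length(m) x Q
    vq <- outer(sig, sqrt(2) * gh$x) + v
    h <- -0.5 * log(2 * pi * s2) - (vq - m)^2 / (2 * s2) + dl * vq -
      kk * exp(vq)
    lw <- matrix(log(gh$w) + gh$x^2, nrow(vq), length(gh$x), byrow = TRUE)
    out[!degen] <- log(sqrt(2) * sig) + logsumexp_rows(lw + h)
  }
  out
}

#' Marginal log-likelihood of the SREM
#'
#' Integrates the random effects out of [subject_loglik_given_b()]. The
#' Gaussian measurement part integrates in closed form; the remaining
#' integral over the association scalar `v = assoc' b` is computed by
#' adaptive (mode-centered) Gauss-Hermite quadrature, deterministic for a
#' fixed node count.
#'
#' @param params an `srem_params`.
#' @param dataset a `joint_dataset`.
#' @param nodes Gauss-Hermite node count (default 9).
#' @param per_subject return the vector of per-subject contributions instead
#'   of their sum.
#' @return scalar log-likelihood (or per-subject vector).
#' @export
srem_marginal_loglik <- function(params, dataset, nodes = 9L,
                                 per_subject = FALSE) {
  ss <- if (inherits(dataset, "joint_suffstats")) dataset else joint_suffstats(dataset)
  parts <- srem_parts(params, ss)
  k <- (ss$T / params$scale)^params$shape * exp(parts$lp)
  log_haz <- log(params$shape / params$scale) +
    (params$shape - 1) * log(ss$T / params$scale)
  li <- log_tilted_integral(parts$m_v, parts$s2_v, ss$delta, k, nodes)
  ll <- parts$ll_y + ss$delta * (log_haz + parts$lp) + li
  if (per_subject) ll else sum(ll)
}

# two-stage initialization: mixed model for the longitudinal part (lme4),
# covariates-only Weibull PH for the survival part, assoc = 0
srem_init <- function(dataset) {
  m <- dataset$measurements
  s <- dataset$subjects
  idx <- match(m$subject_id, s$subject_id)
  df <- data.frame(y = m$marker, time = m$time, sex = s$sex[idx],
                   addiction = s$addiction[idx], age = s$age[idx],
                   id = m$subject_id)
  lmm <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ sex + addiction + age + time + (1 + time | id),
                 data = df, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (!is.null(lmm)) {
    fe <- lme4::fixef(lmm)
    beta <- c(intercept = unname(fe[["(Intercept)"]]),
              time = unname(fe[["time"]]), sex = unname(fe[["sex"]]),
              addiction = unname(fe[["addiction"]]), age = unname(fe[["age"]]))
    vc <- lme4::VarCorr(lmm)
    B <- matrix(as.numeric(vc$id), 2L, 2L)
    if (min(eigen(B, only.values = TRUE)$values) < 1e-6) {
      B <- B + diag(c(1e-3, 1e-4))
    }
    s2 <- attr(vc, "sc")^2
  } else {
    fit <- stats::lm(y ~ sex + addiction + age + time, data = df)
    co <- stats::coef(fit)
    beta <- c(intercept = unname(co[["(Intercept)"]]),
              time = unname(co[["time"]]), sex = unname(co[["sex"]]),
              addiction = unname(co[["addiction"]]), age = unname(co[["age"]]))
    B <- diag(c(0.5, 0.01))
    s2 <- stats::var(stats::residuals(fit)) / 2
  }
  sv <- tryCatch({
    sr <- survival::survreg(
      survival::Surv(event_time, event) ~ sex + addiction + age,
      data = s, dist = "weibull")
    shape <- 1 / sr$scale
    list(shape = shape, scale = exp(stats::coef(sr)[["(Intercept)"]]),
         alpha = -shape * stats::coef(sr)[c("sex", "addiction", "age")])
  }, error = function(e) {
    list(shape = 1, scale = stats::median(s$event_time) * 2, alpha = c(0, 0, 0))
  })
  srem_params(beta = beta, re_cov = B, resid_var = max(s2, 1e-4),
              shape = sv$shape, scale = sv$scale, alpha = sv$alpha,
              assoc = c(0, 0))
}

#' Fit the shared random-effect joint model by maximum likelihood
#'
#' Maximizes [srem_marginal_loglik()] over all 16 parameters. The covariance
#' of the random effects is parameterized by its log-Cholesky factor and the
#' variance/Weibull parameters by their logs, so every iterate is valid.
#'
#' @param dataset a `joint_dataset` (should pass [filter_eligible()]).
#' @param init optional `srem_params` starting point; by default a two-stage
#'   fit (mixed model + covariates-only Weibull PH, association zero).
#' @param nodes Gauss-Hermite node count for the likelihood.
#' @param method `"bfgs"` (default, quasi-Newton) or `"marquardt"`
#'   (Levenberg-Marquardt-damped Newton with numerically differenced
#'   derivatives).
#' @param se compute standard errors from the observed information
#'   (numerically differenced Hessian at the optimum).
#' @param control list: `maxit` (default 400), `reltol` (1e-9).
#' @return an object of classes `srem_fit`/`joint_fit`: `params`, `theta`,
#'   `loglik`, `n_params`, `n_subjects`, `converged`, `iterations`,
#'   `standard_errors`, `vcov`.
#' @export
fit_srem <- function(dataset, init = NULL, nodes = 9L,
                     method = c("bfgs", "marquardt"), se = TRUE,
                     control = list()) {
  method <- match.arg(method)
  maxit <- control$maxit %||% 400L
  reltol <- control$reltol %||% 1e-9
  if (is.null(init)) init <- srem_init(dataset)
  ss <- joint_suffstats(dataset)
  class(ss) <- "joint_suffstats"
  nll <- function(theta) {
    v <- tryCatch(suppressWarnings(
      -srem_marginal_loglik(theta_to_srem(theta), ss, nodes)),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  theta0 <- srem_to_theta(init)
  if (method == "bfgs") {
    opt <- stats::optim(theta0, nll, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol,
                                       ndeps = rep(1e-5, length(theta0))))
    conv <- opt$convergence == 0L
    iters <- opt$counts[["function"]]
  } else {
    opt <- marquardt_optim(theta0, nll, maxit = maxit)
    conv <- opt$convergence == 0L
    iters <- opt$iterations
  }
  theta <- stats::setNames(opt$par, srem_theta_names)
  out <- list(params = theta_to_srem(theta), theta = theta,
              loglik = -opt$value, n_params = length(theta),
              n_subjects = dataset$n, converged = conv, iterations = iters,
              nodes = nodes, method = method,
              standard_errors = NULL, vcov = NULL)
  if (se) {
    H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      out$vcov <- V
      out$standard_errors <- stats::setNames(sqrt(diag(V)), srem_theta_names)
    }
  }
  structure(out, class = c("srem_fit", "joint_fit"))
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(class(x)[1L], ": logLik ", format(x$loglik, digits = 8),
      ", P = ", x$n_params, ", n = ", x$n_subjects,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes posterior of a subject's random effects
#'
#' Posterior mode and curvature of (b0, b1) given the subject's measurements
#' up to a landmark and, optionally, survival to that landmark. Newton
#' iterations on the (concave) log-posterior.
#'
#' @param params an `srem_params`.
#' @param measurements subject measurement rows (`time`, `marker`); rows with
#'   `time > s` are dropped when `s` is given.
#' @param covariates list/row with `sex`, `addiction`, `age`.
#' @param s landmark time (years); required when
#'   `condition_on_survival = TRUE`.
#' @param condition_on_survival include the probability of being event-free
#'   at `s` in the posterior.
#' @return list: `mode` (length 2), `curvature` (2x2 negative Hessian at the
#'   mode, positive definite), `iterations`.
#' @export
empirical_bayes <- function(params, measurements, covariates, s = NULL,
                            condition_on_survival = FALSE) {
  if (!is.null(s)) {
    measurements <- measurements[measurements$time <= s, , drop = FALSE]
  }
  if (condition_on_survival && is.null(s)) {
    stop("condition_on_survival requires a landmark time s")
  }
  Binv <- solve(params$re_cov)
  s2 <- params$resid_var
  a <- params$assoc
  if (nrow(measurements)) {
    Z <- cbind(1, measurements$time)
    r0 <- measurements$marker -
      trajectory_mean(params, covariates, c(0, 0), measurements$time)
    ZtZ <- crossprod(Z)
    Ztr <- crossprod(Z, r0)
  } else {
    ZtZ <- matrix(0, 2, 2)
    Ztr <- matrix(0, 2, 1)
  }
  k_s <- if (condition_on_survival) {
    (s / params$scale)^params$shape *
      exp(covariate_lp(params$alpha, covariates$sex, covariates$addiction,
                       covariates$age))
  } else 0
  b <- c(0, 0)
  it <- 0L
  for (it in 1:100) {
    ek <- k_s * exp(sum(a * b))
    g <- -Binv %*% b + (Ztr - ZtZ %*% b) / s2 - ek * a
    H <- -Binv - ZtZ / s2 - ek * tcrossprod(a)
    step <- solve(H, g)
    b <- b - as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  ek <- k_s * exp(sum(a * b))
  curv <- Binv + ZtZ / s2 + ek * tcrossprod(a)
  list(mode = as.vector(b), curvature = curv, iterations = it)
}
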