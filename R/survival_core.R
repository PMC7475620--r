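#' Weibull proportional-hazards model
#'
#' Baseline hazard lambda0(t) = (shape/scale) * (t/scale)^(shape-1), so the
#' baseline cumulative hazard is (t/scale)^shape. Covariates (sex, addiction,
#' age) act multiplicatively on the hazard through `coefficients`;
#' `extra_log_factor` is an additive log-hazard offset that houses the
#' shared-random-effect term of the SREM (a4*b0 + a5*b1) or the latent-class
#' factor of the JLCM (xi_g).
#'
#' @param shape Weibull shape rho > 0 (dimensionless).
#' @param scale Weibull scale sigma_w > 0 (years).
#' @param coefficients length-3 numeric, log hazard ratios for
#'   (sex, addiction, age).
#' @param extra_log_factor additive log-hazard offset (default 0).
#' @return an object of class `weibull_ph`.
#' @export
weibull_ph <- function(shape, scale, coefficients = c(0, 0, 0),
                       extra_log_factor = 0) {
  stopifnot(shape > 0, scale > 0, length(coefficients) == 3L)
  structure(list(shape = shape, scale = scale,
                 coefficients = as.numeric(coefficients),
                 extra_log_factor = extra_log_factor),
            class = "weibull_ph")
}

#' Baseline cumulative hazard of a Weibull PH model
#' @param model a `weibull_ph`.
#' @param t time(s) in years, >= 0.
#' @return Lambda0(t) = (t/scale)^shape.
#' @export
baseline_cumhaz <- function(model, t) {
  if (any(t < 0)) stop("t must be >= 0")
  (t / model$scale)^model$shape
}

#' Baseline hazard of a Weibull PH model
#' @inheritParams baseline_cumhaz
#' @return lambda0(t) = (shape/scale) * (t/scale)^(shape-1).
#' @export
baseline_hazard <- function(model, t) {
  if (any(t < 0)) stop("t must be >= 0")
  (model$shape / model$scale) * (t / model$scale)^(model$shape - 1)
}

# linear predictor for subject covariate rows; sex/addiction/age may be vectors
weibull_lp <- function(model, sex, addiction, age) {
  covariate_lp(model$coefficients, sex, addiction, age) + model$extra_log_factor
}

#' Survival probability under a Weibull PH model
#'
#' S(t) = exp(-Lambda0(t) * exp(lp)) with lp = coef'(sex, addiction, age) +
#' extra_log_factor.
#'
#' @inheritParams baseline_cumhaz
#' @param covariates list or data.frame row with `sex`, `addiction`, `age`
#'   (vectors allowed; recycled against `t`).
#' @return survival probabilities in (0, 1]; S(0) = 1.
#' @export
survival_prob <- function(model, covariates, t) {
  lp <- weibull_lp(model, covariates$sex, covariates$addiction, covariates$age)
  exp(-baseline_cumhaz(model, t) * exp(lp))
}

#' Log-likelihood contribution of one (or many) survival records
#'
#' event * log lambda(T) - Lambda(T), the usual right-censored PH
#' contribution.
#'
#' @inheritParams survival_prob
#' @param event_time observed time(s), > 0.
#' @param event 0/1 indicator(s).
#' @return numeric vector of per-record log-likelihood contributions.
#' @export
event_loglik <- function(model, covariates, event_time, event) {
  if (any(event_time <= 0)) stop("event_time must be > 0")
  lp <- weibull_lp(model, covariates$sex, covariates$addiction, covariates$age)
  event * (log(baseline_hazard(model, event_time)) + lp) -
    baseline_cumhaz(model, event_time) * exp(lp)
}

#' Martingale residuals of a fitted Weibull PH model
#'
#' r_i = event_i - fitted cumulative hazard at the observed time; values are
#' bounded above by 1 and average to roughly zero under a well-specified
#' model.
#'
#' @param model a `weibull_ph` (extra_log_factor is taken per subject from
#'   `extra` when supplied).
#' @param subjects subject table with `subject_id`, `event_time`, `event`,
#'   `sex`, `addiction`, `age`.
#' @param extra optional per-subject additive log-hazard offsets.
#' @return data.frame `subject_id`, `residual`.
#' @export
martingale_residuals <- function(model, subjects, extra = NULL) {
  lp <- covariate_lp(model$coefficients, subjects$sex, subjects$addiction,
                     subjects$age) +
    (if (is.null(extra)) model$extra_log_factor else extra)
  cumhaz <- baseline_cumhaz(model, subjects$event_time) * exp(lp)
  data.frame(subject_id = subjects$subject_id,
             residual = subjects$event - cumhaz)
}

#' Maximum-likelihood fit of a covariates-only Weibull PH model
#'
#' Used on its own for survival-side diagnostics and as the survival-part
#' initializer of both joint models. Optimization is over (log shape,
#' log scale, coefficients) to keep the Weibull parameters positive.
#'
#' @param subjects subject table (see [martingale_residuals()]).
#' @return a list: `model` (`weibull_ph`), `loglik`, `converged`.
#' @export
fit_weibull_ph <- function(subjects) {
  nll <- function(p) {
    m <- weibull_ph(exp(p[1L]), exp(p[2L]), p[3:5])
    -sum(event_loglik(m, subjects, subjects$event_time, subjects$event))
  }
  init <- c(0, log(stats::median(subjects$event_time) * 2), 0, 0, 0)
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12,
                                     ndeps = rep(1e-6, 5L)))
  list(model = weibull_ph(exp(opt$par[1L]), exp(opt$par[2L]), opt$par[3:5]),
       loglik = -opt$value,
       converged = opt$convergence == 0L)
}
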