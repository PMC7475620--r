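#' Dynamic risk of the event in (s, s+t] under a fitted JLCM
#'
#' Closed-form posterior-weighted conditional risk:
#' `risk = sum_g w_g(s) (S_g(s) - S_g(s+t)) / S_g(s)` with
#' `w_g(s) ~ pi_g L_Y(history <= s | g) S_g(s)` normalized over classes.
#' Updates as measurements accrue: the class weights respond to the
#' subject's observed trajectory.
#'
#' @param params a `jlcm_params`.
#' @param measurements the subject's measurement rows; only rows with
#'   `time <= s` are used (a measurement at exactly `s` is included). May be
#'   empty, in which case the weights reduce to `pi_g S_g(s)`.
#' @param covariates list/row with `sex`, `addiction`, `age`.
#' @param s landmark time (years, >= 0); the subject is assumed event-free
#'   at `s`.
#' @param t prediction window (years, >= 0).
#' @return risk in [0, 1]; 0 when `t = 0`.
#' @export
jlcm_dynamic_risk <- function(params, measurements, covariates, s, t) {
  stopifnot(s >= 0, t >= 0)
  G <- params$n_classes
  hist <- measurements[measurements$time <= s, , drop = FALSE]
  lpi <- log(class_membership_probs(params, covariates))[1L, ]
  lly <- if (nrow(hist)) {
    vapply(seq_len(G), function(g) {
      class_longitudinal_loglik(params, hist, covariates, g)
    }, numeric(1L))
  } else rep(0, G)
  lp <- covariate_lp(params$alpha, covariates$sex, covariates$addiction,
                     covariates$age)
  cum_s <- (s / params$scale)^params$shape *
    exp(lp + params$class_log_hazard)
  cum_st <- ((s + t) / params$scale)^params$shape *
    exp(lp + params$class_log_hazard)
  if (any(-cum_s < log(.Machine$double.xmin))) {
    stop("survival to the landmark is numerically zero in some class")
  }
  lw <- lpi + lly - cum_s        # log(pi_g L_Y S_g(s))
  w <- exp(lw - logsumexp(lw))
  cond_risk <- 1 - exp(-(cum_st - cum_s))
  sum(w * cond_risk)
}

#' Dynamic risk of the event in (s, s+t] under a fitted SREM
#'
#' Risk under the posterior of the random effects given the marker history
#' up to `s` and survival to `s`:
#' `1 - E[S(s+t | b)] / E[S(s | b)]` with the expectation over the
#' measurement-conditional Gaussian posterior of `v = assoc' b`, computed by
#' adaptive Gauss-Hermite quadrature (`method = "quadrature"`, default) or
#' by plugging in the joint posterior mode (`method = "posterior_mode"`,
#' fast approximation).
#'
#' @inheritParams jlcm_dynamic_risk
#' @param params an `srem_params`.
#' @param method `"quadrature"` or `"posterior_mode"`.
#' @param nodes quadrature nodes.
#' @return risk in [0, 1]; 0 when `t = 0`.
#' @export
srem_dynamic_risk <- function(params, measurements, covariates, s, t,
                              method = c("quadrature", "posterior_mode"),
                              nodes = 15L) {
  stopifnot(s >= 0, t >= 0)
  method <- match.arg(method)
  if (t == 0) return(0)
  hist <- measurements[measurements$time <= s, , drop = FALSE]
  lp <- covariate_lp(params$alpha, covariates$sex, covariates$addiction,
                     covariates$age)
  k_s <- (s / params$scale)^params$shape * exp(lp)
  k_st <- ((s + t) / params$scale)^params$shape * exp(lp)
  if (method == "posterior_mode") {
    eb <- empirical_bayes(params, hist, covariates, s = s,
                          condition_on_survival = TRUE)
    v <- sum(params$assoc * eb$mode)
    return(1 - exp(-(k_st - k_s) * exp(v)))
  }
  # Gaussian posterior of v given the measurements alone, then survival-to-s
  # conditioning enters the tilted integrals analytically
  a <- params$assoc
  B <- params$re_cov
  s2 <- params$resid_var
  if (nrow(hist)) {
    Z <- cbind(1, hist$time)
    r0 <- hist$marker - trajectory_mean(params, covariates, c(0, 0), hist$time)
    M <- s2 * solve(B) + crossprod(Z)
    mu <- solve(M, crossprod(Z, r0))
    m_v <- sum(a * mu)
    s2_v <- s2 * drop(t(a) %*% solve(M, a))
  } else {
    m_v <- 0
    s2_v <- drop(t(a) %*% B %*% a)
  }
  zero <- rep(0, 1L)
  log_den <- log_tilted_integral(m_v, s2_v, zero, k_s, nodes)   # E[S(s|b)]
  log_num <- log_tilted_integral(m_v, s2_v, zero, k_st, nodes)  # E[S(s+t|b)]
  if (!is.finite(log_den) || log_den == -Inf) {
    stop("survival to the landmark is numerically zero")
  }
  max(0, min(1, 1 - exp(log_num - log_den)))
}

#' Dynamic predictions for every at-risk subject over a landmark grid
#'
#' One prediction per (subject alive at s) x landmark. Subjects whose event
#' or censoring time is `<= s` are excluded at that landmark (an event at
#' exactly `s` removes the subject); measurements at exactly `s` count as
#' history.
#'
#' @param fit an `srem_fit` or `jlcm_fit`.
#' @param dataset a `joint_dataset`.
#' @param landmarks landmark times s (default `seq(1, 8, by = 0.5)`).
#' @param window prediction window t in years (default 3).
#' @param ... passed to the per-subject risk function
#'   ([srem_dynamic_risk()] / [jlcm_dynamic_risk()]).
#' @return data.frame: `subject_id`, `model`, `landmark`, `window`, `risk`,
#'   `n_history`.
#' @export
batch_dynamic_predictions <- function(fit, dataset,
                                      landmarks = seq(1, 8, by = 0.5),
                                      window = 3, ...) {
  stopifnot(inherits(fit, "joint_fit"), window >= 0)
  tag <- if (inherits(fit, "srem_fit")) "SREM" else "JLCM"
  params <- fit$params
  s_tab <- dataset$subjects
  meas <- split_measurements(dataset)
  rows <- vector("list", length(landmarks) * dataset$n)
  k <- 0L
  for (s in landmarks) {
    at_risk <- which(s_tab$event_time > s)
    if (!length(at_risk)) {
      warning("empty risk set at landmark s = ", s, "; skipped")
      next
    }
    for (i in at_risk) {
      cov <- s_tab[i, ]
      hist <- meas[[i]][meas[[i]]$time <= s, , drop = FALSE]
      risk <- if (tag == "SREM") {
        srem_dynamic_risk(params, hist, cov, s, window, ...)
      } else {
        jlcm_dynamic_risk(params, hist, cov, s, window, ...)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(subject_id = s_tab$subject_id[i], model = tag,
                              landmark = s, window = window, risk = risk,
                              n_history = nrow(hist))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}
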