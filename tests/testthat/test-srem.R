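test_that("trajectory mean is the linear predictor of the mixed model", {
  p0 <- srem_params(beta = c(intercept = 0, time = 0, sex = 0,
                             addiction = 0, age = 0),
                    re_cov = diag(2), resid_var = 1, shape = 1, scale = 1,
                    alpha = c(0, 0, 0))
  cov0 <- list(sex = 0, addiction = 0, age = 0)
  expect_equal(trajectory_mean(p0, cov0, c(0, 0), c(0, 3, 10)), rep(0, 3))
  expect_equal(trajectory_mean(p0, cov0, c(1, 0), c(0, 5)), rep(1, 2))

  p <- default_srem_params()
  expect_equal(trajectory_mean(p, cov0, c(0, 0), 10),
               4.825 - 0.079 * 10)  # 4.035
})

test_that("conditional subject log-likelihood decomposes as claimed", {
  # zero residuals, unit variance, censored subject with ~zero cumulative
  # hazard: only the Gaussian normalizing constants remain
  p <- srem_params(beta = c(intercept = 4, time = 0, sex = 0, addiction = 0,
                            age = 0),
                   re_cov = diag(2), resid_var = 1, shape = 1, scale = 1e8,
                   alpha = c(0, 0, 0), assoc = c(1, 1))
  mm <- data.frame(time = c(0, 1, 2), marker = 4)
  sr <- list(event_time = 2, event = 0)
  cov0 <- list(sex = 0, addiction = 0, age = 0)
  expect_equal(subject_loglik_given_b(p, mm, sr, cov0, c(0, 0)),
               3 * log(1 / sqrt(2 * pi)), tolerance = 1e-6)

  # with assoc = 0 the survival term does not depend on b
  p0 <- p
  p0$assoc <- c(0, 0)
  p0$scale <- 5
  delta <- subject_loglik_given_b(p0, mm, sr, cov0, c(0.7, -0.1)) -
    subject_loglik_given_b(p0, mm, sr, cov0, c(0, 0))
  mu1 <- trajectory_mean(p0, cov0, c(0.7, -0.1), mm$time)
  mu0 <- trajectory_mean(p0, cov0, c(0, 0), mm$time)
  gauss_delta <- sum(stats::dnorm(mm$marker, mu1, 1, log = TRUE)) -
    sum(stats::dnorm(mm$marker, mu0, 1, log = TRUE))
  expect_equal(delta, gauss_delta, tolerance = 1e-12)

  # generic-density recomputation on a simulated subject
  coh <- small_srem_cohort(n = 5, seed = 21)
  ds <- coh$dataset
  p <- default_srem_params()
  sub <- ds$subjects[2, ]
  mm <- ds$measurements[ds$measurements$subject_id == sub$subject_id, ]
  b <- c(0.4, -0.05)
  mu <- trajectory_mean(p, sub, b, mm$time)
  oracle <- sum(stats::dnorm(mm$marker, mu, sqrt(p$resid_var), log = TRUE)) +
    sub$event * log(baseline_hazard(weibull_ph(p$shape, p$scale),
                                    sub$event_time) *
                      exp(sum(p$alpha * c(sub$sex, sub$addiction, sub$age)) +
                            sum(p$assoc * b))) -
    baseline_cumhaz(weibull_ph(p$shape, p$scale), sub$event_time) *
      exp(sum(p$alpha * c(sub$sex, sub$addiction, sub$age)) + sum(p$assoc * b))
  expect_equal(subject_loglik_given_b(p, mm, sub, sub, b), oracle,
               tolerance = 1e-10)
})

test_that("marginal likelihood factorizes when the association is zero", {
  ds <- filter_eligible(small_srem_cohort(n = 40, seed = 31)$dataset)
  p <- default_srem_params()
  p$assoc <- c(0, 0)
  # longitudinal part: direct MVN oracle per subject; survival part: PH fit
  ll_long <- 0
  for (i in seq_len(ds$n)) {
    sub <- ds$subjects[i, ]
    mm <- ds$measurements[ds$measurements$subject_id == sub$subject_id, ]
    ll_long <- ll_long +
      mvn_loglik_oracle(mm, trajectory_mean(p, sub, c(0, 0), mm$time),
                        p$re_cov, p$resid_var)
  }
  ll_surv <- sum(event_loglik(weibull_ph(p$shape, p$scale, p$alpha),
                              ds$subjects, ds$subjects$event_time,
                              ds$subjects$event))
  expect_equal(srem_marginal_loglik(p, ds), ll_long + ll_surv,
               tolerance = 1e-8)
})

test_that("marginal likelihood is invariant to row order and node-stable", {
  ds <- filter_eligible(small_srem_cohort(n = 25, seed = 17)$dataset)
  p <- default_srem_params()
  ll <- srem_marginal_loglik(p, ds)

  # permute subjects and measurement rows
  set.seed(4)
  perm <- sample(ds$n)
  ds2 <- joint_dataset(ds$subjects[perm, ],
                       ds$measurements[sample(nrow(ds$measurements)), ])
  expect_equal(srem_marginal_loglik(p, ds2), ll, tolerance = 1e-10)

  # node refinement stabilizes with shrinking increments
  l9 <- srem_marginal_loglik(p, ds, nodes = 9)
  l15 <- srem_marginal_loglik(p, ds, nodes = 15)
  l25 <- srem_marginal_loglik(p, ds, nodes = 25)
  expect_lte(abs(l25 - l15), abs(l15 - l9) + 1e-10)
  expect_lt(abs(l25 - l9), 1e-4 * abs(l9))
})

test_that("fitting recovers a simulated cohort and honors initialization", {
  cfg <- simulation_config(n_subjects = 150, generator = "SREM", seed = 41)
  ds <- filter_eligible(simulate_srem_cohort(cfg)$dataset)
  truth <- cfg$params
  fit <- quiet(fit_srem(ds, se = FALSE))
  expect_s3_class(fit, "srem_fit")
  expect_true(fit$converged)
  expect_identical(fit$n_params, 16L)
  # a maximum-likelihood fit cannot fall below the truth's likelihood
  expect_gte(fit$loglik, srem_marginal_loglik(truth, ds) - 1e-6)
  # association sign propagates (generated with strongly negative loadings)
  expect_lt(fit$params$assoc[1], 0)

  # initializing at the truth also converges at or above the truth
  fit2 <- quiet(fit_srem(ds, init = truth, se = FALSE,
                         control = list(maxit = 150)))
  expect_gte(fit2$loglik, srem_marginal_loglik(truth, ds) - 1e-6)

  # with the association pinned at zero the fit matches separate fits
  p0 <- fit$params
  p0$assoc <- c(0, 0)
  ll_fact <- srem_marginal_loglik(p0, ds)
  expect_lte(ll_fact, fit$loglik + 1e-8)
})

test_that("empirical-Bayes posterior matches its defining optimum", {
  p <- default_srem_params()
  cov0 <- list(sex = 0, addiction = 0, age = 38)

  # no information: prior mode
  eb0 <- empirical_bayes(p, data.frame(time = numeric(0),
                                       marker = numeric(0)), cov0)
  expect_equal(eb0$mode, c(0, 0))
  expect_error(empirical_bayes(p, data.frame(time = 0, marker = 5), cov0,
                               condition_on_survival = TRUE),
               "landmark")

  # nearly noiseless single measurement: fitted value approaches the datum
  pn <- p
  pn$resid_var <- 1e-8
  mm1 <- data.frame(time = 0, marker = 6)
  eb1 <- empirical_bayes(pn, mm1, cov0)
  fitted <- trajectory_mean(pn, cov0, eb1$mode, 0)
  expect_equal(fitted, 6, tolerance = 1e-4)

  # grid-search oracle on a simulated subject, with survival conditioning
  ds <- small_srem_cohort(n = 30, seed = 13)$dataset
  sub <- ds$subjects[ds$subjects$event_time > 4, ][1, ]
  mm <- ds$measurements[ds$measurements$subject_id == sub$subject_id, ]
  s <- 3
  eb <- empirical_bayes(p, mm, sub, s = s, condition_on_survival = TRUE)
  hist <- mm[mm$time <= s, ]
  lp <- sum(p$alpha * c(sub$sex, sub$addiction, sub$age))
  obj <- function(b0, b1) {
    mu <- trajectory_mean(p, sub, c(b0, b1), hist$time)
    sum(stats::dnorm(hist$marker, mu, sqrt(p$resid_var), log = TRUE)) -
      0.5 * t(c(b0, b1)) %*% solve(p$re_cov) %*% c(b0, b1) -
      (s / p$scale)^p$shape * exp(lp + sum(p$assoc * c(b0, b1)))
  }
  g0 <- seq(eb$mode[1] - 0.5, eb$mode[1] + 0.5, length.out = 41)
  g1 <- seq(eb$mode[2] - 0.1, eb$mode[2] + 0.1, length.out = 41)
  vals <- outer(g0, g1, Vectorize(obj))
  ij <- which(vals == max(vals), arr.ind = TRUE)
  expect_lt(abs(g0[ij[1]] - eb$mode[1]), 0.03)
  expect_lt(abs(g1[ij[2]] - eb$mode[2]), 0.006)
  expect_true(all(eigen(eb$curvature, only.values = TRUE)$values > 0))
})
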