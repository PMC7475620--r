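test_that("class-membership probabilities follow the multinomial logit", {
  mk <- function(memb, G) jlcm_params(G, memb, rep(4, G), rep(-0.1, G),
                                      c(0, 0, 0), diag(c(0.4, 0.01)), 0.2,
                                      1, 10, c(0, 0, 0), rep(0, G))
  cov0 <- list(sex = 0, addiction = 0, age = 0)
  expect_equal(class_membership_probs(mk(matrix(0, 2, 4), 3), cov0)[1, ],
               rep(1 / 3, 3))
  expect_equal(class_membership_probs(mk(matrix(0, 1, 4), 2), cov0)[1, ],
               c(0.5, 0.5))

  # published-style coefficients, male non-addicted aged 40: softmax oracle
  p3 <- default_jlcm_params()
  cov40 <- list(sex = 0, addiction = 0, age = 40)
  eta <- c(1.211 - 0.070 * 40, 4.563 - 0.118 * 40, 0)
  oracle <- exp(eta) / sum(exp(eta))
  got <- class_membership_probs(p3, cov40)[1, ]
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(max(abs(got - c(0.0991, 0.4152, 0.4857))), 2e-4)
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("class-conditional longitudinal likelihood is the closed-form MVN", {
  p <- default_jlcm_params()
  cov0 <- list(sex = 1, addiction = 0, age = 35)
  mm <- data.frame(time = c(0, 0.6, 1.4, 2.2), marker = c(5.1, 4.8, 4.9, 4.4))

  for (g in 1:3) {
    mean_g <- p$traj_intercepts[g] +
      sum(p$traj_common * c(cov0$sex, cov0$addiction, cov0$age)) +
      p$traj_slopes[g] * mm$time
    expect_equal(class_longitudinal_loglik(p, mm, cov0, g),
                 mvn_loglik_oracle(mm, mean_g, p$re_cov, p$resid_var),
                 tolerance = 1e-10)
  }

  # vanishing random effects: independent Gaussians
  p0 <- p
  p0$re_cov <- diag(c(1e-12, 1e-12))
  mean_1 <- p0$traj_intercepts[1] +
    sum(p0$traj_common * c(cov0$sex, cov0$addiction, cov0$age)) +
    p0$traj_slopes[1] * mm$time
  expect_equal(class_longitudinal_loglik(p0, mm, cov0, 1),
               sum(stats::dnorm(mm$marker, mean_1, sqrt(p0$resid_var),
                                log = TRUE)),
               tolerance = 1e-6)

  # single measurement: scalar normal with design-expanded variance
  m1 <- mm[2, ]
  B <- p$re_cov
  v <- B[1, 1] + 2 * m1$time * B[1, 2] + m1$time^2 * B[2, 2] + p$resid_var
  mean_2 <- p$traj_intercepts[2] +
    sum(p$traj_common * c(cov0$sex, cov0$addiction, cov0$age)) +
    p$traj_slopes[2] * m1$time
  expect_equal(class_longitudinal_loglik(p, m1, cov0, 2),
               stats::dnorm(m1$marker, mean_2, sqrt(v), log = TRUE),
               tolerance = 1e-12)
})

test_that("class-conditional survival likelihood shares the PH kernel", {
  p <- default_jlcm_params()
  cov0 <- list(sex = 0, addiction = 1, age = 42)
  sr <- list(event_time = 6, event = 1)
  for (g in 1:3) {
    oracle <- event_loglik(weibull_ph(p$shape, p$scale, p$alpha,
                                      p$class_log_hazard[g]),
                           cov0, sr$event_time, sr$event)
    expect_equal(class_survival_loglik(p, sr, cov0, g), oracle)
  }
  # equal class factors make every class identical
  p0 <- p
  p0$class_log_hazard <- c(0, 0, 0)
  lls <- vapply(1:3, function(g) class_survival_loglik(p0, sr, cov0, g),
                numeric(1))
  expect_equal(lls, rep(lls[1], 3))
  # a log-2 class factor doubles the cumulative hazard vs the reference
  sr0 <- list(event_time = 6, event = 0)
  pl2 <- p0
  pl2$class_log_hazard <- c(log(2), 0, 0)
  expect_equal(class_survival_loglik(pl2, sr0, cov0, 1),
               2 * class_survival_loglik(pl2, sr0, cov0, 3))
})

test_that("mixture likelihood nests the single-class joint model", {
  ds <- filter_eligible(small_jlcm_cohort(n = 40, seed = 23)$dataset)
  p <- default_srem_params()
  p$assoc <- c(0, 0)
  expect_equal(jlcm_marginal_loglik(one_class_params(), ds),
               srem_marginal_loglik(p, ds), tolerance = 1e-9)

  # forced membership reproduces the class-1 joint likelihood
  p3 <- default_jlcm_params()
  pf <- p3
  pf$membership[, 1] <- c(60, -60)  # class 1 certain
  sub <- ds$subjects[1, ]
  mm <- ds$measurements[ds$measurements$subject_id == sub$subject_id, ]
  one <- joint_dataset(ds$subjects[1, ], mm)
  expect_equal(jlcm_marginal_loglik(pf, one),
               class_longitudinal_loglik(p3, mm, sub, 1) +
                 class_survival_loglik(p3, sub, sub, 1),
               tolerance = 1e-9)

  # label switching leaves the likelihood unchanged (the new reference
  # class's hazard factor is folded into the Weibull scale)
  perm <- c(2, 3, 1)
  eta <- rbind(p3$membership, 0)[perm, ]
  shift <- p3$class_log_hazard[perm[3]]
  pp <- jlcm_params(3, sweep(eta[1:2, ], 2, eta[3, ]),
                    p3$traj_intercepts[perm], p3$traj_slopes[perm],
                    p3$traj_common, p3$re_cov, p3$resid_var, p3$shape,
                    p3$scale * exp(-shift / p3$shape), p3$alpha,
                    p3$class_log_hazard[perm] - shift)
  expect_equal(jlcm_marginal_loglik(pp, ds), jlcm_marginal_loglik(p3, ds),
               tolerance = 1e-9)
  # and the canonicalizer is itself a relabeling
  pc <- jointpred:::canonicalize_jlcm(pp)
  expect_equal(jlcm_marginal_loglik(pc, ds), jlcm_marginal_loglik(p3, ds),
               tolerance = 1e-9)
  expect_true(all(diff(pc$class_log_hazard) <= 0))
})

test_that("posterior classification behaves on degenerate and known cases", {
  ds <- filter_eligible(small_jlcm_cohort(n = 30, seed = 29)$dataset)
  post1 <- posterior_class_probs(one_class_params(), ds)
  expect_true(all(post1$prob.1 == 1))
  expect_true(all(post1$assigned_class == 1L))

  # identical classes: posterior equals the membership prior
  p3 <- default_jlcm_params()
  peq <- p3
  peq$traj_intercepts <- rep(5, 3)
  peq$traj_slopes <- rep(-0.1, 3)
  peq$class_log_hazard <- c(0, 0, 0)
  post <- posterior_class_probs(peq, ds)
  prior <- class_membership_probs(peq, ds$subjects)
  expect_equal(as.matrix(post[, c("prob.1", "prob.2", "prob.3")]),
               prior, ignore_attr = TRUE, tolerance = 1e-10)

  # rows are probability vectors
  pr <- as.matrix(posterior_class_probs(p3, ds)[, paste0("prob.", 1:3)])
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-10)
})

test_that("classification quality summarizes assigned-class sharpness", {
  mk_post <- function(p1) {
    data.frame(subject_id = seq_along(p1), prob.1 = p1, prob.2 = 1 - p1,
               assigned_class = ifelse(p1 >= 0.5, 1L, 2L))
  }
  q <- classification_quality(mk_post(c(1, 0, 1, 0)))
  expect_equal(q$mean_max_posterior, c(1, 1))

  q2 <- classification_quality(mk_post(c(0.8, 0.9, 0.2)))
  expect_equal(q2$mean_max_posterior[1], 0.85)
  expect_equal(q2$proportion_pct, c(200 / 3, 100 / 3))

  # proportions match direct counting on 20 labeled subjects
  set.seed(6)
  p1 <- stats::runif(20)
  q3 <- classification_quality(mk_post(p1))
  expect_equal(q3$n_assigned, as.vector(table(factor(ifelse(p1 >= 0.5, 1, 2),
                                                     levels = 1:2))))
  expect_equal(sum(q3$proportion_pct), 100)

  expect_warning(classification_quality(mk_post(c(0.9, 0.8))), "empty")
})

test_that("parameter counting and BIC reproduce the enumeration table", {
  expect_identical(vapply(1:4, count_parameters, integer(1)),
                   c(14L, 21L, 28L, 35L))
  expect_identical(count_parameters(3), 14L + 7L * 2L)
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-1547.86, 14, 213), 2 * 1547.86 + 14 * log(213))
  expect_lt(abs(bic(-1547.86, 14, 213) - 3170.77), 0.05)
  expect_lt(abs(bic(-1505.32, 28, 213) - 3160.76), 0.05)
})

test_that("class-number selection applies the BIC + independence rule", {
  mk_cand <- function(G, loglik, p_ci) {
    fit <- structure(list(loglik = loglik, n_params = count_parameters(G),
                          n_subjects = 213), class = c("jlcm_fit", "joint_fit"))
    score <- structure(list(statistic = stats::qchisq(p_ci, 2,
                                                      lower.tail = FALSE),
                            df = 2L, p_value = p_ci), class = "ci_score_test")
    list(G = G, fit = fit, score = score)
  }
  # lower-BIC 2-class model rejected on independence; 3-class preferred
  sel <- select_num_classes(list(mk_cand(2, -1519.09, 1e-4),
                                 mk_cand(3, -1505.32, 0.5801)))
  expect_identical(sel$G, 3)
  expect_false(sel$ci_rejected_everywhere)
  expect_identical(nrow(sel$trace), 2L)

  expect_identical(select_num_classes(list(mk_cand(2, -1519.09, 0.2)))$G, 2)

  # all candidates pass: pure BIC minimum
  sel3 <- select_num_classes(list(mk_cand(1, -1547.86, 0.4),
                                  mk_cand(2, -1519.09, 0.4),
                                  mk_cand(3, -1505.32, 0.4)))
  expect_identical(sel3$G, 2)

  # everyone rejected: lowest BIC with a warning
  expect_warning(
    sel4 <- select_num_classes(list(mk_cand(2, -1519.09, 1e-4),
                                    mk_cand(3, -1505.32, 1e-4))),
    "rejected")
  expect_identical(sel4$G, 2)
  expect_true(sel4$ci_rejected_everywhere)
})

test_that("class survival curves are ordered by the class hazard factors", {
  p <- default_jlcm_params()
  cov0 <- list(sex = 0, addiction = 0, age = 38)
  tg <- seq(0, 20, by = 2)
  cs <- class_survival_curves(p, cov0, tg)
  for (g in 1:3) {
    sg <- cs$survival[cs$class == g]
    expect_equal(sg[1], 1)
    expect_true(all(diff(sg) <= 0))
    oracle <- survival_prob(weibull_ph(p$shape, p$scale, p$alpha,
                                       p$class_log_hazard[g]), cov0, tg)
    expect_equal(sg, oracle)
  }
  # higher xi => uniformly lower curve
  s1 <- cs$survival[cs$class == 1][-1]
  s3 <- cs$survival[cs$class == 3][-1]
  expect_true(all(s1 < s3))
})

test_that("fitted mixtures respect nesting and recover a clean 2-class cohort", {
  p2 <- separated_jlcm_params(2)
  cfg <- simulation_config(n_subjects = 200, generator = "JLCM", params = p2,
                           seed = 37)
  coh <- simulate_jlcm_cohort(cfg)
  ds <- filter_eligible(coh$dataset)
  f1 <- quiet(fit_jlcm(ds, 1, n_starts = 1, seed = 1))
  f2 <- quiet(fit_jlcm(ds, 2, n_starts = 2, seed = 1))
  expect_true(f2$converged)
  expect_identical(f2$n_params, 21L)
  expect_gte(f2$loglik, f1$loglik - 1e-6)                # nested-fit sanity
  expect_gte(f2$loglik, jlcm_marginal_loglik(p2, ds) - 1e-6)  # MLE property
  # canonical order: highest-risk class first
  expect_true(all(diff(f2$params$class_log_hazard) <= 0))

  # posterior assignment matches the generating class on separated data
  post <- posterior_class_probs(f2$params, ds)
  truth <- coh$truth$class[match(post$subject_id, coh$truth$subject_id)]
  expect_gte(mean(post$assigned_class == truth), 0.9)

  # G = 1 factorizes into separate longitudinal and survival fits
  p0 <- srem_params(
    beta = c(intercept = f1$params$traj_intercepts[1],
             time = f1$params$traj_slopes[1],
             sex = f1$params$traj_common[1],
             addiction = f1$params$traj_common[2],
             age = f1$params$traj_common[3]),
    re_cov = f1$params$re_cov, resid_var = f1$params$resid_var,
    shape = f1$params$shape, scale = f1$params$scale,
    alpha = f1$params$alpha, assoc = c(0, 0))
  ll_surv <- fit_weibull_ph(ds$subjects)$loglik
  ll_long <- srem_marginal_loglik(p0, ds) -
    sum(event_loglik(weibull_ph(p0$shape, p0$scale, p0$alpha), ds$subjects,
                     ds$subjects$event_time, ds$subjects$event))
  expect_equal(f1$loglik, ll_long + ll_surv, tolerance = 1e-5)
})

test_that("score test maps statistics to chi-squared tails and has power", {
  expect_equal(score_test_pvalue(0), 1)
  expect_equal(score_test_pvalue(1.089), exp(-1.089 / 2), tolerance = 1e-12)

  # strong shared-random-effect association, single-class fit: rejection
  cfg <- simulation_config(n_subjects = 150, generator = "SREM", seed = 43)
  ds <- filter_eligible(simulate_srem_cohort(cfg)$dataset)
  fit <- quiet(fit_jlcm(ds, 1, n_starts = 1, seed = 1))
  st <- conditional_independence_score_test(fit, ds)
  expect_s3_class(st, "ci_score_test")
  expect_gte(st$statistic, 0)
  expect_identical(st$df, 2L)
  expect_equal(st$p_value, score_test_pvalue(st$statistic))
  expect_lt(st$p_value, 0.01)
})
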