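# shared fixture builders; everything is generated in code at test time

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# three hand-built subjects with known visit counts (1, 2, 5)
tiny_tables <- function() {
  subjects <- data.frame(
    subject_id = c("a", "b", "c"),
    event_time = c(2, 5, 10),
    event = c(1L, 0L, 1L),
    sex = c(0L, 1L, 0L),
    addiction = c(1L, 0L, 0L),
    age = c(30, 40, 50))
  measurements <- data.frame(
    subject_id = c("a", "b", "b", rep("c", 5)),
    time = c(0, 0, 1.2, 0, 1, 2, 4, 8),
    cd4 = c(400, 500, 450, 600, 550, 500, 300, 150))
  list(subjects = subjects, measurements = measurements)
}

tiny_dataset <- function() {
  tt <- tiny_tables()
  joint_dataset(tt$subjects, tt$measurements)
}

# small simulated cohorts, fixed seeds
small_srem_cohort <- function(n = 60, seed = 7) {
  simulate_srem_cohort(simulation_config(n_subjects = n, generator = "SREM",
                                         seed = seed))
}

small_jlcm_cohort <- function(n = 60, seed = 7, params = NULL) {
  simulate_jlcm_cohort(simulation_config(n_subjects = n, generator = "JLCM",
                                         params = params, seed = seed))
}

# single-class parameter set shared by cross-model identity tests
one_class_params <- function(p = default_srem_params()) {
  jlcm_params(1L, matrix(numeric(0), 0, 4),
              p$beta[["intercept"]], p$beta[["time"]],
              c(p$beta[["sex"]], p$beta[["addiction"]], p$beta[["age"]]),
              p$re_cov, p$resid_var, p$shape, p$scale, p$alpha, 0)
}

# direct multivariate-normal log-density of one subject's measurement
# vector: independent oracle for the closed-form longitudinal likelihoods
mvn_loglik_oracle <- function(measurements, mean_vec, re_cov, resid_var) {
  Z <- cbind(1, measurements$time)
  V <- Z %*% re_cov %*% t(Z) + resid_var * diag(nrow(measurements))
  r <- measurements$marker - mean_vec
  as.numeric(-0.5 * (nrow(measurements) * log(2 * pi) +
                       determinant(V)$modulus + t(r) %*% solve(V, r)))
}
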