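#' Case/control sets for time-dependent discrimination at a landmark
#'
#' Cases: subjects with an observed event in (s, s+t]. Controls: subjects
#' still at risk beyond s+t (event or censoring after s+t). Subjects
#' censored inside the window carry no event-status information and are
#' excluded; subjects with `event_time <= s` never enter.
#'
#' @param dataset a `joint_dataset`.
#' @param s landmark time (>= 0).
#' @param t window (> 0).
#' @return list: `cases`, `controls`, `excluded` (vectors of subject ids).
#' @export
cases_controls <- function(dataset, s, t) {
  stopifnot(s >= 0, t > 0)
  sub <- dataset$subjects
  in_window <- sub$event_time > s & sub$event_time <= s + t
  list(cases = sub$subject_id[in_window & sub$event == 1],
       controls = sub$subject_id[sub$event_time > s + t],
       excluded = sub$subject_id[in_window & sub$event == 0])
}

# censoring survival K-M estimate evaluated at given times (left limit),
# for the optional IPCW weighting
censoring_survfit <- function(dataset) {
  sub <- dataset$subjects
  survival::survfit(survival::Surv(event_time, 1 - event) ~ 1, data = sub)
}

eval_km <- function(km, times) {
  idx <- findInterval(times - 1e-10, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Time-dependent AUC at one landmark
#'
#' Mann-Whitney concordance of the dynamic risks: the fraction of
#' (case, control) pairs in which the case's risk exceeds the control's,
#' ties counting 0.5. With `ipcw = TRUE` pairs are weighted by inverse
#' probabilities of censoring (Kaplan-Meier of the censoring distribution),
#' a sensitivity option; the default is the simple landmark estimator.
#'
#' @param predictions data.frame with `subject_id` and `risk` at one
#'   landmark (e.g. one landmark's slice of
#'   [batch_dynamic_predictions()] output).
#' @param cases,controls subject-id vectors from [cases_controls()].
#' @param s,t landmark and window, recorded in the result (and used for the
#'   IPCW weights).
#' @param dataset required when `ipcw = TRUE`.
#' @param ipcw use inverse-probability-of-censoring weighting.
#' @param model_tag label stored in the result.
#' @return object of class `auc_result`: `landmark`, `window`, `auc`,
#'   `n_cases`, `n_controls`, `n_excluded`, `model_tag`. `auc` is NA (with
#'   `defined = FALSE`) when either set is empty.
#' @export
auc_st <- function(predictions, cases, controls, s = NA_real_, t = NA_real_,
                   dataset = NULL, ipcw = FALSE, model_tag = "") {
  rc <- predictions$risk[match(cases, predictions$subject_id)]
  rk <- predictions$risk[match(controls, predictions$subject_id)]
  if (anyNA(rc) || anyNA(rk)) stop("missing predictions for some subjects")
  res <- list(landmark = s, window = t, auc = NA_real_,
              n_cases = length(cases), n_controls = length(controls),
              n_excluded = NA_integer_, model_tag = model_tag,
              defined = FALSE)
  if (length(rc) && length(rk)) {
    if (ipcw) {
      if (is.null(dataset)) stop("ipcw = TRUE needs the dataset")
      km <- censoring_survfit(dataset)
      et <- dataset$subjects$event_time[match(cases, dataset$subjects$subject_id)]
      wc <- 1 / pmax(eval_km(km, et), 1e-8)
    } else {
      wc <- rep(1, length(rc))
    }
    cmp <- outer(rc, rk, function(a, b) (a > b) + 0.5 * (a == b))
    res$auc <- sum(wc * rowSums(cmp)) / (sum(wc) * length(rk))
    res$defined <- TRUE
  }
  structure(res, class = "auc_result")
}

#' ROC curve for one landmark's dynamic risks
#'
#' Thresholds the risks at every observed value; the trapezoidal area under
#' the returned curve equals [auc_st()] (ties split 0.5).
#'
#' @inheritParams auc_st
#' @return data.frame of ordered (`fpr`, `tpr`) points from (0,0) to (1,1).
#' @export
roc_curve <- function(predictions, cases, controls) {
  rc <- predictions$risk[match(cases, predictions$subject_id)]
  rk <- predictions$risk[match(controls, predictions$subject_id)]
  if (!length(rc) || !length(rk)) stop("need at least one case and one control")
  # ">= threshold" vertices: tied risks produce diagonal segments whose
  # trapezoidal area equals the tie-split concordance
  cuts <- sort(unique(c(rc, rk)), decreasing = TRUE)
  tpr <- vapply(cuts, function(cthr) mean(rc >= cthr), numeric(1L))
  fpr <- vapply(cuts, function(cthr) mean(rk >= cthr), numeric(1L))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Average time-dependent AUC over landmarks
#'
#' Unweighted mean of the defined landmark AUCs; undefined landmarks (no
#' cases or no controls) are skipped.
#'
#' @param results list of `auc_result` objects.
#' @return scalar average AUC.
#' @export
average_auc <- function(results) {
  vals <- vapply(results, function(r) {
    if (isTRUE(r$defined)) r$auc else NA_real_
  }, numeric(1L))
  if (all(is.na(vals))) stop("no landmark has a defined AUC")
  mean(vals, na.rm = TRUE)
}

#' Compare the dynamic-prediction accuracy of the two joint models
#'
#' Computes both models' dynamic risks for every at-risk subject at each
#' landmark, builds the (model-independent) case/control sets, and reports
#' per-landmark AUCs, their difference, and each model's landmark-averaged
#' AUC.
#'
#' @param dataset a `joint_dataset`.
#' @param srem_fit,jlcm_fit fitted models.
#' @param landmarks landmark grid (default `seq(1, 8, by = 0.5)`).
#' @param window window t in years (default 3).
#' @param ipcw use IPCW weighting in the AUCs.
#' @param ... passed to [batch_dynamic_predictions()].
#' @return list of class `model_comparison`: `table` (data.frame with one
#'   row per landmark: `landmark`, `window`, `n_cases`, `n_controls`,
#'   `auc_jlcm`, `auc_srem`, `diff`), `average` (named numeric, JLCM and
#'   SREM), `predictions`.
#' @export
compare_models <- function(dataset, srem_fit, jlcm_fit,
                           landmarks = seq(1, 8, by = 0.5), window = 3,
                           ipcw = FALSE, ...) {
  stopifnot(inherits(srem_fit, "srem_fit"), inherits(jlcm_fit, "jlcm_fit"))
  pred_s <- batch_dynamic_predictions(srem_fit, dataset, landmarks, window, ...)
  pred_j <- batch_dynamic_predictions(jlcm_fit, dataset, landmarks, window)
  res_s <- list()
  res_j <- list()
  rows <- list()
  for (s in landmarks) {
    cc <- cases_controls(dataset, s, window)
    ps <- pred_s[pred_s$landmark == s, ]
    pj <- pred_j[pred_j$landmark == s, ]
    as_ <- auc_st(ps, cc$cases, cc$controls, s, window, dataset, ipcw, "SREM")
    aj <- auc_st(pj, cc$cases, cc$controls, s, window, dataset, ipcw, "JLCM")
    res_s <- c(res_s, list(as_))
    res_j <- c(res_j, list(aj))
    rows <- c(rows, list(data.frame(
      landmark = s, window = window, n_cases = length(cc$cases),
      n_controls = length(cc$controls), auc_jlcm = aj$auc, auc_srem = as_$auc,
      diff = aj$auc - as_$auc)))
  }
  structure(list(table = do.call(rbind, rows),
                 average = c(JLCM = average_auc(res_j),
                             SREM = average_auc(res_s)),
                 predictions = rbind(pred_s, pred_j)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("dynamic-prediction accuracy comparison\n")
  cat("average AUC: JLCM =", round(x$average[["JLCM"]], 3),
      ", SREM =", round(x$average[["SREM"]], 3), "\n")
  print(x$table, digits = 3)
  invisible(x)
}
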