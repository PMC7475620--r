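#' Transform a raw biomarker value to the modeling scale
#'
#' CD4 counts are strongly right-skewed; joint models of CD4 trajectories are
#' conventionally fitted on a root scale. The fourth root is the default;
#' the square root is available by configuration.
#'
#' @param cd4 numeric vector of non-negative counts (cells/mm3).
#' @param mode `"fourth_root"` (default) or `"square_root"`.
#' @return transformed values, same length as `cd4`; strictly increasing in
#'   `cd4`.
#' @examples
#' transform_marker(16)         # 2
#' transform_marker(16, "square_root")  # 4
#' @export
transform_marker <- function(cd4, mode = c("fourth_root", "square_root")) {
  mode <- match.arg(mode)
  if (any(!is.finite(cd4)) || any(cd4 < 0)) {
    stop("marker values must be finite and non-negative")
  }
  if (mode == "fourth_root") cd4^0.25 else sqrt(cd4)
}

#' Inverse of [transform_marker()]
#' @param y transformed values (non-negative).
#' @inheritParams transform_marker
#' @return raw-scale values.
#' @export
transform_inverse <- function(y, mode = c("fourth_root", "square_root")) {
  mode <- match.arg(mode)
  if (any(y < 0)) stop("transformed marker values must be non-negative")
  if (mode == "fourth_root") y^4 else y^2
}

#' Construct and validate a joint longitudinal-survival dataset
#'
#' Binds a subject-level survival/covariate table to a long-format
#' measurement table and enforces the structural invariants both model
#' families rely on: every measurement belongs to a known subject, no
#' duplicate subject rows, measurement times are non-negative and (after an
#' optional trimming step) do not exceed the subject's event/censoring time.
#'
#' @param subjects data.frame with columns `subject_id`, `event_time` (> 0,
#'   years since diagnosis), `event` (1 = death from the studied cause,
#'   0 = censored), `sex` (1 = female), `addiction` (1 = no history of
#'   addiction), `age` (years at diagnosis, > 0).
#' @param measurements data.frame with columns `subject_id`, `time` (years,
#'   >= 0) and `cd4` (raw marker) and/or `marker` (transformed). If `marker`
#'   is absent it is computed from `cd4` via `transform`.
#' @param transform marker transform mode, see [transform_marker()].
#' @param drop_post_event drop measurements recorded strictly after the
#'   subject's event/censoring time, with a warning (registry data often
#'   carries trailing records). If `FALSE` such rows are an error.
#' @return an object of class `joint_dataset`: a list with elements
#'   `subjects`, `measurements`, `n`, `transform`.
#' @export
joint_dataset <- function(subjects, measurements,
                          transform = c("fourth_root", "square_root"),
                          drop_post_event = TRUE) {
  transform <- match.arg(transform)
  req_s <- c("subject_id", "event_time", "event", "sex", "addiction", "age")
  req_m <- c("subject_id", "time")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss)) stop("subjects table lacks columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(req_m, names(measurements))
  if (length(miss)) stop("measurements table lacks columns: ", paste(miss, collapse = ", "))
  if (!("cd4" %in% names(measurements)) && !("marker" %in% names(measurements))) {
    stop("measurements table needs a 'cd4' or 'marker' column")
  }

  subjects <- as.data.frame(subjects)
  measurements <- as.data.frame(measurements)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject rows: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]), collapse = ", "))
  }
  for (col in c("event_time", "event", "sex", "addiction", "age")) {
    if (!is.numeric(subjects[[col]])) stop("non-numeric subjects column: ", col)
  }
  if (any(subjects$event_time <= 0)) stop("event_time must be positive")
  if (!all(subjects$event %in% c(0, 1))) stop("event must be 0/1")
  if (!all(subjects$sex %in% c(0, 1))) stop("sex must be 0/1 (1 = female)")
  if (!all(subjects$addiction %in% c(0, 1))) stop("addiction must be 0/1 (1 = no history)")
  if (any(subjects$age <= 0)) stop("age must be positive")

  unknown <- setdiff(measurements$subject_id, subjects$subject_id)
  if (length(unknown)) {
    stop("measurements reference unknown subject_id(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  if (!is.numeric(measurements$time) || any(measurements$time < 0)) {
    stop("measurement times must be numeric and >= 0")
  }
  if ("marker" %in% names(measurements)) {
    # transformed scale is primary (Gaussian model scale; simulated values
    # may dip slightly below zero); raw counts derived for export
    if (!is.numeric(measurements$marker)) stop("non-numeric measurements column: marker")
    measurements$cd4 <- transform_inverse(pmax(measurements$marker, 0), transform)
  } else {
    if (!is.numeric(measurements$cd4)) stop("non-numeric measurements column: cd4")
    measurements$marker <- transform_marker(measurements$cd4, transform)
  }

  et <- subjects$event_time[match(measurements$subject_id, subjects$subject_id)]
  late <- measurements$time > et
  if (any(late)) {
    if (!drop_post_event) stop(sum(late), " measurement(s) after event_time")
    warning("dropping ", sum(late), " measurement(s) recorded after event_time")
    measurements <- measurements[!late, , drop = FALSE]
  }
  measurements <- measurements[order(match(measurements$subject_id, subjects$subject_id),
                                     measurements$time), , drop = FALSE]
  rownames(subjects) <- rownames(measurements) <- NULL

  structure(list(subjects = subjects, measurements = measurements,
                 n = nrow(subjects), transform = transform),
            class = "joint_dataset")
}

#' @export
print.joint_dataset <- function(x, ...) {
  cat("joint_dataset:", x$n, "subjects,", nrow(x$measurements),
      "measurements (", x$transform, "marker scale )\n")
  invisible(x)
}

#' Read a joint dataset from the two-file CSV format
#'
#' Expects `measurements.csv` (`subject_id,time,cd4`) and `subjects.csv`
#' (`subject_id,event_time,event,sex,addiction,age`), comma-delimited with a
#' header row. Rows with missing required fields are rejected with a
#' line-referenced report.
#'
#' @param measurements_path,subjects_path paths to the CSV files.
#' @inheritParams joint_dataset
#' @return a `joint_dataset`.
#' @export
read_joint_data <- function(measurements_path, subjects_path,
                            transform = c("fourth_root", "square_root"),
                            drop_post_event = TRUE) {
  transform <- match.arg(transform)
  for (p in c(measurements_path, subjects_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  subj <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)

  check_complete <- function(df, cols, label) {
    cols <- intersect(cols, names(df))
    bad <- which(!stats::complete.cases(df[, cols, drop = FALSE]))
    if (length(bad)) {
      stop(label, ": missing required fields at data line(s) ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header row
    }
  }
  check_complete(meas, c("subject_id", "time", "cd4", "marker"), basename(measurements_path))
  check_complete(subj, c("subject_id", "event_time", "event", "sex", "addiction", "age"),
                 basename(subjects_path))
  joint_dataset(subj, meas, transform = transform, drop_post_event = drop_post_event)
}

#' Write a joint dataset to the two-file CSV format
#'
#' @param dataset a `joint_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths written.
#' @export
write_joint_data <- function(dataset, dir) {
  stopifnot(inherits(dataset, "joint_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "measurements.csv")
  sp <- file.path(dir, "subjects.csv")
  fmt <- function(df) {
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    df
  }
  utils::write.csv(fmt(dataset$measurements[, c("subject_id", "time", "cd4",
                                                "marker")]), mp,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(dataset$subjects[, c("subject_id", "event_time", "event",
                                            "sex", "addiction", "age")]), sp,
                   row.names = FALSE, quote = FALSE)
  invisible(c(measurements = mp, subjects = sp))
}

#' Keep subjects with enough longitudinal measurements
#'
#' Registry analyses of biomarker trajectories require a minimum number of
#' measurements per subject (two, by default, so a subject-specific slope is
#' identified). Subjects below the threshold are removed listwise.
#'
#' @param dataset a `joint_dataset`.
#' @param min_measurements minimum retained visits per subject.
#' @return the filtered `joint_dataset`, with an `exclusions` attribute: a
#'   data.frame of removed `subject_id`, `n_measurements`, `reason`.
#' @export
filter_eligible <- function(dataset, min_measurements = 2L) {
  stopifnot(inherits(dataset, "joint_dataset"), min_measurements >= 0)
  counts <- table(factor(dataset$measurements$subject_id,
                         levels = dataset$subjects$subject_id))
  keep <- as.vector(counts) >= min_measurements
  excl <- data.frame(
    subject_id = dataset$subjects$subject_id[!keep],
    n_measurements = as.vector(counts)[!keep],
    reason = if (any(!keep)) {
      sprintf("fewer than %d measurements", min_measurements)
    } else character(0),
    stringsAsFactors = FALSE
  )
  out <- joint_dataset(
    dataset$subjects[keep, , drop = FALSE],
    dataset$measurements[dataset$measurements$subject_id %in%
                           dataset$subjects$subject_id[keep], , drop = FALSE],
    transform = dataset$transform
  )
  attr(out, "exclusions") <- excl
  out
}

#' Summary statistics of a joint cohort
#'
#' @param dataset a non-empty `joint_dataset`.
#' @return a list: `n`, `n_events`, `event_pct`, `total_measurements`,
#'   median/IQR of age, of baseline (first-visit) raw marker, and of visits
#'   per subject.
#' @export
summarize_cohort <- function(dataset) {
  stopifnot(inherits(dataset, "joint_dataset"))
  if (dataset$n == 0L) stop("empty dataset")
  s <- dataset$subjects
  m <- dataset$measurements
  first_idx <- !duplicated(m$subject_id)  # measurements are time-sorted per subject
  visits <- as.vector(table(factor(m$subject_id, levels = s$subject_id)))
  med_iqr <- function(x) c(median = stats::median(x), iqr = stats::IQR(x))
  list(
    n = dataset$n,
    n_events = sum(s$event),
    event_pct = 100 * sum(s$event) / dataset$n,
    total_measurements = nrow(m),
    age = med_iqr(s$age),
    baseline_marker_raw = med_iqr(m$cd4[first_idx]),
    visits_per_subject = med_iqr(visits)
  )
}

# Internal: split a dataset into per-subject pieces aligned with the
# subjects table (used by fitting code and oracles).
split_measurements <- function(dataset) {
  split(dataset$measurements,
        factor(dataset$measurements$subject_id, levels = dataset$subjects$subject_id))
}
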