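#' Longitudinal cohort container
#'
#' Bundles long-format longitudinal marker measurements with per-subject
#' covariates.  `data` has one row per (subject, visit, marker) observation;
#' missing measurements are simply absent rows (the progression model handles
#' missingness natively, no imputation is performed).
#'
#' @param data data frame with columns `subject_id`, `trial`,
#'   `visit_time_years` (observed disease duration at the visit, years since
#'   symptom onset), `marker`, `value`.  An optional `value_raw` column
#'   carries the raw clinical scale (e.g. EDSS steps, seconds) used by the
#'   endpoint layer.
#' @param covariates data frame with columns `subject_id`, `age_onset`
#'   (years), `sex`, `treatment`, `trial`.
#' @param scale `"native"` if `value` is on each marker's modelling scale as
#'   declared by its spec, `"score"` if values are quantile scores.
#'
#' @return An object of class `ppms_cohort`.
#' @export
longitudinal_cohort <- function(data, covariates, scale = c("native", "score")) {
  scale <- match.arg(scale)
  need <- c("subject_id", "trial", "visit_time_years", "marker", "value")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop_ppms(paste("`data` must contain columns", paste(need, collapse = ", ")),
              "ppmsprog_config_error")
  }
  need_cov <- c("subject_id", "age_onset", "sex", "treatment", "trial")
  if (!is.data.frame(covariates) || !all(need_cov %in% names(covariates))) {
    stop_ppms(paste("`covariates` must contain columns",
                    paste(need_cov, collapse = ", ")), "ppmsprog_config_error")
  }
  if (any(is.na(data$visit_time_years)) || any(data$visit_time_years < 0)) {
    stop_ppms("visit times must be non-negative and non-missing",
              "ppmsprog_config_error")
  }
  ## strictly increasing visit times within subject x marker
  ord <- order(data$subject_id, data$marker, data$visit_time_years)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(
    list(data = data, covariates = covariates, scale = scale),
    class = "ppms_cohort"
  )
}

#' @export
print.ppms_cohort <- function(x, ...) {
  cat(sprintf(
    "<ppms_cohort> %d subjects, %d markers, %d observations (%s scale)\n",
    nrow(x$covariates), length(unique(x$data$marker)), nrow(x$data), x$scale))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a `ppms_cohort`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$covariates)

#' Write a cohort to CSV files
#'
#' Writes the long-format measurement table and the covariate table.
#'
#' @param cohort a `ppms_cohort`.
#' @param data_path,covariates_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, data_path, covariates_path) {
  utils::write.csv(cohort$data, data_path, row.names = FALSE)
  utils::write.csv(cohort$covariates, covariates_path, row.names = FALSE)
  invisible(c(data_path, covariates_path))
}

#' Read a cohort from CSV files
#' @inheritParams write_cohort
#' @param scale scale of the `value` column, see [longitudinal_cohort()].
#' @return a `ppms_cohort`.
#' @export
read_cohort <- function(data_path, covariates_path, scale = "native") {
  longitudinal_cohort(
    utils::read.csv(data_path, stringsAsFactors = FALSE),
    utils::read.csv(covariates_path, stringsAsFactors = FALSE),
    scale = scale
  )
}

#' Baseline (first-visit) observed disease duration per subject, in years
#' @param cohort a `ppms_cohort`.
#' @return named numeric vector, one entry per subject.
#' @export
baseline_odd <- function(cohort) {
  m <- tapply(cohort$data$visit_time_years, cohort$data$subject_id, min)
  ids <- cohort$covariates$subject_id
  stats::setNames(as.numeric(m[match(ids, names(m))]), ids)
}
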