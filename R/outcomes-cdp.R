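## Confirmed disability progression (CDP) event detection.
##
## A candidate worsening at visit j counts as an event only if it is
## confirmed at the first scheduled visit occurring at least `confirm_months`
## after the candidate.  In the default strict mode every visit between the
## candidate and the confirmation visit (inclusive) must also meet the
## worsening criterion (sustained worsening); the lenient mode checks the
## confirmation visit only.  Event time is the candidate visit's time;
## subjects without a confirmed event are censored at their last visit.

#' @noRd
detect_cdp_generic <- function(times, worse, confirm_months,
                               strict = TRUE) {
  nv <- length(times)
  if (nv < 1L) stop_ppms("empty visit series", "ppmsprog_config_error")
  if (nv == 1L) {
    warning("single-visit subject: censored at baseline")
    return(list(event = 0L, time = 0))
  }
  if (any(diff(times) <= 0)) {
    stop_ppms("visit times must be strictly increasing",
              "ppmsprog_config_error")
  }
  for (j in 2:nv) {
    if (!worse[j]) next
    conf <- which(times >= times[j] + confirm_months)
    if (length(conf) == 0L) next   # no scheduled visit late enough
    cj <- conf[1]
    ok <- if (strict) all(worse[(j + 1):cj]) else worse[cj]
    if (ok) return(list(event = 1L, time = times[j]))
  }
  list(event = 0L, time = times[nv])
}

#' EDSS step required for confirmed progression given the baseline score
#'
#' 1.0 point for baselines 3.0-5.0, 0.5 point for 5.5-6.5.  Outside the
#' stated bands: baselines below 3.0 require 1.0 point, baselines of 7.0 or
#' more require 0.5 (common trial convention), both configurable.
#'
#' @param baseline baseline EDSS.
#' @param step_low step for baselines below 3.0.
#' @param step_high step for baselines of 7.0 and above.
#' @return required increase (EDSS points).
#' @export
edss_required_step <- function(baseline, step_low = 1.0, step_high = 0.5) {
  if (baseline < 3.0) step_low
  else if (baseline <= 5.0) 1.0
  else if (baseline <= 6.5) 0.5
  else step_high
}

#' Confirmed disability progression on EDSS
#'
#' Worsening is an increase from the fixed study baseline of at least the
#' band-dependent step (see [edss_required_step()]), confirmed at a
#' scheduled visit at least `confirm_months` later.
#'
#' @param times visit times in months from baseline, strictly increasing,
#'   first element the baseline visit.
#' @param values EDSS at each visit.
#' @param confirm_months confirmation window (months).
#' @param strict require worsening sustained at all visits up to the
#'   confirmation visit.
#' @return list with `event` (0/1) and `time` (months from baseline; the
#'   last visit when censored).
#' @export
detect_cdp_edss <- function(times, values, confirm_months = 3,
                            strict = TRUE) {
  if (is.na(values[1])) {
    stop_ppms("baseline EDSS missing", "ppmsprog_config_error")
  }
  req <- edss_required_step(values[1])
  worse <- !is.na(values) & (values >= values[1] + req - 1e-9)
  detect_cdp_generic(times, worse, confirm_months, strict)
}

#' Confirmed percent worsening (timed tests: T25FW, 9HPT)
#'
#' Worsening is an increase of at least `threshold` (default 20\%) from the
#' fixed study baseline, confirmed at a scheduled visit at least
#' `confirm_months` later.  Exactly the threshold qualifies.
#'
#' @inheritParams detect_cdp_edss
#' @param values timed-test values (seconds; larger is worse).
#' @param threshold fractional worsening threshold.
#' @return list with `event` and `time` (months).
#' @export
detect_cdp_percent <- function(times, values, threshold = 0.20,
                               confirm_months = 3, strict = TRUE) {
  if (is.na(values[1]) || values[1] <= 0) {
    stop_ppms("baseline must be positive", "ppmsprog_invalid_baseline")
  }
  cut <- values[1] * (1 + threshold)
  worse <- !is.na(values) & (values >= cut - 1e-9 * abs(cut))
  detect_cdp_generic(times, worse, confirm_months, strict)
}

#' Confirmed SDMT worsening
#'
#' Worsening is a decrease from baseline of at least 3 points or at least
#' 10\% of the baseline score, confirmed at a scheduled visit at least 6
#' months later.
#'
#' @inheritParams detect_cdp_edss
#' @param values SDMT scores (larger is better).
#' @param points_threshold absolute decrease threshold.
#' @param pct_threshold fractional decrease threshold.
#' @return list with `event` and `time` (months).
#' @export
detect_cdp_sdmt <- function(times, values, points_threshold = 3,
                            pct_threshold = 0.10, confirm_months = 6,
                            strict = TRUE) {
  if (is.na(values[1])) {
    stop_ppms("baseline SDMT missing", "ppmsprog_config_error")
  }
  drop_ <- values[1] - values
  req <- min(points_threshold, pct_threshold * values[1])
  worse <- !is.na(values) & (drop_ >= req - 1e-9)
  detect_cdp_generic(times, worse, confirm_months, strict)
}

#' Confirmed EDSS 6 milestone, timed from symptom onset
#'
#' Event at the first visit with EDSS of 6.0 or more confirmed at the next
#' scheduled visit at least 3 months later.  The time axis is years since
#' symptom onset (baseline observed disease duration plus months from
#' baseline); the event age is age at onset plus that time.  Subjects whose
#' baseline EDSS is already 6.0 or more, confirmed, count as prevalent
#' events at baseline.
#'
#' @inheritParams detect_cdp_edss
#' @param baseline_odd_years observed disease duration at baseline (years).
#' @param age_onset age at symptom onset (years); may be `NA`, in which case
#'   `age_event` is `NA`.
#' @return list with `event`, `time_years` (since onset), `age_event`.
#' @export
detect_confirmed_edss6 <- function(times, values, baseline_odd_years,
                                   age_onset = NA_real_, confirm_months = 3,
                                   strict = TRUE) {
  if (is.na(baseline_odd_years)) {
    stop_ppms("missing onset anchor (baseline disease duration)",
              "ppmsprog_config_error")
  }
  worse <- !is.na(values) & (values >= 6.0 - 1e-9)
  nv <- length(times)
  res <- if (nv >= 2 && worse[1]) {
    ## prevalent milestone: baseline itself qualifies if confirmed
    conf <- which(times >= times[1] + confirm_months)
    ok <- length(conf) > 0 &&
      (if (strict) all(worse[2:conf[1]]) else worse[conf[1]])
    if (ok) list(event = 1L, time = times[1])
    else detect_cdp_generic(times, worse, confirm_months, strict)
  } else {
    detect_cdp_generic(times, worse, confirm_months, strict)
  }
  time_years <- baseline_odd_years + res$time / 12
  list(event = res$event, time_years = time_years,
       age_event = if (is.na(age_onset)) NA_real_ else age_onset + time_years)
}

#' Build a per-subject event table for one endpoint across a cohort
#'
#' Applies the endpoint's CDP rule to each subject's raw-scale series of the
#' endpoint marker (`value_raw` column; falls back to `value`), attaching
#' subgroup labels and covariates for the survival layer.  Subjects without
#' the endpoint marker are omitted.
#'
#' @param cohort a `ppms_cohort`.
#' @param endpoint one of `"EDSS"`, `"T25FW"`, `"HPT9_D"`, `"HPT9_ND"`,
#'   `"SDMT"`, `"EDSS6"`.
#' @param assignment optional `subgroup_assignment` supplying group labels.
#' @param strict sustained-worsening confirmation mode.
#' @return data frame: `subject_id`, `time_months` (or `time_years` plus
#'   `age_event` for `"EDSS6"`), `event`, `endpoint`, `group` (if given),
#'   covariates.
#' @export
build_event_table <- function(cohort, endpoint = "EDSS", assignment = NULL,
                              strict = TRUE) {
  marker <- if (endpoint == "EDSS6") "EDSS" else endpoint
  dat <- cohort$data[cohort$data$marker == marker, , drop = FALSE]
  if (nrow(dat) == 0L) {
    stop_ppms(sprintf("no observations of marker '%s'", marker),
              "ppmsprog_config_error")
  }
  val_col <- if ("value_raw" %in% names(dat)) "value_raw" else "value"
  cov <- cohort$covariates
  rows <- lapply(split(dat, dat$subject_id), function(dd) {
    dd <- dd[order(dd$visit_time_years), ]
    keep <- !is.na(dd[[val_col]])
    dd <- dd[keep, , drop = FALSE]
    if (nrow(dd) == 0L) return(NULL)
    tm <- (dd$visit_time_years - dd$visit_time_years[1]) * 12
    v <- dd[[val_col]]
    id <- dd$subject_id[1]
    if (endpoint == "EDSS6") {
      age0 <- cov$age_onset[match(id, cov$subject_id)]
      res <- detect_confirmed_edss6(tm, v, dd$visit_time_years[1], age0,
                                    strict = strict)
      data.frame(subject_id = id, time_years = res$time_years,
                 age_event = res$age_event, event = res$event,
                 endpoint = endpoint, stringsAsFactors = FALSE)
    } else {
      res <- switch(endpoint,
        EDSS = detect_cdp_edss(tm, v, strict = strict),
        T25FW = ,
        HPT9_D = ,
        HPT9_ND = detect_cdp_percent(tm, v, strict = strict),
        SDMT = detect_cdp_sdmt(tm, v, strict = strict),
        stop_ppms(sprintf("unknown endpoint '%s'", endpoint),
                  "ppmsprog_config_error"))
      data.frame(subject_id = id, time_months = res$time, event = res$event,
                 endpoint = endpoint, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(assignment)) {
    lab <- assignment$assignment
    out$group <- lab$label[match(out$subject_id, lab$subject_id)]
  }
  merge(out, cov, by = "subject_id", sort = TRUE)
}
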