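#' Simulation configuration for synthetic PPMS-like cohorts
#'
#' Defines the generating process of the bundled synthetic-cohort module:
#' irregular visit schedules, log-normal baseline disease duration, Gaussian
#' individual time-shifts, monotone sigmoid population trajectories on the
#' score scale, per-subject random intercepts, heteroskedastic Gaussian
#' noise, and trial-blocked marker missingness.
#'
#' Defaults emulate the pooled PPMS clinical-trial setting: visits every
#' 2.76 months over follow-ups of mean 28.2 (SD 10.8) months, baseline
#' disease duration with median 6.3 years and IQR 3.7-9.8 years, three
#' trials with SDMT restricted to one of them.
#'
#' @param n_subjects number of subjects.
#' @param specs `marker_spec_df` of the simulated markers.
#' @param trajectory_params data frame (`name`, `midpoint`, `rate`, `lo`,
#'   `hi`) of sigmoid parameters per marker, on the disease-time axis in
#'   years; `NULL` uses [default_trajectory_params()].
#' @param shift_sd SD (years) of the true Gaussian time-shifts.
#' @param visit_interval_mean mean visit interval, months.
#' @param visit_jitter_sd SD of the visit-interval jitter, months.
#' @param followup_mean,followup_sd follow-up duration distribution, months.
#' @param baseline_dd_median,baseline_dd_iqr median and IQR (years) of the
#'   log-normal baseline disease duration.
#' @param noise_sd measurement noise SD on the score scale; scalar or one
#'   value per marker.
#' @param re_sd SD of per-subject, per-marker random intercepts (score scale).
#' @param trial_probs named probabilities of trial membership.
#' @param missing_blocks named list: trial -> character vector of markers
#'   entirely missing in that trial.
#' @param covariate_params list with `age_onset_mean`, `age_onset_sd`,
#'   `p_male`, `p_treated`.
#' @param seed integer seed; the same config (including seed) always yields
#'   byte-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200,
                       specs = default_marker_specs(),
                       trajectory_params = NULL,
                       shift_sd = 3,
                       visit_interval_mean = 2.76,
                       visit_jitter_sd = 0.15,
                       followup_mean = 28.2,
                       followup_sd = 10.8,
                       baseline_dd_median = 6.3,
                       baseline_dd_iqr = c(3.7, 9.8),
                       noise_sd = 0.06,
                       re_sd = 0.04,
                       trial_probs = c(ARPEGGIO = 0.245, OLYMPUS = 0.288,
                                       ORATORIO = 0.467),
                       missing_blocks = list(OLYMPUS = c("SDMT", "T1LV"),
                                             ORATORIO = "SDMT"),
                       covariate_params = list(age_onset_mean = 38.9,
                                               age_onset_sd = 8.8,
                                               p_male = 0.51,
                                               p_treated = 0.656),
                       seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 1)
  check_scalar(shift_sd, "shift_sd", lower = 0)
  check_scalar(visit_interval_mean, "visit_interval_mean", lower = 0,
               strict = TRUE)
  check_marker_specs(specs)
  if (any(noise_sd < 0)) {
    stop_ppms("noise SDs must be >= 0", "ppmsprog_config_error")
  }
  if (is.null(trajectory_params)) {
    trajectory_params <- default_trajectory_params(specs)
  }
  if (!all(specs$name %in% trajectory_params$name)) {
    stop_ppms("every marker needs trajectory parameters",
              "ppmsprog_config_error")
  }
  K <- nrow(specs)
  noise_sd <- rep_len(noise_sd, K)
  structure(list(
    n_subjects = as.integer(n_subjects), specs = specs,
    trajectory_params = trajectory_params, shift_sd = shift_sd,
    visit_interval_mean = visit_interval_mean,
    visit_jitter_sd = visit_jitter_sd,
    followup_mean = followup_mean, followup_sd = followup_sd,
    baseline_dd_median = baseline_dd_median,
    baseline_dd_iqr = baseline_dd_iqr,
    noise_sd = noise_sd, re_sd = re_sd,
    trial_probs = trial_probs, missing_blocks = missing_blocks,
    covariate_params = covariate_params, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default sigmoid trajectory parameters
#'
#' Midpoints stagger the markers along a multi-decade disease-time axis in
#' the clinically expected order (disability scales first, brain volume
#' last); lesion volumes get shallow slopes so their change is spread over
#' the timeline.  Unknown marker names get midpoints evenly spaced over
#' 5-30 years.
#'
#' @param specs a `marker_spec_df`.
#' @return data frame with columns `name`, `midpoint`, `rate`, `lo`, `hi`.
#' @export
default_trajectory_params <- function(specs = default_marker_specs()) {
  known <- data.frame(
    name = c("EDSS", "T25FW", "HPT9_D", "HPT9_ND", "SDMT", "NBV",
             "T1LV", "T2LV"),
    midpoint = c(12, 18, 24, 26, 22, 32, 20, 16),
    rate = c(0.18, 0.10, 0.10, 0.09, 0.12, 0.08, 0.05, 0.05),
    lo = c(0.05, 0.05, 0.05, 0.05, 0.10, 0.10, 0.05, 0.05),
    hi = c(0.95, 0.90, 0.85, 0.85, 0.90, 0.90, 0.85, 0.85),
    stringsAsFactors = FALSE
  )
  out <- known[match(specs$name, known$name), ]
  miss <- is.na(out$name)
  if (any(miss)) {
    k <- sum(miss)
    out$name[miss] <- specs$name[miss]
    out$midpoint[miss] <- seq(5, 30, length.out = max(k, 2))[seq_len(k)]
    out$rate[miss] <- 0.15
    out$lo[miss] <- 0.05
    out$hi[miss] <- 0.95
  }
  rownames(out) <- NULL
  out
}

#' Evaluate a true sigmoid population trajectory
#'
#' @param tau disease time (years).
#' @param params one row of trajectory parameters.
#' @param direction `"non-decreasing"` or `"non-increasing"`.
#' @param deriv if `TRUE`, return the derivative instead of the value.
#' @return numeric vector.
#' @export
true_trajectory <- function(tau, params, direction = "non-decreasing",
                            deriv = FALSE) {
  s <- stats::plogis(params$rate * (tau - params$midpoint))
  amp <- params$hi - params$lo
  if (deriv) {
    d <- amp * params$rate * s * (1 - s)
    if (direction == "non-increasing") -d else d
  } else {
    if (direction == "non-increasing") params$hi - amp * s
    else params$lo + amp * s
  }
}

## log-normal sdlog calibrated to the configured IQR ratio
#' @noRd
lognormal_sdlog <- function(iqr) log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))

## map score-scale values to a plausible raw clinical scale per marker
#' @noRd
raw_from_score <- function(marker, score) {
  switch(marker,
    EDSS    = pmin(10, pmax(0, round(10 * score * 2) / 2)),
    T25FW   = exp(log(4.5) + 2.3 * score),
    HPT9_D  = exp(log(17) + 1.6 * score),
    HPT9_ND = exp(log(17) + 1.7 * score),
    SDMT    = round(15 + 55 * score),
    NBV     = 1100 + 400 * score,
    T1LV    = exp(-1.5 + 4 * score),
    T2LV    = exp(0.6 + 3 * score),
    score
  )
}

#' Generate a synthetic PPMS-like cohort with known ground truth
#'
#' Each subject draws a trial, covariates, a baseline disease duration, a
#' Gaussian time-shift \eqn{d_s} (centred across the cohort), and an
#' irregular visit schedule.  Visits observed at disease duration `t` carry
#' the latent stage \eqn{\tau = t - d_s}; marker values are the monotone
#' sigmoid population trajectory at \eqn{\tau} plus a per-subject intercept
#' plus Gaussian noise, clamped to the score range \eqn{[0,1]}.  Markers in
#' a trial's missing block yield no rows for that trial's subjects.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (a `ppms_cohort`, values on the
#'   native modelling scale, raw clinical scales in `value_raw`) and `truth`
#'   (true trajectories, shifts, reparametrization parameters
#'   \eqn{\delta = -d_s}, subgroup labels at the 1-SD rule, and the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    specs <- config$specs
    K <- nrow(specs)
    cp <- config$covariate_params

    trial <- sample(names(config$trial_probs), n, replace = TRUE,
                    prob = config$trial_probs)
    age_onset <- stats::rnorm(n, cp$age_onset_mean, cp$age_onset_sd)
    sex <- ifelse(stats::runif(n) < cp$p_male, "M", "F")
    treatment <- ifelse(stats::runif(n) < cp$p_treated, "active", "placebo")

    sdlog <- lognormal_sdlog(config$baseline_dd_iqr)
    ## truncated at 45 y: durations beyond that are implausible for trial
    ## entry given typical onset ages
    base_dd <- pmin(45, stats::rlnorm(n, log(config$baseline_dd_median),
                                      sdlog))

    d <- stats::rnorm(n, 0, config$shift_sd)
    if (config$shift_sd > 0) d <- d - mean(d)

    followup <- pmax(6, stats::rnorm(n, config$followup_mean,
                                     config$followup_sd))
    re <- matrix(stats::rnorm(n * K, 0, config$re_sd), n, K)

    subj_ids <- sprintf("S%04d", seq_len(n))
    rows <- vector("list", n)
    for (s in seq_len(n)) {
      gaps <- pmax(0.5, stats::rnorm(40, config$visit_interval_mean,
                                     config$visit_jitter_sd))
      t_months <- c(0, cumsum(gaps))
      t_months <- t_months[t_months <= followup[s]]
      t_years <- base_dd[s] + t_months / 12
      tau <- t_years - d[s]
      missing_here <- config$missing_blocks[[trial[s]]]
      per_marker <- vector("list", K)
      for (k in seq_len(K)) {
        if (specs$name[k] %in% missing_here) next
        latent <- true_trajectory(tau, config$trajectory_params[
          config$trajectory_params$name == specs$name[k], ],
          specs$monotone_direction[k]) + re[s, k]
        y <- pmin(1, pmax(0, latent + stats::rnorm(length(tau), 0,
                                                   config$noise_sd[k])))
        per_marker[[k]] <- data.frame(
          subject_id = subj_ids[s], trial = trial[s],
          visit_time_years = t_years, marker = specs$name[k],
          value = y, value_raw = raw_from_score(specs$name[k], y),
          stringsAsFactors = FALSE
        )
      }
      rows[[s]] <- do.call(rbind, per_marker)
    }
    data <- do.call(rbind, rows)
    covariates <- data.frame(
      subject_id = subj_ids, age_onset = age_onset, sex = sex,
      treatment = treatment, trial = trial, stringsAsFactors = FALSE
    )
    cohort <- longitudinal_cohort(data, covariates, scale = "native")

    delta <- -d
    names(d) <- names(delta) <- subj_ids
    labels <- if (config$shift_sd > 0 && n >= 2) {
      classify_progressors(delta, k_sd = 1)$assignment$label
    } else rep("G2", n)
    names(labels) <- subj_ids

    truth <- list(
      trajectory_params = config$trajectory_params,
      directions = stats::setNames(specs$monotone_direction, specs$name),
      shifts = d, delta = delta, labels = labels,
      baseline_dd = stats::setNames(base_dd, subj_ids),
      config = config
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Overlay synthetic survival outcomes on a cohort
#'
#' Draws per-subject event times from an exponential proportional-hazards
#' model whose hazard depends on the subject's true subgroup label, censored
#' administratively at each subject's end of follow-up.  Used to test the
#' survival layer against known hazard ratios.
#'
#' @param cohort a `ppms_cohort`.
#' @param truth ground truth from [generate_cohort()] (supplies the labels).
#' @param hr_by_group named hazard-ratio map with names among G1, G2, G3
#'   (G2 is the reference; missing groups default to 1).
#' @param base_median_months median event time in the reference group.
#' @param seed integer seed.
#' @return data frame (`subject_id`, `time_months`, `event`, `group`) merged
#'   with the cohort covariates.
#' @export
generate_survival_overlay <- function(cohort, truth, hr_by_group,
                                      base_median_months = 30, seed = 1L) {
  if (is.null(names(hr_by_group)) ||
      !all(names(hr_by_group) %in% c("G1", "G2", "G3"))) {
    stop_ppms("hr_by_group names must be among G1, G2, G3",
              "ppmsprog_config_error")
  }
  if (any(hr_by_group <= 0)) {
    stop_ppms("hazard ratios must be positive", "ppmsprog_config_error")
  }
  hr <- c(G1 = 1, G2 = 1, G3 = 1)
  hr[names(hr_by_group)] <- hr_by_group
  with_seed(seed, {
    ids <- cohort$covariates$subject_id
    grp <- truth$labels[ids]
    base_rate <- log(2) / base_median_months
    rate <- base_rate * hr[grp]
    t_event <- stats::rexp(length(ids), rate)
    fu <- tapply(cohort$data$visit_time_years, cohort$data$subject_id,
                 function(v) (max(v) - min(v)) * 12)[ids]
    event <- as.integer(t_event <= fu)
    out <- data.frame(
      subject_id = ids,
      time_months = pmin(t_event, fu),
      event = event, group = unname(grp),
      stringsAsFactors = FALSE
    )
    merge(out, cohort$covariates, by = "subject_id", sort = TRUE)
  })
}
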