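## Shared fixtures.  The standard synthetic benchmark (n = 150 subjects,
## K = 4 markers, shift SD 3 y, sigmoid trajectories, generator defaults
## otherwise) is expensive to fit, so it is built lazily once per session.

bench_env <- new.env(parent = emptyenv())

benchmark_specs <- function() default_marker_specs()[1:4, ]

benchmark_gen <- function() {
  if (is.null(bench_env$gen)) {
    bench_env$gen <- generate_cohort(sim_config(
      n_subjects = 150, specs = benchmark_specs(), shift_sd = 3, seed = 42))
  }
  bench_env$gen
}

benchmark_fit <- function() {
  if (is.null(bench_env$fit)) {
    bench_env$fit <- suppressWarnings(gppm_fit(
      benchmark_gen()$cohort, benchmark_specs(),
      gppm_control(max_iter = 30, seed = 1)))
  }
  bench_env$fit
}

## hand-built cohort from a long data frame (fills default covariates)
make_cohort <- function(data, covariates = NULL) {
  if (is.null(covariates)) {
    ids <- unique(data$subject_id)
    covariates <- data.frame(subject_id = ids, age_onset = 38, sex = "M",
                             treatment = "active", trial = "T1",
                             stringsAsFactors = FALSE)
  }
  if (!"trial" %in% names(data)) data$trial <- "T1"
  longitudinal_cohort(data, covariates)
}

## regular-visit cohort where marker values follow value_fn(tau)
cohort_from_fn <- function(value_fn, n = 20, markers = "A",
                           baselines = seq(2, 10, length.out = n),
                           n_visits = 8, visit_gap = 0.25, noise = 0,
                           seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n), function(s) {
    t <- baselines[s] + (seq_len(n_visits) - 1) * visit_gap
    do.call(rbind, lapply(markers, function(mk) {
      data.frame(subject_id = sprintf("S%03d", s), trial = "T1",
                 visit_time_years = t, marker = mk,
                 value = pmin(1, pmax(0, value_fn(t, mk) +
                                        stats::rnorm(length(t), 0, noise))),
                 stringsAsFactors = FALSE)
    }))
  }))
  make_cohort(rows)
}
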