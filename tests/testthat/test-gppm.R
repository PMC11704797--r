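sig <- function(t, mid = 8, rate = 0.3, lo = 0.05, hi = 0.95) {
  lo + (hi - lo) * stats::plogis(rate * (t - mid))
}

test_that("identical subjects receive identical (centred) shifts", {
  t <- seq(3, 7, by = 0.5)
  rows <- do.call(rbind, lapply(1:5, function(s) {
    data.frame(subject_id = paste0("S", s), trial = "T1",
               visit_time_years = t, marker = "A", value = sig(t),
               stringsAsFactors = FALSE)
  }))
  fit <- suppressWarnings(gppm_fit(make_cohort(rows), marker_spec("A"),
                                   gppm_control(max_iter = 8, seed = 1)))
  expect_lt(max(abs(fit$shifts$d_mean)), 1e-6)
  expect_true(all(fit$shifts$d_sd > 0))
})

test_that("a noise-free monotone trajectory is recovered closely", {
  coh <- cohort_from_fn(function(t, mk) sig(t), n = 30,
                        baselines = seq(1, 12, length.out = 30),
                        n_visits = 8, visit_gap = 0.3, noise = 0)
  fit <- suppressWarnings(gppm_fit(coh, marker_spec("A"),
                                   gppm_control(max_iter = 20, seed = 1)))
  tr <- range(coh$data$visit_time_years)
  grid <- seq(tr[1], tr[2], length.out = 150)
  est <- trajectory_mean(fit, grid)[, 1]
  ## shifts stay near zero (identical trajectories, prior prefers 0)
  expect_lt(stats::sd(fit$shifts$d_mean), 0.6)
  expect_lt(max(abs(est - sig(grid + mean(fit$shifts$d_mean)))), 0.05)
})

test_that("an all-missing marker is dropped and does not perturb the fit", {
  coh2 <- cohort_from_fn(function(t, mk) {
    if (mk == "A") sig(t) else sig(t, mid = 12)
  }, n = 15, markers = c("A", "B"), noise = 0.04, seed = 2)
  specs3 <- rbind(marker_spec("A"), marker_spec("B"), marker_spec("C"))
  expect_warning(
    fit3 <- gppm_fit(coh2, specs3, gppm_control(max_iter = 8, seed = 1)),
    "no observations")
  fit2 <- suppressWarnings(gppm_fit(coh2, specs3[1:2, ],
                                    gppm_control(max_iter = 8, seed = 1)))
  expect_identical(fit3$markers, c("A", "B"))
  expect_equal(fit3$shifts$d_mean, fit2$shifts$d_mean, tolerance = 1e-10)
  expect_equal(fit3$dropped_markers, "C")
})

test_that("both monotonicity directions are honoured on the fitted means", {
  coh <- cohort_from_fn(function(t, mk) {
    if (mk == "UP") sig(t) else 1 - sig(t, mid = 10)
  }, n = 25, markers = c("UP", "DOWN"), noise = 0.05, seed = 3)
  specs <- rbind(marker_spec("UP", FALSE, "non-decreasing", "higher"),
                 marker_spec("DOWN", FALSE, "non-increasing", "lower"))
  fit <- suppressWarnings(gppm_fit(coh, specs,
                                   gppm_control(max_iter = 12, seed = 1)))
  grid <- seq(fit$span[1], fit$span[2], length.out = 200)
  est <- trajectory_mean(fit, grid)
  expect_true(all(diff(est[, "UP"]) >= -1e-3))
  expect_true(all(diff(est[, "DOWN"]) <= 1e-3))
})

test_that("posterior trajectory sampling is seeded and converges to the mean", {
  fit <- benchmark_fit()
  grid <- seq(fit$span[1], fit$span[2], length.out = 60)
  s1 <- sample_trajectories(fit, n_samples = 100, grid = grid, seed = 4)
  expect_equal(names(s1), fit$markers)
  expect_equal(dim(s1[[1]]), c(100, 60))
  ## seeded determinism, including single draws
  expect_identical(sample_trajectories(fit, 1, grid, seed = 9),
                   sample_trajectories(fit, 1, grid, seed = 9))
  ## Monte-Carlo convergence: mean of draws within 3 MC SEs of the mean
  big <- sample_trajectories(fit, n_samples = 5000, grid = grid, seed = 5)
  mu <- trajectory_mean(fit, grid)
  for (k in seq_along(fit$markers)) {
    se <- apply(big[[k]], 2, stats::sd) / sqrt(5000)
    expect_true(all(abs(colMeans(big[[k]]) - mu[, k]) <= 3 * se + 1e-8))
  }
  expect_error(sample_trajectories(fit, 10, grid = numeric(0)),
               class = "ppmsprog_config_error")
})

test_that("percent change reflects the traversed score range", {
  ## flat marker: no change
  flat <- cohort_from_fn(function(t, mk) 0.5, n = 12, noise = 0.02, seed = 6)
  fit_flat <- suppressWarnings(gppm_fit(flat, marker_spec("A"),
                                        gppm_control(max_iter = 8, seed = 1)))
  expect_lt(percent_change(fit_flat, seed = 2)$mean, 5)
  ## steep marker traversing most of the range
  steep <- cohort_from_fn(function(t, mk) sig(t, mid = 6, rate = 0.8),
                          n = 25, baselines = seq(0.5, 12, length.out = 25),
                          noise = 0.03, seed = 7)
  fit_steep <- suppressWarnings(gppm_fit(steep, marker_spec("A"),
                                         gppm_control(max_iter = 12, seed = 1)))
  pc <- percent_change(fit_steep, seed = 2)
  expect_gt(pc$mean, 70)
  expect_lt(pc$mean, 101)
  expect_equal(pc$mean, pc$median, tolerance = 0.15)
})

test_that("timeline span reduces to the observed range without shifts", {
  t <- seq(2, 9, by = 1)
  rows <- do.call(rbind, lapply(1:4, function(s) {
    data.frame(subject_id = paste0("S", s), trial = "T1",
               visit_time_years = t, marker = "A", value = sig(t),
               stringsAsFactors = FALSE)
  }))
  fit <- suppressWarnings(gppm_fit(make_cohort(rows), marker_spec("A"),
                                   gppm_control(max_iter = 8, seed = 1)))
  expect_equal(timeline_span(fit), diff(range(t)), tolerance = 0.05)
  ## degenerate: two subjects, one identical visit each
  rows1 <- data.frame(subject_id = c("S1", "S2"), trial = "T1",
                      visit_time_years = c(4, 4), marker = "A",
                      value = c(0.4, 0.4), stringsAsFactors = FALSE)
  fit1 <- suppressWarnings(gppm_fit(make_cohort(rows1), marker_spec("A"),
                                    gppm_control(max_iter = 5, seed = 1)))
  expect_equal(timeline_span(fit1), 0, tolerance = 1e-8)
})

test_that("staging handles on-curve, empty and unknown-marker subjects", {
  fit <- benchmark_fit()
  ## a subject lying exactly on the population mean stages at ~0 shift
  t <- seq(5, 7.5, by = 0.25)
  mu <- trajectory_mean(fit, t)
  rows <- do.call(rbind, lapply(seq_along(fit$markers), function(k) {
    data.frame(subject_id = "NEW1", trial = "T1", visit_time_years = t,
               marker = fit$markers[k], value = mu[, k],
               stringsAsFactors = FALSE)
  }))
  st <- stage_new_subjects(fit, make_cohort(rows))
  expect_lt(abs(st$d_mean), 0.5)
  expect_equal(st$rdd_baseline, min(t) - st$d_mean)
  ## zero usable observations
  empty_cov <- data.frame(subject_id = c("NEW1", "GHOST"), age_onset = 40,
                          sex = "F", treatment = "placebo", trial = "T1",
                          stringsAsFactors = FALSE)
  coh_empty <- longitudinal_cohort(rows, empty_cov)
  expect_error(stage_new_subjects(fit, coh_empty),
               class = "ppmsprog_staging_error")
  st2 <- stage_new_subjects(fit, coh_empty, on_empty = "skip")
  expect_equal(nrow(st2), 1)
  ## unknown marker
  rows_bad <- rows
  rows_bad$marker[1] <- "MYSTERY"
  expect_error(stage_new_subjects(fit, make_cohort(rows_bad)),
               class = "ppmsprog_unknown_marker")
})

test_that("peak ordering flags flat markers and spreads linear ones", {
  ## flat marker reported last with infinite-width interval
  coh <- cohort_from_fn(function(t, mk) {
    if (mk == "S") sig(t) else 0.5
  }, n = 20, markers = c("S", "F"), noise = 0.02, seed = 8)
  specs <- rbind(marker_spec("S"), marker_spec("F"))
  fit <- suppressWarnings(gppm_fit(coh, specs,
                                   gppm_control(max_iter = 10, seed = 1)))
  expect_warning(ord <- peak_rate_ordering(fit, n_samples = 50, seed = 2),
                 "undefined peak")
  expect_identical(ord$marker[nrow(ord)], "F")
  expect_true(ord$undefined[nrow(ord)])
  expect_identical(ord$upper[nrow(ord)] - ord$lower[nrow(ord)], Inf)
  ## linear trajectory: peak position uncertain across most of the span
  lin <- cohort_from_fn(function(t, mk) 0.03 + 0.065 * t, n = 40,
                        baselines = seq(0.5, 12, length.out = 40),
                        noise = 0.01, seed = 9)
  fit_lin <- suppressWarnings(gppm_fit(lin, marker_spec("A"),
                                       gppm_control(max_iter = 10, seed = 1)))
  ord_lin <- peak_rate_ordering(fit_lin, n_samples = 300, seed = 3)
  expect_gt((ord_lin$upper - ord_lin$lower) / diff(fit_lin$span), 0.8)
  ## two identical markers tie within Monte-Carlo tolerance
  twin <- cohort_from_fn(function(t, mk) sig(t), n = 25,
                         markers = c("A", "B"), noise = 0.03, seed = 10)
  fit_twin <- suppressWarnings(gppm_fit(
    twin, rbind(marker_spec("A"), marker_spec("B")),
    gppm_control(max_iter = 10, seed = 1)))
  ord_twin <- peak_rate_ordering(fit_twin, n_samples = 300, seed = 4)
  expect_lt(abs(diff(ord_twin$tau_peak)), 2)
})

test_that("a fitted model survives a JSON round trip", {
  fit <- benchmark_fit()
  path <- tempfile(fileext = ".json")
  save_gppm(fit, path)
  fit2 <- load_gppm(path)
  grid <- seq(fit$span[1], fit$span[2], length.out = 50)
  expect_equal(trajectory_mean(fit2, grid), trajectory_mean(fit, grid),
               tolerance = 1e-8)
  newcoh <- generate_cohort(sim_config(n_subjects = 20,
                                       specs = benchmark_specs(),
                                       shift_sd = 3, seed = 77))$cohort
  expect_equal(stage_new_subjects(fit2, newcoh)$d_mean,
               stage_new_subjects(fit, newcoh)$d_mean, tolerance = 1e-6)
  unlink(path)
})
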