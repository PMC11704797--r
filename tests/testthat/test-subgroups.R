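test_that("the SD rule partitions subjects with the stated orientation", {
  delta <- c(a = 0, b = 1, c = -1, d = 5, e = -5, f = 0.5)
  cl <- classify_progressors(delta, k_sd = 1)
  expect_equal(sum(cl$counts), length(delta))
  ## centre of the distribution is normative
  expect_identical(cl$assignment$label[cl$assignment$delta_years == 0], "G2")
  ## upper tail fast, lower tail slow
  expect_identical(cl$assignment$label[cl$assignment$delta_years == 5], "G3")
  expect_identical(cl$assignment$label[cl$assignment$delta_years == -5], "G1")
  ## sign-flip convention flag
  cl_flip <- classify_progressors(delta, k_sd = 1, flip_sign = TRUE)
  expect_identical(cl_flip$assignment$label[
    cl_flip$assignment$delta_years == 5], "G3")
})

test_that("Gaussian tails give the textbook normative fractions", {
  set.seed(20)
  delta <- stats::rnorm(10000, 2, 3)
  g2_frac <- function(k) {
    cl <- classify_progressors(delta, k_sd = k)
    as.numeric(cl$counts["G2"]) / 10000
  }
  expect_lt(abs(g2_frac(1) - 0.683), 0.015)
  expect_lt(abs(g2_frac(2) - 0.954), 0.010)
})

test_that("raising the cutoff never expels a normative subject", {
  set.seed(21)
  delta <- stats::rnorm(400, 0, 2)
  labs <- lapply(c(1, 1.5, 2), function(k) {
    classify_progressors(delta, k_sd = k)$assignment$label
  })
  for (i in 1:2) {
    expect_true(all(!(labs[[i]] == "G2" & labs[[i + 1]] != "G2")))
  }
})

test_that("degenerate shift distributions are rejected", {
  expect_error(classify_progressors(rep(1.5, 10)),
               class = "ppmsprog_degenerate_distribution")
  expect_error(classify_progressors(c(a = 1)), class = "ppmsprog_config_error")
  expect_error(classify_progressors(c(1, 2), k_sd = 0),
               class = "ppmsprog_config_error")
})

test_that("the ODD-only null model mirrors the SD rule on durations", {
  set.seed(22)
  n <- 10000
  odd <- stats::rnorm(n, 8, 4)
  dat <- data.frame(subject_id = sprintf("S%05d", 1:n), trial = "T1",
                    visit_time_years = pmax(0, odd), marker = "EDSS",
                    value = 0.5, stringsAsFactors = FALSE)
  coh <- make_cohort(dat)
  nc <- null_classify(coh)
  expect_lt(abs(as.numeric(nc$counts["G2"]) / n - 0.683), 0.02)
  ## an extreme-duration subject is in the upper tail
  top <- nc$assignment$subject_id[which.max(nc$assignment$delta_years)]
  expect_identical(nc$assignment$label[nc$assignment$subject_id == top], "G3")
  ## all-identical durations degenerate
  same <- make_cohort(data.frame(subject_id = paste0("S", 1:5), trial = "T1",
                                 visit_time_years = 5, marker = "EDSS",
                                 value = 0.5, stringsAsFactors = FALSE))
  expect_error(null_classify(same),
               class = "ppmsprog_degenerate_distribution")
  ## subjects without any observation are excluded with a warning
  cov2 <- rbind(coh$covariates[1:50, ],
                data.frame(subject_id = "NOVISIT", age_onset = 38, sex = "M",
                           treatment = "active", trial = "T1"))
  coh2 <- longitudinal_cohort(dat[dat$subject_id %in% cov2$subject_id, ],
                              cov2)
  expect_warning(nc2 <- null_classify(coh2), "missing disease duration")
  expect_false("NOVISIT" %in% nc2$assignment$subject_id)
})

test_that("baseline tables use the right tests and calibrate under the null", {
  ## a balanced binary variable gives a chi-squared statistic near zero
  set.seed(23)
  n <- 240
  grp <- rep(c("G1", "G2", "G3"), each = n / 3)
  dat <- data.frame(subject_id = sprintf("S%03d", 1:n), trial = "T1",
                    visit_time_years = stats::runif(n, 2, 10),
                    marker = "EDSS", value = stats::runif(n),
                    stringsAsFactors = FALSE)
  cov <- data.frame(subject_id = dat$subject_id, age_onset = 38,
                    sex = rep(c("M", "F"), n / 2), treatment = "active",
                    trial = "T1", stringsAsFactors = FALSE)
  coh <- longitudinal_cohort(dat, cov)
  asg <- structure(list(assignment = data.frame(
    subject_id = dat$subject_id, delta_years = 0, label = grp,
    stringsAsFactors = FALSE)), class = "subgroup_assignment")
  tab <- compare_baseline_characteristics(coh, asg)
  expect_lt(tab$statistic[tab$variable == "sex"], 1e-6)
  expect_true(all(c("G1", "G2", "G3") %in% names(tab)))

  ## calibration and power of the table's continuous test, through the
  ## package surface: age_onset is the probed variable
  table_p <- function(age, n_per = length(age) / 3, seed) {
    ids <- sprintf("P%04d", seq_along(age))
    dat2 <- data.frame(subject_id = ids, trial = "T1",
                       visit_time_years = 5, marker = "EDSS", value = 0.5,
                       stringsAsFactors = FALSE)
    cov2 <- data.frame(subject_id = ids, age_onset = age, sex = "M",
                       treatment = "active", trial = "T1",
                       stringsAsFactors = FALSE)
    asg2 <- structure(list(assignment = data.frame(
      subject_id = ids, delta_years = 0,
      label = rep(c("G1", "G2", "G3"), each = n_per),
      stringsAsFactors = FALSE)), class = "subgroup_assignment")
    tb <- compare_baseline_characteristics(longitudinal_cohort(dat2, cov2),
                                           asg2, continuous_test = "anova")
    tb$p_value[tb$variable == "age_onset"]
  }
  set.seed(24)
  pvals <- replicate(200, table_p(stats::rnorm(120, 38, 8)))
  expect_lt(unname(suppressWarnings(
    stats::ks.test(pvals, "punif"))$statistic), 0.10)

  ## power: 1-SD separated group means, n = 200 per group
  set.seed(25)
  hits <- replicate(30, {
    age <- c(stats::rnorm(200, 38, 8), stats::rnorm(200, 42, 8),
             stats::rnorm(200, 46, 8))
    table_p(age) < 0.001
  })
  expect_gte(mean(hits), 0.95)
})
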