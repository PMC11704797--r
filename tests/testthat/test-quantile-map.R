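## small raw-scale cohort over two oriented markers
qm_cohort <- function(seed = 1, n = 30) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n), function(s) {
    t <- 2 + s / 10 + 0:2
    data.frame(subject_id = sprintf("S%03d", s), trial = "T1",
               visit_time_years = t,
               marker = rep(c("T25FW", "SDMT"), each = 3),
               value = c(exp(rnorm(3, 2, 0.4)), round(rnorm(3, 45, 8))),
               stringsAsFactors = FALSE)
  }))
  make_cohort(rows)
}

specs2 <- rbind(
  marker_spec("T25FW", TRUE, "non-decreasing", "higher"),
  marker_spec("SDMT", FALSE, "non-increasing", "lower")
)

test_that("quantile scores follow the mid-distribution convention", {
  coh <- qm_cohort()
  qm <- fit_quantile_map(coh, specs2)
  ## odd-n median scores exactly 0.5
  x <- coh$data$value[coh$data$marker == "T25FW"][1:31]
  coh_odd <- make_cohort(data.frame(
    subject_id = sprintf("S%03d", 1:31), trial = "T1",
    visit_time_years = 1:31, marker = "T25FW", value = sort(x)))
  qm_odd <- fit_quantile_map(coh_odd, specs2[1, ])
  expect_equal(quantile_score(qm_odd, "T25FW", stats::median(x)), 0.5)
  ## frozen brute-force value: reference {1,2,3,4}, query 2, worse_is=higher
  coh4 <- make_cohort(data.frame(subject_id = "S1", trial = "T1",
                                 visit_time_years = 1:4, marker = "M",
                                 value = c(1, 2, 3, 4)))
  qm4 <- fit_quantile_map(coh4, marker_spec("M", FALSE, "non-decreasing",
                                            "higher"))
  expect_equal(quantile_score(qm4, "M", 2),
               oracle_quantile(c(1, 2, 3, 4), 2))
  expect_equal(quantile_score(qm4, "M", 2), 0.375)
})

test_that("orientation flips low-is-worse markers to abnormal-high", {
  coh <- qm_cohort()
  qm <- fit_quantile_map(coh, specs2)
  sdmt <- coh$data$value[coh$data$marker == "SDMT"]
  n <- length(sdmt)
  ## best cognition scores (at most) the half-tie mass; worst scores ~1
  expect_lte(quantile_score(qm, "SDMT", max(sdmt)), 1 / (2 * n) + 1e-12)
  expect_gte(quantile_score(qm, "SDMT", min(sdmt)), 1 - 1 / (2 * n) - 1e-12)
  ## out-of-range clamping on a worse_is=higher marker
  t25 <- coh$data$value[coh$data$marker == "T25FW"]
  expect_equal(quantile_score(qm, "T25FW", min(t25) - 10), 0)
  expect_equal(quantile_score(qm, "T25FW", max(t25) + 10), 1)
})

test_that("scores match the brute-force oracle across random queries", {
  coh <- qm_cohort(seed = 7)
  qm <- fit_quantile_map(coh, specs2)
  t25 <- coh$data$value[coh$data$marker == "T25FW"]
  sdmt <- coh$data$value[coh$data$marker == "SDMT"]
  set.seed(99)
  for (x in c(sample(t25, 20), stats::runif(20, min(t25), max(t25)))) {
    expect_equal(quantile_score(qm, "T25FW", x),
                 oracle_quantile(t25, x, log_transform = TRUE))
  }
  for (x in sample(sdmt, 25)) {
    expect_equal(quantile_score(qm, "SDMT", x),
                 oracle_quantile(sdmt, x, flip = TRUE))
  }
})

test_that("mapping its own reference data yields uniform scores", {
  set.seed(3)
  vals <- stats::rlnorm(1000, 2, 0.5)
  coh <- make_cohort(data.frame(subject_id = sprintf("S%04d", 1:1000),
                                trial = "T1", visit_time_years = 1:1000,
                                marker = "T25FW", value = vals))
  qm <- fit_quantile_map(coh, specs2[1, ])
  mapped <- apply_quantile_map(qm, coh)
  sc <- mapped$data$value
  expect_true(all(sc >= 0 & sc <= 1))
  ks <- suppressWarnings(stats::ks.test(sc, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  ## monotone in abnormality
  ord <- order(vals)
  expect_true(all(diff(sc[ord]) >= 0))
})

test_that("quantile mapping of scores is idempotent and keeps missingness", {
  set.seed(4)
  vals <- stats::runif(200)
  vals[c(5, 50)] <- NA
  coh <- make_cohort(data.frame(subject_id = sprintf("S%03d", 1:200),
                                trial = "T1", visit_time_years = 1:200,
                                marker = "M", value = vals))
  id_spec <- marker_spec("M", FALSE, "non-decreasing", "higher")
  qm1 <- fit_quantile_map(coh, id_spec)
  m1 <- apply_quantile_map(qm1, coh)
  qm2 <- fit_quantile_map(m1, id_spec)
  m2 <- apply_quantile_map(qm2, m1)
  expect_equal(m2$data$value, m1$data$value, tolerance = 1e-12)
  expect_true(all(is.na(m1$data$value[is.na(vals)])))
})

test_that("degenerate inputs raise classed errors", {
  coh <- qm_cohort()
  one_obs <- make_cohort(data.frame(subject_id = "S1", trial = "T1",
                                    visit_time_years = 1, marker = "T25FW",
                                    value = 5))
  expect_error(fit_quantile_map(one_obs, specs2[1, ]),
               class = "ppmsprog_insufficient_data")
  qm <- fit_quantile_map(coh, specs2)
  expect_error(quantile_score(qm, "NBV", 1000),
               class = "ppmsprog_unknown_marker")
  bad <- coh
  bad$data$marker[1] <- "UNKNOWN"
  expect_error(apply_quantile_map(qm, bad),
               class = "ppmsprog_unknown_marker")
})

test_that("quantile maps serialize and reload without loss", {
  coh <- qm_cohort(seed = 12)
  qm <- fit_quantile_map(coh, specs2)
  path <- tempfile(fileext = ".json")
  write_quantile_map(qm, path)
  qm2 <- read_quantile_map(path)
  qs <- seq(0.5, 60, length.out = 40)
  expect_equal(quantile_score(qm2, "T25FW", qs),
               quantile_score(qm, "T25FW", qs), tolerance = 1e-12)
  expect_equal(score_directions(qm2), score_directions(qm))
  unlink(path)
})
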