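#' Classify slow / normative / fast progressors
#'
#' Partitions subjects by their time-reparametrization parameter
#' \eqn{\delta_s} (years), defined as reparametrized minus observed disease
#' duration at baseline (RDD - ODD): subjects staged further along the
#' disease-time axis than their reported duration suggests have
#' \eqn{\delta > 0} and progress fast.  Normative progressors (G2) lie
#' within \eqn{k} sample SDs of the population mean \eqn{\delta}; slow
#' progressors (G1) fall below, fast progressors (G3) above.
#'
#' @param delta named numeric vector of per-subject reparametrization
#'   parameters (years), or a `gppm_model` from which they are extracted.
#' @param k_sd cutoff multiplier (default 1; 1.5 and 2 are the usual
#'   sensitivity settings).
#' @param flip_sign set `TRUE` if `delta` is supplied with the opposite sign
#'   convention (ODD - RDD).
#' @return An object of class `subgroup_assignment`: list with `assignment`
#'   (data frame `subject_id`, `delta_years`, `label`), `mean`, `sd`,
#'   `k_sd`, and the group `counts`.
#' @export
classify_progressors <- function(delta, k_sd = 1.0, flip_sign = FALSE) {
  if (inherits(delta, "gppm_model")) delta <- reparam_delta(delta)
  check_scalar(k_sd, "k_sd", lower = 0, strict = TRUE)
  delta <- delta[!is.na(delta)]
  if (length(delta) < 2L) {
    stop_ppms("need >= 2 subjects to classify", "ppmsprog_config_error")
  }
  if (flip_sign) delta <- -delta
  mu <- mean(delta)
  sd_ <- stats::sd(delta)
  if (sd_ <= 0) {
    stop_ppms("degenerate delta distribution (zero variance)",
              "ppmsprog_degenerate_distribution")
  }
  z <- (delta - mu) / sd_
  label <- ifelse(z < -k_sd, "G1", ifelse(z > k_sd, "G3", "G2"))
  ids <- names(delta)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(delta))
  assignment <- data.frame(subject_id = ids, delta_years = unname(delta),
                           label = label, stringsAsFactors = FALSE)
  structure(list(
    assignment = assignment, mean = mu, sd = sd_, k_sd = k_sd,
    counts = table(factor(label, levels = c("G1", "G2", "G3")))
  ), class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  n <- nrow(x$assignment)
  cat(sprintf("<subgroup_assignment> k = %.2g SD, n = %d\n", x$k_sd, n))
  pct <- 100 * as.numeric(x$counts) / n
  cat(sprintf("  G1 (slow) %d (%.1f%%) | G2 (normative) %d (%.1f%%) | G3 (fast) %d (%.1f%%)\n",
              x$counts[1], pct[1], x$counts[2], pct[2], x$counts[3], pct[3]))
  invisible(x)
}

#' Null-model classification from observed disease duration only
#'
#' Comparator that applies the same \eqn{\pm k} SD rule to baseline observed
#' disease duration (ODD) instead of the model's reparametrization
#' parameter.  Baseline ODD plays the role of the staging variable:
#' subjects more than \eqn{k} SD above the mean duration land in the upper
#' tail (G3), those below in the lower tail (G1).  Subjects with missing
#' duration are excluded with a warning.
#'
#' @param cohort a `ppms_cohort`.
#' @param k_sd cutoff multiplier.
#' @return a `subgroup_assignment` (the `delta_years` column holds the
#'   centred ODD).
#' @export
null_classify <- function(cohort, k_sd = 1.0) {
  odd <- baseline_odd(cohort)
  bad <- is.na(odd)
  if (any(bad)) {
    warning(sprintf("%d subject(s) with missing disease duration excluded",
                    sum(bad)))
    odd <- odd[!bad]
  }
  out <- classify_progressors(as.numeric(odd) - mean(as.numeric(odd)),
                              k_sd = k_sd)
  out$assignment$subject_id <- names(odd)
  out
}

#' Baseline characteristics by subgroup, with three-group tests
#'
#' Summarizes baseline covariates and first-visit marker values per subgroup
#' and tests for differences: chi-squared for categorical variables, ANOVA
#' or Kruskal-Wallis for continuous ones.  P-values are two-sided and
#' uncorrected.
#'
#' @param cohort a `ppms_cohort`.
#' @param assignment a `subgroup_assignment`.
#' @param continuous_test `"auto"` (Shapiro normality screen on pooled
#'   residuals decides), `"anova"`, or `"kruskal"`.
#' @return data frame: one row per variable with per-group summaries, the
#'   test used, its statistic and p-value.
#' @export
compare_baseline_characteristics <- function(cohort, assignment,
                                             continuous_test = c("auto", "anova", "kruskal")) {
  continuous_test <- match.arg(continuous_test)
  lab <- stats::setNames(assignment$assignment$label,
                         assignment$assignment$subject_id)
  cov <- cohort$covariates[cohort$covariates$subject_id %in% names(lab), ]
  cov$group <- lab[cov$subject_id]
  groups <- names(which(table(cov$group) > 0))
  if (length(groups) < 2L) {
    stop_ppms("need >= 2 non-empty groups", "ppmsprog_config_error")
  }
  empty <- setdiff(c("G1", "G2", "G3"), groups)
  if (length(empty)) warning("empty group(s) excluded from tests: ",
                             paste(empty, collapse = ", "))

  ## first-visit marker values, wide
  dat <- cohort$data
  bl <- dat[stats::ave(dat$visit_time_years,
                       paste(dat$subject_id, dat$marker),
                       FUN = min) == dat$visit_time_years, ]
  for (m in unique(bl$marker)) {
    v <- bl[bl$marker == m, c("subject_id", "value")]
    cov[[paste0("baseline_", m)]] <- v$value[match(cov$subject_id,
                                                   v$subject_id)]
  }

  vars <- setdiff(names(cov), c("subject_id", "group"))
  rows <- lapply(vars, function(v) {
    tryCatch(summarize_one_variable(cov, v, groups, continuous_test),
             error = function(e) {
               data.frame(variable = v, test = "none",
                          statistic = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE)
             })
  })
  rows <- lapply(rows, function(r) {
    for (gg in groups) if (!gg %in% names(r)) r[[gg]] <- NA_character_
    r[, c("variable", "test", "statistic", "p_value", groups)]
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @noRd
summarize_one_variable <- function(cov, v, groups, continuous_test) {
    x <- cov[[v]]
    g <- factor(cov$group, levels = groups)
    if (is.numeric(x)) {
      use_kw <- continuous_test == "kruskal"
      if (continuous_test == "auto") {
        res <- stats::residuals(stats::lm(x ~ g, na.action = stats::na.exclude))
        res <- res[!is.na(res)]
        if (length(res) >= 8) {
          sh <- stats::shapiro.test(res[seq_len(min(5000, length(res)))])
          use_kw <- sh$p.value < 0.05
        }
      }
      if (use_kw) {
        tt <- stats::kruskal.test(x, g)
        summ <- tapply(x, g, function(z) sprintf(
          "%.2f (%.2f-%.2f)", stats::median(z, na.rm = TRUE),
          stats::quantile(z, 0.25, na.rm = TRUE),
          stats::quantile(z, 0.75, na.rm = TRUE)))
        test <- "kruskal-wallis"
      } else {
        tt <- stats::oneway.test(x ~ g, var.equal = TRUE)
        summ <- tapply(x, g, function(z) sprintf(
          "%.2f (%.2f)", mean(z, na.rm = TRUE), stats::sd(z, na.rm = TRUE)))
        test <- "anova"
      }
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      tab <- table(x, g)
      tt <- suppressWarnings(stats::chisq.test(tab))
      summ <- vapply(groups, function(gg) {
        n1 <- sum(x == x[!is.na(x)][1] & cov$group == gg, na.rm = TRUE)
        ng <- sum(cov$group == gg)
        sprintf("%d (%.1f%%)", n1, 100 * n1 / max(ng, 1))
      }, character(1))
      test <- "chi-squared"
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    out <- data.frame(variable = v, test = test, statistic = stat,
                      p_value = p, stringsAsFactors = FALSE)
    for (gg in groups) out[[gg]] <- unname(summ[gg])
    out
}
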