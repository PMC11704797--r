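#' @noRd
event_time_col <- function(events) {
  if ("time_months" %in% names(events)) "time_months"
  else if ("time_years" %in% names(events)) "time_years"
  else stop_ppms("event table needs a time_months or time_years column",
                 "ppmsprog_config_error")
}

#' @noRd
check_risk_set <- function(events, tcol) {
  if (nrow(events) == 0L || all(events[[tcol]] <= 0 & events$event == 0)) {
    stop_ppms("empty risk set: no follow-up time in the event table",
              "ppmsprog_empty_risk_set")
  }
}

#' Cox proportional-hazards contrasts between progressor subgroups
#'
#' Fits univariable and multivariable Cox models (Efron tie handling) with
#' the normative group (G2) as reference, reporting hazard ratios with 95\%
#' CIs and p-values for the slow-vs-normative (G1 vs G2) and
#' fast-vs-normative (G3 vs G2) contrasts.  The multivariable model adjusts
#' for age at symptom onset, sex and treatment arm (when present); an
#' optional treatment-by-subgroup interaction can be added as a sensitivity
#' analysis.  A contrast whose group has no events is reported as
#' inestimable rather than dropped.
#'
#' @param events event table from [build_event_table()] or
#'   [generate_survival_overlay()], with columns `event`, `group` and a time
#'   column.
#' @param covariates covariate names for the multivariable model.
#' @param interaction add a treatment-by-subgroup interaction term.
#' @return list of class `cox_result`: `table` (one row per contrast and
#'   model), the fitted `survival::coxph` objects, and `interaction_p` when
#'   requested.
#' @export
fit_cox <- function(events, covariates = c("age_onset", "sex", "treatment"),
                    interaction = FALSE) {
  tcol <- event_time_col(events)
  check_risk_set(events, tcol)
  events <- events[!is.na(events$group), , drop = FALSE]
  events$group <- factor(events$group, levels = c("G2", "G1", "G3"))
  covariates <- intersect(covariates, names(events))
  ev_by_group <- tapply(events$event, events$group, sum)

  surv <- survival::Surv(events[[tcol]], events$event)
  fit_uni <- survival::coxph(surv ~ group, data = events, ties = "efron")
  fit_multi <- survival::coxph(
    stats::as.formula(paste("surv ~", paste(c("group", covariates),
                                            collapse = " + "))),
    data = events, ties = "efron")

  extract <- function(fit, model_label) {
    sm <- summary(fit)
    rows <- lapply(c(G1 = "groupG1", G3 = "groupG3"), function(cf) {
      grp <- sub("group", "", cf)
      if (!cf %in% rownames(sm$coefficients) ||
          is.na(ev_by_group[grp]) || ev_by_group[grp] == 0 ||
          ev_by_group["G2"] == 0) {
        return(data.frame(contrast = paste(grp, "vs G2"), model = model_label,
                          hr = NA_real_, lo95 = NA_real_, hi95 = NA_real_,
                          p = NA_real_, n_events = unname(ev_by_group[grp]),
                          note = "inestimable (no events in a group)",
                          stringsAsFactors = FALSE))
      }
      co <- sm$coefficients[cf, ]
      ci <- sm$conf.int[cf, ]
      data.frame(contrast = paste(grp, "vs G2"), model = model_label,
                 hr = unname(co["exp(coef)"]), lo95 = unname(ci["lower .95"]),
                 hi95 = unname(ci["upper .95"]),
                 p = unname(co["Pr(>|z|)"]),
                 n_events = unname(ev_by_group[grp]), note = "",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  table <- rbind(extract(fit_uni, "univariable"),
                 extract(fit_multi, "multivariable"))
  rownames(table) <- NULL

  interaction_p <- NULL
  fit_inter <- NULL
  if (interaction && "treatment" %in% names(events)) {
    fit_inter <- survival::coxph(
      stats::as.formula(paste("surv ~", paste(c("group", covariates,
                                                "group:treatment"),
                                              collapse = " + "))),
      data = events, ties = "efron")
    an <- stats::anova(fit_multi, fit_inter)
    interaction_p <- an[2, "Pr(>|Chi|)"]
  }
  structure(list(table = table, fit_univariable = fit_uni,
                 fit_multivariable = fit_multi, fit_interaction = fit_inter,
                 interaction_p = interaction_p,
                 events_by_group = ev_by_group),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result>\n")
  tb <- x$table
  tb$hr <- sprintf("%.2f (%.2f-%.2f)", tb$hr, tb$lo95, tb$hi95)
  print(tb[, c("contrast", "model", "hr", "p", "n_events", "note")],
        row.names = FALSE)
  if (!is.null(x$interaction_p)) {
    cat(sprintf("treatment-by-subgroup interaction p = %.3f\n",
                x$interaction_p))
  }
  invisible(x)
}

#' Kaplan-Meier medians per subgroup with a log-rank comparison
#'
#' Per-group Kaplan-Meier median survival time with 95\% CI, and the
#' log-rank test across groups (two-sided, uncorrected).  A median is
#' reported as not reached (`NA` with note) when survival never drops to
#' one half.
#'
#' @param events event table with `event`, `group` and a time column.
#' @return list of class `km_result`: `medians` data frame, `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, and the `survival::survfit` object.
#' @export
km_and_logrank <- function(events) {
  tcol <- event_time_col(events)
  check_risk_set(events, tcol)
  events <- events[!is.na(events$group), , drop = FALSE]
  groups <- unique(events$group)
  if (length(groups) < 2L) {
    stop_ppms("need >= 2 groups for a log-rank comparison",
              "ppmsprog_config_error")
  }
  events$group <- factor(events$group)
  surv <- survival::Surv(events[[tcol]], events$event)
  fit <- survival::survfit(surv ~ group, data = events, conf.type = "log-log")
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  medians <- data.frame(
    group = sub("^group=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median = tab[, "median"], lo95 = tab[, "0.95LCL"],
    hi95 = tab[, "0.95UCL"],
    note = ifelse(is.na(tab[, "median"]), "not reached", ""),
    stringsAsFactors = FALSE)
  rownames(medians) <- NULL
  sd_ <- tryCatch(survival::survdiff(surv ~ group, data = events),
                  error = function(e) NULL)
  if (is.null(sd_)) {
    ## degenerate risk structure (e.g. all events tied): statistic undefined
    sd_ <- list(chisq = NA_real_, n = table(events$group))
  }
  df <- length(sd_$n) - 1
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  structure(list(medians = medians, logrank_chisq = unname(sd_$chisq),
                 logrank_df = df, logrank_p = p, survfit = fit),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result>\n")
  print(x$medians, row.names = FALSE)
  cat(sprintf("log-rank chi-squared = %.2f on %d df, p = %.4g\n",
              x$logrank_chisq, x$logrank_df, x$logrank_p))
  invisible(x)
}
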