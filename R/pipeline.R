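#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input source: a [sim_config()] for a synthetic cohort, or a
#' pair of CSV paths (long-format measurements + covariates) for user data.
#'
#' @param sim a `sim_config`, or `NULL` when reading CSVs.
#' @param data_csv,covariates_csv input CSV paths (ignored when `sim` is
#'   given).
#' @param preprocess `"none"` (values already on the modelling scale) or
#'   `"quantile"` (fit and apply the abnormal-high quantile map).
#' @param specs marker specifications.
#' @param fit_control a [gppm_control()].
#' @param k_sd vector of SD-cutoff multipliers for the subgroup sensitivity
#'   analyses; the first element drives the outcome analyses.
#' @param endpoints CDP endpoints to analyse (markers must be present).
#' @param out_dir output directory.
#' @param seed master seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, data_csv = NULL, covariates_csv = NULL,
                       preprocess = c("none", "quantile"),
                       specs = default_marker_specs(),
                       fit_control = gppm_control(),
                       k_sd = c(1.0, 1.5, 2.0),
                       endpoints = c("EDSS", "T25FW", "EDSS6"),
                       out_dir = tempfile("ppmsprog_run_"),
                       seed = 1L) {
  preprocess <- match.arg(preprocess)
  has_sim <- !is.null(sim)
  has_csv <- !is.null(data_csv) && !is.null(covariates_csv)
  if (has_sim == has_csv) {
    stop_ppms("exactly one input source: `sim` or CSV paths",
              "ppmsprog_config_error")
  }
  if (any(k_sd <= 0)) {
    stop_ppms("k_sd values must be positive", "ppmsprog_config_error")
  }
  structure(list(sim = sim, data_csv = data_csv,
                 covariates_csv = covariates_csv, preprocess = preprocess,
                 specs = specs, fit_control = fit_control, k_sd = k_sd,
                 endpoints = endpoints, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @noRd
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' @noRd
table_header <- function(hash) {
  c(sprintf("# config_hash: %s", hash),
    sprintf("# ppmsprog %s | R %s | survival %s",
            as.character(utils::packageVersion("ppmsprog")),
            paste(R.version$major, R.version$minor, sep = "."),
            as.character(utils::packageVersion("survival"))))
}

#' @noRd
write_table_with_meta <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(table_header(hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run the full progression-modelling pipeline
#'
#' Simulate or load a cohort, preprocess, fit the monotonic GP progression
#' model, classify progressor subgroups at each SD cutoff, detect confirmed
#' disability progression on the requested endpoints, fit Cox contrasts and
#' Kaplan-Meier/log-rank comparisons, and write tables, figures and the
#' serialized model under `config$out_dir`.  Every artefact is reproducible
#' from the same config and seed; CSV/JSON artefacts are checksummed into
#' the report.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: artefact `paths`, `metrics`
#'   (timeline span, subgroup fractions, shift-recovery correlation when
#'   ground truth is available), `checksums`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- file.path(config$out_dir, "partial_manifest.json")
      jsonlite::write_json(list(failed_stage = name,
                                message = conditionMessage(e),
                                completed = names(paths)),
                           manifest, auto_unbox = TRUE)
      stop_ppms(sprintf("[stage %s] %s", name, conditionMessage(e)),
                "ppmsprog_stage_error")
    })
  }

  ## --- input ---------------------------------------------------------
  truth <- NULL
  cohort <- stage("input", {
    if (!is.null(config$sim)) {
      gen <- generate_cohort(config$sim)
      truth <- gen$truth
      gen$cohort
    } else {
      read_cohort(config$data_csv, config$covariates_csv, scale = "native")
    }
  })

  ## --- preprocess ----------------------------------------------------
  qmap <- NULL
  cohort_fit <- stage("preprocess", {
    if (config$preprocess == "quantile") {
      qmap <- fit_quantile_map(cohort, config$specs)
      paths$quantile_map <- file.path(config$out_dir, "quantile_map.json")
      write_quantile_map(qmap, paths$quantile_map)
      apply_quantile_map(qmap, cohort)
    } else cohort
  })

  ## --- fit -----------------------------------------------------------
  ctrl <- config$fit_control
  ctrl$seed <- config$seed
  model <- stage("fit", gppm_fit(cohort_fit, config$specs, ctrl))
  paths$model <- file.path(config$out_dir, "model.json")
  save_gppm(model, paths$model)

  ## --- subgroups -----------------------------------------------------
  assignments <- stage("subgroups", {
    lapply(config$k_sd, function(k) classify_progressors(model, k_sd = k))
  })
  names(assignments) <- paste0("k", config$k_sd)
  for (nm in names(assignments)) {
    a <- assignments[[nm]]
    df <- a$assignment
    df$cutoff_years <- a$k_sd * a$sd
    paths[[paste0("subgroups_", nm)]] <-
      write_table_with_meta(df, file.path(
        config$out_dir, paste0("subgroups_", nm, ".csv")), hash)
  }
  main_assign <- assignments[[1]]
  paths$baseline_table <- write_table_with_meta(
    stage("baseline_table",
          compare_baseline_characteristics(cohort, main_assign)),
    file.path(config$out_dir, "baseline_characteristics.csv"), hash)

  ## --- outcomes ------------------------------------------------------
  cox_tables <- list()
  km_list <- list()
  available <- unique(cohort$data$marker)
  for (ep in config$endpoints) {
    mk <- if (ep == "EDSS6") "EDSS" else ep
    if (!mk %in% available) {
      message("endpoint ", ep, " skipped: marker ", mk, " absent")
      next
    }
    et <- stage(paste0("events_", ep),
                suppressWarnings(build_event_table(cohort, ep, main_assign)))
    km_list[[ep]] <- stage(paste0("km_", ep), km_and_logrank(et))
    if (ep != "EDSS6") {
      cx <- stage(paste0("cox_", ep), fit_cox(et))
      tb <- cx$table
      tb$endpoint <- ep
      cox_tables[[ep]] <- tb
    }
  }
  if (length(cox_tables)) {
    paths$cox_table <- write_table_with_meta(
      do.call(rbind, cox_tables), file.path(config$out_dir, "cox_table.csv"),
      hash)
  }
  if (length(km_list)) {
    km_df <- do.call(rbind, lapply(names(km_list), function(ep) {
      md <- km_list[[ep]]$medians
      md$endpoint <- ep
      md$logrank_p <- km_list[[ep]]$logrank_p
      md
    }))
    paths$km_table <- write_table_with_meta(
      km_df, file.path(config$out_dir, "km_table.csv"), hash)
  }

  ## --- figures -------------------------------------------------------
  stage("figures", {
    paths$fig_trajectories <- file.path(config$out_dir, "trajectories.pdf")
    plot_trajectory_panel(model, paths$fig_trajectories, seed = config$seed)
    paths$fig_ordering <- file.path(config$out_dir, "peak_rate_ordering.pdf")
    ord <- peak_rate_ordering(model, seed = config$seed)
    plot_peak_ordering(ord, paths$fig_ordering)
    paths$fig_percent <- file.path(config$out_dir, "percent_change.pdf")
    plot_percent_change(percent_change(model, seed = config$seed),
                        paths$fig_percent)
    paths$fig_shifts <- file.path(config$out_dir, "shift_distribution.pdf")
    plot_shift_distribution(main_assign, paths$fig_shifts)
    if (length(km_list)) {
      paths$fig_km <- file.path(config$out_dir, "km_curves.pdf")
      plot_km_curves(km_list, paths$fig_km)
    }
    NULL
  })

  ## --- report --------------------------------------------------------
  metrics <- list(
    n_subjects = model$n_subjects,
    timeline_span_years = timeline_span(model),
    converged = model$converged,
    subgroup_pct = as.list(100 * as.numeric(main_assign$counts) /
                             nrow(main_assign$assignment))
  )
  names(metrics$subgroup_pct) <- c("G1", "G2", "G3")
  if (!is.null(truth)) {
    common <- intersect(names(truth$shifts), model$shifts$subject_id)
    metrics$shift_recovery_r <- stats::cor(
      truth$shifts[common],
      model$shifts$d_mean[match(common, model$shifts$subject_id)])
  }
  data_paths <- paths[!grepl("^fig_", names(paths))]
  checksums <- tools::md5sum(unlist(data_paths))
  report <- structure(list(paths = paths, metrics = metrics,
                           checksums = as.list(checksums),
                           config_hash = hash, assignments = assignments,
                           model = model, km = km_list),
                      class = "run_report")
  paths$report <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(list(metrics = metrics,
                            checksums = as.list(checksums),
                            config_hash = hash,
                            paths = lapply(paths, as.character)),
                       paths$report, auto_unbox = TRUE, digits = NA)
  report$paths <- paths
  report
}

#' Stage an external cohort with a trained model and analyse its outcomes
#'
#' Mirrors external validation: subjects of the test cohort are staged with
#' the training trajectories held fixed, subgroup cutoffs are recomputed on
#' the test-set reparametrization-parameter distribution (a carry-over mode
#' uses the training mean/SD instead), and endpoint contrasts are computed;
#' endpoints whose marker is missing from the test cohort are skipped with
#' a notice.
#'
#' @param model_path path to a model saved with [save_gppm()] (or a
#'   `gppm_model`).
#' @param cohort a `ppms_cohort`, or `data_csv`/`covariates_csv` paths.
#' @param data_csv,covariates_csv test cohort CSV paths (used when `cohort`
#'   is `NULL`).
#' @param k_sd SD-cutoff multiplier.
#' @param cutoffs `"recompute"` (default) or `"carry_over"`.
#' @param training_assignment required for carry-over cutoffs.
#' @param endpoints endpoints to analyse.
#' @return list: `staging` (per-subject shifts), `assignment`, `cox`
#'   (per endpoint), `km` (per endpoint), `skipped_endpoints`.
#' @export
stage_external <- function(model_path, cohort = NULL, data_csv = NULL,
                           covariates_csv = NULL, k_sd = 1.0,
                           cutoffs = c("recompute", "carry_over"),
                           training_assignment = NULL,
                           endpoints = c("EDSS", "T25FW")) {
  cutoffs <- match.arg(cutoffs)
  model <- if (inherits(model_path, "gppm_model")) model_path
           else load_gppm(model_path)
  if (is.null(cohort)) {
    if (is.null(data_csv) || is.null(covariates_csv)) {
      stop_ppms("supply `cohort` or both CSV paths", "ppmsprog_config_error")
    }
    cohort <- read_cohort(data_csv, covariates_csv)
  }
  if (nrow(cohort$data) == 0L) {
    stop_ppms("empty test cohort", "ppmsprog_config_error")
  }
  staging <- stage_new_subjects(model, cohort)
  delta <- stats::setNames(staging$delta, staging$subject_id)
  assignment <- if (cutoffs == "recompute") {
    classify_progressors(delta, k_sd = k_sd)
  } else {
    if (is.null(training_assignment)) {
      stop_ppms("carry_over cutoffs need `training_assignment`",
                "ppmsprog_config_error")
    }
    mu <- training_assignment$mean; sd_ <- training_assignment$sd
    z <- (delta - mu) / sd_
    label <- ifelse(z < -k_sd, "G1", ifelse(z > k_sd, "G3", "G2"))
    structure(list(assignment = data.frame(
      subject_id = names(delta), delta_years = unname(delta), label = label,
      stringsAsFactors = FALSE), mean = mu, sd = sd_, k_sd = k_sd,
      counts = table(factor(label, levels = c("G1", "G2", "G3")))),
      class = "subgroup_assignment")
  }
  available <- unique(cohort$data$marker)
  cox <- list(); km <- list(); skipped <- character(0)
  for (ep in endpoints) {
    mk <- if (ep == "EDSS6") "EDSS" else ep
    if (!mk %in% available) {
      message("endpoint ", ep, " skipped: marker ", mk,
              " not assessed in the test cohort")
      skipped <- c(skipped, ep)
      next
    }
    et <- suppressWarnings(build_event_table(cohort, ep, assignment))
    km[[ep]] <- km_and_logrank(et)
    if (ep != "EDSS6") cox[[ep]] <- fit_cox(et)
  }
  list(staging = staging, assignment = assignment, cox = cox, km = km,
       skipped_endpoints = skipped)
}
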