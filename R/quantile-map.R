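#' Fit per-marker empirical quantile maps
#'
#' Converts raw marker values to quantile scores according to their empirical
#' distribution over all pooled observations of the cohort.  Markers flagged
#' for log transformation are log-transformed first.  With the default
#' `orientation = "abnormal_high"` scores are flipped so that 1 is the most
#' abnormal value for every marker regardless of the raw direction of
#' worsening; `orientation = "native"` keeps the raw direction (so measures
#' that decline with disease, such as SDMT and NBV, yield declining score
#' trajectories, matching their non-increasing model constraints).
#'
#' The empirical-CDF convention is the mid-distribution rule
#' \eqn{q(x) = (\#\{ref < x\} + \tfrac12\#\{ref = x\}) / n}: symmetric in
#' ties, exactly 0.5 at the sample median for odd n, and clamped to
#' \eqn{[0,1]} for out-of-sample queries.
#'
#' @param cohort a `ppms_cohort` on the raw scale.
#' @param specs a `marker_spec_df` covering the cohort's markers.
#' @param orientation `"abnormal_high"` or `"native"`.
#' @param baseline_only fit the reference distributions on first visits only
#'   (sensitivity option); default pools all visits.
#' @return An object of class `quantile_map`.
#' @export
fit_quantile_map <- function(cohort, specs = default_marker_specs(),
                             orientation = c("abnormal_high", "native"),
                             baseline_only = FALSE) {
  orientation <- match.arg(orientation)
  check_marker_specs(specs)
  dat <- cohort$data
  if (baseline_only) {
    bl <- stats::ave(dat$visit_time_years, dat$subject_id, FUN = min)
    dat <- dat[dat$visit_time_years == bl, , drop = FALSE]
  }
  markers <- intersect(specs$name, unique(dat$marker))
  if (length(markers) == 0L) {
    stop_ppms("no cohort marker matches `specs`", "ppmsprog_config_error")
  }
  ref <- lapply(markers, function(m) {
    spec <- specs[specs$name == m, ]
    x <- dat$value[dat$marker == m]
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      stop_ppms(sprintf("marker '%s' has fewer than 2 observations", m),
                "ppmsprog_insufficient_data")
    }
    if (spec$log_transform) {
      if (any(x <= 0)) {
        stop_ppms(sprintf("marker '%s' flagged log_transform has values <= 0", m),
                  "ppmsprog_config_error")
      }
      x <- log(x)
    }
    list(sorted = sort(x), log_transform = spec$log_transform,
         worse_is = spec$worse_is,
         monotone_direction = spec$monotone_direction)
  })
  names(ref) <- markers
  structure(list(reference = ref, orientation = orientation),
            class = "quantile_map")
}

#' Score raw values of one marker through a fitted quantile map
#'
#' @param map a `quantile_map`.
#' @param marker marker name present in the map.
#' @param values numeric raw values (NA passes through).
#' @return numeric quantile scores in \eqn{[0,1]}.
#' @export
quantile_score <- function(map, marker, values) {
  if (!marker %in% names(map$reference)) {
    stop_ppms(sprintf("marker '%s' is not in the quantile map", marker),
              "ppmsprog_unknown_marker")
  }
  r <- map$reference[[marker]]
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  x <- values[ok]
  if (r$log_transform) {
    ## non-positive queries sit below every positive reference value
    x <- suppressWarnings(log(x))
    x[is.nan(x)] <- -Inf
  }
  n <- length(r$sorted)
  n_leq <- findInterval(x, r$sorted)
  n_lt <- findInterval(x, r$sorted, left.open = TRUE)
  q <- (n_lt + 0.5 * (n_leq - n_lt)) / n
  if (map$orientation == "abnormal_high" && r$worse_is == "lower") q <- 1 - q
  out[ok] <- pmin(1, pmax(0, q))
  out
}

#' Apply a fitted quantile map to a whole cohort
#'
#' Replaces `value` with the per-marker quantile score; missing values stay
#' missing; the raw values are preserved in `value_raw`.
#'
#' @param map a `quantile_map`.
#' @param cohort a `ppms_cohort` whose markers are all present in the map.
#' @return a `ppms_cohort` on the `"score"` scale.
#' @export
apply_quantile_map <- function(map, cohort) {
  dat <- cohort$data
  unknown <- setdiff(unique(dat$marker), names(map$reference))
  if (length(unknown)) {
    stop_ppms(paste("markers absent from map:", paste(unknown, collapse = ", ")),
              "ppmsprog_unknown_marker")
  }
  if (!"value_raw" %in% names(dat)) dat$value_raw <- dat$value
  for (m in unique(dat$marker)) {
    idx <- dat$marker == m
    dat$value[idx] <- quantile_score(map, m, dat$value[idx])
  }
  out <- longitudinal_cohort(dat, cohort$covariates, scale = "score")
  attr(out, "orientation") <- map$orientation
  out
}

#' Effective monotone direction of each mapped marker on the score scale
#'
#' Under `"abnormal_high"` orientation every marker progresses upward; under
#' `"native"` orientation the declared directions apply.
#'
#' @param map a `quantile_map`.
#' @return named character vector of directions.
#' @export
score_directions <- function(map) {
  vapply(map$reference, function(r) {
    if (map$orientation == "abnormal_high") "non-decreasing"
    else r$monotone_direction
  }, character(1))
}

#' Serialize a quantile map to JSON
#' @param map a `quantile_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_quantile_map <- function(map, path) {
  payload <- list(
    orientation = map$orientation,
    reference = lapply(map$reference, function(r) {
      list(sorted = r$sorted, log_transform = r$log_transform,
           worse_is = r$worse_is, monotone_direction = r$monotone_direction)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quantile map from JSON
#' @param path JSON path written by [write_quantile_map()].
#' @return a `quantile_map`.
#' @export
read_quantile_map <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- lapply(payload$reference, function(r) {
    list(sorted = as.numeric(r$sorted),
         log_transform = isTRUE(r$log_transform),
         worse_is = r$worse_is, monotone_direction = r$monotone_direction)
  })
  structure(list(reference = ref, orientation = payload$orientation),
            class = "quantile_map")
}
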