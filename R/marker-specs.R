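#' Marker specifications
#'
#' A marker specification records, for each longitudinal disease measure, how
#' it enters the model: whether the raw value is log-transformed before
#' quantile scoring, the direction in which its population trajectory is
#' constrained to be monotone on the modelling scale, and which direction of
#' the raw scale is clinically worse.
#'
#' @param name marker name (character).
#' @param log_transform logical; log-transform raw values before quantile
#'   scoring (used for right-skewed measures such as lesion volumes and the
#'   timed tests).
#' @param monotone_direction `"non-decreasing"` or `"non-increasing"`;
#'   direction of the population trajectory on the modelling scale.
#' @param worse_is `"higher"` or `"lower"`; direction of clinical worsening
#'   on the raw scale.
#'
#' @return A one-row data frame of class `marker_spec_df`.
#' @export
marker_spec <- function(name, log_transform = FALSE,
                        monotone_direction = c("non-decreasing", "non-increasing"),
                        worse_is = c("higher", "lower")) {
  monotone_direction <- match.arg(monotone_direction)
  worse_is <- match.arg(worse_is)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(log_transform), length(log_transform) == 1L)
  out <- data.frame(
    name = name,
    log_transform = log_transform,
    monotone_direction = monotone_direction,
    worse_is = worse_is,
    stringsAsFactors = FALSE
  )
  class(out) <- c("marker_spec_df", "data.frame")
  out
}

#' Default specifications for the eight PPMS disease measures
#'
#' EDSS, the timed 25-foot walk (T25FW), the 9-hole peg test for dominant and
#' non-dominant hand (HPT9_D, HPT9_ND), the symbol digit modalities test
#' (SDMT), normalized brain volume (NBV) and T1/T2 lesion volumes (T1LV,
#' T2LV).  Lesion volumes and the timed tests (T25FW, 9HPT) are
#' log-transformed; SDMT and NBV carry non-increasing trajectory constraints
#' (they decline as disease advances on their native scale), the remaining
#' six are non-decreasing.
#'
#' @return A `marker_spec_df` with eight rows.
#' @export
default_marker_specs <- function() {
  out <- rbind(
    marker_spec("EDSS",    FALSE, "non-decreasing", "higher"),
    marker_spec("T25FW",   TRUE,  "non-decreasing", "higher"),
    marker_spec("HPT9_D",  TRUE,  "non-decreasing", "higher"),
    marker_spec("HPT9_ND", TRUE,  "non-decreasing", "higher"),
    marker_spec("SDMT",    FALSE, "non-increasing", "lower"),
    marker_spec("NBV",     FALSE, "non-increasing", "lower"),
    marker_spec("T1LV",    TRUE,  "non-decreasing", "higher"),
    marker_spec("T2LV",    TRUE,  "non-decreasing", "higher")
  )
  class(out) <- c("marker_spec_df", "data.frame")
  out
}

#' @noRd
check_marker_specs <- function(specs) {
  if (!is.data.frame(specs) || nrow(specs) < 1L ||
      !all(c("name", "log_transform", "monotone_direction", "worse_is")
           %in% names(specs))) {
    stop_ppms("`specs` must be a marker_spec_df with >= 1 marker",
              "ppmsprog_config_error")
  }
  if (anyDuplicated(specs$name)) {
    stop_ppms("duplicate marker names in `specs`", "ppmsprog_config_error")
  }
  invisible(specs)
}

#' Direction sign on the modelling scale: +1 non-decreasing, -1 non-increasing
#' @noRd
direction_sign <- function(specs) {
  ifelse(specs$monotone_direction == "non-decreasing", 1, -1)
}
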