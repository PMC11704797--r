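#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Stop with a classed condition
#' @noRd
stop_ppms <- function(msg, class, call. = FALSE) {
  cnd <- structure(
    class = c(class, "ppmsprog_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}

#' Validate a single positive scalar
#' @noRd
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_ppms(sprintf("`%s` must be a single non-missing number", name),
              "ppmsprog_config_error")
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop_ppms(sprintf("`%s` must be %s %s", name,
                      if (strict) ">" else ">=", format(lower)),
              "ppmsprog_config_error")
  }
  invisible(x)
}

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Linear interpolation that clamps outside the grid
#' @noRd
interp_clamped <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}
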