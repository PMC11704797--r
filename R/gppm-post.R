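#' Per-subject time-reparametrization parameters
#'
#' \eqn{\delta_s = RDD - ODD = -d_s} at baseline: positive values mean the
#' subject is staged further along the disease-time axis than the reported
#' disease duration suggests (fast progression).
#'
#' @param model a `gppm_model`.
#' @return named numeric vector (years).
#' @export
reparam_delta <- function(model) {
  stats::setNames(model$shifts$delta, model$shifts$subject_id)
}

#' Span of the reconstructed disease timeline
#'
#' Difference between the largest and smallest reparametrized disease
#' duration across all training visits.
#'
#' @param model a `gppm_model`.
#' @return years (scalar).
#' @export
timeline_span <- function(model) unname(diff(model$span))

## Shared staging engine: MAP shift by global grid search + local refine on
## the subject's marginal likelihood, with the Gaussian random intercepts
## integrated out analytically (compound-symmetry residual covariance
## sigma^2 I + rho^2 J per marker).  Returns the shift, its Laplace SD, and
## the intercepts' posterior means/variances given the shift.
## `obs` is a list with vectors t, y, k (marker index) for one subject.
#' @noRd
stage_one_subject <- function(obs, f_fine, fine, m, sigma2, rho2, sd_d2,
                              dmax, n_shift_grid, gstep) {
  tt <- obs$t; yy <- obs$y; kk <- obs$k
  K <- ncol(f_fine)
  ks <- sort(unique(kk))
  nk <- tabulate(kk, nbins = K)
  shrink <- rho2[ks] / (sigma2[ks] * (sigma2[ks] + nk[ks] * rho2[ks]))
  marg_nll <- function(r) {
    s1 <- drop(rowsum(r, kk))
    s2 <- drop(rowsum(r^2, kk))
    sum(s2 / (2 * sigma2[ks]) - 0.5 * shrink * s1^2)
  }
  fv_at <- function(dc) {
    fv <- numeric(length(tt))
    for (k in ks) {
      j <- kk == k
      fv[j] <- interp_clamped(fine, f_fine[, k], tt[j] - dc)
    }
    fv
  }
  obj_s <- function(dc) {
    marg_nll(yy - m[kk] - fv_at(dc)) + dc^2 / (2 * sd_d2)
  }
  d_cand <- seq(-dmax, dmax, length.out = n_shift_grid)
  g0 <- fine[1]
  sc <- vapply(d_cand, function(dc) {
    gi <- pmin(length(fine), pmax(1L, as.integer(
      round((tt - dc - g0) / gstep) + 1L)))
    marg_nll(yy - m[kk] - f_fine[cbind(gi, kk)]) + dc^2 / (2 * sd_d2)
  }, numeric(1))
  best <- d_cand[which.min(sc)]
  step <- d_cand[2] - d_cand[1]
  d_hat <- stats::optimize(obj_s, c(best - step, best + step))$minimum

  ## intercept posterior given the shift
  r <- yy - m[kk] - fv_at(d_hat)
  bk <- rep(0, K); vk <- rep(0, K)
  for (k in ks) {
    j <- kk == k
    bk[k] <- rho2[k] * sum(r[j]) / (sigma2[k] + nk[k] * rho2[k])
    vk[k] <- sigma2[k] * rho2[k] / (sigma2[k] + nk[k] * rho2[k])
  }
  h <- 0.25
  h2 <- (obj_s(d_hat + h) - 2 * obj_s(d_hat) + obj_s(d_hat - h)) / h^2
  list(d = d_hat, d_sd = 1 / sqrt(max(h2, 1e-6)), b = bk, b_var = vk)
}

#' Stage new subjects against a fitted progression model
#'
#' Population trajectories, noise scales and the shift prior are held fixed;
#' only each new subject's time-shift (and random intercepts) are inferred,
#' by a global search over the shift window followed by local refinement,
#' alternated with closed-form intercept updates.  Returns the expectation
#' and Laplace SD of the shift and the implied baseline reparametrized
#' disease duration.  Subjects may miss whole markers (e.g. cohorts without
#' 9HPT); markers unknown to the model raise an error.
#'
#' @param model a `gppm_model`.
#' @param cohort a `ppms_cohort` on the same modelling scale as the
#'   training data.
#' @param on_empty `"error"` (default) or `"skip"` for subjects with zero
#'   usable observations.
#' @return data frame: `subject_id`, `d_mean`, `d_sd`, `delta`
#'   (= RDD - ODD), `rdd_baseline`.
#' @export
stage_new_subjects <- function(model, cohort, on_empty = c("error", "skip")) {
  on_empty <- match.arg(on_empty)
  dat <- cohort$data
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  unknown <- setdiff(unique(dat$marker), model$markers)
  if (length(unknown)) {
    stop_ppms(paste("markers not in the fitted model:",
                    paste(unknown, collapse = ", ")),
              "ppmsprog_unknown_marker")
  }
  subj_ids <- unique(cohort$covariates$subject_id)
  fine <- model$fine
  K <- length(model$markers)
  Phi_fine <- phi_basis(fine, model$H)
  f_fine <- vapply(seq_len(K), function(k) drop(Phi_fine %*% model$u[[k]]),
                   numeric(length(fine)))
  rows <- lapply(subj_ids, function(id) {
    idx <- which(dat$subject_id == id)
    if (length(idx) == 0L) {
      if (on_empty == "error") {
        stop_ppms(sprintf("subject '%s' has no usable observations: staging impossible", id),
                  "ppmsprog_staging_error")
      }
      return(NULL)
    }
    obs <- list(t = dat$visit_time_years[idx], y = dat$value[idx],
                k = match(dat$marker[idx], model$markers))
    st <- stage_one_subject(obs, f_fine, fine, model$m, model$sigma^2,
                            model$rho^2, model$shift_sd^2,
                            model$control$shift_max,
                            model$control$n_shift_grid,
                            model$control$grid_step)
    data.frame(subject_id = id, d_mean = st$d, d_sd = st$d_sd,
               delta = -st$d, rdd_baseline = min(obs$t) - st$d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample posterior realizations of the population trajectories
#'
#' Draws from the Laplace posterior of each marker's trajectory on a grid;
#' the average of many draws converges to the posterior mean.
#'
#' @param model a `gppm_model`.
#' @param n_samples number of posterior realizations.
#' @param grid disease-time grid (default 200 points over the training
#'   span).
#' @param seed integer seed.
#' @return named list, one `n_samples x length(grid)` matrix per marker,
#'   with the grid attached as attribute `"grid"`.
#' @export
sample_trajectories <- function(model, n_samples = 100, grid = NULL,
                                seed = 1L) {
  if (!is.null(grid) && length(grid) == 0L) {
    stop_ppms("empty evaluation grid", "ppmsprog_config_error")
  }
  if (is.null(grid)) grid <- seq(model$span[1], model$span[2],
                                 length.out = 200)
  check_scalar(n_samples, "n_samples", lower = 1)
  Phi <- phi_basis(grid, model$H)
  out <- with_seed(seed, {
    lapply(seq_along(model$markers), function(k) {
      L <- chol(model$Su[[k]] + diag(1e-10, ncol(model$Su[[k]])))
      E <- matrix(stats::rnorm(n_samples * length(model$u[[k]])),
                  n_samples)
      U <- sweep(E %*% L, 2, model$u[[k]], "+")
      curves <- U %*% t(Phi) + model$m[k]
      attr(curves, "grid") <- grid
      curves
    })
  })
  names(out) <- model$markers
  out
}

#' Temporal ordering of peak rate of change across markers
#'
#' For each posterior trajectory draw, finds the disease time at which the
#' absolute derivative of each marker's population trajectory is largest;
#' reports the median and a 95\% credible interval over draws, ordered by
#' median.  Markers whose posterior-mean trajectory is essentially flat over
#' the span have no defined peak: they are flagged, reported last, and given
#' an infinite-width interval, with a warning.
#'
#' @param model a `gppm_model`.
#' @param n_samples posterior draws.
#' @param grid evaluation grid (default 200 points over the span).
#' @param seed integer seed.
#' @param flat_tol minimum posterior-mean total change (score units) for a
#'   peak to be considered defined.
#' @return data frame ordered by median peak time: `marker`, `tau_peak`,
#'   `lower`, `upper`, `undefined`.
#' @export
peak_rate_ordering <- function(model, n_samples = 100, grid = NULL,
                               seed = 1L, flat_tol = 0.05) {
  if (is.null(grid)) grid <- seq(model$span[1], model$span[2],
                                 length.out = 200)
  Dg <- phi_basis(grid, model$H, deriv = TRUE)
  mean_traj <- trajectory_mean(model, grid)
  rows <- with_seed(seed, {
    lapply(seq_along(model$markers), function(k) {
      total_change <- abs(mean_traj[nrow(mean_traj), k] - mean_traj[1, k])
      if (total_change < flat_tol) {
        return(data.frame(marker = model$markers[k], tau_peak = Inf,
                          lower = -Inf, upper = Inf, undefined = TRUE,
                          stringsAsFactors = FALSE))
      }
      L <- chol(model$Su[[k]] + diag(1e-10, ncol(model$Su[[k]])))
      E <- matrix(stats::rnorm(n_samples * length(model$u[[k]])), n_samples)
      U <- sweep(E %*% L, 2, model$u[[k]], "+")
      Dcurves <- abs(U %*% t(Dg))
      peaks <- grid[max.col(Dcurves, ties.method = "first")]
      data.frame(marker = model$markers[k],
                 tau_peak = stats::median(peaks),
                 lower = unname(stats::quantile(peaks, 0.025)),
                 upper = unname(stats::quantile(peaks, 0.975)),
                 undefined = FALSE, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  if (any(out$undefined)) {
    warning("undefined peak for flat marker(s): ",
            paste(out$marker[out$undefined], collapse = ", "))
  }
  out <- out[order(out$undefined, out$tau_peak), ]
  rownames(out) <- NULL
  out
}

#' Global percent change of each marker over the estimated timeline
#'
#' Per marker, \eqn{100 |f(\tau_{max}) - f(\tau_{min})|} relative to the
#' unit score range, summarized over posterior draws (mean and median) and
#' for the posterior-mean curve.
#'
#' @param model a `gppm_model`.
#' @param n_samples posterior draws.
#' @param seed integer seed.
#' @return data frame: `marker`, `mean`, `median`, `point` (percent).
#' @export
percent_change <- function(model, n_samples = 200, seed = 1L) {
  grid <- c(model$span[1], model$span[2])
  draws <- sample_trajectories(model, n_samples, grid = grid, seed = seed)
  mean_traj <- trajectory_mean(model, grid)
  rows <- lapply(seq_along(model$markers), function(k) {
    pc <- 100 * abs(draws[[k]][, 2] - draws[[k]][, 1])
    data.frame(marker = model$markers[k], mean = mean(pc),
               median = stats::median(pc),
               point = 100 * abs(mean_traj[2, k] - mean_traj[1, k]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a fitted progression model to JSON
#' @param model a `gppm_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_gppm <- function(model, path) {
  payload <- list(
    markers = model$markers,
    specs = model$specs,
    directions = as.list(model$directions),
    Z = model$H$Z, a = model$H$a, l = model$H$l,
    u = model$u, Su = lapply(model$Su, as.vector),
    m = model$m, lambda = model$lambda,
    sigma = model$sigma, rho = model$rho, shift_sd = model$shift_sd,
    shifts = model$shifts, span = model$span, extent = model$extent,
    converged = model$converged,
    control = model$control[c("shift_max", "n_shift_grid", "grid_step",
                              "n_mono")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a progression model saved with [save_gppm()]
#' @param path JSON path.
#' @return a `gppm_model` (without training-data diagnostics).
#' @export
load_gppm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- length(p$Z)
  Kzz <- k_se(p$Z, p$Z, p$a, p$l)
  Kinv <- chol2inv(chol(Kzz + diag(p$a^2 * 1e-6, M)))
  H <- list(Z = p$Z, a = p$a, l = p$l, Kinv = Kinv)
  ctrl <- gppm_control(shift_max = p$control$shift_max,
                       n_shift_grid = p$control$n_shift_grid,
                       grid_step = p$control$grid_step,
                       n_mono = p$control$n_mono)
  g_mono <- seq(p$extent[1], p$extent[2], length.out = p$control$n_mono)
  specs <- as.data.frame(p$specs, stringsAsFactors = FALSE)
  class(specs) <- c("marker_spec_df", "data.frame")
  structure(list(
    markers = p$markers, specs = specs,
    directions = unlist(p$directions),
    sgn = ifelse(unlist(p$directions) == "non-decreasing", 1, -1),
    H = H, u = if (is.matrix(p$u)) lapply(seq_len(nrow(p$u)), function(k) p$u[k, ])
         else lapply(p$u, as.numeric),
    Su = if (is.matrix(p$Su)) {
      lapply(seq_len(nrow(p$Su)), function(k) matrix(p$Su[k, ], M, M))
    } else lapply(p$Su, function(v) matrix(as.numeric(v), M, M)),
    m = as.numeric(p$m), Dmono = phi_basis(g_mono, H, deriv = TRUE),
    mono_grid = g_mono, lambda = p$lambda,
    sigma = as.numeric(p$sigma), rho = as.numeric(p$rho),
    shift_sd = p$shift_sd,
    shifts = as.data.frame(p$shifts, stringsAsFactors = FALSE),
    span = as.numeric(p$span), extent = as.numeric(p$extent),
    fine = seq(p$extent[1], p$extent[2], by = p$control$grid_step),
    trace = numeric(0), converged = isTRUE(p$converged), control = ctrl,
    n_subjects = nrow(as.data.frame(p$shifts)), dropped_markers = character(0)
  ), class = "gppm_model")
}
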