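#' Control parameters for the progression-model fit
#'
#' The population trajectories are Gaussian processes represented on a set
#' of inducing points along the disease-time axis, with a squared-exponential
#' kernel whose lengthscale keeps the curves smooth over a multi-decade
#' timeline.  Monotonicity is enforced softly through virtual-derivative
#' observations pushed through a steep logistic link applied to the
#' population curves only.  Estimation alternates maximum-a-posteriori
#' updates of the trajectory weights, per-subject random intercepts,
#' per-subject time-shifts (with Laplace posterior SDs), and the noise /
#' random-effect / shift-scale hyperparameters.
#'
#' @param n_inducing number of inducing points on the disease-time axis.
#' @param lengthscale kernel lengthscale in years; `NULL` picks a quarter of
#'   the observed time range (clamped to 2-15 years).
#' @param amplitude kernel amplitude (prior SD of the trajectory around the
#'   marker mean, score units).
#' @param mono_lambda steepness of the logistic monotonicity link; larger
#'   values make sign violations of the trajectory derivative costlier.
#' @param n_mono number of virtual-derivative grid points.
#' @param max_iter maximum outer iterations.
#' @param tol relative-objective convergence tolerance.
#' @param shift_prior_sd initial SD (years) of the Gaussian time-shift prior.
#' @param estimate_shift_sd update the shift-prior SD empirically.
#' @param shift_max half-width of the shift search window (years); `NULL`
#'   uses three prior SDs.
#' @param noise_floor lower bound on the per-marker noise SD.
#' @param re_sd initial SD of per-subject, per-marker random intercepts.
#' @param estimate_re update the random-intercept SD empirically.
#' @param grid_step step (years) of the internal evaluation grid.
#' @param n_shift_grid number of candidate shifts in the global search.
#' @param inner_maxit BFGS iterations per trajectory update.
#' @param seed integer seed controlling all randomness of the fit.
#' @param verbose print the objective trace.
#' @return a list of class `gppm_control`.
#' @export
gppm_control <- function(n_inducing = 25, lengthscale = NULL, amplitude = 0.6,
                         mono_lambda = 1000, n_mono = 80, max_iter = 40,
                         tol = 1e-5, shift_prior_sd = 5,
                         estimate_shift_sd = TRUE, shift_max = NULL,
                         noise_floor = 1e-3, re_sd = 0.05, estimate_re = TRUE,
                         grid_step = 0.05, n_shift_grid = 61,
                         inner_maxit = 50, seed = 1L, verbose = FALSE) {
  check_scalar(n_inducing, "n_inducing", lower = 5)
  check_scalar(max_iter, "max_iter", lower = 1)
  if (is.null(shift_max)) shift_max <- 3 * shift_prior_sd
  structure(as.list(environment()), class = "gppm_control")
}

## --- kernel machinery -----------------------------------------------------

#' @noRd
k_se <- function(x, z, a, l) {
  D <- outer(x, z, "-")
  a^2 * exp(-0.5 * D^2 / l^2)
}

#' @noRd
k_se_d1 <- function(x, z, a, l) {
  D <- outer(x, z, "-")
  -a^2 * (D / l^2) * exp(-0.5 * D^2 / l^2)
}

## basis rows mapping inducing values u to f(x) (and f'(x))
#' @noRd
phi_basis <- function(x, H, deriv = FALSE) {
  if (deriv) k_se_d1(x, H$Z, H$a, H$l) %*% H$Kinv
  else k_se(x, H$Z, H$a, H$l) %*% H$Kinv
}

## resolve monotone directions for the scale the cohort is on
#' @noRd
resolve_directions <- function(cohort, specs) {
  orient <- attr(cohort, "orientation")
  if (identical(cohort$scale, "score") && identical(orient, "abnormal_high")) {
    stats::setNames(rep("non-decreasing", nrow(specs)), specs$name)
  } else {
    stats::setNames(specs$monotone_direction, specs$name)
  }
}

#' Fit the monotonic Gaussian-process progression model
#'
#' Joint estimation of (i) one monotone population trajectory per marker
#' over a common disease-time axis, (ii) per-subject Gaussian random
#' intercepts, (iii) per-marker Gaussian measurement-noise scales, and (iv)
#' per-subject time-shifts \eqn{d_s} mapping observed disease duration
#' \eqn{t} to reparametrized disease duration \eqn{\tau = t - d_s}.  The
#' shift posterior means are centred so the cohort mean shift is zero (the
#' identifiability gauge).  Missing marker entries contribute nothing to the
#' likelihood; markers with no observations at all are dropped with a
#' warning.
#'
#' @param cohort a `ppms_cohort` whose `value` column is on the modelling
#'   scale (scores in \eqn{[0,1]}).
#' @param specs `marker_spec_df`; directions are interpreted on the
#'   cohort's scale (after abnormal-high quantile orientation all markers
#'   progress upward).
#' @param control a [gppm_control()].
#' @return An object of class `gppm_model`; see [stage_new_subjects()],
#'   [sample_trajectories()], [peak_rate_ordering()], [percent_change()],
#'   [timeline_span()], [reparam_delta()].
#' @export
gppm_fit <- function(cohort, specs = default_marker_specs(),
                     control = gppm_control()) {
  stopifnot(inherits(cohort, "ppms_cohort"), inherits(control, "gppm_control"))
  check_marker_specs(specs)
  dat <- cohort$data
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  dat <- dat[dat$marker %in% specs$name, , drop = FALSE]
  absent <- setdiff(specs$name, unique(dat$marker))
  if (length(absent)) {
    warning("marker(s) with no observations dropped: ",
            paste(absent, collapse = ", "))
    specs <- specs[!specs$name %in% absent, , drop = FALSE]
  }
  if (nrow(specs) == 0L) {
    stop_ppms("no marker with observations remains", "ppmsprog_config_error")
  }
  subj_ids <- sort(unique(dat$subject_id))
  n <- length(subj_ids)
  if (n < 2L) stop_ppms("need >= 2 subjects", "ppmsprog_config_error")

  directions <- resolve_directions(cohort, specs)
  K <- nrow(specs)
  markers <- specs$name
  sgn <- ifelse(directions[markers] == "non-decreasing", 1, -1)

  s_idx <- match(dat$subject_id, subj_ids)
  k_idx <- match(dat$marker, markers)
  t_obs <- dat$visit_time_years
  y_obs <- dat$value

  ## hyper setup
  t_range <- range(t_obs)
  l <- control$lengthscale
  if (is.null(l)) l <- min(15, max(2, diff(t_range) / 4))
  a <- control$amplitude
  dmax <- control$shift_max
  ext <- c(t_range[1] - dmax - 1, t_range[2] + dmax + 1)
  Z <- seq(ext[1], ext[2], length.out = control$n_inducing)
  Kzz <- k_se(Z, Z, a, l)
  Kinv <- chol2inv(chol(Kzz + diag(a^2 * 1e-6, length(Z))))
  H <- list(Z = Z, a = a, l = l, Kinv = Kinv)
  g_mono <- seq(ext[1], ext[2], length.out = control$n_mono)
  Dmono <- phi_basis(g_mono, H, deriv = TRUE)
  lambda <- control$mono_lambda

  ## fine grid for shift search
  fine <- seq(ext[1], ext[2], by = control$grid_step)
  Phi_fine <- phi_basis(fine, H)

  ## state
  m <- vapply(seq_len(K), function(k) mean(y_obs[k_idx == k]), numeric(1))
  u <- vector("list", K); for (k in seq_len(K)) u[[k]] <- rep(0, length(Z))
  d <- rep(0, n)
  b <- matrix(0, n, K)
  sigma2 <- vapply(seq_len(K), function(k) {
    max(stats::var(y_obs[k_idx == k]) * 0.5, control$noise_floor^2)
  }, numeric(1))
  rho2 <- rep(control$re_sd^2, K)
  sd_d2 <- control$shift_prior_sd^2

  obs_by_k <- lapply(seq_len(K), function(k) which(k_idx == k))
  obs_by_s <- lapply(seq_len(n), function(s) which(s_idx == s))
  sk_group <- (s_idx - 1L) * K + k_idx  # per (subject, marker) cell

  obj_trace <- numeric(0)
  converged <- FALSE

  neg_logpost <- function(fit_vals) {
    resid <- y_obs - fit_vals - b[cbind(s_idx, k_idx)] - m[k_idx]
    data_term <- sum(resid^2 / (2 * sigma2[k_idx]) +
                       0.5 * log(2 * pi * sigma2[k_idx]))
    prior_u <- sum(vapply(seq_len(K), function(k) {
      0.5 * sum(u[[k]] * (Kinv %*% u[[k]]))
    }, numeric(1)))
    mono_term <- -sum(vapply(seq_len(K), function(k) {
      sum(stats::plogis(lambda * sgn[k] * drop(Dmono %*% u[[k]]),
                        log.p = TRUE))
    }, numeric(1)))
    shift_term <- sum(d^2) / (2 * sd_d2)
    re_term <- sum(sweep(b^2, 2, 2 * rho2, "/"))
    data_term + prior_u + mono_term + shift_term + re_term
  }

  with_seed(control$seed, {
    for (it in seq_len(control$max_iter)) {
      tau_obs <- t_obs - d[s_idx]

      ## (1) trajectory update per marker (MAP over inducing values)
      for (k in seq_len(K)) {
        idx <- obs_by_k[[k]]
        A <- phi_basis(tau_obs[idx], H)
        r <- y_obs[idx] - m[k] - b[cbind(s_idx[idx], k)]
        s2 <- sigma2[k]; sg <- sgn[k]
        fn <- function(uu) {
          e <- r - drop(A %*% uu)
          z <- lambda * sg * drop(Dmono %*% uu)
          sum(e^2) / (2 * s2) + 0.5 * sum(uu * (Kinv %*% uu)) -
            sum(stats::plogis(z, log.p = TRUE))
        }
        gr <- function(uu) {
          e <- r - drop(A %*% uu)
          z <- lambda * sg * drop(Dmono %*% uu)
          drop(-crossprod(A, e) / s2 + Kinv %*% uu -
                 lambda * sg * crossprod(Dmono, 1 - stats::plogis(z)))
        }
        opt <- stats::optim(u[[k]], fn, gr, method = "BFGS",
                            control = list(maxit = control$inner_maxit))
        u[[k]] <- opt$par
      }

      ## (2) evaluate trajectories on the fine grid for the shift search
      f_fine <- vapply(seq_len(K), function(k) drop(Phi_fine %*% u[[k]]),
                       numeric(length(fine)))

      ## (3) per-subject shift + intercept update on the marginal
      ##     likelihood (intercepts integrated out, then conditioned)
      d_var <- numeric(n)
      b_var <- matrix(0, n, K)
      for (s in seq_len(n)) {
        idx <- obs_by_s[[s]]
        st <- stage_one_subject(
          list(t = t_obs[idx], y = y_obs[idx], k = k_idx[idx]),
          f_fine, fine, m, sigma2, rho2, sd_d2,
          dmax, control$n_shift_grid, control$grid_step)
        d[s] <- st$d; d_var[s] <- st$d_sd^2
        b[s, ] <- st$b; b_var[s, ] <- st$b_var
      }
      d <- d - mean(d)  # identifiability gauge

      ## (4) hyperparameter updates (EM-style, posterior moments included)
      tau_obs <- t_obs - d[s_idx]
      fit_vals <- numeric(length(y_obs))
      for (k in seq_len(K)) {
        idx <- obs_by_k[[k]]
        fit_vals[idx] <- drop(phi_basis(tau_obs[idx], H) %*% u[[k]])
      }
      resid <- y_obs - m[k_idx] - fit_vals - b[cbind(s_idx, k_idx)]
      has_bk <- b_var > 0
      for (k in seq_len(K)) {
        idx <- obs_by_k[[k]]
        sigma2[k] <- max(mean(resid[idx]^2 + b_var[s_idx[idx], k]),
                         control$noise_floor^2)
      }
      if (control$estimate_re) {
        for (k in seq_len(K)) {
          sk <- has_bk[, k]
          if (any(sk)) rho2[k] <- max(mean(b[sk, k]^2 + b_var[sk, k]), 1e-6)
        }
      }
      if (control$estimate_shift_sd) {
        sd_d2 <- max(mean(d^2 + pmin(d_var, sd_d2)), 0.25)
      }

      ## (6) convergence on the full negative log posterior
      obj <- neg_logpost(fit_vals)
      obj_trace <- c(obj_trace, obj)
      if (control$verbose) {
        message(sprintf("iter %2d  objective %.4f", it, obj))
      }
      if (it >= 3) {
        prev <- obj_trace[it - 1]
        if (abs(prev - obj) <= control$tol * (abs(prev) + 1e-8)) {
          converged <- TRUE
          break
        }
      }
    }
  })
  if (!converged) {
    warning("progression-model fit did not meet the objective tolerance ",
            "within max_iter iterations; results flagged unconverged")
  }

  ## Final shift pass: same engine as stage_new_subjects(), so self-staging
  ## reproduces the fitted shifts exactly (up to the centring gauge).
  f_fine_final <- vapply(seq_len(K), function(k) drop(Phi_fine %*% u[[k]]),
                         numeric(length(fine)))
  d_sd <- numeric(n)
  for (s in seq_len(n)) {
    idx <- obs_by_s[[s]]
    st <- stage_one_subject(
      list(t = t_obs[idx], y = y_obs[idx], k = k_idx[idx]),
      f_fine_final, fine, m, sigma2, rho2, sd_d2,
      dmax, control$n_shift_grid, control$grid_step)
    d[s] <- st$d; d_sd[s] <- st$d_sd; b[s, ] <- st$b
  }
  d <- d - mean(d)

  ## Laplace posterior covariance of inducing values (for sampling)
  tau_obs <- t_obs - d[s_idx]
  Su <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- obs_by_k[[k]]
    A <- phi_basis(tau_obs[idx], H)
    z <- lambda * sgn[k] * drop(Dmono %*% u[[k]])
    wgt <- stats::plogis(z) * (1 - stats::plogis(z)) * lambda^2
    Hmat <- crossprod(A) / sigma2[k] + Kinv + crossprod(Dmono * sqrt(wgt))
    Su[[k]] <- chol2inv(chol(Hmat + diag(1e-8, ncol(Hmat))))
  }

  rdd <- t_obs - d[s_idx]
  shifts <- data.frame(
    subject_id = subj_ids, d_mean = d, d_sd = d_sd, delta = -d,
    rdd_baseline = tapply(rdd, factor(s_idx, levels = seq_len(n)), min),
    stringsAsFactors = FALSE
  )
  structure(list(
    markers = markers, specs = specs, directions = directions, sgn = sgn,
    H = H, u = u, Su = Su, m = m, Dmono = Dmono, mono_grid = g_mono,
    lambda = lambda, sigma = sqrt(sigma2), rho = sqrt(rho2),
    shift_sd = sqrt(sd_d2), shifts = shifts, b = b,
    rdd = data.frame(subject_id = dat$subject_id, marker = dat$marker,
                     odd = t_obs, rdd = rdd, stringsAsFactors = FALSE),
    span = range(rdd), extent = ext, fine = fine,
    trace = obj_trace, converged = converged, control = control,
    n_subjects = n, dropped_markers = absent
  ), class = "gppm_model")
}

#' @export
print.gppm_model <- function(x, ...) {
  cat(sprintf(
    "<gppm_model> %d markers, %d subjects, timeline span %.1f years%s\n",
    length(x$markers), x$n_subjects, diff(x$span),
    if (x$converged) "" else " [not converged]"))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("  shift-prior SD %.2f y; noise SD %s\n", x$shift_sd,
              paste(sprintf("%.3f", x$sigma), collapse = "/")))
  invisible(x)
}

#' Posterior-mean population trajectory on a grid
#'
#' @param model a `gppm_model`.
#' @param grid disease-time grid (years); default 200 points over the
#'   training reparametrized-duration span.
#' @param markers markers to evaluate (default all).
#' @return matrix (length(grid) x markers) of posterior-mean scores.
#' @export
trajectory_mean <- function(model, grid = NULL, markers = model$markers) {
  if (is.null(grid)) grid <- seq(model$span[1], model$span[2],
                                 length.out = 200)
  Phi <- phi_basis(grid, model$H)
  out <- vapply(markers, function(mk) {
    k <- match(mk, model$markers)
    model$m[k] + drop(Phi %*% model$u[[k]])
  }, numeric(length(grid)))
  rownames(out) <- NULL
  out
}
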