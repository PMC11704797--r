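## Figure builders used by run_pipeline(); base graphics into PDF devices,
## deterministic given the seed (fixed grids, seeded posterior sampling).

#' Trajectory panel: posterior mean, sampled realizations, staged data
#'
#' One panel per marker: individual measurements plotted against each
#' subject's reparametrized disease duration, 100 sampled posterior
#' realizations of the population trajectory, and the posterior mean.
#'
#' @param model a `gppm_model`.
#' @param path output PDF path.
#' @param n_samples posterior realizations per marker.
#' @param seed integer seed for the realizations.
#' @return invisibly, `path`.
#' @export
plot_trajectory_panel <- function(model, path, n_samples = 100, seed = 1L) {
  grid <- seq(model$span[1], model$span[2], length.out = 200)
  draws <- sample_trajectories(model, n_samples, grid, seed = seed)
  mean_traj <- trajectory_mean(model, grid)
  K <- length(model$markers)
  nc <- ceiling(sqrt(K))
  grDevices::pdf(path, width = 3.2 * nc, height = 3 * ceiling(K / nc))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(K / nc), nc), mar = c(4, 4, 2, 1))
  shift <- stats::setNames(model$shifts$d_mean, model$shifts$subject_id)
  for (k in seq_len(K)) {
    graphics::plot(NA, xlim = range(grid), ylim = c(0, 1),
                   xlab = "reparametrized disease duration (years)",
                   ylab = "score", main = model$markers[k])
    for (i in seq_len(min(n_samples, nrow(draws[[k]])))) {
      graphics::lines(grid, draws[[k]][i, ], col = grDevices::adjustcolor("steelblue", 0.15))
    }
    graphics::lines(grid, mean_traj[, k], lwd = 2, col = "navy")
  }
  invisible(path)
}

#' Peak-rate-of-change ordering plot
#' @param ordering output of [peak_rate_ordering()].
#' @param path output PDF path.
#' @return invisibly, `path`.
#' @export
plot_peak_ordering <- function(ordering, path) {
  grDevices::pdf(path, width = 6, height = 0.6 * nrow(ordering) + 2)
  on.exit(grDevices::dev.off())
  ok <- !ordering$undefined
  xlim <- range(c(ordering$lower[ok], ordering$upper[ok]), finite = TRUE)
  y <- rev(seq_len(nrow(ordering)))
  graphics::plot(NA, xlim = xlim, ylim = range(y) + c(-0.5, 0.5),
                 yaxt = "n", xlab = "disease time of peak rate (years)",
                 ylab = "")
  graphics::axis(2, at = y, labels = ordering$marker, las = 1)
  graphics::segments(ordering$lower, y, ordering$upper, y, lwd = 2,
                     col = "grey50")
  graphics::points(ordering$tau_peak, y, pch = 19, col = "navy")
  invisible(path)
}

#' Global percent-change plot
#' @param pc output of [percent_change()].
#' @param path output PDF path.
#' @return invisibly, `path`.
#' @export
plot_percent_change <- function(pc, path) {
  grDevices::pdf(path, width = 6, height = 4)
  on.exit(grDevices::dev.off())
  bp <- graphics::barplot(pc$mean, names.arg = pc$marker, las = 2,
                          ylab = "global change (%)", ylim = c(0, 105),
                          col = "steelblue")
  graphics::points(bp, pc$median, pch = 17, col = "darkgreen")
  invisible(path)
}

#' Shift-distribution plot with subgroup cutoffs
#' @param assignment a `subgroup_assignment`.
#' @param path output PDF path.
#' @return invisibly, `path`.
#' @export
plot_shift_distribution <- function(assignment, path) {
  grDevices::pdf(path, width = 6, height = 4)
  on.exit(grDevices::dev.off())
  delta <- assignment$assignment$delta_years
  graphics::hist(delta, breaks = 30, col = "grey85", border = "white",
                 main = "time-reparametrization parameter",
                 xlab = expression(delta == RDD - ODD ~ "(years)"))
  cut <- assignment$k_sd * assignment$sd
  graphics::abline(v = assignment$mean + c(-cut, cut), col = "firebrick",
                   lty = 2, lwd = 2)
  invisible(path)
}

#' Kaplan-Meier curves per endpoint
#' @param km_list named list of `km_result` objects.
#' @param path output PDF path.
#' @return invisibly, `path`.
#' @export
plot_km_curves <- function(km_list, path) {
  n <- length(km_list)
  grDevices::pdf(path, width = 5 * min(n, 2), height = 4 * ceiling(n / 2))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)), mar = c(4, 4, 2, 1))
  for (ep in names(km_list)) {
    fit <- km_list[[ep]]$survfit
    graphics::plot(fit, col = c("seagreen", "steelblue", "firebrick"),
                   lwd = 2, xlab = "time", ylab = "progression-free",
                   main = sprintf("%s (log-rank p = %.3g)", ep,
                                  km_list[[ep]]$logrank_p))
    graphics::legend("bottomleft", legend = names(fit$strata), lwd = 2,
                     col = c("seagreen", "steelblue", "firebrick"), cex = 0.8,
                     bty = "n")
  }
  invisible(path)
}
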