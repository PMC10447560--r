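# Posterior difference curve between two group trajectories and the
# earliest age at which its credible band excludes zero.

#' Per-draw difference curves
#'
#' Elementwise `A - B` over matched draws and grid ages; antisymmetric
#' under swapping the groups.
#'
#' @param curves_A,curves_B Matrices (draws x ages) of the same shape.
#' @return Matrix of per-draw differences.
#' @export
difference_draws <- function(curves_A, curves_B) {
  if (!all(dim(curves_A) == dim(curves_B))) {
    stop("curve draw matrices must have identical shape")
  }
  curves_A - curves_B
}

#' Equal-tailed credible band
#'
#' Pointwise empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`
#' per grid age, using the type-7 quantile rule.
#'
#' @param diffs Matrix (draws x ages) of difference draws; at least 100
#'   draws are required.
#' @param level Credible level in (0, 1), default 0.99.
#' @return List with numeric vectors `lower`, `upper`, `median`.
#' @export
credible_band <- function(diffs, level = 0.99) {
  diffs <- as.matrix(diffs)
  if (nrow(diffs) < 100L) {
    stop("at least 100 draws are required to estimate the band (got ",
         nrow(diffs), ")")
  }
  if (level <= 0 || level >= 1) stop("level must be strictly between 0 and 1")
  a <- (1 - level) / 2
  list(lower = apply(diffs, 2L, stats::quantile, probs = a, type = 7),
       upper = apply(diffs, 2L, stats::quantile, probs = 1 - a, type = 7),
       median = apply(diffs, 2L, stats::median))
}

#' Earliest sustained divergence age
#'
#' The smallest grid age from which the credible band excludes zero for at
#' least `sustain_years` consecutive years of age ("begins to differ, and
#' stays different"). A run of exclusion that reaches the end of the grid
#' also qualifies, since it cannot be falsified there; `sustain_years =
#' Inf` therefore demands exclusion through the oldest grid age. The
#' persistence requirement prevents isolated noisy grid points from
#' defining onset, while remaining well defined on a bounded scale whose
#' groups re-converge once both reach the floor.
#'
#' Exclusion direction: `"lower"` means the band lies entirely below zero
#' (group A under group B), `"upper"` entirely above, and `"two-sided"`
#' either side pointwise.
#'
#' @param ages Monotone increasing grid.
#' @param lower,upper Band limits per grid age.
#' @param direction `"lower"`, `"upper"` or `"two-sided"`.
#' @param sustain_years Minimum persistence of exclusion, in years
#'   (default 5).
#' @return The divergence age (a grid value), or `NA` if no exclusion run
#'   persists long enough.
#' @export
divergence_age <- function(ages, lower, upper,
                           direction = c("lower", "upper", "two-sided"),
                           sustain_years = 5) {
  direction <- match.arg(direction)
  stopifnot(length(ages) == length(lower), length(ages) == length(upper),
            !is.unsorted(ages), sustain_years > 0)
  excluded <- switch(direction,
    lower = upper < 0,
    upper = lower > 0,
    `two-sided` = upper < 0 | lower > 0
  )
  if (!any(excluded)) return(NA_real_)
  n <- length(excluded)
  runs <- rle(excluded)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    span <- ages[ends[r]] - ages[starts[r]]
    if (span >= sustain_years || ends[r] == n) return(ages[starts[r]])
  }
  NA_real_
}

#' Posterior divergence analysis of a trajectory fit
#'
#' Computes the posterior difference curve (group A minus group B) on a
#' fixed-step age grid spanning the 1st to 99th percentile of the analysed
#' ages, its equal-tailed credible band, and the earliest sustained
#' divergence age.
#'
#' @param fit A [fit_trajectory()] result.
#' @param level Credible level (default 0.99).
#' @param grid_step Grid step in years (default 0.1, matching one-decimal
#'   reporting of divergence ages).
#' @param direction Exclusion direction (see [divergence_age()]); default
#'   `"lower"` (group A hypothesised below group B). Use `"upper"` for
#'   protective comparisons such as e2+ vs e2-.
#' @param sustain_years Minimum persistence of band exclusion in years
#'   (default 5; `Inf` requires exclusion through the oldest grid age).
#' @param grid_range Optional length-2 override of the grid range.
#' @return An object of class `traj_divergence`: data frame-like list with
#'   `table` (age, median difference, band, exclusion flag),
#'   `divergence_age` (years or `NA`), `level`, `direction`, `labels`.
#' @export
divergence <- function(fit, level = 0.99, grid_step = 0.1,
                       direction = c("lower", "upper", "two-sided"),
                       sustain_years = 5, grid_range = NULL) {
  stopifnot(inherits(fit, "traj_fit"))
  direction <- match.arg(direction)
  if (is.null(grid_range)) {
    grid_range <- stats::quantile(fit$data$age, c(0.01, 0.99), type = 7)
  }
  grid <- seq(ceiling(grid_range[1] / grid_step) * grid_step,
              floor(grid_range[2] / grid_step) * grid_step,
              by = grid_step)
  grid <- round(grid, 6)
  cv <- posterior_curves(fit, grid)
  diffs <- difference_draws(cv$A, cv$B)
  band <- credible_band(diffs, level = level)
  excluded <- switch(direction,
    lower = band$upper < 0,
    upper = band$lower > 0,
    `two-sided` = band$upper < 0 | band$lower > 0
  )
  div_age <- divergence_age(grid, band$lower, band$upper, direction,
                            sustain_years = sustain_years)
  structure(
    list(table = data.frame(age = grid, median_diff = band$median,
                            lo = band$lower, hi = band$upper,
                            excluded = excluded),
         divergence_age = div_age, level = level, direction = direction,
         labels = fit$labels),
    class = "traj_divergence"
  )
}

#' @export
print.traj_divergence <- function(x, ...) {
  cat("Posterior difference: ", x$labels[1], " - ", x$labels[2], "\n", sep = "")
  cat(100 * x$level, "% band, direction '", x$direction, "': ", sep = "")
  if (is.na(x$divergence_age)) {
    cat("no sustained divergence on the grid\n")
  } else {
    cat("trajectories begin to differ at ",
        sprintf("%.1f", x$divergence_age), " years\n", sep = "")
  }
  invisible(x)
}

#' Plot a posterior difference curve
#'
#' Difference curve with shaded credible band and a dashed zero line; the
#' divergence age, when present, is marked.
#'
#' @param x A `traj_divergence`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.traj_divergence <- function(x, ...) {
  tb <- x$table
  graphics::plot(tb$age, tb$median_diff, type = "n",
                 ylim = range(tb$lo, tb$hi),
                 xlab = "Age (years)",
                 ylab = paste0("MMSE difference (", x$labels[1], " - ",
                               x$labels[2], ")"), ...)
  graphics::polygon(c(tb$age, rev(tb$age)), c(tb$lo, rev(tb$hi)),
                    col = grDevices::rgb(0.8, 0.1, 0.1, 0.25), border = NA)
  graphics::lines(tb$age, tb$median_diff, col = grDevices::rgb(0.8, 0.1, 0.1),
                  lwd = 2)
  graphics::abline(h = 0, lty = 2)
  if (!is.na(x$divergence_age)) {
    graphics::abline(v = x$divergence_age, lty = 3)
    graphics::mtext(sprintf("divergence at %.1f y", x$divergence_age),
                    side = 3, line = 0, adj = 1, cex = 0.8)
  }
  invisible(x)
}
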