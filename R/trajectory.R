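# Two-group Bayesian restricted-cubic-spline trajectory model.
#
# MMSE in each group is Gaussian around a spline in age; both groups share
# the spline basis (knots from the pooled ages) and the noise scale, so the
# between-group difference curve has a single coherent posterior. Because
# the likelihood is Gaussian, the log posterior and its gradient depend on
# the data only through the per-group sufficient statistics (X'X, X'y, y'y,
# n), which makes each leapfrog step O(k^2) regardless of sample size.

#' Prior specification for the trajectory model
#'
#' Coefficient priors are independent Cauchy(0, `beta_scale`) on the
#' centred, column-scaled basis coefficients (weakly informative; default
#' scale 2.5). The noise scale gets a half-Cauchy(0, `sigma_scale`) prior
#' and is sampled on the log scale with the Jacobian correction. A Gaussian
#' coefficient-prior variant is provided for validation against the
#' closed-form conjugate posterior.
#'
#' @param beta_scale Cauchy (or Gaussian SD) scale for coefficients.
#' @param sigma_scale Half-Cauchy scale for the noise SD.
#' @param family `"cauchy"` (default) or `"gaussian"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_scale = 2.5, sigma_scale = 5,
                       family = c("cauchy", "gaussian")) {
  family <- match.arg(family)
  stopifnot(beta_scale > 0, sigma_scale > 0)
  structure(list(beta_scale = beta_scale, sigma_scale = sigma_scale,
                 family = family), class = "prior_spec")
}

# Sufficient statistics of one group's Gaussian spline regression.
suff_stats <- function(X, y) {
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
       yty = sum(y^2), n = length(y))
}

# Log posterior and gradient from sufficient statistics.
# theta = c(beta_A, beta_B[, log sigma]); sigma_fixed short-circuits the
# noise-scale parameter (used by the conjugate validation variant).
lp_kernel <- function(theta, ssA, ssB, k, priors, sigma_fixed = NULL) {
  beta_A <- theta[seq_len(k)]
  beta_B <- theta[k + seq_len(k)]
  sample_sigma <- is.null(sigma_fixed)
  if (sample_sigma) {
    zeta <- theta[2 * k + 1]
    sigma <- exp(zeta)
  } else {
    sigma <- sigma_fixed
  }
  rss_grad <- function(ss, beta) {
    XtXb <- drop(ss$XtX %*% beta)
    list(rss = ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * XtXb),
         grad = (ss$Xty - XtXb))
  }
  gA <- rss_grad(ssA, beta_A)
  gB <- rss_grad(ssB, beta_B)
  ntot <- ssA$n + ssB$n
  rss <- gA$rss + gB$rss
  value <- -0.5 * ntot * log(2 * pi) - ntot * log(sigma) - rss / (2 * sigma^2)
  grad_beta <- c(gA$grad, gB$grad) / sigma^2

  s <- priors$beta_scale
  betas <- c(beta_A, beta_B)
  if (priors$family == "cauchy") {
    value <- value + sum(-log(pi * s) - log1p((betas / s)^2))
    grad_beta <- grad_beta - 2 * betas / (s^2 + betas^2)
  } else {
    value <- value + sum(-0.5 * log(2 * pi * s^2) - betas^2 / (2 * s^2))
    grad_beta <- grad_beta - betas / s^2
  }

  if (sample_sigma) {
    ss_s <- priors$sigma_scale
    # half-Cauchy on sigma plus log|d sigma / d zeta| = zeta
    value <- value + log(2 / (pi * ss_s)) - log1p((sigma / ss_s)^2) + zeta
    grad_zeta <- -ntot + rss / sigma^2 - 2 * sigma^2 / (ss_s^2 + sigma^2) + 1
    list(value = value, grad = c(grad_beta, grad_zeta))
  } else {
    list(value = value, grad = grad_beta)
  }
}

#' Log posterior of the two-group spline trajectory model
#'
#' Gaussian likelihood with shared noise scale over both groups, plus the
#' coefficient and noise priors of [prior_spec()]. When `sigma_fixed` is
#' `NULL` the last element of `theta` is log(sigma) and the returned value
#' includes the Jacobian of the log transform. Groups may have zero rows
#' (the value is then prior-only).
#'
#' @param theta Parameter vector `c(beta_A, beta_B, log_sigma)` (or without
#'   the last element when `sigma_fixed` is given).
#' @param X_A,X_B Design matrices with equal column counts.
#' @param y_A,y_B Response vectors.
#' @param priors A [prior_spec()].
#' @param sigma_fixed Optional fixed noise SD (conjugate validation variant).
#' @return List with `value` (log posterior) and `grad` (exact gradient).
#' @export
log_posterior <- function(theta, X_A, y_A, X_B, y_B,
                          priors = prior_spec(), sigma_fixed = NULL) {
  X_A <- as.matrix(X_A); X_B <- as.matrix(X_B)
  if (ncol(X_A) != ncol(X_B)) stop("design matrices must have equal column counts")
  if (nrow(X_A) != length(y_A) || nrow(X_B) != length(y_B)) {
    stop("design matrix rows must match response lengths")
  }
  k <- ncol(X_A)
  expected <- 2 * k + if (is.null(sigma_fixed)) 1L else 0L
  if (length(theta) != expected) {
    stop("theta must have length ", expected, " (got ", length(theta), ")")
  }
  if (!all(is.finite(theta)) || !all(is.finite(X_A)) || !all(is.finite(X_B)) ||
      !all(is.finite(y_A)) || !all(is.finite(y_B))) {
    stop("non-finite inputs")
  }
  lp_kernel(theta, suff_stats(X_A, y_A), suff_stats(X_B, y_B), k, priors,
            sigma_fixed)
}

#' Fit a two-group spline trajectory model by HMC
#'
#' Builds a shared restricted cubic spline basis on the pooled ages of the
#' two comparison groups, orthonormalizes it (thin-QR reparameterization of
#' the centred design) for sampler conditioning, and samples both groups'
#' coefficients and the shared noise scale jointly by Hamiltonian Monte
#' Carlo. Coefficient priors act on the orthonormalized basis; draws are
#' mapped back exactly to the raw basis scale for reporting.
#'
#' Group A is the hypothesised-risk group of each comparison: PSEN1 carriers
#' (`"psen1"`), APOE e4+ (`"e4"`), or APOE e2+ (`"e2"`; protective, so the
#' expected difference is positive).
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @param group `"psen1"`, `"e4"` or `"e2"`.
#' @param stratum `"all"`, `"carriers"` or `"noncarriers"`; APOE comparisons
#'   are usually run within a PSEN1 stratum. Ignored rows are dropped before
#'   knot placement.
#' @param n_knots Number of spline knots (3--7, default 5), placed by
#'   [place_knots()] on the pooled ages; or supply `spec` directly.
#' @param spec Optional [rcs_spec()] overriding `n_knots`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()] (default: the full 8-chain configuration;
#'   see [mcmc_preset()] for a lighter preset).
#' @return An object of class `traj_fit` with posterior draws of the group
#'   coefficient vectors (raw basis scale) and noise SD, the spline spec,
#'   the analysis data, and MCMC diagnostics (split R-hat, ESS, acceptance,
#'   divergences). A warning is issued if any split R-hat exceeds 1.01.
#' @seealso [divergence()], [posterior_curves()], [predict.traj_fit()]
#' @export
fit_trajectory <- function(cohort,
                           group = c("psen1", "e4", "e2"),
                           stratum = c("all", "carriers", "noncarriers"),
                           n_knots = 5L, spec = NULL,
                           priors = prior_spec(),
                           mcmc = mcmc_config()) {
  group <- match.arg(group)
  stratum <- match.arg(stratum)
  cohort <- add_apoe_groups(cohort)
  if (stratum != "all") {
    keep <- if (stratum == "carriers") cohort$psen1_carrier else !cohort$psen1_carrier
    cohort <- cohort[keep, , drop = FALSE]
  }
  in_a <- switch(group,
    psen1 = cohort$psen1_carrier,
    e4 = cohort$e4_positive,
    e2 = cohort$e2_positive
  )
  labels <- switch(group,
    psen1 = c("PSEN1 carriers", "PSEN1 non-carriers"),
    e4 = c("APOE e4+", "APOE e4-"),
    e2 = c("APOE e2+", "APOE e2-")
  )
  if (is.null(spec)) spec <- place_knots(cohort$age, n_knots)
  k <- length(spec$knots)
  for (g in 1:2) {
    n_g <- sum(in_a == (g == 1))
    if (n_g < k + 2L) {
      stop("group '", labels[g], "' has only ", n_g,
           " observations; at least ", k + 2L, " are required")
    }
  }

  # Thin-QR reparameterization: centre the nonconstant columns, then sample
  # on the orthonormalized basis scaled to unit column norm-per-row. This
  # removes the near-collinearity of adjacent cubic columns (condition
  # numbers ~1e4 otherwise) so identity-mass HMC mixes; draws are mapped
  # back to the raw basis exactly.
  X <- rcs_design(cohort$age, spec)
  n_all <- nrow(X)
  centers <- c(0, colMeans(X[, -1, drop = FALSE]))
  Xc <- sweep(X, 2L, centers, "-")
  qrx <- qr(Xc)
  if (qrx$rank < k) stop("degenerate spline design (constant ages?)")
  Z <- qr.Q(qrx) * sqrt(n_all)
  R_mat <- qr.R(qrx)[, order(qrx$pivot), drop = FALSE] / sqrt(n_all)
  # Xc = Z %*% R_mat (pivot-corrected)

  y <- cohort$mmse
  ZA <- Z[in_a, , drop = FALSE]; yA <- y[in_a]
  ZB <- Z[!in_a, , drop = FALSE]; yB <- y[!in_a]
  ssA <- suff_stats(ZA, yA)
  ssB <- suff_stats(ZB, yB)
  lp <- function(theta) lp_kernel(theta, ssA, ssB, k, priors)

  ls_init <- function(Zg, yg) {
    fit <- stats::lm.fit(Zg, yg)
    list(coef = fit$coefficients,
         sd = sqrt(sum(fit$residuals^2) / max(length(yg) - k, 1)))
  }
  iA <- ls_init(ZA, yA); iB <- ls_init(ZB, yB)
  theta0 <- c(iA$coef, iB$coef,
              log(max(mean(c(iA$sd, iB$sd)), 1e-3)))
  init_fun <- function(chain) theta0 + stats::rnorm(length(theta0), 0, 0.1)

  draws <- hmc_sample(lp, init_fun, mcmc)

  # back-transform: sampled b -> centered-basis gamma -> raw basis beta
  D <- draws$draws
  Tmat <- solve(R_mat)
  unstd <- function(B) {
    G <- B %*% t(Tmat)
    G[, 1] <- G[, 1] - as.matrix(G[, -1, drop = FALSE]) %*% centers[-1]
    G
  }
  beta_A <- unstd(D[, seq_len(k), drop = FALSE])
  beta_B <- unstd(D[, k + seq_len(k), drop = FALSE])
  sigma <- exp(D[, 2 * k + 1])
  colnames(beta_A) <- colnames(beta_B) <- colnames(X)

  par_names <- c(paste0("beta_A.", colnames(X)), paste0("beta_B.", colnames(X)),
                 "log_sigma")
  names(draws$diagnostics$rhat) <- par_names
  names(draws$diagnostics$ess) <- par_names
  max_rhat <- max(draws$diagnostics$rhat, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > 1.01) {
    warning("max split R-hat = ", format(max_rhat, digits = 4),
            " exceeds 1.01; consider more iterations")
  }

  structure(
    list(draws = list(beta_A = beta_A, beta_B = beta_B, sigma = sigma),
         chain = draws$chain,
         spec = spec, priors = priors, mcmc = mcmc,
         group = group, labels = labels,
         data = data.frame(age = cohort$age, mmse = y, group_a = in_a),
         diagnostics = draws$diagnostics,
         call = match.call()),
    class = "traj_fit"
  )
}

#' Posterior mean-curve draws on an age grid
#'
#' Evaluates each retained draw's group mean curve,
#' `curve_d(age) = rcs_design(age) %*% beta_{g,d}`.
#'
#' @param fit A [fit_trajectory()] result.
#' @param ages Numeric age grid.
#' @return List with matrices `A` and `B` (draws x ages) and `ages`.
#' @export
posterior_curves <- function(fit, ages) {
  stopifnot(inherits(fit, "traj_fit"))
  Xg <- rcs_design(ages, fit$spec)
  list(A = fit$draws$beta_A %*% t(Xg),
       B = fit$draws$beta_B %*% t(Xg),
       ages = as.numeric(ages))
}

#' @export
coef.traj_fit <- function(object, ...) {
  cbind(A = apply(object$draws$beta_A, 2L, stats::median),
        B = apply(object$draws$beta_B, 2L, stats::median))
}

#' Posterior summaries of the fitted trajectories
#'
#' @param object A `traj_fit`.
#' @param level Credible level for coefficient intervals.
#' @param ... Unused.
#' @export
summary.traj_fit <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  summarize <- function(B) {
    t(apply(B, 2L, function(x) {
      c(median = stats::median(x), stats::quantile(x, c(a, 1 - a)))
    }))
  }
  out <- list(
    labels = object$labels,
    coef_A = summarize(object$draws$beta_A),
    coef_B = summarize(object$draws$beta_B),
    sigma = stats::quantile(object$draws$sigma, c(a, 0.5, 1 - a)),
    n = c(A = sum(object$data$group_a), B = sum(!object$data$group_a)),
    knots = object$spec$knots,
    max_rhat = max(object$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(object$diagnostics$ess, na.rm = TRUE),
    divergences = sum(object$diagnostics$per_chain$divergences),
    level = level
  )
  class(out) <- "summary.traj_fit"
  out
}

#' @export
print.summary.traj_fit <- function(x, ...) {
  cat("Bayesian restricted cubic spline trajectory fit\n")
  cat("  groups: ", x$labels[1], " (n=", x$n["A"], ") vs ",
      x$labels[2], " (n=", x$n["B"], ")\n", sep = "")
  cat("  knots:", paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  cat("  posterior medians and", paste0(100 * x$level, "%"), "intervals:\n")
  cat("  --", x$labels[1], "--\n"); print(round(x$coef_A, 3))
  cat("  --", x$labels[2], "--\n"); print(round(x$coef_B, 3))
  cat("  sigma:", paste(format(x$sigma, digits = 3), collapse = " / "), "\n")
  cat("  diagnostics: max split R-hat ", format(x$max_rhat, digits = 4),
      ", min ESS ", format(x$min_ess, digits = 4),
      ", divergences ", x$divergences, "\n", sep = "")
  invisible(x)
}

#' @export
print.traj_fit <- function(x, ...) {
  cat("traj_fit: ", x$labels[1], " vs ", x$labels[2],
      " (", nrow(x$draws$beta_A), " posterior draws, ",
      length(x$spec$knots), " knots)\n", sep = "")
  cat("max split R-hat:", format(max(x$diagnostics$rhat, na.rm = TRUE),
                                 digits = 4), "\n")
  invisible(x)
}

#' Posterior trajectory prediction
#'
#' @param object A `traj_fit`.
#' @param ages Age grid (default: 200 points over the observed range).
#' @param level Credible level for the equal-tailed band (default 0.99).
#' @param ... Unused.
#' @return Data frame with `age`, `group` (the two group labels), posterior
#'   `median`, and band `lo`/`hi`.
#' @export
predict.traj_fit <- function(object, ages = NULL, level = 0.99, ...) {
  if (is.null(ages)) {
    ages <- seq(min(object$data$age), max(object$data$age), length.out = 200L)
  }
  cv <- posterior_curves(object, ages)
  a <- (1 - level) / 2
  one <- function(M, label) {
    data.frame(age = ages, group = label,
               median = apply(M, 2L, stats::median),
               lo = apply(M, 2L, stats::quantile, probs = a),
               hi = apply(M, 2L, stats::quantile, probs = 1 - a),
               stringsAsFactors = FALSE)
  }
  rbind(one(cv$A, object$labels[1]), one(cv$B, object$labels[2]))
}

#' @export
fitted.traj_fit <- function(object, ...) {
  X <- rcs_design(object$data$age, object$spec)
  med_A <- drop(X %*% apply(object$draws$beta_A, 2L, stats::median))
  med_B <- drop(X %*% apply(object$draws$beta_B, 2L, stats::median))
  ifelse(object$data$group_a, med_A, med_B)
}

#' @export
residuals.traj_fit <- function(object, ...) {
  object$data$mmse - fitted(object)
}

#' Posterior predictive MMSE simulation
#'
#' Draws replicate MMSE scores at the observed ages: for each simulation a
#' posterior draw (coefficients and noise SD) is selected at random and
#' Gaussian observation noise added, then scores are rounded and clipped to
#' 0--30.
#'
#' @param object A `traj_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Integer matrix, one column per simulation.
#' @export
simulate.traj_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- rcs_design(object$data$age, object$spec)
  n <- nrow(X)
  D <- nrow(object$draws$beta_A)
  out <- matrix(NA_integer_, n, nsim)
  for (s in seq_len(nsim)) {
    d <- sample.int(D, 1L)
    mu_A <- drop(X %*% object$draws$beta_A[d, ])
    mu_B <- drop(X %*% object$draws$beta_B[d, ])
    mu <- ifelse(object$data$group_a, mu_A, mu_B)
    y <- round(mu + stats::rnorm(n, 0, object$draws$sigma[d]))
    out[, s] <- as.integer(pmin(pmax(y, 0), 30))
  }
  out
}

#' Plot fitted trajectories
#'
#' Scatter of MMSE by age with posterior median curves and shaded credible
#' bands for both groups (group A in red, group B in black).
#'
#' @param x A `traj_fit`.
#' @param level Credible level for the bands (default 0.99).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.traj_fit <- function(x, level = 0.99, ...) {
  pred <- predict(x, level = level)
  cols <- c(grDevices::rgb(0.8, 0.1, 0.1), "black")
  band_cols <- c(grDevices::rgb(0.8, 0.1, 0.1, 0.25),
                 grDevices::rgb(0, 0, 0, 0.25))
  graphics::plot(x$data$age, x$data$mmse,
                 col = ifelse(x$data$group_a, cols[1], cols[2]),
                 pch = 16, cex = 0.4, xlab = "Age (years)", ylab = "MMSE", ...)
  for (g in 1:2) {
    pg <- pred[pred$group == x$labels[g], ]
    graphics::polygon(c(pg$age, rev(pg$age)), c(pg$lo, rev(pg$hi)),
                      col = band_cols[g], border = NA)
    graphics::lines(pg$age, pg$median, col = cols[g], lwd = 2)
  }
  graphics::legend("bottomleft", legend = x$labels, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
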