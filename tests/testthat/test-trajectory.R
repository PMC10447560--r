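make_two_group_data <- function(n = 60, seed = 3, noise = 1) {
  set.seed(seed)
  age_A <- runif(n, 20, 70); age_B <- runif(n, 20, 70)
  list(age_A = age_A, age_B = age_B,
       y_A = 28 - 0.2 * age_A + rnorm(n, 0, noise),
       y_B = 29 - 0.05 * age_B + rnorm(n, 0, noise))
}

test_that("log_posterior matches an independent term-by-term evaluation", {
  spec <- rcs_spec(c(30, 45, 60))
  d <- make_two_group_data(n = 3)
  X_A <- rcs_design(d$age_A, spec); X_B <- rcs_design(d$age_B, spec)
  k <- ncol(X_A)
  beta_A <- c(27, -0.1, 0.4); beta_B <- c(29, -0.02, -0.1)
  sigma <- 1.7
  pr <- prior_spec(beta_scale = 2.5, sigma_scale = 5)
  got <- log_posterior(c(beta_A, beta_B, log(sigma)), X_A, d$y_A, X_B, d$y_B,
                       priors = pr)
  want <- sum(dnorm(d$y_A, drop(X_A %*% beta_A), sigma, log = TRUE)) +
    sum(dnorm(d$y_B, drop(X_B %*% beta_B), sigma, log = TRUE)) +
    sum(dcauchy(c(beta_A, beta_B), 0, 2.5, log = TRUE)) +
    log(2) + dcauchy(sigma, 0, 5, log = TRUE) +
    log(sigma)  # Jacobian of the log transform
  expect_equal(got$value, want, tolerance = 1e-10)

  # zero data rows: prior only
  X0 <- matrix(numeric(0), 0, k)
  got0 <- log_posterior(c(beta_A, beta_B, log(sigma)), X0, numeric(0),
                        X0, numeric(0), priors = pr)
  want0 <- sum(dcauchy(c(beta_A, beta_B), 0, 2.5, log = TRUE)) +
    log(2) + dcauchy(sigma, 0, 5, log = TRUE) + log(sigma)
  expect_equal(got0$value, want0, tolerance = 1e-10)

  # Gaussian-prior, fixed-sigma variant
  prg <- prior_spec(beta_scale = 2, family = "gaussian")
  gotg <- log_posterior(c(beta_A, beta_B), X_A, d$y_A, X_B, d$y_B,
                        priors = prg, sigma_fixed = sigma)
  wantg <- sum(dnorm(d$y_A, drop(X_A %*% beta_A), sigma, log = TRUE)) +
    sum(dnorm(d$y_B, drop(X_B %*% beta_B), sigma, log = TRUE)) +
    sum(dnorm(c(beta_A, beta_B), 0, 2, log = TRUE))
  expect_equal(gotg$value, wantg, tolerance = 1e-10)
  expect_error(log_posterior(c(beta_A, beta_B), X_A, d$y_A, X_B, d$y_B),
               "length")
  expect_error(log_posterior(c(beta_A, beta_B, NaN), X_A, d$y_A, X_B, d$y_B),
               "non-finite")
})

test_that("analytic gradients match central finite differences", {
  spec <- rcs_spec(c(25, 40, 55, 68))
  d <- make_two_group_data(n = 15, seed = 10)
  X_A <- rcs_design(d$age_A, spec); X_B <- rcs_design(d$age_B, spec)
  k <- ncol(X_A)
  set.seed(99)
  for (fam in c("cauchy", "gaussian")) {
    pr <- prior_spec(family = fam)
    for (rep in 1:5) {
      theta <- c(rnorm(2 * k, 0, 2), log(runif(1, 0.5, 3)))
      got <- log_posterior(theta, X_A, d$y_A, X_B, d$y_B, priors = pr)
      num <- num_grad(function(t) {
        log_posterior(t, X_A, d$y_A, X_B, d$y_B, priors = pr)$value
      }, theta)
      expect_lt(max(abs(got$grad - num)), 1e-5)
    }
  }
})

test_that("noiseless linear trajectories are recovered within 0.1 point", {
  set.seed(4)
  n <- 80
  co <- data.frame(
    id = paste0("L", 1:(2 * n)),
    age = runif(2 * n, 20, 70),
    sex = "F", education_years = 8,
    psen1_carrier = rep(c(TRUE, FALSE), each = n),
    apoe_allele_1 = "e3", apoe_allele_2 = "e3",
    stringsAsFactors = FALSE
  )
  mu <- ifelse(co$psen1_carrier, 28 - 0.20 * co$age, 29.5 - 0.03 * co$age)
  co$mmse <- as.integer(round(pmin(pmax(mu, 0), 30)))
  # rounding to integers is the only noise; the affine truth is exactly
  # representable in the basis
  fit <- suppressWarnings(fit_trajectory(
    co, group = "psen1",
    mcmc = mcmc_config(chains = 2, iterations = 1500, thin = 1, seed = 2)))
  grid <- seq(22, 68, by = 1)
  cv <- posterior_curves(fit, grid)
  med_A <- apply(cv$A, 2, median)
  med_B <- apply(cv$B, 2, median)
  # integer rounding of a nearly flat line leaves a staircase the spline
  # tracks; allow half a rounding step beyond the exact-representation error
  expect_lt(max(abs(med_A - (28 - 0.20 * grid))), 0.5)
  expect_lt(max(abs(med_B - (29.5 - 0.03 * grid))), 0.5)
})

test_that("undersized groups are refused by name", {
  co <- tiny_cohort(12)
  co$psen1_carrier <- rep(c(TRUE, FALSE), c(3, 9))
  expect_error(
    fit_trajectory(co, group = "psen1", n_knots = 3),
    "PSEN1 carriers.*3 observations")
})

test_that("posterior curves are linear in the coefficients", {
  spec <- rcs_spec(c(30, 45, 60))
  fake <- structure(list(
    draws = list(beta_A = matrix(0, 150, 3),
                 beta_B = matrix(rnorm(450), 150, 3),
                 sigma = rep(1, 150)),
    spec = spec, labels = c("A", "B"),
    data = data.frame(age = c(30, 60), mmse = c(30, 20),
                      group_a = c(TRUE, FALSE))
  ), class = "traj_fit")
  cv <- posterior_curves(fake, c(35, 50, 65))
  expect_equal(cv$A, matrix(0, 150, 3))
  # doubling coefficients doubles the curve
  fake2 <- fake
  fake2$draws$beta_B <- 2 * fake$draws$beta_B
  expect_equal(posterior_curves(fake2, c(35, 50, 65))$B, 2 * cv$B)
})

test_that("thinning and chain count move Monte-Carlo error, not location", {
  sim <- simulate_cohort(cohort_params(n_carriers = 120, n_noncarriers = 100),
                         seed = 6)
  f1 <- suppressWarnings(fit_trajectory(
    sim$cohort, group = "psen1",
    mcmc = mcmc_config(chains = 4, iterations = 1600, thin = 4, seed = 11)))
  f2 <- suppressWarnings(fit_trajectory(
    sim$cohort, group = "psen1",
    mcmc = mcmc_config(chains = 2, iterations = 1600, thin = 1, seed = 12)))
  grid <- c(30, 40, 50, 60)
  for (a in seq_along(grid)) {
    c1 <- posterior_curves(f1, grid[a])$A[, 1]
    c2 <- posterior_curves(f2, grid[a])$A[, 1]
    mcse1 <- mcse_mean(split(c1, f1$chain))
    mcse2 <- mcse_mean(split(c2, f2$chain))
    expect_lt(abs(median(c1) - median(c2)),
              3 * sqrt(mcse1^2 + mcse2^2) + 0.05)
  }
})

test_that("fit methods return coherent shapes", {
  sim <- simulate_cohort(cohort_params(n_carriers = 100, n_noncarriers = 80),
                         seed = 14)
  fit <- suppressWarnings(fit_trajectory(
    sim$cohort, group = "psen1",
    mcmc = mcmc_config(chains = 2, iterations = 800, thin = 2, seed = 3)))
  expect_equal(dim(coef(fit)), c(5L, 2L))
  pr <- predict(fit, ages = c(30, 50), level = 0.95)
  expect_equal(nrow(pr), 4L)
  expect_true(all(pr$lo <= pr$median & pr$median <= pr$hi))
  expect_length(residuals(fit), 180L)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(180L, 2L))
  expect_true(all(sims >= 0 & sims <= 30))
  s <- summary(fit)
  expect_s3_class(s, "summary.traj_fit")
  expect_output(print(s), "restricted cubic spline")
})
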