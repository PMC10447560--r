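test_that("difference draws are elementwise and antisymmetric", {
  set.seed(1)
  A <- matrix(rnorm(200 * 5), 200, 5)
  B <- matrix(rnorm(200 * 5), 200, 5)
  expect_equal(difference_draws(A, A), matrix(0, 200, 5))
  expect_equal(difference_draws(A, B), -difference_draws(B, A))
  expect_equal(difference_draws(A + 2.5, B), difference_draws(A, B) + 2.5)
  expect_error(difference_draws(A, B[, 1:3]), "shape")
})

test_that("credible bands are equal-tailed empirical quantiles", {
  set.seed(2)
  draws <- matrix(rnorm(4000), ncol = 1)
  band <- credible_band(draws, level = 0.99)
  expect_lt(abs(band$lower + 2.576), 0.25)
  expect_lt(abs(band$upper - 2.576), 0.25)
  # constant draws collapse the band
  const <- matrix(3.3, 200, 2)
  bc <- credible_band(const)
  expect_equal(bc$lower, c(3.3, 3.3))
  expect_equal(bc$upper, c(3.3, 3.3))
  expect_error(credible_band(draws[1:50, , drop = FALSE]), "100 draws")
  expect_error(credible_band(draws, level = 0), "level")
  expect_error(credible_band(draws, level = 1), "level")
})

test_that("divergence age is the earliest sustained band exclusion", {
  ages <- seq(40, 50, by = 0.1)
  # strictly positive band everywhere: first grid age
  expect_equal(divergence_age(ages, rep(1, 101), rep(2, 101), "upper"), 40)
  # band straddles zero everywhere: none
  expect_true(is.na(divergence_age(ages, rep(-1, 101), rep(1, 101), "lower")))
  # under the strict to-the-end rule, exclusion that lapses does not count
  lo <- rep(-1, 101); hi <- rep(-0.1, 101)
  hi[60:101] <- 1  # re-includes zero at old ages
  expect_true(is.na(divergence_age(ages, lo, hi, "lower",
                                   sustain_years = Inf)))
  # ...but a run persisting >= sustain_years does (40 to 45.9 = 5.9 years)
  expect_equal(divergence_age(ages, lo, hi, "lower", sustain_years = 5), 40)
  # a short blip (< sustain_years) never defines onset
  hi2 <- rep(1, 101); hi2[20:30] <- -0.1  # 1.0-year run at 41.9
  expect_true(is.na(divergence_age(ages, rep(-2, 101), hi2, "lower",
                                   sustain_years = 5)))
  # a run reaching the end of the grid qualifies even if short
  hi3 <- rep(1, 101); hi3[95:101] <- -0.1
  expect_equal(divergence_age(ages, rep(-2, 101), hi3, "lower"), 49.4)
})

test_that("constructed noisy ramp reproduces the brute-force scan", {
  set.seed(42)
  ages <- seq(35, 55, by = 0.1)
  n_draws <- 2000
  # difference zero before 45, then linearly growing, with draw noise
  signal <- pmax(ages - 45, 0) * 0.35
  diffs <- matrix(rep(signal, each = n_draws), n_draws) +
    matrix(rnorm(n_draws * length(ages), 0, 0.4), n_draws)
  band <- credible_band(diffs, 0.99)
  got <- divergence_age(ages, band$lower, band$upper, "upper")
  want <- brute_divergence_age(diffs, ages, 0.99, "upper")
  expect_equal(got, want)
  expect_lt(abs(got - 45 - 2.576 * 0.4 / 0.35), 1.5)
})

test_that("bands and divergence ages are monotone in the credible level", {
  set.seed(7)
  ages <- seq(30, 60, by = 0.5)
  signal <- pmax(ages - 44, 0) * 0.3
  diffs <- matrix(rep(signal, each = 800), 800) +
    matrix(rnorm(800 * length(ages), 0, 0.5), 800)
  b99 <- credible_band(diffs, 0.99)
  b95 <- credible_band(diffs, 0.95)
  expect_true(all(b99$lower <= b95$lower + 1e-12))
  expect_true(all(b99$upper >= b95$upper - 1e-12))
  a99 <- divergence_age(ages, b99$lower, b99$upper, "upper")
  a95 <- divergence_age(ages, b95$lower, b95$upper, "upper")
  expect_true(is.na(a99) || a99 >= a95)
})

test_that("divergence() summarises a fit on the documented grid", {
  sim <- simulate_cohort(cohort_params(n_carriers = 150, n_noncarriers = 120),
                         seed = 8)
  fit <- suppressWarnings(fit_trajectory(
    sim$cohort, group = "psen1",
    mcmc = mcmc_config(chains = 2, iterations = 1000, thin = 2, seed = 9)))
  div <- divergence(fit, level = 0.99, grid_step = 0.1, direction = "lower")
  tb <- div$table
  expect_equal(diff(tb$age)[1], 0.1, tolerance = 1e-9)
  qs <- quantile(fit$data$age, c(0.01, 0.99), type = 7)
  expect_gte(min(tb$age), qs[[1]] - 0.1)
  expect_lte(max(tb$age), qs[[2]] + 0.1)
  expect_true(all(tb$lo <= tb$median_diff & tb$median_diff <= tb$hi))
  if (!is.na(div$divergence_age)) {
    expect_true(div$divergence_age %in% tb$age)
    # exclusion persists for the sustain window after the divergence age
    win <- tb$age >= div$divergence_age &
      tb$age <= min(div$divergence_age + 5, max(tb$age))
    expect_true(all(tb$hi[win] < 0))
  }
})
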