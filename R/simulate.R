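# Synthetic kindred-cohort generator with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: cross-sectional adult ages, APOE genotypes drawn i.i.d. from the
# kindred's genotype distribution, a broad education distribution, and MMSE
# that is roughly flat in non-carriers but declines sigmoidally in mutation
# carriers, with the onset age shifted earlier by e4, later by e2, and later
# with more education.

#' Sigmoid mean MMSE curve
#'
#' `floor + (ceiling - floor) / (1 + exp(rate * (age - onset_age)))`:
#' a plateau at `ceiling` for ages well before `onset_age`, a monotone
#' decline through the midpoint at `onset_age`, and a floor thereafter.
#'
#' @param age Age(s) in years.
#' @param onset_age Inflection age of the decline (years).
#' @param rate Decline steepness (1/years), > 0.
#' @param ceiling,floor MMSE plateau and floor, `floor < ceiling`.
#' @return Mean MMSE at `age` (not rounded or clipped).
#' @export
mean_mmse <- function(age, onset_age, rate, ceiling = 30, floor = 0) {
  if (any(rate <= 0)) stop("rate must be > 0")
  if (any(floor >= ceiling)) stop("floor must be < ceiling")
  floor + (ceiling - floor) / (1 + exp(rate * (age - onset_age)))
}

#' Generator parameters
#'
#' Defaults mirror the kindred sample: 675 carriers and 594 non-carriers,
#' ages 18--75, APOE genotype probabilities equal to the carrier-stratum
#' genotype proportions of [apoe_reference_counts()], education ~ 7.4 +/- 4.4
#' years. The decline model places the carrier onset (sigmoid midpoint) at
#' `base_onset_age` 49, shifts it -5 years for e4+, +5 for e2+, and +0.3
#' years per education year (centred at `education_mean`); these are
#' simulation defaults chosen so the e4 divergence lands in the mid-40s, not
#' estimates of the kindred. Ages are uniform by default; `age_dist =
#' "truncnorm"` draws ages from a normal(`age_mean`, `age_sd`) truncated to
#' `age_range`, matching the kindred's observed age moments (about 34 +/- 11).
#'
#' @param n_carriers,n_noncarriers Stratum sizes.
#' @param age_range Length-2 numeric, minimum >= 18.
#' @param age_dist `"uniform"` or `"truncnorm"`.
#' @param age_mean,age_sd Moments for the truncated-normal age mode.
#' @param apoe_genotype_probs Named probabilities over the six unordered
#'   genotypes (must sum to 1).
#' @param education_mean,education_sd Education draw is
#'   normal(mean, sd) clipped to [0, 20] years.
#' @param p_female Probability a participant is female.
#' @param mmse_ceiling,mmse_floor MMSE plateau and floor.
#' @param base_onset_age Carrier onset age before genotype/education shifts.
#' @param decline_rate Sigmoid steepness (1/years).
#' @param e4_onset_shift,e2_onset_shift Onset shift (years) for e4+/e2+
#'   carriers; negative = earlier.
#' @param education_onset_shift_per_year Onset shift per education year.
#' @param noncarrier_slope Small linear MMSE loss per year in non-carriers.
#' @param noise_sd Observation noise SD in MMSE points (>= 0; 0 gives the
#'   noiseless mean curve, useful for validation).
#' @return An object of class `cohort_params` (a validated list).
#' @export
cohort_params <- function(n_carriers = 675L,
                          n_noncarriers = 594L,
                          age_range = c(18, 75),
                          age_dist = c("uniform", "truncnorm"),
                          age_mean = 34,
                          age_sd = 11,
                          apoe_genotype_probs = NULL,
                          education_mean = 7.4,
                          education_sd = 4.4,
                          p_female = 0.55,
                          mmse_ceiling = 30,
                          mmse_floor = 0,
                          base_onset_age = 49,
                          decline_rate = 0.45,
                          e4_onset_shift = -5,
                          e2_onset_shift = 5,
                          education_onset_shift_per_year = 0.3,
                          noncarrier_slope = 0.03,
                          noise_sd = 2.5) {
  age_dist <- match.arg(age_dist)
  if (is.null(apoe_genotype_probs)) {
    counts <- apoe_reference_counts()
    apoe_genotype_probs <- stats::setNames(counts$carriers / sum(counts$carriers),
                                           counts$genotype)
  }
  if (!setequal(names(apoe_genotype_probs), apoe_genotypes())) {
    stop("apoe_genotype_probs must be named by the six unordered genotypes")
  }
  apoe_genotype_probs <- apoe_genotype_probs[apoe_genotypes()]
  if (abs(sum(apoe_genotype_probs) - 1) > 1e-12) {
    stop("apoe_genotype_probs must sum to 1")
  }
  if (age_range[1] < 18) stop("age_range minimum must be >= 18")
  if (diff(age_range) <= 0) stop("age_range must be increasing")
  if (mmse_floor >= mmse_ceiling) stop("mmse_floor must be < mmse_ceiling")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (decline_rate <= 0) stop("decline_rate must be > 0")
  structure(as.list(environment()), class = "cohort_params")
}

# Deterministic sub-stream seeds: one stream per random component so that
# enlarging the cohort appends draws without reshuffling earlier ones.
sub_seed <- function(seed, component) {
  as.integer((as.numeric(seed) + 104729 * component) %% 2147483587) + 1L
}

draw_ages <- function(n, p) {
  if (p$age_dist == "uniform") {
    stats::runif(n, p$age_range[1], p$age_range[2])
  } else {
    # truncated normal by inversion
    lo <- stats::pnorm(p$age_range[1], p$age_mean, p$age_sd)
    hi <- stats::pnorm(p$age_range[2], p$age_mean, p$age_sd)
    stats::qnorm(stats::runif(n, lo, hi), p$age_mean, p$age_sd)
  }
}

#' Generate a synthetic cohort with ground truth
#'
#' Ages, genotypes, sex and education are drawn independently per
#' participant; carrier MMSE is `round(clip(mean_mmse(age, onset) + noise))`
#' where each carrier's latent onset is
#' `base_onset_age + e4_shift * I(e4+) + e2_shift * I(e2+) +
#'  edu_shift * (education - education_mean)`;
#' non-carrier MMSE declines linearly and shallowly from the ceiling.
#' Identical `params` and `seed` reproduce the cohort exactly.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @return An object of class `sim_cohort`: list with `cohort` (validated
#'   cohort data frame), `truth` (per-participant latent onset age and
#'   noiseless mean MMSE), `params`, `seed`.
#' @seealso [truth_mean_curve()]
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n_carriers + p$n_noncarriers
  carrier <- rep(c(TRUE, FALSE), c(p$n_carriers, p$n_noncarriers))

  with_seed <- function(component, expr) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(sub_seed(seed, component))
    expr
  }
  age <- with_seed(1L, draw_ages(n, p))
  genotype <- with_seed(2L, sample(apoe_genotypes(), n, replace = TRUE,
                                   prob = p$apoe_genotype_probs))
  education <- with_seed(3L, pmin(pmax(stats::rnorm(n, p$education_mean,
                                                    p$education_sd), 0), 20))
  sex <- with_seed(4L, ifelse(stats::runif(n) < p$p_female, "F", "M"))
  noise <- with_seed(5L, stats::rnorm(n, 0, max(p$noise_sd, .Machine$double.eps)))
  if (p$noise_sd == 0) noise[] <- 0

  flags <- classify_apoe(sub("/.*", "", genotype), sub(".*/", "", genotype))
  onset <- p$base_onset_age +
    p$e4_onset_shift * flags$e4_positive +
    p$e2_onset_shift * flags$e2_positive +
    p$education_onset_shift_per_year * (education - p$education_mean)
  onset[!carrier] <- NA_real_

  mu <- numeric(n)
  mu[carrier] <- mean_mmse(age[carrier], onset[carrier], p$decline_rate,
                           p$mmse_ceiling, p$mmse_floor)
  mu[!carrier] <- p$mmse_ceiling - p$noncarrier_slope * (age[!carrier] - 18)
  mmse <- as.integer(round(pmin(pmax(mu + noise, p$mmse_floor), p$mmse_ceiling)))

  cohort <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, education_years = education, mmse = mmse,
    psen1_carrier = carrier,
    apoe_allele_1 = sub("/.*", "", genotype),
    apoe_allele_2 = sub(".*/", "", genotype),
    stringsAsFactors = FALSE
  )
  cohort <- validate_cohort(cohort)
  truth <- data.frame(id = cohort$id, onset_age = onset, mean_mmse = mu,
                      stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth, params = p, seed = seed),
            class = "sim_cohort")
}

#' Noiseless group-mean MMSE curve from generator ground truth
#'
#' Returns the population-average mean curve of a subset of participants:
#' the pointwise average over the subset of each participant's noiseless
#' mean-MMSE curve (sigmoid with that participant's latent onset for
#' carriers, the shallow linear trend for non-carriers).
#'
#' @param sim A [simulate_cohort()] result.
#' @param subset Logical or integer index into the cohort rows.
#' @return A function of age returning the group-mean MMSE.
#' @export
truth_mean_curve <- function(sim, subset) {
  stopifnot(inherits(sim, "sim_cohort"))
  p <- sim$params
  rows <- seq_len(nrow(sim$cohort))[subset]
  if (length(rows) == 0L) stop("subset selects no participants")
  carrier <- sim$cohort$psen1_carrier[rows]
  onset <- sim$truth$onset_age[rows]
  function(age) {
    vapply(age, function(a) {
      vals <- numeric(length(rows))
      vals[carrier] <- mean_mmse(a, onset[carrier], p$decline_rate,
                                 p$mmse_ceiling, p$mmse_floor)
      vals[!carrier] <- p$mmse_ceiling - p$noncarrier_slope * (a - 18)
      mean(vals)
    }, numeric(1))
  }
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic kindred cohort: ", x$params$n_carriers, " carriers + ",
      x$params$n_noncarriers, " non-carriers (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
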