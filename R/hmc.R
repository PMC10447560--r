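# Hamiltonian Monte Carlo with a fixed-length leapfrog integrator, identity
# mass matrix, and dual-averaging step-size adaptation (frozen after
# warmup). The sampler is generic: it takes any log-density that also
# returns its gradient.

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2; default 8).
#' @param iterations Total iterations per chain, including warmup
#'   (default 10000).
#' @param thin Post-warmup thinning interval (default 10).
#' @param warmup Warmup iterations (default `iterations / 2`); step size is
#'   adapted during warmup only.
#' @param L Leapfrog steps per proposal (default 20).
#' @param target_accept Dual-averaging target acceptance rate (default 0.8).
#' @param step_init Initial leapfrog step size (default 0.1).
#' @param seed Integer seed; per-chain seeds are derived deterministically.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 8L, iterations = 10000L, thin = 10L,
                        warmup = NULL, L = 20L, target_accept = 0.8,
                        step_init = 0.1, seed = 1L) {
  if (is.null(warmup)) warmup <- iterations %/% 2L
  stopifnot(chains >= 2L, thin >= 1L, warmup < iterations, L >= 1L,
            target_accept > 0, target_accept < 1, step_init > 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin), warmup = as.integer(warmup),
                 L = as.integer(L), target_accept = target_accept,
                 step_init = step_init, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Desk- and paper-scale MCMC presets
#'
#' `"desk"` (chains = 4, iterations = 2000, thin = 2) is sized for
#' interactive use and test suites; `"paper"` (chains = 8, iterations =
#' 10000, thin = 10) matches the full analysis configuration. Both retain
#' draws after a half-length warmup.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Integer seed.
#' @return An [mcmc_config()] object.
#' @export
mcmc_preset <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    mcmc_config(chains = 4L, iterations = 2000L, thin = 2L, seed = seed)
  } else {
    mcmc_config(chains = 8L, iterations = 10000L, thin = 10L, seed = seed)
  }
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) + 1000003 * chain) %% 2147483587) + 1L
}

#' Sample from a log-density by Hamiltonian Monte Carlo
#'
#' Standard HMC: momenta are refreshed from a standard normal, a fixed
#' number of leapfrog steps integrates Hamilton's equations under an
#' identity mass matrix, and the proposal is accepted by a Metropolis test
#' on the change in Hamiltonian. During warmup the step size is adapted to
#' the target acceptance rate by dual averaging, then frozen. A proposal
#' whose Hamiltonian becomes non-finite or increases by more than 1000 is
#' counted as divergent and rejected; if more than half of post-warmup
#' proposals diverge a warning suggests a smaller initial step size.
#'
#' @param log_post Function of the parameter vector returning a list with
#'   elements `value` (log density) and `grad` (its gradient).
#' @param init Numeric initial parameter vector, or a function of the chain
#'   index returning one.
#' @param config An [mcmc_config()].
#' @return An object of class `hmc_draws`: list with `draws` (matrix, one
#'   row per retained draw), `chain` (chain index per draw), and
#'   `diagnostics` (per-chain acceptance rate, step size, divergence count;
#'   split R-hat and effective sample size per parameter).
#' @export
hmc_sample <- function(log_post, init, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  init_fun <- if (is.function(init)) init else function(chain) init
  kept_per_chain <- (config$iterations - config$warmup) %/% config$thin
  chains_out <- vector("list", config$chains)
  diag_rows <- vector("list", config$chains)

  for (ch in seq_len(config$chains)) {
    set.seed(chain_seed(config$seed, ch))
    theta <- as.numeric(init_fun(ch))
    d <- length(theta)
    cur <- log_post(theta)
    if (!is.finite(cur$value)) stop("initial state has non-finite log density")

    # dual averaging state (Hoffman & Gelman 2014 defaults)
    eps <- config$step_init
    mu <- log(10 * eps)
    log_eps_bar <- 0
    h_bar <- 0
    gamma <- 0.05; t0 <- 10; kappa <- 0.75

    kept <- matrix(NA_real_, kept_per_chain, d)
    kept_i <- 0L
    n_accept <- 0L; n_post <- 0L; n_div <- 0L

    for (it in seq_len(config$iterations)) {
      p0 <- stats::rnorm(d)
      th <- theta; gr <- cur$grad; p <- p0
      h0 <- -cur$value + 0.5 * sum(p0^2)
      # leapfrog
      p <- p + 0.5 * eps * gr
      divergent <- FALSE
      lp <- cur
      for (l in seq_len(config$L)) {
        th <- th + eps * p
        lp <- log_post(th)
        if (!all(is.finite(lp$grad)) || !is.finite(lp$value)) {
          divergent <- TRUE; break
        }
        if (l < config$L) p <- p + eps * lp$grad
      }
      if (!divergent) {
        p <- p + 0.5 * eps * lp$grad
        h1 <- -lp$value + 0.5 * sum(p^2)
        delta_h <- h1 - h0
        if (!is.finite(delta_h) || delta_h > 1000) divergent <- TRUE
      }
      if (divergent) {
        accept_prob <- 0
        if (it > config$warmup) n_div <- n_div + 1L
      } else {
        accept_prob <- min(1, exp(-delta_h))
        if (stats::runif(1) < accept_prob) {
          theta <- th
          cur <- lp
        }
      }
      if (it <= config$warmup) {
        m <- it
        h_bar <- (1 - 1 / (m + t0)) * h_bar +
          (config$target_accept - accept_prob) / (m + t0)
        log_eps <- mu - sqrt(m) / gamma * h_bar
        w <- m^(-kappa)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
        eps <- exp(log_eps)
        if (m == config$warmup) eps <- exp(log_eps_bar)
      } else {
        n_post <- n_post + 1L
        n_accept <- n_accept + accept_prob
        post_it <- it - config$warmup
        if (post_it %% config$thin == 0L && kept_i < kept_per_chain) {
          kept_i <- kept_i + 1L
          kept[kept_i, ] <- theta
        }
      }
    }
    if (n_post > 0 && n_div > n_post / 2) {
      warning("chain ", ch, ": more than half of post-warmup proposals ",
              "diverged; consider a smaller step_init or fewer leapfrog steps")
    }
    chains_out[[ch]] <- kept
    diag_rows[[ch]] <- data.frame(
      chain = ch,
      accept_rate = if (n_post > 0) n_accept / n_post else NA_real_,
      step_size = eps, divergences = n_div
    )
  }

  draws <- do.call(rbind, chains_out)
  chain_id <- rep(seq_len(config$chains), each = kept_per_chain)
  rhat <- apply_chainwise(draws, chain_id, split_rhat)
  ess <- apply_chainwise(draws, chain_id, ess_mean)
  structure(
    list(draws = draws, chain = chain_id,
         diagnostics = list(per_chain = do.call(rbind, diag_rows),
                            rhat = rhat, ess = ess),
         config = config),
    class = "hmc_draws"
  )
}

apply_chainwise <- function(draws, chain_id, fn) {
  apply(draws, 2L, function(x) fn(split(x, chain_id)))
}

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' statistic is computed over the resulting 2m half-chains.
#'
#' @param chains List of numeric vectors, one per chain (equal lengths).
#' @return The split R-hat (>= 1; values near 1 indicate mixing).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size for a posterior mean
#'
#' Combined over chains using chain-averaged autocorrelations with Geyer's
#' initial monotone positive sequence truncation.
#'
#' @param chains List of numeric vectors, one per chain.
#' @return Estimated effective sample size.
#' @export
ess_mean <- function(chains) {
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4L) return(NA_real_)
  total_var <- stats::var(unlist(chains))
  if (total_var == 0) return(m * n)
  max_lag <- min(n - 2L, 500L)
  acov <- sapply(chains, function(x) {
    x <- x[seq_len(n)] - mean(x[seq_len(n)])
    vapply(0:max_lag, function(l) {
      sum(x[seq_len(n - l)] * x[(1 + l):n]) / n
    }, numeric(1))
  })
  rho <- rowMeans(acov) / total_var  # rho[1] is lag 0
  # Geyer initial monotone positive sequence on paired lag sums
  # P_m = rho_{2m} + rho_{2m+1}
  n_pairs <- length(rho) %/% 2L
  pair_sums <- rho[2 * seq_len(n_pairs) - 1L] + rho[2 * seq_len(n_pairs)]
  pos <- which(pair_sums <= 0)
  k <- if (length(pos)) pos[1] - 1L else n_pairs
  if (k == 0L) return(m * n)
  ps <- cummin(pair_sums[seq_len(k)])
  tau <- -1 + 2 * sum(ps)
  max(m * n / max(tau, 1e-3), 1)
}

#' Monte Carlo standard error of a posterior mean
#'
#' @param chains List of numeric vectors, one per chain.
#' @return `sd / sqrt(ess)`.
#' @export
mcse_mean <- function(chains) {
  stats::sd(unlist(chains)) / sqrt(ess_mean(chains))
}

#' @export
print.hmc_draws <- function(x, ...) {
  cat("HMC draws: ", nrow(x$draws), " retained draws (",
      x$config$chains, " chains x ", ncol(x$draws), " parameters)\n", sep = "")
  cat("max split R-hat:", format(max(x$diagnostics$rhat), digits = 4),
      " min ESS:", format(min(x$diagnostics$ess), digits = 4), "\n")
  cat("mean acceptance:",
      format(mean(x$diagnostics$per_chain$accept_rate), digits = 3),
      " divergences:", sum(x$diagnostics$per_chain$divergences), "\n")
  invisible(x)
}
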