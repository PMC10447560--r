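# Independent oracles used across the suite. These deliberately use the
# naive textbook formulas, not the package's code paths.

# OLS by explicit normal equations.
brute_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(sigma2 * diag(solve(XtX)))
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * pt(abs(tval), n - p, lower.tail = FALSE))
}

# Exact two-sided Mann-Whitney p by full enumeration of all assignments of
# the pooled (tie-free) sample to the two groups.
mw_exact_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2L, u_of)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Numerical gradient by the 4th-order five-point central stencil (keeps
# roundoff below ~1e-7 even when |f| is ~1e5).
num_grad <- function(f, theta, h = 1e-4) {
  vapply(seq_along(theta), function(i) {
    hp <- h * (1 + abs(theta[i]))
    at <- function(d) { t <- theta; t[i] <- t[i] + d; f(t) }
    (at(-2 * hp) - 8 * at(-hp) + 8 * at(hp) - at(2 * hp)) / (12 * hp)
  }, numeric(1))
}

# Earliest sustained band exclusion by a naive per-age quantile scan
# (independent of divergence_age()): walk the grid, tracking runs of
# exclusion, and return the start of the first run that spans at least
# `sustain` years or hits the end of the grid.
brute_divergence_age <- function(diffs, ages, level = 0.99,
                                 direction = "lower", sustain = 5) {
  a <- (1 - level) / 2
  excl <- logical(length(ages))
  for (j in seq_along(ages)) {
    q <- quantile(diffs[, j], c(a, 1 - a), type = 7)
    excl[j] <- switch(direction,
      lower = q[2] < 0, upper = q[1] > 0,
      `two-sided` = q[2] < 0 || q[1] > 0)
  }
  start <- NA_integer_
  for (j in seq_along(ages)) {
    if (excl[j]) {
      if (is.na(start)) start <- j
      if (ages[j] - ages[start] >= sustain || j == length(ages)) {
        return(ages[start])
      }
    } else {
      start <- NA_integer_
    }
  }
  NA_real_
}

# Small valid cohort for IO and table tests.
tiny_cohort <- function(n = 6L) {
  data.frame(
    id = paste0("P", seq_len(n)),
    age = seq(20, 70, length.out = n),
    sex = rep_len(c("M", "F"), n),
    education_years = rep_len(c(4, 8, 12), n),
    mmse = rep_len(c(30L, 28L, 25L), n),
    psen1_carrier = rep_len(c(TRUE, FALSE), n),
    apoe_allele_1 = rep_len(c("e3", "e2", "e4"), n),
    apoe_allele_2 = rep_len("e3", n),
    stringsAsFactors = FALSE
  )
}
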