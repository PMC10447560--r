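# Two-sample comparison battery used for the demographic tables.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The U statistic is computed by the midrank
#' method. The p-value comes from exact enumeration when the combined sample
#' size is at most 12 and there are no ties, and otherwise from the normal
#' approximation with the tie-corrected variance and a continuity
#' correction (both delegated to [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples, both non-empty.
#' @return An object of class `group_test`: list with `statistic` (U for
#'   `x`), `p.value`, `n1`, `n2`, `ties` (number of tied values in the
#'   pooled sample), `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pooled <- c(x, y)
  ties <- sum(table(pooled)[table(pooled) > 1L])
  exact <- (n1 + n2 <= 12L) && ties == 0L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(u_x), p.value = wt$p.value, n1 = n1, n2 = n2,
         ties = ties,
         method = if (exact) "Mann-Whitney U (exact)"
                  else "Mann-Whitney U (normal approximation, tie/continuity corrected)"),
    class = "group_test"
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's X^2 = sum (O - E)^2 / E without Yates continuity correction,
#' compared to a chi-square distribution with 1 degree of freedom.
#'
#' @param counts 2x2 matrix (or table) of counts.
#' @return An object of class `group_test`: list with `statistic` (X^2),
#'   `p.value`, `df`, `expected`, `method`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(counts < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) stop("all expected counts must be > 0")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(statistic = unname(ct$statistic), p.value = ct$p.value,
         df = unname(ct$parameter), expected = expected,
         method = "Pearson chi-square (no continuity correction)"),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("statistic =", format(x$statistic), "  p =", format.pval(x$p.value), "\n")
  invisible(x)
}
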