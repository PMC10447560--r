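# Genotype x education interaction regressions on MMSE.

#' Ordinary least squares with a classical inference table
#'
#' Coefficients are obtained from the QR decomposition of the design (not
#' the normal equations); standard errors are
#' `sigma_hat * sqrt(diag((X'X)^-1))` with `sigma_hat^2 = RSS / (n - p)`,
#' and two-sided p-values come from the t distribution with `n - p`
#' degrees of freedom.
#'
#' @param y Response vector.
#' @param X Design matrix (include an intercept column if wanted); must
#'   have more rows than columns and full column rank.
#' @return An object of class `ols_fit`: list with `table` (term, estimate,
#'   se, t, p), `n`, `rank`, `sigma` (residual SD), `r.squared`,
#'   `residuals`, `fitted`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  if (nrow(X) <= ncol(X)) stop("more observations than columns are required")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  n <- length(y); p <- ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(
    list(table = data.frame(term = colnames(X), estimate = unname(beta),
                            se = unname(se), t = unname(tval),
                            p = unname(pval), stringsAsFactors = FALSE),
         n = n, rank = p, sigma = sqrt(sigma2),
         r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
         residuals = res, fitted = fitted),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  tb <- x$table
  tb$estimate <- signif(tb$estimate, digits)
  tb$se <- signif(tb$se, digits)
  tb$t <- signif(tb$t, digits)
  tb$p <- signif(tb$p, digits)
  print.data.frame(tb, row.names = FALSE)
  cat("n =", x$n, " residual SD =", signif(x$sigma, digits),
      " R^2 =", signif(x$r.squared, digits), "\n")
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  stats::setNames(object$table$estimate, object$table$term)
}

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
fitted.ols_fit <- function(object, ...) object$fitted

#' Genotype-by-education regression on MMSE
#'
#' Within one PSEN1 stratum, fits
#' `MMSE ~ genotype + education_years + genotype:education_years` by OLS.
#' The genotype indicator is coded in the risk orientation: for the e4
#' comparison, 1 = e4+ (at least one e4 allele); for the e2 comparison,
#' 1 = e2- (no e2 allele, the unprotected group). With this coding a
#' negative genotype coefficient means the risk group scores lower, and a
#' positive interaction means education attenuates that deficit. Education
#' is raw years (uncentred) by default.
#'
#' @param cohort A cohort data frame.
#' @param stratum `"carriers"` or `"noncarriers"`.
#' @param allele `"e4"` or `"e2"`.
#' @param center_education If `TRUE`, education is centred at its stratum
#'   mean before the interaction is formed (changes the genotype main
#'   effect's interpretation, not the interaction).
#' @return An `ols_fit` with terms `(Intercept)`, `genotype`,
#'   `education_years`, `genotype:education_years`, plus attributes
#'   `stratum`, `allele`, `risk_label`.
#' @export
education_model <- function(cohort,
                            stratum = c("carriers", "noncarriers"),
                            allele = c("e4", "e2"),
                            center_education = FALSE) {
  stratum <- match.arg(stratum)
  allele <- match.arg(allele)
  cohort <- add_apoe_groups(cohort)
  keep <- if (stratum == "carriers") cohort$psen1_carrier else !cohort$psen1_carrier
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0L) stop("stratum '", stratum, "' is empty")
  genotype <- if (allele == "e4") {
    as.numeric(cohort$e4_positive)          # 1 = e4+ (risk)
  } else {
    as.numeric(!cohort$e2_positive)         # 1 = e2- (unprotected)
  }
  if (length(unique(genotype)) < 2L) {
    stop("stratum '", stratum, "' contains a single ", allele,
         " genotype group; both groups are required")
  }
  edu <- cohort$education_years
  if (center_education) edu <- edu - mean(edu)
  X <- cbind(`(Intercept)` = 1, genotype = genotype,
             education_years = edu,
             `genotype:education_years` = genotype * edu)
  fit <- fit_ols(cohort$mmse, X)
  attr(fit, "stratum") <- stratum
  attr(fit, "allele") <- allele
  attr(fit, "risk_label") <- if (allele == "e4") "APOE e4+" else "APOE e2-"
  fit
}
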