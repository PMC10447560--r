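# Restricted (natural) cubic spline basis on age.

# Harrell's default knot-placement quantiles by knot count.
rcs_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
    stop("n_knots must be between 3 and 7")
  )
}

#' Spline specification from explicit knots
#'
#' @param knots Strictly increasing numeric vector of at least 3 knot ages.
#' @return An object of class `rcs_spec` with elements `knots` and
#'   `n_basis` (= k - 1 nonconstant columns: 1 linear + k - 2 cubic terms).
#' @export
rcs_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) stop("at least 3 knots are required")
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing and distinct; got ",
         paste(format(knots), collapse = ", "),
         " (a degenerate age distribution? try fewer knots)")
  }
  structure(list(knots = knots, n_basis = length(knots) - 1L),
            class = "rcs_spec")
}

#' Place spline knots at empirical age quantiles
#'
#' Knots are placed at Harrell's conventional quantiles for the requested
#' knot count (for k = 5: 0.05, 0.275, 0.5, 0.725, 0.95), computed with the
#' type-7 rule (linear interpolation between order statistics) so placement
#' is reproducible.
#'
#' @param ages Numeric vector of observed ages.
#' @param n_knots Number of knots, 3--7 (default 5).
#' @return An [rcs_spec()] object.
#' @export
place_knots <- function(ages, n_knots = 5L) {
  ages <- as.numeric(ages)
  if (anyNA(ages)) stop("ages must not contain NA")
  probs <- rcs_quantiles(n_knots)
  knots <- unname(stats::quantile(ages, probs = probs, type = 7))
  rcs_spec(knots)
}

#' Restricted cubic spline design matrix
#'
#' Columns are `[1, x, c_1(x), ..., c_{k-2}(x)]` where, with knots
#' `t_1 < ... < t_k` and `(u)+ = max(u, 0)`,
#' \deqn{c_j(x) = \frac{(x-t_j)_+^3
#'   - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})}{(t_k-t_1)^2}.}
#' Any linear combination of the columns is linear beyond the boundary knots
#' with continuous value, first and second derivatives everywhere. The
#' division by `(t_k - t_1)^2` keeps the cubic columns on a scale comparable
#' to the linear column.
#'
#' @param x Numeric vector of ages.
#' @param spec An [rcs_spec()] object.
#' @return Numeric matrix with `length(x)` rows and `k` columns.
#' @export
rcs_design <- function(x, spec) {
  stopifnot(inherits(spec, "rcs_spec"))
  x <- as.numeric(x)
  t <- spec$knots
  k <- length(t)
  cube <- function(u) pmax(u, 0)^3
  scale2 <- (t[k] - t[1])^2
  denom <- t[k] - t[k - 1]
  X <- matrix(0, nrow = length(x), ncol = k)
  X[, 1] <- 1
  X[, 2] <- x
  for (j in seq_len(k - 2L)) {
    X[, j + 2L] <- (cube(x - t[j]) -
                      cube(x - t[k - 1]) * (t[k] - t[j]) / denom +
                      cube(x - t[k]) * (t[k - 1] - t[j]) / denom) / scale2
  }
  colnames(X) <- c("(Intercept)", "age", paste0("age.s", seq_len(k - 2L)))
  X
}

#' @export
print.rcs_spec <- function(x, ...) {
  cat("Restricted cubic spline:", length(x$knots), "knots at",
      paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
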