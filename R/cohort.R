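# Cohort data model: schema validation, CSV IO, APOE allele-group
# classification, and genotype/demographic summary tables.

COHORT_COLUMNS <- c("id", "age", "sex", "education_years", "mmse",
                    "psen1_carrier", "apoe_allele_1", "apoe_allele_2")

APOE_ALLELES <- c("e2", "e3", "e4")

#' Six unordered APOE genotypes
#'
#' Genotypes are keyed on the sorted allele pair, so e2/e4 and e4/e2 are the
#' same genotype.
#'
#' @return Character vector of the six unordered genotype labels.
#' @export
apoe_genotypes <- function() {
  c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")
}

#' Validate a cohort data frame
#'
#' Checks the participant-level schema: one row per participant with columns
#' `id, age, sex, education_years, mmse, psen1_carrier, apoe_allele_1,
#' apoe_allele_2`. MMSE must be an integer in 0--30, age at least 18,
#' education non-negative, alleles in {e2, e3, e4}, sex in {M, F}, carrier
#' flag 0/1 (or logical), ids unique. Missing values are rejected: the v1
#' schema has no missingness convention.
#'
#' @param cohort A data frame.
#' @return The validated cohort, invisibly, with `psen1_carrier` coerced to
#'   logical and `id` to character.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cohort$id <- as.character(cohort$id)
  if (anyNA(cohort[COHORT_COLUMNS])) {
    bad <- cohort$id[!stats::complete.cases(cohort[COHORT_COLUMNS])]
    stop("missing values are not permitted; offending row id(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) {
    stop("participant ids must be unique; duplicated: ",
         paste(unique(cohort$id[duplicated(cohort$id)])[1:1], collapse = ", "))
  }
  check_rows <- function(ok, what) {
    if (!all(ok)) {
      stop(what, "; offending row id(s): ",
           paste(utils::head(cohort$id[!ok], 5L), collapse = ", "))
    }
  }
  check_rows(is.numeric(cohort$age) & cohort$age >= 18,
             "age must be numeric and >= 18")
  check_rows(cohort$sex %in% c("M", "F"), "sex must be 'M' or 'F'")
  check_rows(is.numeric(cohort$education_years) & cohort$education_years >= 0,
             "education_years must be numeric and >= 0")
  mmse_ok <- is.numeric(cohort$mmse) & cohort$mmse >= 0 & cohort$mmse <= 30 &
    cohort$mmse == round(cohort$mmse)
  check_rows(mmse_ok, "mmse must be an integer in [0, 30]")
  if (is.logical(cohort$psen1_carrier)) {
    carrier <- cohort$psen1_carrier
  } else {
    check_rows(cohort$psen1_carrier %in% c(0, 1), "psen1_carrier must be 0 or 1")
    carrier <- cohort$psen1_carrier == 1
  }
  cohort$psen1_carrier <- carrier
  check_rows(cohort$apoe_allele_1 %in% APOE_ALLELES,
             "apoe_allele_1 must be one of e2, e3, e4")
  check_rows(cohort$apoe_allele_2 %in% APOE_ALLELES,
             "apoe_allele_2 must be one of e2, e3, e4")
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a participant-level cohort table. Expected header:
#' `id,age,sex,education_years,mmse,psen1_carrier,apoe_allele_1,apoe_allele_2`
#' (UTF-8, comma-separated, "." decimal; `sex` in M/F, `psen1_carrier` 0/1,
#' alleles in e2/e3/e4). Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  validate_cohort(raw)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` returns `x`
#' (with the carrier flag in canonical 0/1 form on disk).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort[COHORT_COLUMNS]
  out$psen1_carrier <- as.integer(out$psen1_carrier)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify APOE alleles into e4+/e2+ groups
#'
#' Participants are classified by the presence of at least one e4 allele
#' (e4+) and, separately, at least one e2 allele (e2+). An e2/e4 heterozygote
#' belongs to both groups. Classification is symmetric in allele order.
#'
#' @param allele_1,allele_2 Character vectors with values in e2/e3/e4
#'   (recycled to common length).
#' @return A data frame with logical columns `e4_positive` and `e2_positive`
#'   and character column `genotype` (unordered, e.g. "e2/e4").
#' @export
classify_apoe <- function(allele_1, allele_2) {
  n <- max(length(allele_1), length(allele_2))
  a1 <- rep_len(as.character(allele_1), n)
  a2 <- rep_len(as.character(allele_2), n)
  if (!all(a1 %in% APOE_ALLELES) || !all(a2 %in% APOE_ALLELES)) {
    bad <- unique(c(a1, a2)[!c(a1, a2) %in% APOE_ALLELES])
    stop("unknown APOE allele(s): ", paste(bad, collapse = ", "))
  }
  lo <- pmin(a1, a2)  # lexicographic order coincides with e2 < e3 < e4
  hi <- pmax(a1, a2)
  data.frame(
    e4_positive = a1 == "e4" | a2 == "e4",
    e2_positive = a1 == "e2" | a2 == "e2",
    genotype = paste(lo, hi, sep = "/"),
    stringsAsFactors = FALSE
  )
}

#' APOE group flags for a cohort
#'
#' @param cohort A cohort data frame.
#' @return The cohort with `e4_positive`, `e2_positive` and `genotype`
#'   columns appended.
#' @export
add_apoe_groups <- function(cohort) {
  cohort <- validate_cohort(cohort)
  cbind(cohort, classify_apoe(cohort$apoe_allele_1, cohort$apoe_allele_2))
}

#' Genotype distribution table
#'
#' Counts and percentages of the six unordered APOE genotypes, split by
#' PSEN1 carrier status. Percentages are count / stratum size * 100, rounded
#' half-to-even to 2 decimals for display; raw counts are exact.
#'
#' @param cohort A cohort data frame.
#' @return A data frame with one row per genotype and columns
#'   `carriers_n`, `carriers_pct`, `noncarriers_n`, `noncarriers_pct`.
#' @export
genotype_table <- function(cohort) {
  cohort <- add_apoe_groups(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty")
  geno <- factor(cohort$genotype, levels = apoe_genotypes())
  tab_c <- table(geno[cohort$psen1_carrier])
  tab_n <- table(geno[!cohort$psen1_carrier])
  pct <- function(tab) {
    tot <- sum(tab)
    if (tot == 0L) rep(NA_real_, length(tab)) else round(100 * as.numeric(tab) / tot, 2)
  }
  data.frame(
    genotype = apoe_genotypes(),
    carriers_n = as.integer(tab_c),
    carriers_pct = pct(tab_c),
    noncarriers_n = as.integer(tab_n),
    noncarriers_pct = pct(tab_n),
    stringsAsFactors = FALSE
  )
}

#' Published kindred APOE genotype counts
#'
#' The genotype distribution of the PSEN1 E280A kindred sample used as a
#' reference input throughout the package: 675 mutation carriers and 594
#' non-carriers across the six unordered APOE genotypes.
#'
#' @return A data frame with columns `genotype`, `carriers`, `noncarriers`.
#' @export
apoe_reference_counts <- function() {
  data.frame(
    genotype = apoe_genotypes(),
    carriers = c(4L, 85L, 13L, 445L, 117L, 11L),
    noncarriers = c(2L, 55L, 16L, 389L, 122L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Expand genotype counts into a minimal cohort
#'
#' Builds a schema-valid cohort with the requested number of participants
#' per genotype and carrier stratum. Demographics are placeholders (age 40,
#' 10 education years, MMSE 30, alternating sex): the result supports
#' genotype bookkeeping, not trajectory modelling.
#'
#' @param counts Data frame as returned by [apoe_reference_counts()]:
#'   columns `genotype`, `carriers`, `noncarriers`.
#' @return A cohort data frame with `sum(carriers) + sum(noncarriers)` rows.
#' @export
cohort_from_genotype_counts <- function(counts = apoe_reference_counts()) {
  stopifnot(all(c("genotype", "carriers", "noncarriers") %in% names(counts)))
  alleles <- strsplit(counts$genotype, "/", fixed = TRUE)
  one_stratum <- function(n_per_geno, carrier, prefix) {
    a1 <- rep(vapply(alleles, `[`, "", 1L), n_per_geno)
    a2 <- rep(vapply(alleles, `[`, "", 2L), n_per_geno)
    n <- length(a1)
    if (n == 0L) return(NULL)
    data.frame(
      id = paste0(prefix, seq_len(n)),
      age = 40, sex = rep_len(c("M", "F"), n), education_years = 10,
      mmse = 30L, psen1_carrier = carrier,
      apoe_allele_1 = a1, apoe_allele_2 = a2,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_stratum(counts$carriers, TRUE, "C"),
               one_stratum(counts$noncarriers, FALSE, "N"))
  validate_cohort(out)
}

#' Demographic comparison table
#'
#' Mean +/- SD (n-1 denominator) of age, education and MMSE, sex counts, and
#' two-sided p-values comparing two groups: Mann-Whitney U for the continuous
#' variables, Pearson chi-square (no continuity correction) for sex.
#' p-values are reported uncorrected.
#'
#' @param cohort A cohort data frame.
#' @param group `"e4"` or `"e2"` (APOE allele-group split) or `"psen1"`
#'   (carriers vs non-carriers; `stratum` is then ignored).
#' @param stratum For APOE splits, which PSEN1 stratum to compare within:
#'   `"carriers"` or `"noncarriers"`.
#' @return An object of class `demographics_table`: a data frame with one
#'   row per variable and columns for each group plus the p-value.
#' @export
demographics_table <- function(cohort,
                               group = c("e4", "e2", "psen1"),
                               stratum = c("carriers", "noncarriers")) {
  group <- match.arg(group)
  stratum <- match.arg(stratum)
  cohort <- add_apoe_groups(cohort)
  if (group == "psen1") {
    in_a <- cohort$psen1_carrier
    labels <- c("PSEN1 carriers", "PSEN1 non-carriers")
  } else {
    keep <- if (stratum == "carriers") cohort$psen1_carrier else !cohort$psen1_carrier
    cohort <- cohort[keep, , drop = FALSE]
    flag <- if (group == "e4") cohort$e4_positive else cohort$e2_positive
    in_a <- flag
    labels <- paste0("APOE ", group, c("+", "-"))
  }
  a <- cohort[in_a, , drop = FALSE]
  b <- cohort[!in_a, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("both comparison groups must be non-empty (", labels[1], ": ",
         nrow(a), ", ", labels[2], ": ", nrow(b), ")")
  }
  mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  cont_row <- function(var) {
    tst <- mann_whitney_u(a[[var]], b[[var]])
    c(mean_sd(a[[var]]), mean_sd(b[[var]]), format_p(tst$p.value))
  }
  sex_tab <- rbind(table(factor(a$sex, c("M", "F"))),
                   table(factor(b$sex, c("M", "F"))))
  sex_p <- chi_square(sex_tab)$p.value
  rows <- rbind(
    N = c(nrow(a), nrow(b), ""),
    Age = cont_row("age"),
    `Sex (M/F)` = c(paste0(sex_tab[1, 1], "/", sex_tab[1, 2]),
                    paste0(sex_tab[2, 1], "/", sex_tab[2, 2]),
                    format_p(sex_p)),
    `Educational attainment (years)` = cont_row("education_years"),
    `MMSE` = cont_row("mmse")
  )
  out <- data.frame(variable = rownames(rows), rows, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out) <- c("variable", labels, "p")
  class(out) <- c("demographics_table", "data.frame")
  out
}

format_p <- function(p) {
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

#' @export
print.demographics_table <- function(x, ...) {
  print.data.frame(x, right = FALSE, row.names = FALSE)
  invisible(x)
}
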