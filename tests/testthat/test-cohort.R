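test_that("cohort CSV round-trips through write/read unchanged", {
  co <- tiny_cohort(3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$id, co$id)
  expect_equal(back$age, co$age)
  expect_equal(back$mmse, co$mmse)
  expect_equal(back$psen1_carrier, co$psen1_carrier)
  expect_equal(back$apoe_allele_1, co$apoe_allele_1)
})

test_that("schema violations are rejected with informative errors", {
  co <- tiny_cohort()
  bad <- co; bad$mmse[2] <- 31L
  expect_error(validate_cohort(bad), "mmse.*P2")
  bad <- co; bad$apoe_allele_1[3] <- "e5"
  expect_error(validate_cohort(bad), "apoe_allele_1.*P3")
  bad <- co; bad$age[1] <- 12
  expect_error(validate_cohort(bad), "age")
  bad <- co; bad$education_years[4] <- NA
  expect_error(validate_cohort(bad), "missing values")
  bad <- co; bad$id[2] <- bad$id[1]
  expect_error(validate_cohort(bad), "unique")
  bad <- co[, setdiff(names(co), "sex")]
  expect_error(validate_cohort(bad), "missing required column.*sex")
})

test_that("classify_apoe implements at-least-one-allele groups, symmetrically", {
  expect_equal(classify_apoe("e3", "e4")[, c("e4_positive", "e2_positive")],
               data.frame(e4_positive = TRUE, e2_positive = FALSE))
  # e2/e4 heterozygotes belong to both groups
  both <- classify_apoe("e2", "e4")
  expect_true(both$e4_positive && both$e2_positive)
  neither <- classify_apoe("e3", "e3")
  expect_false(neither$e4_positive || neither$e2_positive)
  # order invariance and unordered genotype key, all 9 ordered pairs
  for (a in c("e2", "e3", "e4")) for (b in c("e2", "e3", "e4")) {
    ab <- classify_apoe(a, b); ba <- classify_apoe(b, a)
    expect_equal(ab$e4_positive, ba$e4_positive)
    expect_equal(ab$e2_positive, ba$e2_positive)
    expect_equal(ab$genotype, ba$genotype)
    expect_true(ab$genotype %in% apoe_genotypes())
  }
  expect_error(classify_apoe("e5", "e3"), "unknown APOE allele")
})

test_that("genotype_table reproduces the kindred bookkeeping and marginals", {
  co <- cohort_from_genotype_counts(apoe_reference_counts())
  tab <- genotype_table(co)
  expect_equal(sum(tab$carriers_n), 675L)
  expect_equal(sum(tab$noncarriers_n), 594L)
  flags <- add_apoe_groups(co)
  expect_equal(sum(flags$e4_positive & flags$psen1_carrier), 141L)
  expect_equal(sum(flags$e2_positive & flags$psen1_carrier), 102L)
  expect_equal(tab$carriers_pct[tab$genotype == "e3/e3"], 65.93)
})

test_that("genotype_table marginals partition by allele flags on random cohorts", {
  sim <- simulate_cohort(cohort_params(n_carriers = 120, n_noncarriers = 80),
                         seed = 7)
  tab <- genotype_table(sim$cohort)
  flags <- add_apoe_groups(sim$cohort)
  e4_genos <- c("e2/e4", "e3/e4", "e4/e4")
  e2_genos <- c("e2/e2", "e2/e3", "e2/e4")
  expect_equal(sum(tab$carriers_n[tab$genotype %in% e4_genos]),
               sum(flags$e4_positive & flags$psen1_carrier))
  expect_equal(sum(tab$noncarriers_n[tab$genotype %in% e2_genos]),
               sum(flags$e2_positive & !flags$psen1_carrier))
})

test_that("single-participant stratum gives count 1 at 100.00%", {
  co <- tiny_cohort(1)
  co$apoe_allele_1 <- "e3"; co$apoe_allele_2 <- "e3"
  co$psen1_carrier <- TRUE
  tab <- genotype_table(co)
  expect_equal(tab$carriers_n[tab$genotype == "e3/e3"], 1L)
  expect_equal(tab$carriers_pct[tab$genotype == "e3/e3"], 100)
})

test_that("demographics table uses n-1 SDs and symmetric tests", {
  # two identical groups: identical means, Mann-Whitney p = 1
  co <- rbind(tiny_cohort(6), within(tiny_cohort(6), id <- paste0(id, "b")))
  co$psen1_carrier <- TRUE
  co$apoe_allele_1 <- rep(c("e4", "e3"), each = 6)  # same demographics per group
  co$apoe_allele_2 <- "e3"
  tab <- demographics_table(co, group = "e4", stratum = "carriers")
  expect_equal(tab[tab$variable == "Age", 2], tab[tab$variable == "Age", 3])
  expect_equal(tab[tab$variable == "Age", "p"], "1.000")
  # sample SD convention: {10, 20, 30} -> mean 20, SD 10
  co2 <- tiny_cohort(6)
  co2$psen1_carrier <- TRUE
  co2$apoe_allele_1 <- rep(c("e4", "e3"), each = 3)
  co2$apoe_allele_2 <- "e3"
  co2$education_years <- c(10, 20, 30, 5, 5, 5)
  tab2 <- demographics_table(co2, group = "e4", stratum = "carriers")
  expect_equal(tab2[tab2$variable == "Educational attainment (years)", 2],
               "20.00 ± 10.00")
  # shifted education raises the group mean
  sim <- simulate_cohort(cohort_params(n_carriers = 400, n_noncarriers = 100),
                         seed = 11)
  co3 <- add_apoe_groups(sim$cohort)
  co3$education_years <- pmin(co3$education_years + co3$e4_positive * 1, 20)
  co3 <- co3[, names(sim$cohort)]
  tab3 <- demographics_table(co3, group = "e4", stratum = "carriers")
  edu <- tab3[tab3$variable == "Educational attainment (years)", 2:3]
  means <- as.numeric(sub(" .*", "", unlist(edu)))
  expect_gt(means[1], means[2])
  # empty group errors
  co4 <- tiny_cohort(4)
  co4$apoe_allele_1 <- "e3"; co4$apoe_allele_2 <- "e3"
  co4$psen1_carrier <- TRUE
  expect_error(demographics_table(co4, group = "e4", stratum = "carriers"),
               "non-empty")
})
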