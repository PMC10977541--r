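cohort <- reconstructed_cohort()

test_that("round-half-up matches clinical-report rounding", {
  expect_equal(round_half_up(0.125, 2), 0.13)   # base round() would give 0.12
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(47.877358 , 2), 47.88)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(31.6467, 2), 31.65)
})

test_that("detection rates carry explicit counts, denominators and percentages", {
  dr <- detection_rates(cohort)
  get <- function(g, col) dr[dr$group == g, col]
  expect_equal(get("any_chromosomal_abnormality", "count"), 330)
  expect_equal(get("common_autosomal_aneuploidy", "count"), 203)
  expect_equal(get("sex_chromosome_aneuploidy", "count"), 91)
  expect_equal(get("multiple_chromosome_abnormality", "count"), 33)
  expect_equal(get("rare_autosomal_aneuploidy", "count"), 3)
  expect_equal(get("cnv", "count"), 94)
  expect_equal(get("pathogenic_cnv", "count"), 63)
  expect_true(all(dr$denominator == 424))
  # percentages equal the round-half-up of 100*count/denominator exactly
  expect_equal(dr$pct, round_half_up(100 * dr$count / dr$denominator, 2))
  # zero-count group renders as 0.00
  expect_equal(get("normal", "pct"), 0)
  expect_error(detection_rates(cohort[0, ]), "empty")
})

test_that("packaged report tables conserve their published totals", {
  zt <- aneuploidy_zone_table(cohort)
  expect_equal(sum(zt$n), 297)
  expect_equal(zt$n[zt$zone == "dup(21)(q11.2q22.3)"], 147)
  expect_equal(zt$n[zt$zone == "dup(21)(q11.1q22.3)"], 16)
  expect_equal(zt$n[zt$zone == "dup(18)(p11.32q23)"], 24)
  kt <- karyotype_reference_tables()
  expect_equal(sum(kt$autosomal$n), 156)
  expect_equal(sum(kt$sex$n), 68)
})

test_that("karyotype concordance finds exactly one discordant fetus", {
  cc <- concordance(cohort)
  tab <- table(cc$status)
  expect_equal(unname(tab["discordant"]), 1)
  expect_equal(unname(tab["concordant"]), 243)
  expect_equal(sum(tab), 424)
  # the discordant case is a sub-5-Mb CNV a normal karyotype cannot see
  disc <- cohort[cc$status == "discordant", ]
  expect_equal(disc$category, "pathogenic_cnv")
  expect_lt(disc$cnv_size_mb, 5)
  expect_equal(cc$subtype[cc$status == "discordant"], "expected")
  # tetraploidy is invisible to depth ratios: compared but not comparable
  expect_equal(sum(cc$subtype == "ploidy_invisible", na.rm = TRUE), 1)
  # trisomy 21 calls agree with their +21 karyotypes, rob carriers included
  t21 <- cohort$label == "trisomy 21" & !is.na(cohort$karyotype)
  expect_true(all(cc$status[t21] == "concordant"))
})

test_that("demographic strata reproduce the published cohort description", {
  d <- stratify_demographics(cohort)
  expect_equal(d$age$mean[d$age$stratum == "overall"], 31.65)
  # independent oracle: case-weighted mean of the published stratum means
  w <- c(63, 102, 108, 97, 49, 5)
  m <- c(21.81, 27.08, 31.85, 36.96, 41.39, 45.8)
  expect_equal(round_half_up(sum(w * m) / sum(w), 2), 31.65)
  expect_equal(d$age$n[-1], w)
  expect_equal(d$age$mean[-1], m)
  expect_equal(d$ga$n[-1], c(415, 9))
  expect_equal(d$ga$mean[-1], c(19.95, 30.44))
  # single-case cohort: mean = median, sd 0 by convention
  one <- cohort[5, ]
  d1 <- stratify_demographics(one)
  expect_equal(d1$age$mean[1], d1$age$median[1])
  expect_equal(d1$age$sd[1], 0)
  # empty strata report n = 0 without failing
  expect_true(any(stratify_demographics(cohort[1:63, ])$age$n == 0))
  young <- cohort[1:2, ]; young$age <- c(14, 30)
  expect_warning(stratify_demographics(young), "16-60")
})

test_that("outcome tabulation conserves the cohort and rejects unknown outcomes", {
  tab <- outcome_table(cohort)
  expect_equal(sum(tab), 424)
  # trisomy 18 narrative: 23 terminations, 1 lost to follow-up of 24
  t18 <- outcome_table(cohort[cohort$label == "trisomy 18", ])
  expect_equal(sum(t18), 24)
  expect_equal(unname(t18[1, "termination of pregnancy"]), 23)
  expect_equal(unname(t18[1, "failure to follow-up"]), 1)
  # three cases, three distinct outcomes -> three cells of one
  three <- cohort[c(1, 126, 127), ]
  cells <- as.vector(outcome_table(three))
  expect_equal(sort(cells), c(0, 0, 1, 1, 1))
  expect_equal(sum(cells), 3)
  bad <- cohort[1:2, ]; bad$outcome[1] <- "emigrated"
  expect_error(outcome_table(bad), "emigrated")
})

test_that("karyotype subgroup summary uses the stored report groups", {
  ks <- karyotype_summary(cohort)
  expect_equal(ks$count[ks$group == "autosomal"], 156)
  expect_equal(ks$count[ks$group == "sex"], 68)
  expect_equal(ks$count[ks$group == "tetraploid"], 1)
  expect_true(all(ks$denominator == 245))
  expect_equal(sum(ks$count), 245)
})

test_that("cohort tables round-trip through TSV", {
  path <- tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  c2 <- read_cohort(path)
  expect_equal(nrow(c2), 424)
  expect_equal(c2$category, cohort$category)
  expect_equal(c2$karyotype, cohort$karyotype)
  expect_equal(sum(!is.na(c2$karyotype)), 245)
})
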