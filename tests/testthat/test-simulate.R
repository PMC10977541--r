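test_that("identical seed and config give identical counts", {
  for (noise in c("poisson", "multinomial", "nb")) {
    a <- simulate_case(toy, toy_grid, NULL,
                       seq_config(n_mapped = 1e5, noise = noise), seed = 3)
    b <- simulate_case(toy, toy_grid, NULL,
                       seq_config(n_mapped = 1e5, noise = noise), seed = 3)
    expect_identical(a$counts, b$counts)
  }
})

test_that("multinomial allocation conserves the mapped-read total exactly", {
  bc <- simulate_case(toy, toy_grid, NULL,
                      seq_config(n_mapped = 123457, noise = "multinomial"),
                      seed = 5)
  expect_identical(sum(bc$counts), 123457L)
  expect_identical(bc$total, sum(bc$counts))
})

test_that("noise-free expectations match the analytic count model", {
  bc <- toy_flat(n_mapped = 2e5)
  rate <- bc$counts / toy_grid$width_share
  auto <- is_autosome(toy_grid$chrom)
  # all autosomal bins share one rate; chrY carries none in an XX sample
  expect_equal(stats::var(rate[auto]), 0, tolerance = 1e-18)
  expect_equal(sum(bc$counts), 2e5)
  expect_equal(sum(bc$counts[chrom_label(toy_grid$chrom) == "Y"]), 0)
})

test_that("simulated dosage follows the mixture relation 2 + f*(cn-2)", {
  base <- toy_flat()
  base_rate <- base$counts[1] / toy_grid$width_share[1]
  for (f in seq(0.1, 1, by = 0.1)) {
    bc <- simulate_case(toy, toy_grid, truth_event("chr21", cn = 3, f = f),
                        seq_config(n_mapped = 2e5, noise = "none"),
                        sex = "XX")
    i <- which(toy_grid$chrom == "chr21")
    rate <- bc$counts[i] / toy_grid$width_share[i]
    j <- which(!toy_grid$chrom %in% c("chr21", "chrY"))[1]
    ref <- bc$counts[j] / toy_grid$width_share[j]
    expect_equal(unique(round(rate / ref, 10)), (2 + f * (3 - 2)) / 2)
  }
  # whole-chromosome trisomy at f = 1 scales chr21 relative depth by 1.5
  tri <- simulate_case(toy, toy_grid, truth_event("chr21", cn = 3, f = 1),
                       seq_config(n_mapped = 2e5, noise = "none"))
  i <- toy_grid$chrom == "chr21"; j <- toy_grid$chrom == "chr1"
  expect_equal((sum(tri$counts[i]) / sum(tri$counts[j])) /
                 (sum(base$counts[i]) / sum(base$counts[j])),
               1.5, tolerance = 1e-9)
  # chrX monosomy at f = 0.5 in an XX baseline sits at dosage 1.5
  xm <- simulate_case(toy, toy_grid, truth_event("chrX", cn = 1, f = 0.5),
                      seq_config(n_mapped = 2e5, noise = "none"), sex = "XX")
  i <- which(toy_grid$chrom == "chrX")
  j <- which(toy_grid$chrom == "chr1")[1]
  expect_equal(unique(round((xm$counts[i] / toy_grid$width_share[i]) /
                              (xm$counts[j] / toy_grid$width_share[j]), 10)),
               1.5 / 2)
})

test_that("invalid truth events are rejected", {
  expect_error(truth_event("chr21", cn = 3, f = 0), "\\(0, 1\\]")
  expect_error(truth_event("chr21", cn = 3, f = 1.2), "\\(0, 1\\]")
  expect_error(truth_event("chr21", cn = 2.5, f = 1), "integer")
  two <- rbind(truth_event("chr1", 1, 50000, cn = 3),
               truth_event("chr1", 30000, 90000, cn = 1))
  expect_error(simulate_case(toy, toy_grid, two,
                             seq_config(n_mapped = 1e4)), "overlapping")
  expect_error(simulate_case(toy, toy_grid,
                             truth_event("chrQ", cn = 3),
                             seq_config(n_mapped = 1e4)), "unknown")
  expect_error(seq_config(n_mapped = 6e6), "exceed")
  expect_error(seq_config(trim_len = 50, read_len = 45), "exceed")
})

test_that("cohort simulation is reproducible and honours the category mix", {
  co <- simulate_cohort(20, mix = c(t21 = 1), seed = 9)
  expect_equal(nrow(co$records), 20)
  expect_true(all(grepl("chr21", co$records$truth)))
  co2 <- simulate_cohort(20, mix = c(t21 = 1), seed = 9)
  expect_identical(co$records, co2$records)
  expect_identical(co$cases[[5]]$counts, co2$cases[[5]]$counts)

  mixed <- simulate_cohort(100, mix = c(t21 = 0.4, normal = 0.6), seed = 2)
  expect_equal(nrow(mixed$records), 100)
  expect_equal(sum(table(mixed$records$category)), 100)

  expect_error(simulate_cohort(0), "positive")
  expect_error(simulate_cohort(5, mix = c(t21 = 0.5, normal = 0.2)),
               "sum to 1")
})

test_that("bin-count tables round-trip through TSV", {
  bc <- simulate_case(toy, toy_grid, NULL, seq_config(n_mapped = 5e4),
                      seed = 12, sample_id = "rt")
  path <- tempfile(fileext = ".tsv")
  write_bin_counts(bc, path)
  bc2 <- read_bin_counts(path)
  expect_equal(bc2$sample_id, "rt")
  expect_equal(bc2$counts, bc$counts)
  expect_equal(bc2$grid$start, bc$grid$start)
  expect_equal(attr(bc2$grid, "bin_width"), 20000)
})
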