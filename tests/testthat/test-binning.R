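test_that("read trimming returns the 36-bp genomic portion", {
  expect_equal(trim_read_length(45), 36)
  expect_equal(trim_read_length(36), 36)
  expect_equal(trim_read_length(100), 36)
  expect_warning(out <- trim_read_length(30), "shorter")
  expect_equal(out, 30)
  expect_equal(trim_read_length(c(45, 36, 80)), c(36, 36, 36))
})

test_that("uniqueness filtering keeps flagged reads in order", {
  reads <- data.frame(chrom = "chr1", pos = 1:10,
                      unique = rep(c(TRUE, TRUE, FALSE), length.out = 10))
  out <- filter_unique(reads)
  expect_equal(nrow(out), 7)
  expect_equal(out$pos, which(reads$unique))
  expect_equal(nrow(filter_unique(reads[0, ])), 0)
  none <- data.frame(chrom = "chr1", pos = 1:3, unique = FALSE)
  expect_warning(out0 <- filter_unique(none), "no uniquely")
  expect_equal(nrow(out0), 0)
})

test_that("reads land in the bin containing their leftmost position", {
  g <- genome_model(c(chr1 = 100000))
  grid <- build_bin_grid(g, 20000)
  reads <- data.frame(chrom = "chr1", pos = c(25000, 20000, 20001, 1))
  bc <- assign_reads_to_bins(reads, grid)
  # 25,000 -> bin 2; boundary 20,000 -> lower bin 1; 20,001 -> bin 2; 1 -> bin 1
  expect_equal(bc$counts, c(2, 2, 0, 0, 0))
  expect_equal(bc$total, 4)
})

test_that("bin counting agrees with a brute-force per-read tally", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 500
    reads <- data.frame(
      chrom = sample(toy$chrom, n, replace = TRUE),
      pos = sample.int(2e6, n, replace = TRUE))
    bc <- assign_reads_to_bins(reads, toy_grid)
    # independent oracle: loop every read, find its bin by interval scan
    oracle <- integer(nrow(toy_grid))
    for (k in seq_len(n)) {
      i <- which(toy_grid$chrom == reads$chrom[k] &
                   toy_grid$start <= reads$pos[k] &
                   toy_grid$end >= reads$pos[k])
      oracle[i] <- oracle[i] + 1L
    }
    expect_identical(bc$counts, oracle)
    expect_identical(bc$total, sum(oracle))
    # permutation invariance
    perm <- reads[sample.int(n), ]
    expect_identical(assign_reads_to_bins(perm, toy_grid)$counts, bc$counts)
  }
})

test_that("unknown chromosomes and out-of-bounds positions are rejected", {
  g <- genome_model(c(chr1 = 100000))
  grid <- build_bin_grid(g, 20000)
  reads <- data.frame(chrom = c("chr1", "chrNope", "chr1"),
                      pos = c(50, 10, 200000))
  expect_message(expect_message(bc <- assign_reads_to_bins(reads, grid),
                                "unknown"), "outside")
  expect_equal(bc$total, 1)
  expect_equal(bc$meta$n_rejected, 2)
})

test_that("the SAM reader extracts mapped positions and MAPQ uniqueness", {
  sam <- write_test_sam(tempfile(fileext = ".sam"))
  reads <- read_sam(sam, mapq_min = 30)
  expect_equal(nrow(reads), 4)          # unmapped r4 dropped
  expect_equal(reads$pos, c(25000, 20000, 100, 40001))
  expect_equal(reads$unique, c(TRUE, TRUE, FALSE, TRUE))
  uniq <- filter_unique(reads)
  expect_equal(uniq$pos, c(25000, 20000, 40001))
  g <- genome_model(c(chr1 = 249250621, chr2 = 243199373))
  bc <- assign_reads_to_bins(uniq, build_bin_grid(g, 20000))
  expect_equal(bc$total, 3)
})

test_that("BED dialects differ by exactly the 0/1-based start convention", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t24999\t25035", "chr1\t0\t36"), path)
  b0 <- read_bed_reads(path, "bed0")
  expect_equal(b0$pos, c(25000, 1))
  b1 <- read_bed_reads(path, "bed1")
  expect_equal(b1$pos, c(24999, 0))
  expect_true(all(b0$unique))
})
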