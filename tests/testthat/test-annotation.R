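bands <- read_cytoband()

test_that("band lookup reproduces the reporting coordinates of the screen", {
  expect_equal(band_lookup("chr21", 14300000, 48129895, bands), "q11.2q22.3")
  expect_equal(band_lookup("chr18", 1, 78077248, bands), "p11.32q23")
  expect_equal(band_lookup("chr13", 19500000, 115169878, bands), "q12.11q34")
  expect_equal(band_lookup("chr15", 20700000, 102531392, bands), "q11.1q26.3")
  expect_equal(band_lookup("chrX", 1, 155270560, bands), "p22.33q28")
  expect_equal(band_lookup("chrY", 1, 59373566, bands), "p11.32q12")
  expect_equal(band_lookup("chr7", 1, 159138663, bands), "p22.3q36.3")
  # interval inside a single band collapses to that band's name
  expect_equal(band_lookup("chrX", 6500000, 7000000, bands), "p22.31")
  expect_error(band_lookup("chr21", 1, 9e7, bands), "outside")
})

test_that("call strings format and parse as exact inverses", {
  fc <- format_call("chr13", 19500000, 115169878, "dup", FALSE, bands)
  expect_equal(fc$iscn, "dup(13)(q12.11q34)")
  expect_equal(fc$g, "chr13:g.19500000_115169878dup")
  fm <- format_call("chrX", 1, 155270560, "del", TRUE, bands)
  expect_equal(fm$iscn, "del(X)(p22.33q28)(mos)")
  expect_equal(fm$g, "chrX:g.1_155270560del")
  p <- parse_call(fm$iscn)
  expect_equal(p$type, "del"); expect_equal(p$chrom, "X")
  expect_true(p$mosaic); expect_equal(p$zone, "p22.33q28")
  p2 <- parse_call(fm$g)
  expect_equal(c(p2$start, p2$end), c(1, 155270560))
  # round-trip across every distinct zone string of the packaged report
  zt <- aneuploidy_zone_table(reconstructed_cohort())
  for (k in seq_len(nrow(zt))) {
    pz <- parse_call(zt$zone[k]); pg <- parse_call(zt$location[k])
    expect_equal(pz$type, pg$type)
    expect_equal(pz$chrom, pg$chrom)
    refc <- format_call(paste0("chr", pg$chrom), pg$start, pg$end,
                        pg$type, pz$mosaic, bands)
    expect_equal(refc$g, zt$location[k])
  }
})

test_that("fragment sizes follow the 1-based inclusive convention", {
  expect_equal(fragment_size(1, 78077248), 78077248)
  expect_equal(format_mb(fragment_size(1, 78077248)), 78.08)
  expect_equal(fragment_size(14300000, 48129895), 33829896)
  expect_equal(fragment_size(5, 5), 1)
  expect_error(fragment_size(10, 5), ">=")
})

test_that("UCSC zero-based band files are converted on load", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("chr1\t0\t1000\tp36.33\tgneg",
               "chr1\t1000\t2000\tp36.32\tgneg"), path)
  b <- read_cytoband(path, zero_based = TRUE)
  expect_equal(b$start, c(1, 1001))
  expect_equal(band_lookup("chr1", 1000, 1000, b), "p36.33")
  # a gapped table is rejected
  bad <- tempfile(fileext = ".txt")
  writeLines(c("chr1\t1\t1000\tp1\tgneg", "chr1\t1500\t2000\tp2\tgneg"), bad)
  expect_error(read_cytoband(bad), "tile")
})

test_that("triage applies the documented category precedence", {
  rules <- triage_rules()
  # whole-chromosome trisomy 21 -> common aneuploidy
  t21 <- mk_call("chr21", 1, 48129895, "duplication", 3, frac_chrom = 1)
  tr <- triage_case(t21, sex = "XX", rules = rules)
  expect_equal(tr$category, "common_autosomal_aneuploidy")
  expect_equal(tr$label, "trisomy 21")
  # extra X in a male background -> Klinefelter
  xxy <- mk_call("chrX", 1, 155270560, "duplication", 4, frac_chrom = 1)
  tr <- triage_case(xxy, sex = "XY", rules = rules,
                    sex_dosage = c(X = 2, Y = 1))
  expect_equal(tr$category, "sex_chromosome_aneuploidy")
  expect_equal(tr$label, "47,XXY")
  # monosomy X in a female background -> Turner
  tr <- triage_case(mk_call("chrX", 1, 155270560, "deletion", 1,
                            frac_chrom = 1),
                    sex = "XX", rules = rules, sex_dosage = c(X = 1, Y = 0))
  expect_equal(tr$label, "45,X")
  # recurrent-region deletion -> pathogenic CNV
  sts <- mk_call("chrX", 6600001, 7800000, "deletion", 1, frac_chrom = 0.008)
  tr <- triage_case(sts, sex = "XY", rules = rules)
  expect_equal(tr$category, "pathogenic_cnv")
  expect_match(tr$label, "STS")
  # whole-chromosome mosaic trisomy 7 -> rare autosomal aneuploidy
  r7 <- mk_call("chr7", 1, 159138663, "mosaic_trisomy", 2.5,
                frac_chrom = 1, mosaic = TRUE)
  expect_equal(triage_case(r7, "XX", rules)$category,
               "rare_autosomal_aneuploidy")
  # two whole chromosomes outrank everything
  multi <- rbind(t21, mk_call("chr18", 1, 78077248, "duplication", 3,
                              frac_chrom = 1))
  expect_equal(triage_case(multi, "XX", rules)$category,
               "multiple_chromosome_abnormality")
  # small unremarkable CNV -> uncertain significance; none -> normal
  vus <- mk_call("chr5", 1e6 + 1, 1.4e6, "duplication", 3, frac_chrom = 0.01)
  expect_equal(triage_case(vus, "XX", rules)$category, "vus_cnv")
  expect_equal(triage_case(vus[0, ], "XX", rules)$category, "normal")
  # >= 1 Mb clears the pathogenic size floor even off the region list
  big <- mk_call("chr5", 1e6 + 1, 2.2e6, "duplication", 3, frac_chrom = 0.02)
  expect_equal(triage_case(big, "XX", rules)$category, "pathogenic_cnv")
  # precedence: an aneuploidy beats a coexisting small CNV
  both <- rbind(t21, vus)
  expect_equal(triage_case(both, "XX", rules)$category,
               "common_autosomal_aneuploidy")
})

test_that("annotate_calls decorates a fit with nomenclature and triage", {
  gh <- genome_model(hg19_chrom_lengths())
  gridh <- build_bin_grid(gh)
  bc <- simulate_case(gh, gridh, truth_event("chr21", cn = 3, f = 1),
                      seq_config(n_mapped = 3e6), sex = "XX", seed = 51)
  fit <- suppressMessages(rcnv(bc))
  ann <- annotate_calls(fit, bands)
  expect_equal(ann$triage$category, "common_autosomal_aneuploidy")
  c21 <- ann$calls[ann$calls$chrom == "chr21" & ann$calls$frac_chrom >= 0.9, ]
  expect_match(c21$iscn, "^dup\\(21\\)\\(")
  expect_match(c21$g, "^chr21:g\\.")
  expect_equal(c21$size_mb, 48.13)
})
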