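# Shared fixtures: built once per test run, all deterministic.

toy <- toy_genome()
toy_grid <- build_bin_grid(toy)

# a noise-free disomic sample: counts equal their expectations exactly
toy_flat <- function(sex = "XX", n_mapped = 2e5) {
  simulate_case(toy, toy_grid, NULL, seq_config(n_mapped = n_mapped,
                                                noise = "none"), sex = sex)
}

# hand-build a bin_counts object from explicit counts (constant GC so the
# GC stage is an exact identity)
manual_counts <- function(counts, bin_width = 20000, gc = 0.5) {
  n <- length(counts)
  grid <- data.frame(chrom = "chr1",
                     start = bin_width * (seq_len(n) - 1) + 1,
                     end = bin_width * seq_len(n), gc = gc,
                     width_share = 1, stringsAsFactors = FALSE)
  attr(grid, "bin_width") <- bin_width
  class(grid) <- c("bin_grid", "data.frame")
  structure(list(sample_id = "manual", grid = grid, counts = counts,
                 total = sum(counts), truth = data.frame(), meta = list()),
            class = "bin_counts")
}

# minimal single-end SAM text for the reader tests
write_test_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:249250621",
    "@SQ\tSN:chr2\tLN:243199373",
    # qname flag rname pos mapq cigar rnext pnext tlen seq qual
    "r1\t0\tchr1\t25000\t60\t36M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t20000\t60\t36M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t100\t10\t36M\t*\t0\t0\t*\t*",   # low MAPQ: not unique
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",           # unmapped
    "r5\t0\tchr2\t40001\t37\t36M\t*\t0\t0\t*\t*")
  writeLines(lines, path)
  path
}

# minimal calls table for triage tests (what an rcnv fit's $calls carries)
mk_call <- function(chrom, start, end, state, rel_cn, frac_chrom = NA,
                    mosaic = FALSE) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             rel_cn = rel_cn, mosaic = mosaic, frac_chrom = frac_chrom,
             stringsAsFactors = FALSE)
}
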