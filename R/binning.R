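#' Read-trimming policy
#'
#' Returns the usable genomic read length after removing the artificial
#' adapter portion: `min(raw_len, 36)` bp, so 45-bp raw reads yield the
#' 36-bp genomic sequence. Raw reads already at or below the cap pass
#' through (with a warning below 36 bp, a degenerate input).
#'
#' @param raw_len Raw read length(s) in bp.
#' @param trim_len Genomic length cap, default 36.
#' @return Trimmed length(s) in bp.
#' @examples
#' trim_read_length(45)  # 36
#' @export
trim_read_length <- function(raw_len, trim_len = 36) {
  if (any(raw_len < trim_len))
    warning("read(s) shorter than the ", trim_len,
            " bp cap passed through untrimmed")
  pmin(raw_len, trim_len)
}

#' Keep uniquely mapped reads
#'
#' Filters a read table to records whose uniqueness flag is set, preserving
#' input order. A warning is emitted when nothing survives.
#'
#' @param reads data.frame with at least a logical `unique` column (as
#'   produced by [read_sam()] / [read_bed_reads()]).
#' @return The filtered data.frame.
#' @export
filter_unique <- function(reads) {
  stopifnot(is.data.frame(reads), "unique" %in% names(reads))
  out <- reads[reads$unique, , drop = FALSE]
  if (nrow(reads) > 0 && nrow(out) == 0)
    warning("no uniquely mapped reads after filtering")
  rownames(out) <- NULL
  out
}

#' Count reads in genomic bins
#'
#' Assigns each read to the bin containing its leftmost mapped position
#' (1-based inclusive; a position exactly on a bin boundary belongs to the
#' lower bin, e.g. chr1:20,000 with 20-kb bins falls in bin 1-20,000).
#' Reads on unknown chromosomes or outside chromosome bounds are rejected
#' and reported via `message()`.
#'
#' @param reads data.frame with columns `chrom` and `pos` (leftmost mapped
#'   position, 1-based); pass the output of [filter_unique()].
#' @param grid A [build_bin_grid()] grid.
#' @param sample_id Sample label.
#' @return A `bin_counts` object; its `total` equals the number of
#'   accepted reads and always equals `sum(counts)`.
#' @export
assign_reads_to_bins <- function(reads, grid, sample_id = "sample") {
  stopifnot(is.data.frame(reads), all(c("chrom", "pos") %in% names(reads)),
            inherits(grid, "bin_grid"))
  bw <- attr(grid, "bin_width")
  chroms <- unique(grid$chrom)
  # per-chromosome bin offsets into the grid and chromosome ends
  offset <- c(0, cumsum(tabulate(match(grid$chrom, chroms),
                                 nbins = length(chroms))))[seq_along(chroms)]
  names(offset) <- chroms
  chrom_end <- tapply(grid$end, factor(grid$chrom, levels = chroms), max)

  ci <- match(reads$chrom, chroms)
  unknown <- is.na(ci)
  oob <- !unknown & (reads$pos < 1 | reads$pos > chrom_end[ci])
  keep <- !unknown & !oob
  if (any(unknown))
    message(sum(unknown), " read(s) on unknown chromosomes rejected")
  if (any(oob))
    message(sum(oob), " read(s) outside chromosome bounds rejected")

  bin_idx <- offset[ci[keep]] + (reads$pos[keep] - 1) %/% bw + 1
  counts <- tabulate(bin_idx, nbins = nrow(grid))
  structure(list(sample_id = sample_id, grid = grid, counts = counts,
                 total = sum(counts), truth = data.frame(),
                 meta = list(n_input = nrow(reads),
                             n_rejected = sum(!keep))),
            class = "bin_counts")
}

#' Read aligned read positions from a SAM file
#'
#' Parses the text SAM columns needed for bin counting: reference name,
#' leftmost 1-based position, FLAG (to drop unmapped records) and MAPQ.
#' A read is marked `unique` when its MAPQ is at least `mapq_min`
#' (default 30), the configurable stand-in for a mapper-specific
#' uniqueness flag.
#'
#' @param path SAM file path.
#' @param mapq_min Minimum mapping quality for uniqueness, default 30.
#' @return data.frame with columns `chrom`, `pos`, `mapq`, `unique`.
#' @export
read_sam <- function(path, mapq_min = 30) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(),
                      mapq = integer(), unique = logical()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  chrom <- vapply(fields, `[`, character(1), 3)
  pos <- vapply(fields, function(f) as.integer(f[4]), integer(1))
  mapq <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L & chrom != "*"
  out <- data.frame(chrom = chrom, pos = pos, mapq = mapq,
                    unique = mapq >= mapq_min, stringsAsFactors = FALSE)
  out[mapped, , drop = FALSE]
}

#' Read read positions from a BED-like table
#'
#' Three-column `chrom, start, end` tables. `dialect = "bed0"` is standard
#' BED (0-based half-open starts, converted to 1-based on read);
#' `"bed1"` declares starts already 1-based inclusive. All records are
#' marked `unique` (BED carries no mapping quality).
#'
#' @param path File path.
#' @param dialect `"bed0"` (default) or `"bed1"`.
#' @return data.frame with columns `chrom`, `pos`, `unique`.
#' @export
read_bed_reads <- function(path, dialect = c("bed0", "bed1")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  pos <- if (dialect == "bed0") tab[[2]] + 1L else tab[[2]]
  data.frame(chrom = tab[[1]], pos = pos, unique = TRUE,
             stringsAsFactors = FALSE)
}
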