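#' hg19 chromosome lengths
#'
#' Lengths in base pairs of the 24 human chromosomes (1-22, X, Y) on the
#' GRCh37/hg19 assembly. These provide the coordinate system for full-size
#' simulations and for interpreting g.-notation coordinates; no sequence is
#' required anywhere in the package.
#'
#' @return Named integer-valued numeric vector of length 24, names
#'   `"chr1"`..`"chr22"`, `"chrX"`, `"chrY"`.
#' @examples
#' hg19_chrom_lengths()[["chr21"]]
#' @export
hg19_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Build a genome model
#'
#' A genome model is the coordinate authority for everything downstream: a
#' set of uniquely named chromosomes with positive lengths, plus a
#' deterministic GC-content function used to attach a GC fraction to each
#' bin when a bin grid is built. The default GC function is a smooth
#' synthetic track (two superimposed long-wavelength oscillations around
#' 0.42); it emulates the broad isochore-like variation real genomes show
#' without requiring any sequence.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @param gc_fun Function `(chrom_index, mid_bp) -> gc fraction in [0,1]`
#'   evaluated at bin midpoints, or `NULL` for the default synthetic track.
#' @return Object of class `"genome_model"`.
#' @seealso [toy_genome()], [build_bin_grid()]
#' @examples
#' g <- genome_model(hg19_chrom_lengths())
#' g$chrom[1:3]
#' @export
genome_model <- function(lengths = hg19_chrom_lengths(), gc_fun = NULL) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome names must be present and unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(gc_fun)) gc_fun <- default_gc_track
  structure(list(chrom = names(lengths), length = unname(lengths),
                 gc_fun = gc_fun),
            class = "genome_model")
}

# Smooth deterministic synthetic GC track in roughly [0.30, 0.55].
default_gc_track <- function(chrom_index, mid_bp) {
  gc <- 0.42 + 0.05 * sin(mid_bp / 7e6 + chrom_index) +
    0.04 * sin(mid_bp / 1.3e6 + 2 * chrom_index)
  pmin(pmax(gc, 0), 1)
}

#' Scaled toy genome for fast tests
#'
#' Twenty-four chromosomes of 2-5 Mb with the same naming scheme as hg19.
#' Sized so a full simulate-fit cycle runs in well under a second while
#' preserving every structural property of the full-size grid (per-
#' chromosome tiling, truncated last bins, X/Y dosage handling).
#'
#' @param seed Integer controlling the (deterministic) length draw.
#' @return Object of class `"genome_model"`.
#' @export
toy_genome <- function(seed = 101) {
  nm <- names(hg19_chrom_lengths())
  # deterministic lengths spread over 2-5 Mb, largest first like a real genome
  base <- seq(5e6, 2e6, length.out = 24)
  jitter <- ((seed + seq_len(24) * 7919) %% 11) * 2e4
  lengths <- round(base + jitter)
  names(lengths) <- nm
  genome_model(lengths)
}

#' Partition a genome into fixed-width bins
#'
#' Tiles every chromosome with 1-based inclusive bins
#' `[w(k-1)+1, wk]` of width `w` (default 20 kb); the last bin of each
#' chromosome is truncated at the chromosome end. Bins carry the genome
#' model's GC fraction evaluated at their midpoint and a `width_share`
#' column (bin width / nominal width) used as an exposure weight so that
#' truncated terminal bins are not misread as deletions.
#'
#' @param genome A [genome_model()].
#' @param bin_width Bin width in bp, default `20000`.
#' @return A `data.frame` of class `"bin_grid"` with columns `chrom`,
#'   `start`, `end`, `gc`, `width_share`; attribute `bin_width`.
#' @examples
#' g <- genome_model(c(chrA = 50000))
#' build_bin_grid(g)  # 3 bins, last truncated at 50 kb
#' @export
build_bin_grid <- function(genome, bin_width = 20000) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    stop("bin_width must be a single positive number")
  pieces <- lapply(seq_along(genome$chrom), function(i) {
    len <- genome$length[i]
    n <- ceiling(len / bin_width)
    start <- bin_width * (seq_len(n) - 1) + 1
    end <- pmin(bin_width * seq_len(n), len)
    mid <- (start + end) / 2
    data.frame(chrom = genome$chrom[i], start = start, end = end,
               gc = genome$gc_fun(i, mid),
               width_share = (end - start + 1) / bin_width,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "bin_width") <- bin_width
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin grid: %d bins of %g bp over %d chromosomes\n",
              nrow(x), attr(x, "bin_width"), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Autosome indicator for chromosome names
#' @param chrom Character vector of chromosome names (with or without a
#'   `"chr"` prefix).
#' @return Logical vector, `TRUE` for chromosomes 1-22.
#' @export
is_autosome <- function(chrom) {
  grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", chrom)
}

# strip an optional "chr" prefix ("chr21" -> "21")
chrom_label <- function(chrom) sub("^chr", "", chrom)

#' Write / read a chromosome-lengths table
#'
#' Two-column tab-separated format (`chrom`, `length`).
#' @param genome A [genome_model()].
#' @param path File path.
#' @return `write_chrom_lengths` returns `path` invisibly;
#'   `read_chrom_lengths` returns a [genome_model()].
#' @export
write_chrom_lengths <- function(genome, path) {
  utils::write.table(data.frame(chrom = genome$chrom, length = genome$length),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_lengths
#' @export
read_chrom_lengths <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lengths <- tab$length
  names(lengths) <- tab$chrom
  genome_model(lengths)
}
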