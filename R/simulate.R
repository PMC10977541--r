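#' Sequencing design configuration for the simulator
#'
#' Captures the shallow single-end sequencing design the simulator
#' emulates: about 5 million 45-bp raw reads per sample, trimmed to the
#' 36-bp genomic portion, of which 2.8-3.2 million map uniquely. Counts per
#' bin are drawn from a configurable noise model.
#'
#' @param n_raw Raw read count (default 5e6). Bookkeeping only; bin counts
#'   are driven by `n_mapped`.
#' @param read_len Raw read length in bp (default 45).
#' @param trim_len Genomic read length after adapter removal (default 36).
#' @param n_mapped Uniquely mapped read count. `NULL` draws uniformly from
#'   `mapped_range` when the case is simulated.
#' @param mapped_range Range the mapped count is drawn from when
#'   `n_mapped` is `NULL` (default `c(2.8e6, 3.2e6)`).
#' @param noise One of `"poisson"` (independent shot noise, the default at
#'   ~19 reads per 20-kb bin), `"multinomial"` (reads allocated exactly, so
#'   bin counts sum to `n_mapped`), `"nb"` (negative binomial with
#'   `dispersion`), or `"none"` (noise-free expectations, for oracle tests).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); used only when `noise = "nb"`.
#' @param gc_bias Numeric pair `c(linear, quadratic)`: coefficients of the
#'   bias curve `g(gc) = 1 + linear*(gc - 0.42) + quadratic*(gc - 0.42)^2`,
#'   applied multiplicatively to expected counts. `c(0, 0)` (default)
#'   disables bias.
#' @return Object of class `"seq_config"`.
#' @export
seq_config <- function(n_raw = 5e6, read_len = 45, trim_len = 36,
                       n_mapped = NULL, mapped_range = c(2.8e6, 3.2e6),
                       noise = c("poisson", "multinomial", "nb", "none"),
                       dispersion = 0.02, gc_bias = c(0, 0)) {
  noise <- match.arg(noise)
  if (trim_len > read_len) stop("trimmed length cannot exceed raw length")
  if (!is.null(n_mapped)) {
    if (n_mapped > n_raw) stop("mapped count cannot exceed raw count")
    if (n_mapped <= 0) stop("mapped count must be positive")
  }
  if (length(gc_bias) != 2) stop("gc_bias must be two coefficients")
  structure(list(n_raw = n_raw, read_len = read_len, trim_len = trim_len,
                 n_mapped = n_mapped, mapped_range = mapped_range,
                 noise = noise, dispersion = dispersion, gc_bias = gc_bias),
            class = "seq_config")
}

#' Describe a true copy-number event for the simulator
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bp interval; `NULL` start/end means
#'   the whole chromosome.
#' @param cn Integer target copy number of the affected cell line
#'   (e.g. 3 for trisomy, 1 for monosomy).
#' @param f Mixture fraction in (0, 1]: mosaic fraction of the aberrant
#'   cell line (or, for cell-free DNA, the fetal fraction). The simulated
#'   dosage of affected bins is `2 + f * (cn - 2)`.
#' @return Object of class `"truth_event"` (a one-row data.frame).
#' @export
truth_event <- function(chrom, start = NULL, end = NULL, cn, f = 1) {
  if (f <= 0 || f > 1) stop("mixture fraction f must be in (0, 1]")
  if (cn < 0 || cn != round(cn)) stop("target copy number must be a non-negative integer")
  structure(data.frame(chrom = chrom,
                       start = if (is.null(start)) NA_real_ else start,
                       end = if (is.null(end)) NA_real_ else end,
                       cn = cn, f = f, stringsAsFactors = FALSE),
            class = c("truth_event", "data.frame"))
}

# resolve whole-chromosome events and validate against the genome
resolve_truth <- function(truth, genome) {
  if (is.null(truth) || nrow(truth) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cn = numeric(), f = numeric()))
  truth <- as.data.frame(truth)
  idx <- match(truth$chrom, genome$chrom)
  if (anyNA(idx)) stop("truth event on unknown chromosome: ",
                       paste(truth$chrom[is.na(idx)], collapse = ", "))
  len <- genome$length[idx]
  truth$start[is.na(truth$start)] <- 1
  truth$end[is.na(truth$end)] <- len[is.na(truth$end)]
  if (any(truth$start < 1) || any(truth$end > len))
    stop("truth event outside chromosome bounds")
  if (any(truth$f <= 0 | truth$f > 1)) stop("mixture fraction f must be in (0, 1]")
  # reject overlapping events on the same chromosome
  for (ch in unique(truth$chrom)) {
    ev <- truth[truth$chrom == ch, , drop = FALSE]
    if (nrow(ev) > 1) {
      ev <- ev[order(ev$start), ]
      if (any(ev$start[-1] <= ev$end[-nrow(ev)]))
        stop("overlapping truth events on ", ch)
    }
  }
  truth
}

# expected dosage per bin: baseline sex dosage plus mosaic mixture under events
bin_dosage <- function(grid, truth, sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  dosage <- rep(2, nrow(grid))
  lab <- chrom_label(grid$chrom)
  if (sex == "XY") {
    dosage[lab == "X"] <- 1
    dosage[lab == "Y"] <- 1
  } else {
    dosage[lab == "Y"] <- 0
  }
  if (nrow(truth)) {
    for (k in seq_len(nrow(truth))) {
      on <- grid$chrom == truth$chrom[k]
      ov <- pmax(0, pmin(grid$end, truth$end[k]) -
                   pmax(grid$start, truth$start[k]) + 1)
      frac <- ov / (grid$end - grid$start + 1)
      base <- dosage
      dosage <- ifelse(on & frac > 0,
                       base + frac * truth$f[k] * (truth$cn[k] - base),
                       dosage)
    }
  }
  dosage
}

#' Simulate one sample's bin counts
#'
#' Generates per-bin read counts under the configured sequencing design.
#' The expected count of bin *i* is `m * w_i * (c_i / 2) * g(gc_i)` where
#' `m` scales the mapped-read budget over the effective genome weight,
#' `w_i` is the bin's width share, `c_i` its dosage (2 away from events,
#' `2 + f*(cn - 2)` under an event, and the sex-appropriate X/Y baseline),
#' and `g` the GC-bias curve (identity when bias is disabled). Counts are
#' then drawn from the configured noise model. Identical `seed` gives
#' identical output.
#'
#' @param genome A [genome_model()].
#' @param grid A [build_bin_grid()] grid on `genome`.
#' @param truth A data.frame of [truth_event()] rows (rbind them), or
#'   `NULL` for a normal sample.
#' @param seq A [seq_config()].
#' @param sex Constitutional sex baseline: `"XX"` (chrX dosage 2, chrY 0)
#'   or `"XY"` (1 and 1).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @param sample_id Sample label stored with the counts.
#' @return Object of class `"bin_counts"`: list with the grid, integer (or
#'   noise-free real) `counts`, `total`, the resolved `truth` table and a
#'   `meta` record (seed, noise model, mapped reads, sex).
#' @examples
#' g <- toy_genome()
#' grid <- build_bin_grid(g, 20000)
#' bc <- simulate_case(g, grid, truth_event("chr21", cn = 3, f = 1),
#'                     seq_config(n_mapped = 1e5), sex = "XX", seed = 1)
#' sum(bc$counts) == bc$total
#' @export
simulate_case <- function(genome, grid, truth = NULL, seq = seq_config(),
                          sex = c("XX", "XY"), seed = NULL,
                          sample_id = "sim") {
  stopifnot(inherits(genome, "genome_model"), inherits(grid, "bin_grid"),
            inherits(seq, "seq_config"))
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(truth, "truth_event")) truth <- as.data.frame(truth)
  truth <- resolve_truth(truth, genome)

  n_mapped <- seq$n_mapped
  if (is.null(n_mapped))
    n_mapped <- round(stats::runif(1, seq$mapped_range[1], seq$mapped_range[2]))

  dosage <- bin_dosage(grid, truth, sex)
  g <- 1 + seq$gc_bias[1] * (grid$gc - 0.42) +
    seq$gc_bias[2] * (grid$gc - 0.42)^2
  g <- pmax(g, 0.05)
  weight <- grid$width_share * (dosage / 2) * g
  mu <- n_mapped * weight / sum(weight)

  counts <- switch(seq$noise,
    poisson = stats::rpois(length(mu), mu),
    multinomial = as.vector(stats::rmultinom(1, size = n_mapped, prob = weight)),
    nb = stats::rnbinom(length(mu), mu = mu, size = 1 / seq$dispersion),
    none = mu)

  structure(list(sample_id = sample_id, grid = grid, counts = counts,
                 total = sum(counts), truth = truth,
                 meta = list(seed = seed, noise = seq$noise,
                             n_mapped = n_mapped, n_raw = seq$n_raw,
                             read_len = seq$read_len, trim_len = seq$trim_len,
                             gc_bias = seq$gc_bias, sex = sex)),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin counts '%s': %d bins, %.4g reads (%s noise)\n",
              x$sample_id, length(x$counts), x$total,
              if (is.null(x$meta$noise)) "unknown" else x$meta$noise))
  if (nrow(x$truth)) {
    cat("truth events:\n")
    print(x$truth)
  }
  invisible(x)
}

#' Simulate a cohort of cases with truth labels
#'
#' Draws case categories from `mix`, simulates each case's bin counts, and
#' returns per-case truth records -- a statistical stand-in for a high-risk
#' prenatal cohort so every downstream stage can be exercised without any
#' external data. Available categories: `"normal"`, `"t21"`, `"t18"`,
#' `"t13"`, `"t21_mosaic"`, `"monosomy_x"`, `"xxy"`, `"segmental_dup"`,
#' `"segmental_del"`.
#'
#' @param n_cases Number of cases (> 0).
#' @param mix Named numeric vector of category proportions summing to 1.
#' @param genome,grid Genome and bin grid shared by all cases.
#' @param seq A [seq_config()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return List with `cases` (list of `bin_counts`) and `records`
#'   (data.frame: case_id, category, sex, truth summary).
#' @export
simulate_cohort <- function(n_cases, mix = c(normal = 0.6, t21 = 0.4),
                            genome = toy_genome(),
                            grid = build_bin_grid(genome),
                            seq = seq_config(n_mapped = 2e5), seed = 1) {
  if (n_cases <= 0) stop("n_cases must be positive")
  if (abs(sum(mix) - 1) > 1e-8) stop("category proportions must sum to 1")
  set.seed(seed)
  categories <- sample(names(mix), n_cases, replace = TRUE, prob = mix)
  seg_len <- function(ch) {
    L <- genome$length[match(ch, genome$chrom)]
    c(round(L * 0.3), round(L * 0.3) + 10 * attr(grid, "bin_width") - 1)
  }
  cases <- vector("list", n_cases)
  records <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cat_i <- categories[i]
    sex <- if (stats::runif(1) < 0.5) "XX" else "XY"
    truth <- switch(cat_i,
      normal = NULL,
      t21 = truth_event("chr21", cn = 3, f = 1),
      t18 = truth_event("chr18", cn = 3, f = 1),
      t13 = truth_event("chr13", cn = 3, f = 1),
      t21_mosaic = truth_event("chr21", cn = 3,
                               f = stats::runif(1, 0.3, 0.7)),
      monosomy_x = { sex <- "XX"; truth_event("chrX", cn = 1, f = 1) },
      xxy = { sex <- "XY"; truth_event("chrX", cn = 2, f = 1) },
      segmental_dup = { sl <- seg_len("chr4")
        truth_event("chr4", sl[1], sl[2], cn = 3, f = 1) },
      segmental_del = { sl <- seg_len("chr5")
        truth_event("chr5", sl[1], sl[2], cn = 1, f = 1) },
      stop("unknown cohort category: ", cat_i))
    cases[[i]] <- simulate_case(genome, grid, truth, seq, sex = sex,
                                sample_id = sprintf("case%03d", i))
    tr <- cases[[i]]$truth
    records[[i]] <- data.frame(
      case_id = cases[[i]]$sample_id, category = cat_i, sex = sex,
      truth = if (nrow(tr)) paste(sprintf("%s:%d-%d cn%d f%.2f", tr$chrom,
                                          tr$start, tr$end, tr$cn, tr$f),
                                  collapse = ";") else "",
      stringsAsFactors = FALSE)
  }
  list(cases = cases, records = do.call(rbind, records))
}

#' Write / read bin-count tables
#'
#' Tab-separated schema `chrom, start, end, gc, count` (1-based inclusive
#' coordinates), with the simulation/processing metadata in `#`-prefixed
#' header lines.
#'
#' @param x A `bin_counts` object.
#' @param path File path.
#' @return `write_bin_counts` returns `path` invisibly; `read_bin_counts`
#'   returns a `bin_counts` object (grid rebuilt from the file columns).
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "bin_counts"))
  hdr <- c(sprintf("# sample_id=%s", x$sample_id),
           sprintf("# total=%s", format(x$total, scientific = FALSE)),
           sprintf("# bin_width=%g", attr(x$grid, "bin_width")),
           sprintf("# meta=%s", paste(names(x$meta),
                                      vapply(x$meta, function(v)
                                        paste(format(v), collapse = ","),
                                        character(1)),
                                      sep = ":", collapse = ";")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(chrom = x$grid$chrom, start = x$grid$start,
                                end = x$grid$end, gc = x$grid$gc,
                                count = x$counts),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  sample_id <- sub("^# sample_id=", "", grep("^# sample_id=", hdr, value = TRUE))
  bw_line <- grep("^# bin_width=", hdr, value = TRUE)
  bw <- if (length(bw_line)) as.numeric(sub("^# bin_width=", "", bw_line)) else
    max(tab$end - tab$start + 1)
  grid <- data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
                     gc = tab$gc,
                     width_share = (tab$end - tab$start + 1) / bw,
                     stringsAsFactors = FALSE)
  attr(grid, "bin_width") <- bw
  class(grid) <- c("bin_grid", "data.frame")
  structure(list(sample_id = if (length(sample_id)) sample_id else "sample",
                 grid = grid, counts = tab$count, total = sum(tab$count),
                 truth = data.frame(), meta = list(source = path)),
            class = "bin_counts")
}
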