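#' Fit the copy-number model to one sample's bin counts
#'
#' The package's central estimator. Takes per-bin read counts (from
#' [assign_reads_to_bins()], [simulate_case()] or [read_bin_counts()]),
#' optionally removes GC bias, normalizes to the diploid copy-number
#' scale against a robust autosomal baseline, infers constitutional sex
#' from chrY dosage, segments the profile with a deterministic
#' multi-scale scan, and classifies every segment into the five
#' diagnostic states (duplication, mosaic trisomy, disomy, mosaic
#' monosomy, deletion). The result is an object of class `"rcnv"` with
#' the usual modelling methods: [print()], [summary()], [coef()]
#' (per-chromosome mean CN), [fitted()] (expected bin counts under the
#' segmented model), [residuals()] (Pearson), [predict()] (CN or state
#' for arbitrary intervals), [plot()] (the 24-chromosome CN plot) and
#' [simulate()] (parametric bootstrap of bin counts).
#'
#' @param counts A `bin_counts` object.
#' @param thresholds A [cn_thresholds()].
#' @param gc_correct Apply [gc_correct()] first (default `TRUE` when the
#'   grid carries GC fractions).
#' @param baseline Passed to [estimate_cn()].
#' @param sex `"auto"`, `"XX"` or `"XY"`.
#' @param min_bins,z_cut Passed to [segment_profile()].
#' @return Object of class `"rcnv"`.
#' @examples
#' g <- toy_genome()
#' grid <- build_bin_grid(g)
#' bc <- simulate_case(g, grid, truth_event("chr21", cn = 3, f = 1),
#'                     seq_config(n_mapped = 2e5), sex = "XX", seed = 7)
#' fit <- rcnv(bc)
#' round(coef(fit)[["chr21"]], 2)
#' @export
rcnv <- function(counts, thresholds = cn_thresholds(), gc_correct = TRUE,
                 baseline = "trimmed", sex = "auto", min_bins = 5,
                 z_cut = 3.2) {
  stopifnot(inherits(counts, "bin_counts"))
  corrected <- counts
  if (isTRUE(gc_correct) && !is.null(counts$grid$gc) &&
      !all(is.na(counts$grid$gc)))
    corrected <- rcnvseq::gc_correct(counts)
  profile <- estimate_cn(corrected, baseline = baseline, sex = sex)
  segments <- segment_profile(profile, thresholds, min_bins, z_cut)
  calls <- segments[segments$state != "disomy", , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(counts = counts, corrected = corrected, profile = profile,
                 segments = segments, calls = calls,
                 thresholds = thresholds,
                 params = list(min_bins = min_bins, z_cut = z_cut,
                               baseline = baseline,
                               gc_correct = isTRUE(gc_correct))),
            class = "rcnv")
}

#' @export
print.rcnv <- function(x, ...) {
  cat(sprintf("rCNV-seq fit '%s': %d bins, %.4g reads, inferred sex %s\n",
              x$profile$sample_id, length(x$profile$cn),
              x$counts$total, x$profile$sex))
  cat(sprintf("baseline %.3f reads/bin; %d non-disomic segment(s)\n",
              x$profile$baseline, nrow(x$calls)))
  if (nrow(x$calls)) {
    show <- x$calls
    show$mean_cn <- round(show$mean_cn, 3)
    show$rel_cn <- round(show$rel_cn, 3)
    show$f <- round(show$f, 3)
    print(show[, c("chrom", "start", "end", "n_bins", "rel_cn", "state",
                   "mosaic", "f")], row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn rcnv Per-chromosome CN table, calls and (when cytobands are
#'   supplied at annotation time) the case triage.
#' @param object,x An `"rcnv"` fit.
#' @param ... Unused.
#' @export
summary.rcnv <- function(object, ...) {
  out <- list(sample_id = object$profile$sample_id,
              sex = object$profile$sex,
              total_reads = object$counts$total,
              baseline = object$profile$baseline,
              per_chrom = object$profile$per_chrom,
              calls = object$calls)
  class(out) <- "summary.rcnv"
  out
}

#' @export
print.summary.rcnv <- function(x, ...) {
  cat(sprintf("sample %s (inferred %s), %.4g mapped reads\n", x$sample_id,
              x$sex, x$total_reads))
  cat("per-chromosome mean copy number:\n")
  pc <- x$per_chrom
  pc$mean_cn <- round(pc$mean_cn, 3)
  print(pc, row.names = FALSE)
  cat(sprintf("%d non-disomic segment call(s)\n", nrow(x$calls)))
  invisible(x)
}

#' @export
coef.rcnv <- function(object, ...) {
  stats::setNames(object$profile$per_chrom$mean_cn,
                  object$profile$per_chrom$chrom)
}

#' @export
fitted.rcnv <- function(object, ...) {
  grid <- object$profile$grid
  cn <- rep(NA_real_, nrow(grid))
  seg <- object$segments
  for (k in seq_len(nrow(seg))) {
    i <- which(grid$chrom == seg$chrom[k])
    cn[i[seg$start_bin[k]:seg$end_bin[k]]] <- seg$mean_cn[k]
  }
  object$profile$baseline * grid$width_share * cn / 2
}

#' @export
residuals.rcnv <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  obs <- object$corrected$counts
  r <- obs - mu
  if (type == "pearson") {
    r <- ifelse(mu > 0, r / sqrt(mu), 0)
  }
  r
}

#' Predict copy number or state for arbitrary intervals
#'
#' @param object An `"rcnv"` fit.
#' @param newdata data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive bp); `NULL` returns per-bin values.
#' @param type `"cn"` (interval mean CN) or `"state"` (its five-state
#'   classification, dosage-relative on the sex chromosomes).
#' @param ... Unused.
#' @return Numeric vector (`"cn"`) or factor (`"state"`).
#' @export
predict.rcnv <- function(object, newdata = NULL,
                         type = c("cn", "state"), ...) {
  type <- match.arg(type)
  grid <- object$profile$grid
  if (is.null(newdata)) {
    cn <- object$profile$cn
    if (type == "cn") return(cn)
    d <- expected_dosage(grid$chrom, object$profile$sex)
    rel <- ifelse(d > 0, cn * 2 / d, cn)
    return(classify_cn(pmax(rel, 0), object$thresholds))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(newdata)))
  cn <- numeric(nrow(newdata)); rel <- numeric(nrow(newdata))
  for (k in seq_len(nrow(newdata))) {
    i <- which(grid$chrom == newdata$chrom[k] &
                 grid$end >= newdata$start[k] &
                 grid$start <= newdata$end[k])
    if (!length(i)) { cn[k] <- NA; rel[k] <- NA; next }
    w <- grid$width_share[i]
    cn[k] <- sum(object$profile$cn[i] * w) / sum(w)
    d <- expected_dosage(newdata$chrom[k], object$profile$sex)
    rel[k] <- if (d > 0) cn[k] * 2 / d else cn[k]
  }
  if (type == "cn") cn else classify_cn(pmax(rel, 0), object$thresholds)
}

#' Parametric bootstrap of bin counts from a fit
#'
#' Draws new Poisson bin counts with means given by the fitted segmented
#' model, mirroring [stats::simulate()] semantics.
#'
#' @param object An `"rcnv"` fit.
#' @param nsim Number of replicate count vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return data.frame with `nsim` columns `sim_1..sim_nsim`.
#' @export
simulate.rcnv <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(lapply(seq_len(nsim), function(k)
    stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' 24-chromosome copy-number plot
#'
#' One panel per chromosome: per-bin CN estimates with the segment means
#' and the five-state threshold lines, the standard visual read-out of a
#' shallow-coverage CNV screen.
#'
#' @param x An `"rcnv"` fit.
#' @param chroms Chromosomes to show (default: all in the grid).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rcnv <- function(x, chroms = NULL, ...) {
  grid <- x$profile$grid
  if (is.null(chroms)) chroms <- unique(grid$chrom)
  nc <- length(chroms)
  mf <- grDevices::n2mfrow(nc)
  old <- graphics::par(mfrow = mf, mar = c(2, 3, 1.5, 0.5))
  on.exit(graphics::par(old))
  t <- x$thresholds
  for (ch in chroms) {
    i <- which(grid$chrom == ch)
    pos <- (grid$start[i] + grid$end[i]) / 2e6
    graphics::plot(pos, x$profile$cn[i], pch = ".", col = "grey40",
                   ylim = c(0, 4), xlab = "", ylab = "CN", main = ch, ...)
    graphics::abline(h = c(t$del_max, t$disomy_lo, t$disomy_hi, t$dup_min),
                     col = "steelblue", lty = 3)
    seg <- x$segments[x$segments$chrom == ch, , drop = FALSE]
    graphics::segments(seg$start / 1e6, seg$mean_cn, seg$end / 1e6,
                       seg$mean_cn, col = ifelse(seg$state == "disomy",
                                                 "black", "red"), lwd = 2)
  }
  invisible(x)
}
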