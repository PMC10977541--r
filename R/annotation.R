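#' Read a cytogenetic band table
#'
#' Five tab-separated columns `chrom, start, end, band, stain`. The
#' packaged condensed hg19 table uses 1-based inclusive coordinates;
#' genuine UCSC `cytoBand.txt` files (0-based half-open starts) are
#' converted on load with `zero_based = TRUE`. Bands must tile each
#' chromosome without gap or overlap and be uniquely named per
#' chromosome.
#'
#' @param path File path; default the packaged condensed hg19 table.
#' @param zero_based Set `TRUE` for UCSC-convention input.
#' @return data.frame of class `"cytoband_table"`.
#' @export
read_cytoband <- function(path = system.file("extdata",
                                             "cytoband_hg19_condensed.tsv",
                                             package = "rcnvseq"),
                          zero_based = FALSE) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "band", "stain"))
  if (zero_based) tab$start <- tab$start + 1L
  for (ch in unique(tab$chrom)) {
    b <- tab[tab$chrom == ch, ]
    b <- b[order(b$start), ]
    if (any(b$start[-1] != b$end[-nrow(b)] + 1))
      stop("bands do not tile ", ch)
    if (anyDuplicated(b$band)) stop("duplicate band names on ", ch)
  }
  class(tab) <- c("cytoband_table", "data.frame")
  tab
}

#' Cytoband name(s) spanning an interval
#'
#' Returns the concatenated band names of the interval's start and end
#' positions (e.g. `"q11.2q22.3"`), collapsing to a single band name when
#' both ends fall in the same band.
#'
#' @param chrom Chromosome name (with or without `"chr"` prefix).
#' @param start,end 1-based inclusive bp positions.
#' @param bands A [read_cytoband()] table.
#' @return Band string.
#' @examples
#' \dontrun{
#' band_lookup("chr18", 1, 78077248, read_cytoband())  # "p11.32q23"
#' }
#' @export
band_lookup <- function(chrom, start, end, bands) {
  stopifnot(inherits(bands, "cytoband_table"), end >= start)
  b <- bands[chrom_label(bands$chrom) == chrom_label(chrom), , drop = FALSE]
  if (!nrow(b)) stop("no bands for chromosome ", chrom)
  b <- b[order(b$start), ]
  locate <- function(pos) {
    i <- findInterval(pos, b$start)
    if (i < 1 || pos > b$end[i]) stop("position ", pos, " outside band table for ",
                                      chrom)
    b$band[i]
  }
  b1 <- locate(start); b2 <- locate(end)
  if (b1 == b2) b1 else paste0(b1, b2)
}

#' Format a CNV call as ISCN-like and g.-notation strings
#'
#' `dup(21)(q11.2q22.3)` style region strings (with a `(mos)` suffix for
#' mosaic calls) and `chr21:g.14300000_48129895dup` HGVS-like genomic
#' coordinates; both round-trip through [parse_call()].
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bp interval.
#' @param type `"dup"` or `"del"`.
#' @param mosaic Logical mosaic flag.
#' @param bands A [read_cytoband()] table (used for the region string).
#' @return List with elements `iscn` and `g`.
#' @export
format_call <- function(chrom, start, end, type = c("dup", "del"),
                        mosaic = FALSE, bands) {
  type <- match.arg(type)
  zone <- band_lookup(chrom, start, end, bands)
  lab <- chrom_label(chrom)
  list(iscn = sprintf("%s(%s)(%s)%s", type, lab, zone,
                      if (mosaic) "(mos)" else ""),
       g = sprintf("chr%s:g.%d_%d%s", lab, as.integer(start),
                   as.integer(end), type))
}

#' Parse ISCN-like region and g.-notation strings
#'
#' Inverse of [format_call()]: accepts either a region string
#' (`dup(21)(q11.2q22.3)(mos)`) or a g.-notation string
#' (`chr21:g.14300000_48129895dup`), returning the encoded fields.
#'
#' @param s Call string.
#' @return List with `type`, `chrom`, and either `zone` + `mosaic`
#'   (region string) or `start` + `end` (g. string).
#' @export
parse_call <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^(dup|del)\\(([0-9XY]+)\\)\\(([^)]+)\\)(\\(mos\\))?$", s))[[1]]
  if (length(m)) {
    return(list(type = m[2], chrom = m[3], zone = m[4],
                mosaic = nzchar(m[5])))
  }
  m <- regmatches(s, regexec("^chr([0-9XY]+):g\\.([0-9]+)_([0-9]+)(dup|del)$", s))[[1]]
  if (length(m)) {
    return(list(type = m[5], chrom = m[2], start = as.numeric(m[3]),
                end = as.numeric(m[4])))
  }
  stop("unparseable call string: ", s)
}

#' Fragment size of a call
#'
#' @param start,end 1-based inclusive bp interval (`end >= start`).
#' @return Size in bp, `end - start + 1`.
#' @seealso [format_mb()] for the 2-decimal Mb rendering used in reports.
#' @export
fragment_size <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  end - start + 1
}

#' @rdname fragment_size
#' @param size_bp Size in bp.
#' @export
format_mb <- function(size_bp) round_half_up(size_bp / 1e6, 2)

#' Diagnostic triage rules
#'
#' The category vocabulary of the screen: whole-chromosome events on the
#' common trisomy chromosomes (21, 18, 13), sex-chromosome dosage
#' anomalies (with karyotype labels from the X+Y copy map), rare
#' whole-autosome aneuploidies, multi-chromosome abnormalities, and
#' sub-chromosomal CNVs split into pathogenic (membership in the packaged
#' recurrent-region list -- seeded with the Xp22.31/STS deletion region --
#' or size at least `size_floor`) versus variants of uncertain
#' significance.
#'
#' @param common_chroms Common-aneuploidy chromosomes.
#' @param pathogenic_regions data.frame `chrom, start, end, name`.
#' @param size_floor Pathogenic size floor in bp, default 1e6.
#' @param whole_chrom_frac Fraction of a chromosome's bins a call must
#'   span to count as whole-chromosome, default 0.9.
#' @return Object of class `"triage_rules"`.
#' @export
triage_rules <- function(common_chroms = c("21", "18", "13"),
                         pathogenic_regions = data.frame(
                           chrom = "X", start = 6000001, end = 9500000,
                           name = "Xp22.31 (STS)",
                           stringsAsFactors = FALSE),
                         size_floor = 1e6, whole_chrom_frac = 0.9) {
  structure(list(common_chroms = common_chroms,
                 pathogenic_regions = pathogenic_regions,
                 size_floor = size_floor,
                 whole_chrom_frac = whole_chrom_frac,
                 sex_labels = list("1,0" = "45,X", "2,1" = "47,XXY",
                                   "1,2" = "47,XYY", "3,0" = "47,XXX",
                                   "1,3" = "48,XYYY")),
            class = "triage_rules")
}

#' Case triage categories
#' @return Character vector of the seven categories in precedence order
#'   (multi-chromosome first, normal last).
#' @export
triage_categories <- function() {
  c("multiple_chromosome_abnormality", "common_autosomal_aneuploidy",
    "sex_chromosome_aneuploidy", "rare_autosomal_aneuploidy",
    "pathogenic_cnv", "vus_cnv", "normal")
}

#' Triage a case from its CNV calls
#'
#' Applies the documented precedence: whole-chromosome events on two or
#' more chromosomes beat everything; then common aneuploidy (21/18/13),
#' sex-chromosome aneuploidy (labelled from the rounded X+Y dosage map),
#' rare whole-autosome aneuploidy, pathogenic CNV, uncertain CNV, normal.
#' Every case receives exactly one category.
#'
#' @param calls Segment-call data.frame (an `rcnv` fit's `$calls`, or an
#'   [annotate_calls()] table).
#' @param sex Constitutional sex of the sample (`"XX"`/`"XY"`).
#' @param rules A [triage_rules()].
#' @param sex_dosage Optional named numeric `c(X = , Y = )` observed mean
#'   CN of the sex chromosomes (used for the karyotype label); derived
#'   from the calls and `sex` when omitted.
#' @return List with `category`, `label` (e.g. `"trisomy 21"`,
#'   `"47,XXY"`) and the whole-chromosome call chromosomes.
#' @export
triage_case <- function(calls, sex = "XX", rules = triage_rules(),
                        sex_dosage = NULL) {
  if (is.null(calls) || nrow(calls) == 0)
    return(list(category = "normal", label = "normal",
                whole_chroms = character()))
  calls$chrom_lab <- chrom_label(calls$chrom)
  wc <- calls[!is.na(calls$frac_chrom) &
                calls$frac_chrom >= rules$whole_chrom_frac, , drop = FALSE]
  wc_chroms <- unique(wc$chrom_lab)
  sub <- calls[is.na(calls$frac_chrom) |
                 calls$frac_chrom < rules$whole_chrom_frac, , drop = FALSE]

  sexy <- wc_chroms[wc_chroms %in% c("X", "Y")]
  auto_wc <- setdiff(wc_chroms, c("X", "Y"))

  if (length(wc_chroms) >= 2)
    return(list(category = "multiple_chromosome_abnormality",
                label = paste("whole-chromosome events on",
                              paste(wc_chroms, collapse = ", ")),
                whole_chroms = wc_chroms))
  if (length(auto_wc) && auto_wc %in% rules$common_chroms) {
    gain <- wc$state[wc$chrom_lab == auto_wc][1] %in%
      c("duplication", "mosaic_trisomy")
    return(list(category = "common_autosomal_aneuploidy",
                label = paste(if (gain) "trisomy" else "monosomy", auto_wc),
                whole_chroms = wc_chroms))
  }
  if (length(sexy)) {
    if (is.null(sex_dosage)) {
      base <- if (sex == "XY") c(X = 1, Y = 1) else c(X = 2, Y = 0)
      for (ch in sexy) {
        delta <- if (wc$state[wc$chrom_lab == ch][1] %in%
                     c("duplication", "mosaic_trisomy")) 1 else -1
        base[ch] <- base[ch] + delta
      }
      sex_dosage <- base
    }
    key <- paste(max(0, round(sex_dosage[["X"]])),
                 max(0, round(sex_dosage[["Y"]])), sep = ",")
    lab <- rules$sex_labels[[key]]
    if (is.null(lab))
      lab <- sprintf("%d,%s%s", 44 + sum(round(sex_dosage)),
                     strrep("X", round(sex_dosage[["X"]])),
                     strrep("Y", round(sex_dosage[["Y"]])))
    return(list(category = "sex_chromosome_aneuploidy", label = lab,
                whole_chroms = wc_chroms))
  }
  if (length(auto_wc)) {
    gain <- wc$state[wc$chrom_lab == auto_wc][1] %in%
      c("duplication", "mosaic_trisomy")
    return(list(category = "rare_autosomal_aneuploidy",
                label = paste(if (gain) "trisomy" else "monosomy", auto_wc),
                whole_chroms = wc_chroms))
  }
  # sub-chromosomal only
  if (nrow(sub)) {
    size <- fragment_size(sub$start, sub$end)
    reg <- rules$pathogenic_regions
    in_region <- vapply(seq_len(nrow(sub)), function(k) {
      any(chrom_label(reg$chrom) == sub$chrom_lab[k] &
            reg$start <= sub$end[k] & reg$end >= sub$start[k])
    }, logical(1))
    if (any(in_region | size >= rules$size_floor))
      return(list(category = "pathogenic_cnv",
                  label = if (any(in_region))
                    reg$name[match(TRUE, in_region)] else "large CNV",
                  whole_chroms = character()))
    return(list(category = "vus_cnv", label = "CNV of uncertain significance",
                whole_chroms = character()))
  }
  list(category = "normal", label = "normal", whole_chroms = character())
}

#' Annotate segment calls with bands, nomenclature, sizes and triage
#'
#' Turns an `rcnv` fit's calls into the reporting vocabulary: ISCN-like
#' region string, g.-notation string, fragment size (bp and Mb) and the
#' case-level triage category.
#'
#' @param fit An [rcnv()] fit.
#' @param bands A [read_cytoband()] table.
#' @param rules A [triage_rules()].
#' @return List with `calls` (annotated data.frame) and `triage`
#'   (the [triage_case()] result).
#' @export
annotate_calls <- function(fit, bands = read_cytoband(),
                           rules = triage_rules()) {
  stopifnot(inherits(fit, "rcnv"))
  calls <- fit$calls
  if (nrow(calls)) {
    ann <- lapply(seq_len(nrow(calls)), function(k) {
      type <- if (calls$rel_cn[k] >= 2) "dup" else "del"
      fc <- format_call(calls$chrom[k], calls$start[k], calls$end[k],
                        type, calls$mosaic[k], bands)
      data.frame(iscn = fc$iscn, g = fc$g, type = type,
                 size_bp = fragment_size(calls$start[k], calls$end[k]),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, ann)
    ann$size_mb <- format_mb(ann$size_bp)
    calls <- cbind(calls, ann)
  }
  cc <- coef(fit)
  sex_dosage <- if (all(c("chrX", "chrY") %in% names(cc)))
    c(X = unname(cc[["chrX"]]), Y = unname(cc[["chrY"]])) else NULL
  triage <- triage_case(calls, sex = fit$profile$sex, rules = rules,
                        sex_dosage = sex_dosage)
  list(calls = calls, triage = triage)
}
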