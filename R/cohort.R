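#' Round half away from zero
#'
#' Decimal rounding with ties going up (`round_half_up(0.125, 2)` is
#' 0.13), the convention clinical reports use, as opposed to R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 2.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Pregnancy-outcome vocabulary
#' @return The closed set of follow-up outcomes.
#' @export
outcome_levels <- function() {
  c("continued gestation", "live birth", "miscarriage",
    "termination of pregnancy", "failure to follow-up")
}

# deterministic within-stratum values: symmetric grid with the stratum
# mean hit exactly and spread as close to the target SD as the bounds allow
stratum_values <- function(n, mean, sd, lo, hi) {
  if (n == 1) return(mean)
  z <- seq_len(n) - (n + 1) / 2
  z <- z / sqrt(mean(z^2))
  zmax <- max(abs(z))
  s <- min(sd, 0.999 * (hi - mean) / zmax, 0.999 * (mean - lo) / zmax)
  mean + s * z
}

# karyotype reference tables: the G-banding strings of the autosomal- and
# sex-aneuploidy report groups, with case multiplicities (totals 156 / 68)
#' Reference karyotype tables of the reconstructed cohort
#'
#' The distinct G-banding karyotype strings observed in the cohort's
#' autosomal-aneuploidy and sex-chromosome-aneuploidy groups, with their
#' case counts (156 and 68 cases respectively). These drive the
#' [reconstructed_cohort()] assignment and the karyotype-parser
#' regression suite.
#'
#' @return List of two data.frames (`autosomal`, `sex`) with columns
#'   `group`, `karyotype`, `n`, `mosaic`.
#' @export
karyotype_reference_tables <- function() {
  autosomal <- data.frame(
    group = c(rep("trisomy 21", 9), rep("trisomy 21 (mos)", 2),
              rep("trisomy 18", 3), rep("trisomy 13", 3),
              "trisomy 13 (mos)"),
    karyotype = c("47,XY + 21", "47,XX + 21", "46,XX + 21,rob(15;22)",
                  "46,XX,rob(21;21) + 21", "47,XX + 21,t(9;15)",
                  "47,XX,inv (9) + 21", "47,XX,14ps+,+21",
                  "46,XY,rob(15;22) + 21", "46,XY,rob(14;21) + 21",
                  "47,XY + 21[]/46,XY[]", "47,XX + 21[]/46,XX[]",
                  "47,XX + 18", "47,XY + 18", "47,XY + 18,t(2;7)",
                  "47,XY + 13", "47,XX + 13", "46,XY,rob(13;13) + 13",
                  "47,XX + 13[46]/46,XX[26]"),
    n = c(66, 53, 1, 1, 1, 1, 1, 1, 1, 3, 1, 12, 6, 1, 3, 2, 1, 1),
    stringsAsFactors = FALSE)
  autosomal$mosaic <- grepl("/", autosomal$karyotype)
  sex <- data.frame(
    group = c("Klinefelter", "Klinefelter", "Klinefelter (mos)",
              "Jacob", "Superman", "Triple X", "Triple X", "Triple X",
              "Turner", "Turner", "Turner", "Turner (mos)"),
    karyotype = c("47,XXY", "47,XXY,15ps+", "47,XXY[]/46,XY[]",
                  "47,XYY", "48,XYYY", "47,XXX", "47,XXX,1qh+,22ps+",
                  "47,XXX[56]/45,X0[6]", "45,X0", "45,XY,rob (15;22)",
                  "46,X,+mar[14]/45,X[56]", "45,XO[]/46,XX[]"),
    n = c(19, 1, 5, 13, 1, 10, 1, 1, 5, 1, 1, 10),
    stringsAsFactors = FALSE)
  sex$mosaic <- grepl("/", sex$karyotype)
  list(autosomal = autosomal, sex = sex)
}

# expand a reference table to one string per case, mosaic strings first
expand_karyotypes <- function(tab, groups) {
  tab <- tab[tab$group %in% groups, , drop = FALSE]
  rep(tab$karyotype, tab$n)
}

#' Reconstructed high-risk prenatal cohort
#'
#' A per-case table of 424 high-risk pregnancies screened by shallow
#' whole-genome sequencing, reconstructed from the published aggregate
#' report tables (aneuploidy region/zone counts, G-banding karyotype
#' tables, age and gestational-age strata, follow-up narrative). It is a
#' synthetic reconstruction, not deposited per-case data: where only
#' aggregates were published, rows carry the category-level labels and
#' deterministic within-stratum values, so every aggregate summary in the
#' package reproduces the published counts. Column `karyotype_class`
#' stores the karyotype report group each string was published under.
#'
#' @return data.frame of class `"cohort_table"`, 424 rows: `case_id`,
#'   `age`, `ga_weeks`, `category`, `label`, `mosaic`, `call_iscn`,
#'   `call_g`, `cnv_size_mb`, `karyotype`, `karyotype_class`, `outcome`.
#' @export
reconstructed_cohort <- function() {
  kt <- karyotype_reference_tables()
  blk <- function(n, ...) {
    args <- list(...)
    df <- data.frame(category = args$category, label = args$label,
                     mosaic = args$mosaic %||% FALSE,
                     call_iscn = args$iscn %||% NA_character_,
                     call_g = args$g %||% NA_character_,
                     cnv_size_mb = args$size_mb %||% NA_real_,
                     karyotype = args$karyotype %||% NA_character_,
                     karyotype_class = args$kclass %||% NA_character_,
                     outcome = args$outcome,
                     stringsAsFactors = FALSE)
    if (nrow(df) == 1 && n > 1) df <- df[rep(1, n), , drop = FALSE]
    stopifnot(nrow(df) == n)
    df
  }
  out <- list()

  # --- trisomy 21: 169 cases (147 q11.2 zone, 16 q11.1 zone, 6 mosaic) ----
  t21 <- blk(169, category = "common_autosomal_aneuploidy",
             label = "trisomy 21",
             mosaic = rep(c(FALSE, TRUE), c(163, 6)),
             iscn = rep(c("dup(21)(q11.2q22.3)", "dup(21)(q11.1q22.3)",
                          "dup(21)(q11.2q22.3)(mos)"), c(147, 16, 6)),
             g = "chr21:g.14300000_48129895dup",
             outcome = rep(c("termination of pregnancy", "live birth",
                             "failure to follow-up"), c(125, 1, 43)))
  k_nonmos <- expand_karyotypes(kt$autosomal, "trisomy 21")        # 126
  k_mos <- expand_karyotypes(kt$autosomal, "trisomy 21 (mos)")     # 4
  t21$karyotype[seq_along(k_nonmos)] <- k_nonmos
  t21$karyotype[163 + seq_along(k_mos)] <- k_mos
  t21$karyotype_class[!is.na(t21$karyotype)] <- "autosomal"
  out$t21 <- t21

  # --- trisomy 18: 24 cases -----------------------------------------------
  t18 <- blk(24, category = "common_autosomal_aneuploidy",
             label = "trisomy 18", iscn = "dup(18)(p11.32q23)",
             g = "chr18:g.1_78077248dup",
             outcome = rep(c("termination of pregnancy",
                             "failure to follow-up"), c(23, 1)))
  k18 <- expand_karyotypes(kt$autosomal, "trisomy 18")             # 19
  t18$karyotype[seq_along(k18)] <- k18
  t18$karyotype_class[!is.na(t18$karyotype)] <- "autosomal"
  out$t18 <- t18

  # --- trisomy 13: 10 cases (1 mosaic) ------------------------------------
  t13 <- blk(10, category = "common_autosomal_aneuploidy",
             label = "trisomy 13",
             mosaic = rep(c(FALSE, TRUE), c(9, 1)),
             iscn = rep(c("dup(13)(q12.11q34)", "dup(13)(q12.11q34)(mos)"),
                        c(9, 1)),
             g = "chr13:g.19500000_115169878dup",
             outcome = rep(c("termination of pregnancy",
                             "failure to follow-up"), c(9, 1)))
  k13 <- expand_karyotypes(kt$autosomal, "trisomy 13")             # 6
  t13$karyotype[seq_along(k13)] <- k13
  t13$karyotype[10] <- expand_karyotypes(kt$autosomal, "trisomy 13 (mos)")
  t13$karyotype_class[!is.na(t13$karyotype)] <- "autosomal"
  out$t13 <- t13

  # --- sex-chromosome aneuploidy: 91 cases --------------------------------
  xxy <- blk(35, category = "sex_chromosome_aneuploidy", label = "47,XXY",
             mosaic = rep(c(FALSE, TRUE), c(29, 6)),
             iscn = rep(c("dup(X)(p22.33q28)", "dup(X)(p22.33q28)(mos)"),
                        c(29, 6)),
             g = "chrX:g.1_155270560dup",
             outcome = rep(c("termination of pregnancy", "live birth",
                             "failure to follow-up"), c(22, 6, 7)))
  xxy$karyotype[1:20] <- expand_karyotypes(kt$sex, "Klinefelter")
  xxy$karyotype[29 + 1:5] <- expand_karyotypes(kt$sex, "Klinefelter (mos)")
  xxy$karyotype_class[!is.na(xxy$karyotype)] <- "sex"
  out$xxy <- xxy

  turner <- blk(22, category = "sex_chromosome_aneuploidy", label = "45,X",
                mosaic = rep(c(FALSE, TRUE), c(9, 13)),
                iscn = rep(c("del(X)(p22.33q28)", "del(X)(p22.33q28)(mos)"),
                           c(9, 13)),
                g = "chrX:g.1_155270560del",
                outcome = rep(c("miscarriage", "termination of pregnancy"),
                              c(1, 21)))
  k_t <- expand_karyotypes(kt$sex, "Turner")   # 5x 45,X0, rob, mar-mosaic
  turner$karyotype[1:6] <- k_t[1:6]
  k_tmos <- c(k_t[7], expand_karyotypes(kt$sex, "Turner (mos)"))   # 11
  turner$karyotype[9 + seq_along(k_tmos)] <- k_tmos
  turner$karyotype_class[!is.na(turner$karyotype)] <- "sex"
  out$turner <- turner

  xyy <- blk(19, category = "sex_chromosome_aneuploidy", label = "47,XYY",
             mosaic = rep(c(FALSE, TRUE), c(16, 3)),
             iscn = rep(c("dup(Y)(p11.32q12)", "dup(Y)(p11.32q12)(mos)"),
                        c(16, 3)),
             g = "chrY:g.1_59373566dup",
             outcome = rep(c("termination of pregnancy",
                             "continued gestation", "failure to follow-up"),
                           c(3, 2, 14)))
  xyy$karyotype[1:14] <- c(expand_karyotypes(kt$sex, "Jacob"),
                           expand_karyotypes(kt$sex, "Superman"))
  xyy$karyotype_class[!is.na(xyy$karyotype)] <- "sex"
  out$xyy <- xyy

  xxx <- blk(15, category = "sex_chromosome_aneuploidy", label = "47,XXX",
             iscn = "dup(X)(p22.33q28)", g = "chrX:g.1_155270560dup",
             outcome = "failure to follow-up")
  xxx$karyotype[1:12] <- expand_karyotypes(kt$sex, "Triple X")
  xxx$karyotype_class[!is.na(xxx$karyotype)] <- "sex"
  out$xxx <- xxx

  # --- rare autosomal aneuploidy: 3 cases (chr7 x1, chr15 x2, all mosaic) -
  out$rare <- blk(3, category = "rare_autosomal_aneuploidy",
                  label = c("trisomy 7", "trisomy 15", "trisomy 15"),
                  mosaic = TRUE,
                  iscn = c("dup(7)(p22.3q36.3)(mos)",
                           "dup(15)(q11.1q26.3)(mos)",
                           "dup(15)(q11.1q26.3)(mos)"),
                  g = c("chr7:g.1_159138663dup",
                        "chr15:g.20700000_102531392dup",
                        "chr15:g.20700000_102531392dup"),
                  outcome = "termination of pregnancy")

  # --- abnormalities on two or more chromosomes: 33 cases -----------------
  multi_sex <- rep(c("XY", "XX"), length.out = 33)
  multi <- blk(33, category = "multiple_chromosome_abnormality",
               label = "multiple (18, 21)",
               iscn = "dup(18)(p11.32q23);dup(21)(q11.2q22.3)",
               g = "chr18:g.1_78077248dup;chr21:g.14300000_48129895dup",
               outcome = "termination of pregnancy")
  multi$karyotype[1:17] <- paste0("48,", multi_sex[1:17], ",+18,+21")
  multi$karyotype_class[1:17] <- "other"
  out$multi <- multi

  # --- pathogenic CNVs: 63 cases ------------------------------------------
  sts_size <- round(seq(0.98e6, 1.70e6, length.out = 24))
  sts_start <- 7000001
  sts <- blk(24, category = "pathogenic_cnv", label = "Xp22.31 (STS)",
             iscn = "del(X)(p22.31)",
             g = sprintf("chrX:g.%d_%ddel", sts_start,
                         sts_start + sts_size - 1),
             size_mb = round_half_up(sts_size / 1e6, 2),
             outcome = "continued gestation")
  sts$karyotype[1] <- "46,XY"       # the single discordant fetus
  sts$karyotype_class[1] <- "normal"
  out$sts <- sts

  chr1_sizes <- c(38.26e6, 7.28e6)
  out$chr1 <- blk(2, category = "pathogenic_cnv", label = "large CNV",
                  iscn = "dup(1)(q21)",
                  g = sprintf("chr1:g.%d_%ddup", 128000001,
                              128000000 + chr1_sizes),
                  size_mb = round_half_up(chr1_sizes / 1e6, 2),
                  karyotype = c("46,XX,dup(1)(q21q31)",
                                "46,XY,dup(1)(q21q25)"),
                  kclass = "other",
                  outcome = "continued gestation")

  big_sizes <- round(seq(1.1e6, 5.5e6, length.out = 37))
  out$pcnv <- blk(37, category = "pathogenic_cnv", label = "large CNV",
                  iscn = "dup(2)(p16)",
                  g = sprintf("chr2:g.%d_%ddup", 40000001,
                              40000000 + big_sizes),
                  size_mb = round_half_up(big_sizes / 1e6, 2),
                  outcome = "continued gestation")

  # --- CNVs of uncertain significance: 31 cases ---------------------------
  vus_sizes <- round(seq(0.3e6, 0.9e6, length.out = 31))
  vus <- blk(31, category = "vus_cnv",
             label = "CNV of uncertain significance",
             iscn = "dup(3)(p14)",
             g = sprintf("chr3:g.%d_%ddup", 50000001,
                         50000000 + vus_sizes),
             size_mb = round_half_up(vus_sizes / 1e6, 2),
             outcome = "continued gestation")
  vus$karyotype[1] <- "92,XXXX"     # tetraploidy, invisible to depth ratios
  vus$karyotype_class[1] <- "tetraploid"
  out$vus <- vus

  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  stopifnot(nrow(cohort) == 424)

  # ages from the published strata (n, mean, sd within band)
  age_strata <- list(c(63, 21.81, 2.18, 16, 24.99),
                     c(102, 27.08, 1.37, 25, 29.99),
                     c(108, 31.85, 1.41, 30, 34.99),
                     c(97, 36.96, 1.46, 35, 39.99),
                     c(49, 41.39, 1.32, 40, 44.99),
                     c(5, 45.8, 1.09, 45, 47))
  cohort$age <- unlist(lapply(age_strata, function(s)
    stratum_values(s[1], s[2], s[3], s[4], s[5])))
  # gestational age: 415 second-trimester, 9 third-trimester cases
  cohort$ga_weeks <- c(stratum_values(415, 19.95, 2.08, 14, 27.99),
                       stratum_values(9, 30.44, 2.00, 28.1, 40))
  cohort$case_id <- sprintf("case%03d", seq_len(nrow(cohort)))
  cohort <- cohort[, c("case_id", "age", "ga_weeks", "category", "label",
                       "mosaic", "call_iscn", "call_g", "cnv_size_mb",
                       "karyotype", "karyotype_class", "outcome")]
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate aneuploidy calls into the region/zone report table
#'
#' Counts the cohort's aneuploidy calls (common, sex-chromosome and rare
#' categories; multi-chromosome cases are reported separately) by their
#' region string and g.-notation coordinates -- the zone report of a CNV
#' screen.
#'
#' @param cohort A [reconstructed_cohort()]-shaped table.
#' @return data.frame `chrom`, `zone`, `location`, `n`, ordered by
#'   chromosome.
#' @export
aneuploidy_zone_table <- function(cohort) {
  aneu <- cohort[cohort$category %in%
                   c("common_autosomal_aneuploidy",
                     "sex_chromosome_aneuploidy",
                     "rare_autosomal_aneuploidy"), , drop = FALSE]
  key <- paste(aneu$call_iscn, aneu$call_g, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(zone = vapply(parts, `[`, character(1), 1),
                    location = vapply(parts, `[`, character(1), 2),
                    n = as.integer(tab), stringsAsFactors = FALSE)
  out$chrom <- vapply(out$zone, function(z) parse_call(z)$chrom, character(1))
  ord <- order(match(out$chrom, c(as.character(1:22), "X", "Y")), -out$n)
  out <- out[ord, c("chrom", "zone", "location", "n")]
  rownames(out) <- NULL
  out
}

#' Detection-rate table
#'
#' Counts and percentages per diagnostic category over an explicit
#' denominator (the full cohort by default). `any_chromosomal_abnormality`
#' covers the four aneuploidy-level categories; copy-number variants are
#' reported separately and split into pathogenic and uncertain.
#' Percentages are rounded half-up to 2 decimals.
#'
#' @param cohort A cohort table with a `category` column.
#' @param denominator Rate denominator, default `nrow(cohort)`.
#' @return data.frame `group`, `count`, `denominator`, `pct`.
#' @export
detection_rates <- function(cohort, denominator = nrow(cohort)) {
  if (!nrow(cohort)) stop("empty cohort")
  cat_n <- function(cats) sum(cohort$category %in% cats)
  groups <- list(
    any_chromosomal_abnormality = c("common_autosomal_aneuploidy",
                                    "sex_chromosome_aneuploidy",
                                    "multiple_chromosome_abnormality",
                                    "rare_autosomal_aneuploidy"),
    common_autosomal_aneuploidy = "common_autosomal_aneuploidy",
    sex_chromosome_aneuploidy = "sex_chromosome_aneuploidy",
    multiple_chromosome_abnormality = "multiple_chromosome_abnormality",
    rare_autosomal_aneuploidy = "rare_autosomal_aneuploidy",
    cnv = c("pathogenic_cnv", "vus_cnv"),
    pathogenic_cnv = "pathogenic_cnv",
    vus_cnv = "vus_cnv",
    normal = "normal")
  count <- vapply(groups, cat_n, numeric(1))
  data.frame(group = names(groups), count = unname(count),
             denominator = denominator,
             pct = round_half_up(100 * unname(count) / denominator, 2),
             stringsAsFactors = FALSE)
}

#' Karyotype-subgroup summary
#'
#' Rates of the G-banding report groups among karyotyped cases
#' (autosomal aneuploidy, sex-chromosome aneuploidy, tetraploidy, other
#' abnormal, normal), using the stored report-group labels.
#'
#' @param cohort A cohort table with `karyotype` / `karyotype_class`.
#' @return data.frame `group`, `count`, `denominator`, `pct`.
#' @export
karyotype_summary <- function(cohort) {
  k <- cohort[!is.na(cohort$karyotype), , drop = FALSE]
  denom <- nrow(k)
  groups <- c("autosomal", "sex", "tetraploid", "other", "normal")
  count <- vapply(groups, function(g) sum(k$karyotype_class == g,
                                          na.rm = TRUE), numeric(1))
  data.frame(group = groups, count = unname(count), denominator = denom,
             pct = round_half_up(100 * unname(count) / denom, 2),
             stringsAsFactors = FALSE)
}

#' Compare sequencing calls with karyotype results
#'
#' Per-case concordance at the whole-chromosome level. Cases without a
#' karyotype are `not_compared`; whole-genome ploidy multiples
#' (e.g. tetraploidy) are `not_compared` with subtype
#' `ploidy_invisible`, since read-depth ratios cannot see them. A normal
#' karyotype facing only sub-karyotype-resolution CNVs (< 5 Mb) is
#' `discordant` with subtype `expected` -- G-banding cannot resolve such
#' events.
#'
#' @param cohort A cohort table.
#' @return data.frame `case_id`, `status`
#'   (concordant/discordant/not_compared), `subtype`.
#' @export
concordance <- function(cohort) {
  status <- character(nrow(cohort)); subtype <- NA_character_
  subtype <- rep(NA_character_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ks <- cohort$karyotype[i]
    if (is.na(ks)) { status[i] <- "not_compared"; subtype[i] <- "no_karyotype"; next }
    k <- parse_karyotype(ks)
    kc <- classify_karyotype(k)
    if (kc == "polyploid") {
      status[i] <- "not_compared"; subtype[i] <- "ploidy_invisible"; next
    }
    cat_i <- cohort$category[i]
    gains <- unlist(lapply(k$lines, `[[`, "gains"))
    has_cnv_tag <- any(grepl("^(dup|del)\\(",
                             unlist(lapply(k$lines, `[[`, "structural"))))
    counts <- vapply(k$lines, `[[`, integer(1), "count")
    ok <- switch(cat_i,
      common_autosomal_aneuploidy = ,
      rare_autosomal_aneuploidy = {
        chrom <- sub("^trisomy ", "", cohort$label[i])
        chrom %in% gains
      },
      multiple_chromosome_abnormality = length(gains) >= 2 ||
        kc %in% c("autosomal_aneuploidy", "sex_aneuploidy"),
      sex_chromosome_aneuploidy = kc == "sex_aneuploidy" ||
        any(counts != 46),
      pathogenic_cnv = ,
      vus_cnv = has_cnv_tag,
      normal = kc == "normal")
    if (isTRUE(ok)) { status[i] <- "concordant"; next }
    status[i] <- "discordant"
    small <- !is.na(cohort$cnv_size_mb[i]) && cohort$cnv_size_mb[i] < 5
    subtype[i] <- if (cat_i %in% c("pathogenic_cnv", "vus_cnv") &&
                        kc == "normal" && small) "expected" else "unexpected"
  }
  data.frame(case_id = cohort$case_id, status = status, subtype = subtype,
             stringsAsFactors = FALSE)
}

#' Demographic stratification (age and gestational age)
#'
#' Reproduces the standard cohort-description table: per-stratum n, mean,
#' SD and median for maternal age (bands 16-24, 25-29, 30-34, 35-39,
#' 40-44, >=45 years) and gestational age (second trimester 14-28 weeks,
#' third trimester > 28 weeks), plus overall rows. SD of a single-case
#' stratum is 0 by convention; ages outside 16-60 are flagged with a
#' warning.
#'
#' @param cohort A cohort table with `age` and `ga_weeks`.
#' @return List of two data.frames, `age` and `ga`, each with columns
#'   `stratum`, `n`, `pct`, `mean`, `sd`, `median`.
#' @export
stratify_demographics <- function(cohort) {
  if (any(cohort$age < 16 | cohort$age > 60))
    warning("age(s) outside the 16-60 screening range flagged")
  n_all <- nrow(cohort)
  strat_table <- function(x, idx_list, labels) {
    rows <- lapply(seq_along(idx_list), function(k) {
      v <- x[idx_list[[k]]]
      data.frame(stratum = labels[k], n = length(v),
                 pct = round_half_up(100 * length(v) / n_all, 2),
                 mean = if (length(v)) round_half_up(mean(v), 2) else NA,
                 sd = if (length(v) > 1) round_half_up(stats::sd(v), 2)
                      else if (length(v) == 1) 0 else NA,
                 median = if (length(v)) round_half_up(stats::median(v), 2)
                          else NA,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  age_breaks <- c(16, 25, 30, 35, 40, 45, Inf)
  age_labels <- c("16-24", "25-29", "30-34", "35-39", "40-44", ">=45")
  age_idx <- lapply(seq_len(6), function(k)
    which(cohort$age >= age_breaks[k] & cohort$age < age_breaks[k + 1]))
  age <- rbind(strat_table(cohort$age, list(seq_len(n_all)), "overall"),
               strat_table(cohort$age, age_idx, age_labels))
  ga_idx <- list(which(cohort$ga_weeks >= 14 & cohort$ga_weeks <= 28),
                 which(cohort$ga_weeks > 28))
  ga <- rbind(strat_table(cohort$ga_weeks, list(seq_len(n_all)), "overall"),
              strat_table(cohort$ga_weeks, ga_idx,
                          c("second-trimester", "third-trimester")))
  list(age = age, ga = ga)
}

#' Outcome-by-category contingency table
#'
#' @param cohort A cohort table whose `outcome` values come from
#'   [outcome_levels()]; unknown outcome strings are rejected.
#' @return Integer matrix category x outcome whose grand total equals the
#'   cohort size.
#' @export
outcome_table <- function(cohort) {
  bad <- setdiff(unique(cohort$outcome), outcome_levels())
  if (length(bad))
    stop("unknown outcome value(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(cohort$category, levels = unique(cohort$category)),
               factor(cohort$outcome, levels = outcome_levels()))
  stopifnot(sum(tab) == nrow(cohort))
  unclass(tab)
}

#' Write / read a cohort table
#' @param cohort A cohort table.
#' @param path File path (TSV).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
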