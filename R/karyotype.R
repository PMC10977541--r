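#' Parse an ISCN karyotype string
#'
#' Handles the notation used in clinical G-banding reports: modal
#' chromosome number, sex-chromosome complement (with `"X0"`/`"XO"`
#' normalized to `"X"`), whole-chromosome gains/losses (`+21`, `-13`),
#' structural tags (Robertsonian `rob(14;21)`, translocation `t(9;15)`,
#' inversion `inv(9)`, satellite/heterochromatin polymorphisms `14ps+`,
#' `1qh+`, markers `+mar`, duplications/deletions `dup(1)(q21q44)`), and
#' mosaic cell lines separated by `/` with optional cell counts in
#' brackets (`[46]`; an empty `[]` records a mosaic of unknown
#' proportions). Whitespace is ignored.
#'
#' @param s Karyotype string, e.g. `"47,XY,+21"` or
#'   `"47,XX,+13[46]/46,XX[26]"`.
#' @return Object of class `"karyotype"`: list with `raw`, `mosaic` flag
#'   and `lines`, a list of per-cell-line records (`count`, `sex`,
#'   `gains`, `losses`, `structural`, `cells`).
#' @examples
#' k <- parse_karyotype("47,XY + 21")
#' k$lines[[1]]$gains  # "21"
#' @export
parse_karyotype <- function(s) {
  if (!is.character(s) || length(s) != 1 || !nzchar(trimws(s)))
    stop("karyotype string must be a non-empty character scalar")
  raw <- s
  s <- gsub("[[:space:]]", "", s)
  line_strs <- strsplit(s, "/", fixed = TRUE)[[1]]
  lines <- lapply(line_strs, parse_karyotype_line, raw = raw)
  structure(list(raw = raw, mosaic = length(lines) > 1, lines = lines),
            class = "karyotype")
}

parse_karyotype_line <- function(ls, raw) {
  cells <- NA_integer_
  m <- regmatches(ls, regexec("\\[([0-9]*)\\]$", ls))[[1]]
  if (length(m)) {
    if (nzchar(m[2])) cells <- as.integer(m[2])
    ls <- sub("\\[[0-9]*\\]$", "", ls)
  }
  # split fused gain tokens ('XY+21', 'inv(9)+21', 'rob(21;21)+21') so '+N'
  # stands alone; leaves 'ps+'/'qh+' suffixes and existing ',+N' untouched
  ls <- gsub("(\\)|[XY0O])\\+(?=[0-9XY])", "\\1,+", ls, perl = TRUE)
  # protect commas inside (...) groups before splitting on token commas
  toks <- character(); buf <- ""; depth <- 0
  for (chr in strsplit(ls, "")[[1]]) {
    if (chr == "(") depth <- depth + 1
    if (chr == ")") depth <- depth - 1
    if (chr == "," && depth == 0) { toks <- c(toks, buf); buf <- "" }
    else buf <- paste0(buf, chr)
  }
  toks <- c(toks, buf)
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2 || !grepl("^[0-9]+$", toks[1]))
    stop("unparseable karyotype line '", ls, "' in: ", raw)
  count <- as.integer(toks[1])
  sex <- toupper(toks[2])
  if (!grepl("^[XY0O]+$", sex))
    stop("unparseable sex complement token '", toks[2], "' in: ", raw)
  sex <- gsub("[0O]", "", gsub("X0|XO", "X", sex))
  if (!nzchar(sex)) sex <- "0"
  gains <- character(); losses <- character(); structural <- character()
  for (tk in toks[-(1:2)]) {
    if (grepl("^\\+(\\d+|X|Y)$", tk)) {
      gains <- c(gains, sub("^\\+", "", tk))
    } else if (grepl("^-(\\d+|X|Y)$", tk)) {
      losses <- c(losses, sub("^-", "", tk))
    } else if (grepl("^\\+?mar$", tk)) {
      structural <- c(structural, "mar")
    } else if (grepl("^rob\\(\\d+;\\d+\\)(\\+\\d+)?$", tk)) {
      # tolerate a fused "+N" after rob(...) (seen as 'rob(21;21) + 21')
      extra <- regmatches(tk, regexec("\\)\\+(\\d+)$", tk))[[1]]
      if (length(extra)) gains <- c(gains, extra[2])
      structural <- c(structural, sub("\\+\\d+$", "", tk))
    } else if (grepl("^t\\([0-9XY;]+\\)$", tk) ||
               grepl("^inv\\([0-9XY]+\\)$", tk) ||
               grepl("^\\d+(ps|qh)\\+$", tk) ||
               grepl("^(dup|del)\\([0-9XY]+\\)\\([^)]*\\)$", tk)) {
      structural <- c(structural, tk)
    } else {
      stop("unparseable karyotype token '", tk, "' in: ", raw)
    }
  }
  list(count = count, sex = sex, cells = cells,
       gains = gains, losses = losses, structural = structural)
}

#' Format a parsed karyotype back to a normalized string
#'
#' Canonical rendering (`"47,XY,+21"`, mosaic lines joined by `/` with
#' their `[cells]` brackets). `parse_karyotype()` composed with
#' `format_karyotype()` is normalization-stable: re-parsing the formatted
#' string recovers identical fields.
#'
#' @param k A [parse_karyotype()] object.
#' @return Normalized karyotype string.
#' @export
format_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  fmt_line <- function(ln) {
    toks <- c(ln$count, ln$sex,
              if (length(ln$gains)) paste0("+", ln$gains),
              if (length(ln$losses)) paste0("-", ln$losses),
              ln$structural)
    out <- paste(toks, collapse = ",")
    if (k$mosaic) out <- paste0(out, "[",
                                if (is.na(ln$cells)) "" else ln$cells, "]")
    out
  }
  paste(vapply(k$lines, fmt_line, character(1)), collapse = "/")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("karyotype:", format_karyotype(x),
      if (x$mosaic) sprintf("(mosaic, %d cell lines)", length(x$lines)) else "",
      "\n")
  invisible(x)
}

#' Classify a parsed karyotype
#'
#' Rule-based grouping used when comparing G-banding results with
#' sequencing calls: `"polyploid"` (tetraploidy and other whole-genome ploidy
#' multiples, invisible to read-depth ratios), `"autosomal_aneuploidy"`
#' (any cell line with an autosomal gain/loss), `"sex_aneuploidy"` (any
#' cell line whose sex complement is not XX/XY), `"structural"`
#' (structural tags only) or `"normal"`.
#'
#' @param k A [parse_karyotype()] object (or string).
#' @return Character class label.
#' @export
classify_karyotype <- function(k) {
  if (is.character(k)) k <- parse_karyotype(k)
  counts <- vapply(k$lines, `[[`, integer(1), "count")
  if (any(counts >= 69 & counts %% 23 == 0)) return("polyploid")
  gains <- unlist(lapply(k$lines, `[[`, "gains"))
  losses <- unlist(lapply(k$lines, `[[`, "losses"))
  auto <- c(gains, losses)
  auto <- auto[!auto %in% c("X", "Y")]
  if (length(auto)) return("autosomal_aneuploidy")
  sexes <- vapply(k$lines, `[[`, character(1), "sex")
  if (any(!sexes %in% c("XX", "XY")) || any(c(gains, losses) %in% c("X", "Y")))
    return("sex_aneuploidy")
  if (length(unlist(lapply(k$lines, `[[`, "structural")))) return("structural")
  "normal"
}
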