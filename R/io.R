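#' Read a bisulfite cytosine coverage table
#'
#' Reads the standard six-column coverage output of bisulfite methylation
#' callers: chromosome, start, end (1-based inclusive, start == end for a
#' single cytosine), methylation percentage, methylated read count,
#' unmethylated read count. The percentage column is ignored in favour of the
#' raw counts.
#'
#' @param path Path to a tab-separated coverage file (no header).
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`
#'   (`"*"` — the coverage format carries no strand), `meth`, `unmeth`,
#'   sorted by (chrom, pos).
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) md_abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      pct = readr::col_double(),
      meth = readr::col_double(),
      unmeth = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      meth = integer(), unmeth = integer()
    ))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    md_abort(sprintf(
      "malformed coverage line %d in %s: expected %s, got %s",
      probs$row[1], path, probs$expected[1], probs$actual[1]
    ), class = "methdmc_parse_error")
  }
  bad <- which(is.na(raw$meth) | is.na(raw$unmeth) | is.na(raw$start) |
                 raw$meth < 0 | raw$unmeth < 0 | raw$start < 1)
  if (length(bad) > 0) {
    md_abort(sprintf(
      "invalid counts/position at line %d of %s (counts must be non-negative, position >= 1)",
      bad[1], path
    ), class = "methdmc_validation_error")
  }
  raw %>%
    dplyr::transmute(
      chrom = .data$chrom,
      pos = as.integer(.data$start),
      strand = "*",
      meth = as.integer(.data$meth),
      unmeth = as.integer(.data$unmeth)
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write a coverage table
#'
#' Inverse of [read_coverage_table()]: writes the six-column coverage format
#' so that reading the file back reproduces the records.
#'
#' @param records Tibble with columns `chrom`, `pos`, `meth`, `unmeth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(records, path) {
  cov <- records$meth + records$unmeth
  pct <- ifelse(cov > 0, 100 * records$meth / cov, 0)
  out <- tibble::tibble(
    chrom = records$chrom, start = records$pos, end = records$pos,
    pct = pct, meth = records$meth, unmeth = records$unmeth
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a SNP table with per-group allele frequencies
#'
#' Accepts either a VCF (alternate-allele frequencies taken from the INFO
#' fields named in `af_fields`) or a headerless four-column TSV
#' (chrom, pos, af_group1, af_group2). A position is retained when its
#' alternate-allele frequency exceeds `min_af` in at least one group —
#' strictly greater, so "more than 10%" keeps 0.1001 but not 0.10.
#'
#' @param path Path to a `.vcf` file or a TSV.
#' @param min_af Allele-frequency threshold in `[0, 1]`; default 0.10.
#' @param af_fields Length-2 character, INFO keys holding the two groups'
#'   alternate-allele frequencies in a VCF (default `c("AFA", "AFB")`). If the
#'   first key is absent a single `AF` field is used for both groups.
#' @return A tibble (`chrom`, `pos`, `af_a`, `af_b`), positions unique and
#'   sorted within chromosome.
#' @export
read_snp_table <- function(path, min_af = 0.10, af_fields = c("AFA", "AFB")) {
  if (!file.exists(path)) md_abort(paste0("file not found: ", path))
  check_range(min_af, 0, 1, "min_af")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("vcf", "gz")) {
    vcf <- tryCatch(
      vcfR::read.vcfR(path, verbose = FALSE),
      error = function(e) md_abort(paste0("unreadable VCF: ", conditionMessage(e)),
                                   class = "methdmc_format_error")
    )
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    af_a <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, af_fields[1])))
    if (all(is.na(af_a))) {
      af_a <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))
      af_b <- af_a
    } else {
      af_b <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, af_fields[2])))
    }
    snp <- tibble::tibble(
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      af_a = af_a, af_b = af_b
    )
  } else {
    snp <- readr::read_tsv(
      path,
      col_names = c("chrom", "pos", "af_a", "af_b"),
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_integer(),
        af_a = readr::col_double(), af_b = readr::col_double()
      ),
      progress = FALSE
    )
  }
  check_range(snp$af_a, 0, 1, "allele frequency (group 1)")
  check_range(snp$af_b, 0, 1, "allele frequency (group 2)")
  snp %>%
    dplyr::filter(
      (!is.na(.data$af_a) & .data$af_a > min_af) |
        (!is.na(.data$af_b) & .data$af_b > min_af)
    ) %>%
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Read a repeat annotation
#'
#' Accepts BED (0-based half-open; repeat name in column 4, class/family in
#' column 7 when present) or RepeatMasker `.out` (1-based inclusive; converted
#' to the internal half-open convention). All intervals are stored 0-based
#' half-open in `start`/`end`.
#'
#' @param path Path to a `.bed` file or a RepeatMasker `.out` file.
#' @return A tibble (`chrom`, `start`, `end`, `class`, `name`).
#' @export
read_repeat_annotation <- function(path) {
  if (!file.exists(path)) md_abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), class = character(), name = character()))
    }
    f <- stringr::str_split_fixed(lines, "\\t| +", 8)
    has_class <- nzchar(f[, 7])
    rep_tbl <- tibble::tibble(
      chrom = f[, 1],
      start = as.integer(f[, 2]),
      end = as.integer(f[, 3]),
      name = ifelse(nzchar(f[, 4]), f[, 4], NA_character_),
      class = ifelse(has_class, f[, 7], f[, 4])
    )
  } else if (ext == "out") {
    rep_tbl <- read_repeatmasker_out(path)
  } else {
    md_abort(paste0("unknown repeat-annotation extension: .", ext),
             class = "methdmc_format_error")
  }
  if (any(is.na(rep_tbl$start) | is.na(rep_tbl$end))) {
    md_abort("unparseable interval coordinates in repeat annotation",
             class = "methdmc_parse_error")
  }
  if (any(rep_tbl$start >= rep_tbl$end)) {
    md_abort("repeat interval with start >= end after normalization",
             class = "methdmc_validation_error")
  }
  if (any(!nzchar(rep_tbl$class) | is.na(rep_tbl$class))) {
    md_abort("empty repeat class label", class = "methdmc_validation_error")
  }
  rep_tbl %>%
    dplyr::select("chrom", "start", "end", "class", "name") %>%
    dplyr::arrange(.data$chrom, .data$start)
}

# RepeatMasker .out: whitespace-delimited, 3 header lines, query coords in
# columns 5-7 (1-based inclusive), repeat name col 10, class/family col 11.
read_repeatmasker_out <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # drop the two header lines + blank; detect by non-numeric first field
  body <- lines[grepl("^\\s*\\d+", lines)]
  if (length(body) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), class = character(), name = character()))
  }
  f <- stringr::str_split_fixed(trimws(body), "\\s+", 12)
  tibble::tibble(
    chrom = f[, 5],
    start = as.integer(f[, 6]) - 1L,  # 1-based inclusive -> 0-based half-open
    end = as.integer(f[, 7]),
    name = f[, 10],
    class = f[, 11]
  )
}

#' Read a set of point positions
#'
#' Reads a reference position list — for example a previously published DMC
#' list — from BED (0-based half-open single-base features, converted to
#' 1-based points) or a headerless two-column TSV (chrom, 1-based pos).
#'
#' @param path Path to a `.bed` or TSV file.
#' @return A tibble (`chrom`, `pos`), unique positions sorted per chromosome.
#' @export
read_position_set <- function(path) {
  if (!file.exists(path)) md_abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer()))
  }
  f <- stringr::str_split_fixed(lines, "\\t| +", 3)
  pos_tbl <- tibble::tibble(
    chrom = f[, 1],
    pos = if (ext == "bed") as.integer(f[, 2]) + 1L else as.integer(f[, 2])
  )
  if (any(is.na(pos_tbl$pos))) {
    md_abort("unparseable position in position set", class = "methdmc_parse_error")
  }
  pos_tbl %>%
    dplyr::distinct(.data$chrom, .data$pos) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}
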