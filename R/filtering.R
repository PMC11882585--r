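#' Build a multi-sample methylation count table
#'
#' Combines per-sample coverage records into one long table over the union of
#' sites. A site absent from a sample receives `(meth, unmeth) = (0, 0)` for
#' that sample.
#'
#' @param records Named list of per-sample record tibbles as returned by
#'   [read_coverage_table()]; names are sample ids.
#' @param sample_sheet Tibble with columns `sample` and `group` assigning each
#'   sample to one of exactly two groups.
#' @return A long tibble with columns `chrom`, `pos`, `strand`, `sample`,
#'   `group`, `meth`, `unmeth`, sorted by (chrom, pos, sample).
#' @export
build_matrix <- function(records, sample_sheet) {
  if (nrow(sample_sheet) == 0) md_abort("empty sample sheet")
  if (anyDuplicated(sample_sheet$sample)) {
    md_abort("duplicate sample id in sample sheet")
  }
  groups <- sort(unique(sample_sheet$group))
  if (length(groups) != 2) {
    md_abort(sprintf("exactly two groups required, found %d", length(groups)))
  }
  missing <- setdiff(sample_sheet$sample, names(records))
  if (length(missing) > 0) {
    md_abort(paste0("sample(s) in sheet with no records: ",
                    paste(missing, collapse = ", ")))
  }
  long <- purrr::imap_dfr(
    records[sample_sheet$sample],
    ~ dplyr::mutate(.x, sample = .y)
  )
  chroms_by_sample <- purrr::map(records[sample_sheet$sample], ~ unique(.x$chrom))
  all_chroms <- unique(unlist(chroms_by_sample))
  shared <- Reduce(intersect, chroms_by_sample)
  if (length(setdiff(all_chroms, shared)) > 0) {
    rlang::warn(paste0("chromosomes not present in every sample: ",
                       paste(setdiff(all_chroms, shared), collapse = ", ")),
                class = "methdmc_chrom_mismatch")
  }
  long %>%
    tidyr::complete(
      tidyr::nesting(chrom, pos, strand),
      sample = sample_sheet$sample,
      fill = list(meth = 0L, unmeth = 0L)
    ) %>%
    dplyr::left_join(sample_sheet, by = "sample") %>%
    dplyr::select("chrom", "pos", "strand", "sample", "group", "meth", "unmeth") %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$sample)
}

#' Filter sites by read coverage
#'
#' Keeps sites whose coverage (`meth + unmeth`) reaches `min_cov` either in
#' every sample (`require_all = TRUE`, the default, matching a
#' "10X in all animals" rule) or in at least one sample.
#'
#' @param mat Long methylation table from [build_matrix()].
#' @param min_cov Minimum coverage (reads); default 10.
#' @param require_all Require the threshold in every sample (default) or in
#'   at least one.
#' @return The filtered long table; counts are unchanged.
#' @export
filter_coverage <- function(mat, min_cov = 10, require_all = TRUE) {
  if (min_cov < 0) md_abort("min_cov must be >= 0")
  keep <- mat %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::summarise(
      .cov_stat = if (require_all) min(.data$meth + .data$unmeth)
                  else max(.data$meth + .data$unmeth),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$.cov_stat >= min_cov) %>%
    dplyr::select(-".cov_stat")
  dplyr::semi_join(mat, keep, by = c("chrom", "pos", "strand"))
}

#' Remove CpG sites overlapping SNP positions
#'
#' Drops sites whose cytosine position equals a SNP position. With
#' `dyad_mode = TRUE`, the guanine position of the CpG dyad is masked as well:
#' a forward-strand cytosine is removed when a SNP sits at `pos + 1`, a
#' reverse-strand cytosine when a SNP sits at `pos - 1` (sites of unknown
#' strand are checked on both sides). The default masks the cytosine position
#' only.
#'
#' @param mat Long methylation table.
#' @param snps SNP tibble (`chrom`, `pos`), already allele-frequency filtered.
#' @param dyad_mode Also mask the paired G position; default `FALSE`.
#' @return The masked long table, with attribute `n_removed` giving the number
#'   of removed sites.
#' @export
mask_snp_positions <- function(mat, snps, dyad_mode = FALSE) {
  snp_keys <- site_key(snps$chrom, snps$pos)
  hit <- site_key(mat$chrom, mat$pos) %in% snp_keys
  if (dyad_mode) {
    fwd <- mat$strand %in% c("+", "*")
    rev <- mat$strand %in% c("-", "*")
    hit <- hit |
      (fwd & site_key(mat$chrom, mat$pos + 1L) %in% snp_keys) |
      (rev & site_key(mat$chrom, mat$pos - 1L) %in% snp_keys)
  }
  n_sites_in <- dplyr::n_distinct(site_key(mat$chrom, mat$pos), mat$strand)
  out <- mat[!hit, , drop = FALSE]
  n_sites_out <- dplyr::n_distinct(site_key(out$chrom, out$pos), out$strand)
  attr(out, "n_removed") <- n_sites_in - n_sites_out
  out
}

#' Distinct sites of a methylation table
#'
#' @param mat Long methylation table.
#' @return Tibble (`chrom`, `pos`, `strand`) of unique sites, sorted.
#' @export
matrix_sites <- function(mat) {
  mat %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}
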