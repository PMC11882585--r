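#' Run the full differential-methylation pipeline
#'
#' Orchestrates every stage from files on disk: read coverage tables and the
#' sample sheet, apply the coverage-in-all-samples filter and SNP masking,
#' call DMCs, draw the k random control subsets, run proximity enrichment
#' against SNPs (and any reference position sets), stretch analysis, repeat
#' enrichment, high-confidence selection, and sample-level QC. All result
#' tables and a reproducibility manifest (parameters, seed, per-stage site
#' counts, input/output MD5 checksums — no timestamps, so identical runs are
#' byte-identical) are written under `out_dir`.
#'
#' @param input_dir Directory holding `sample_sheet.tsv` (columns `sample`,
#'   `group`, `file`), the coverage files it names, `snps.vcf` and
#'   `repeats.bed` (as produced by [emit_files()]).
#' @param out_dir Output directory (created).
#' @param min_cov,require_all Coverage filter (default 10X in all samples).
#' @param min_af SNP allele-frequency threshold; default 0.10.
#' @param mask_dyad Mask the full CpG dyad; default `FALSE`.
#' @param fdr FDR threshold for DMC calling; default 0.05.
#' @param k Number of control subsets; default 10.
#' @param thresholds Proximity thresholds in bp; default `c(2, 10, 100, 2000)`.
#' @param max_gap,min_sites Stretch definition; defaults 2000 bp, 2 sites.
#' @param min_delta,min_snp_dist High-confidence selection; defaults 0.20
#'   and 100 bp.
#' @param ref_sets Optional named character vector of reference position-set
#'   paths (BED/TSV), each analysed like the SNP proximity stage.
#' @param seed Master seed for the subset draws.
#' @return Invisibly, a list with all stage results plus the `manifest`.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         min_cov = 10, require_all = TRUE,
                         min_af = 0.10, mask_dyad = FALSE,
                         fdr = 0.05, k = 10,
                         thresholds = c(2, 10, 100, 2000),
                         max_gap = 2000, min_sites = 2,
                         min_delta = 0.20, min_snp_dist = 100,
                         ref_sets = NULL, seed = 1) {
  if (k < 2) md_abort("k must be >= 2 (subset t-test undefined otherwise)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet_path <- file.path(input_dir, "sample_sheet.tsv")
  sheet <- readr::read_tsv(sheet_path, col_types = readr::cols(), progress = FALSE)
  records <- stats::setNames(
    purrr::map(file.path(input_dir, sheet$file), read_coverage_table),
    sheet$sample
  )
  snps <- read_snp_table(file.path(input_dir, "snps.vcf"), min_af = min_af)
  repeats <- read_repeat_annotation(file.path(input_dir, "repeats.bed"))

  mat <- build_matrix(records, sheet[c("sample", "group")])
  n_sites_union <- nrow(matrix_sites(mat))
  mat_cov <- filter_coverage(mat, min_cov = min_cov, require_all = require_all)
  n_sites_cov <- nrow(matrix_sites(mat_cov))
  mat_clean <- mask_snp_positions(mat_cov, snps, dyad_mode = mask_dyad)
  n_sites_clean <- nrow(matrix_sites(mat_clean))
  stopifnot(n_sites_cov <= n_sites_union, n_sites_clean <= n_sites_cov)

  dmc <- call_dmcs(mat_clean, fdr_threshold = fdr)
  dmc_sites <- dplyr::filter(tibble::as_tibble(dmc), .data$is_dmc)[
    c("chrom", "pos")]
  universe <- dplyr::filter(tibble::as_tibble(dmc), !.data$is_dmc)[
    c("chrom", "pos")]

  results <- list(
    dmc_table = dmc,
    high_confidence = select_high_confidence(dmc, snps,
                                             min_delta = min_delta,
                                             min_snp_dist = min_snp_dist),
    qc = global_methylation_stats(mat_clean),
    pca = pca_samples(mat_clean)
  )

  if (nrow(dmc_sites) >= 2 && nrow(universe) >= nrow(dmc_sites)) {
    subsets <- draw_subsets(universe, n = nrow(dmc_sites), k = k, seed = seed)
    # invariant: control subsets never contain a DMC
    stopifnot(!any(site_key(subsets$chrom, subsets$pos) %in%
                     site_key(dmc_sites$chrom, dmc_sites$pos)))
    results$subsets <- subsets
    results$proximity_snps <- proximity_enrichment(dmc_sites, subsets,
                                                   snps, thresholds)
    if (!is.null(ref_sets)) {
      results$proximity_refs <- purrr::imap(ref_sets, function(path, nm) {
        proximity_enrichment(dmc_sites, subsets, read_position_set(path),
                             thresholds)
      })
    }
    results$stretch <- stretch_enrichment(dmc_sites, subsets,
                                          max_gap = max_gap,
                                          min_sites = min_sites)
    results$repeat_enrichment <- class_enrichment(dmc_sites, subsets, repeats)
  } else {
    rlang::inform("fewer than 2 DMCs: enrichment stages skipped")
  }

  written <- write_pipeline_outputs(results, out_dir)
  input_files <- c(sheet_path, file.path(input_dir, sheet$file),
                   file.path(input_dir, c("snps.vcf", "repeats.bed")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("methdmc")),
    parameters = list(
      min_cov = min_cov, require_all = require_all, min_af = min_af,
      mask_dyad = mask_dyad, fdr = fdr, k = k, thresholds = thresholds,
      max_gap = max_gap, min_sites = min_sites, min_delta = min_delta,
      min_snp_dist = min_snp_dist, seed = seed
    ),
    counts = list(
      n_snps = nrow(snps),
      n_sites_union = n_sites_union,
      n_sites_after_coverage = n_sites_cov,
      n_sites_after_masking = n_sites_clean,
      n_tested = nrow(dmc),
      n_dmc = nrow(dmc_sites),
      n_high_confidence = nrow(results$high_confidence)
    ),
    input_md5 = as.list(stats::setNames(tools::md5sum(input_files),
                                        basename(input_files))),
    output_md5 = as.list(stats::setNames(tools::md5sum(written),
                                         basename(written)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# Serialize stage results as TSV under out_dir; returns written paths.
write_pipeline_outputs <- function(results, out_dir) {
  written <- character(0)
  put <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    written <<- c(written, p)
  }
  put(tibble::as_tibble(results$dmc_table), "dmc_table.tsv")
  put(results$high_confidence, "high_confidence.tsv")
  put(results$qc$per_sample, "qc_per_sample.tsv")
  put(results$qc$overall, "qc_overall.tsv")
  put(results$pca$scores, "pca_scores.tsv")
  if (!is.null(results$subsets)) {
    put(tibble::as_tibble(results$subsets), "subsets.tsv")
    put(flatten_enrich(results$proximity_snps), "proximity_snps.tsv")
    if (!is.null(results$proximity_refs)) {
      for (nm in names(results$proximity_refs)) {
        put(flatten_enrich(results$proximity_refs[[nm]]),
            paste0("proximity_", nm, ".tsv"))
      }
    }
    put(flatten_enrich(results$stretch$enrichment), "stretch_enrichment.tsv")
    put(results$stretch$distance_classes, "distance_classes.tsv")
    st <- results$stretch$dmc_stretches
    put(dplyr::select(st, -"positions"), "dmc_stretches.tsv")
    # stretch BED: 0-based half-open, name = member count
    bed <- sprintf("%s\t%d\t%d\t%d", st$chrom, st$start - 1L, st$end, st$n_sites)
    bed_path <- file.path(out_dir, "dmc_stretches.bed")
    writeLines(bed, bed_path)
    written <- c(written, bed_path)
    put(flatten_enrich(results$repeat_enrichment), "repeat_enrichment.tsv")
  }
  written
}

# Expand the subset_values list column into subset_1..subset_k columns.
flatten_enrich <- function(x) {
  tbl <- tibble::as_tibble(x)
  k <- if (nrow(tbl)) length(tbl$subset_values[[1]]) else 0
  sv <- if (k > 0) {
    m <- do.call(rbind, tbl$subset_values)
    colnames(m) <- paste0("subset_", seq_len(k))
    tibble::as_tibble(m)
  } else {
    NULL
  }
  out <- dplyr::select(tbl, -"subset_values")
  if (!is.null(sv)) out <- dplyr::bind_cols(out, sv)
  out
}
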