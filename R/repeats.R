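#' Count site overlaps per repeat class
#'
#' A 1-based site overlaps a half-open repeat interval `[start, end)` when
#' `start < pos < end` (the package's boundary convention: a position equal
#' to either stored bound is not counted). A site inside repeats of several
#' classes increments every such class; within one class a site counts once.
#'
#' @param query Tibble (`chrom`, `pos`) of sites.
#' @param repeats Repeat annotation tibble from [read_repeat_annotation()].
#' @return Tibble (`class`, `count`, `fraction`), one row per repeat class
#'   present in the annotation; `fraction` is `count / nrow(query)`.
#' @export
overlap_by_class <- function(query, repeats) {
  classes <- sort(unique(repeats$class))
  if (length(classes) == 0 || nrow(query) == 0) {
    return(tibble::tibble(class = classes,
                          count = integer(length(classes)),
                          fraction = numeric(length(classes))))
  }
  counts <- vapply(classes, function(cl) {
    r <- repeats[repeats$class == cl, , drop = FALSE]
    sum(sites_in_intervals(query, r))
  }, integer(1))
  tibble::tibble(class = classes, count = unname(counts),
                 fraction = unname(counts) / nrow(query))
}

# Logical: does each query site fall strictly inside some interval?
# Merges intervals per chromosome, then stabs with findInterval.
sites_in_intervals <- function(query, intervals) {
  hit <- rep(FALSE, nrow(query))
  by_chr <- split(intervals, intervals$chrom)
  for (chr in intersect(names(by_chr), unique(query$chrom))) {
    iv <- by_chr[[chr]]
    # strict interior in 1-based coordinates: pos in [start + 1, end - 1]
    lo <- iv$start + 1L
    hi <- iv$end - 1L
    keep <- lo <= hi
    lo <- lo[keep]; hi <- hi[keep]
    if (length(lo) == 0) next
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    # merge overlapping/adjacent closed intervals
    merged_hi <- cummax(hi)
    new_block <- c(TRUE, lo[-1] > merged_hi[-length(hi)] + 1L)
    block <- cumsum(new_block)
    mlo <- tapply(lo, block, min)
    mhi <- tapply(merged_hi, block, max)
    qi <- which(query$chrom == chr)
    q <- query$pos[qi]
    j <- findInterval(q, mlo)
    hit[qi] <- j >= 1 & q <= mhi[pmax(j, 1)]
  }
  hit
}

#' Repeat-class enrichment of DMCs versus control subsets
#'
#' Per repeat class, compares the number of DMCs overlapping that class to
#' the counts in the k control subsets ([subset_ttest()]), with
#' Benjamini-Hochberg correction across classes. `direction` is
#' `"enriched"` when the observed count exceeds the subset mean,
#' `"depleted"` otherwise.
#'
#' @param dmc_sites Tibble (`chrom`, `pos`).
#' @param subsets A `subset_collection`.
#' @param repeats Repeat annotation tibble.
#' @param var_adjust Passed to [subset_ttest()].
#' @return An `enrich_tbl` tibble, one row per class: `class`, `observed`
#'   (DMC count), `subset_mean`, `subset_sd`, `statistic`, `df`, `p_value`,
#'   `q_value`, `direction`, `subset_values` (list column of the k counts).
#'   Empty annotation gives an empty report.
#' @export
class_enrichment <- function(dmc_sites, subsets, repeats, var_adjust = TRUE) {
  classes <- sort(unique(repeats$class))
  if (length(classes) == 0) {
    out <- tibble::tibble(
      class = character(), observed = integer(),
      subset_mean = double(), subset_sd = double(),
      statistic = double(), df = double(), p_value = double(),
      q_value = double(), direction = character(), subset_values = list()
    )
    return(new_enrich_tbl(out, kind = "repeat", key = "class"))
  }
  obs <- overlap_by_class(dmc_sites, repeats)
  sub_tbl <- tibble::as_tibble(subsets)
  sub_counts <- purrr::imap_dfr(split(sub_tbl, sub_tbl$subset), function(s, i) {
    dplyr::mutate(overlap_by_class(s, repeats), subset = as.integer(i))
  })
  out <- purrr::map_dfr(classes, function(cl) {
    sv <- sub_counts$count[sub_counts$class == cl]
    o <- obs$count[obs$class == cl]
    tt <- subset_ttest(as.numeric(sv), as.numeric(o), var_adjust = var_adjust)
    tibble::tibble(
      class = cl, observed = o,
      subset_mean = tt$subset_mean, subset_sd = tt$subset_sd,
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
      subset_values = list(as.numeric(sv))
    )
  })
  out <- out %>%
    dplyr::mutate(
      q_value = bh_fdr(.data$p_value),
      direction = ifelse(.data$observed > .data$subset_mean,
                         "enriched", "depleted")
    ) %>%
    dplyr::relocate("q_value", "direction", .after = "p_value")
  new_enrich_tbl(out, kind = "repeat", key = "class")
}
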