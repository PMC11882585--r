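#' Classify distances to the next CpG
#'
#' For every site except the last on each chromosome, the distance to the
#' next site is classified into `=1 bp` (a CpG dyad pair on opposite
#' strands), `2..max_gap bp`, and `> max_gap bp`.
#'
#' @param sites Tibble (`chrom`, `pos`); strands pooled.
#' @param max_gap Upper bound of the middle class in bp; default 2000.
#' @return Tibble (`class`, `count`, `fraction`); fractions over all
#'   next-distances (all zero counts when no chromosome has two sites).
#' @export
next_distance_classes <- function(sites, max_gap = 2000) {
  s <- dplyr::arrange(sites, .data$chrom, .data$pos)
  d <- unlist(lapply(split(s$pos, s$chrom), diff), use.names = FALSE)
  labels <- c("1bp", paste0("2-", max_gap, "bp"), paste0(">", max_gap, "bp"))
  counts <- c(sum(d == 1), sum(d >= 2 & d <= max_gap), sum(d > max_gap))
  tibble::tibble(
    class = factor(labels, levels = labels),
    count = counts,
    fraction = if (length(d) > 0) counts / length(d) else rep(0, 3)
  )
}

#' Find CpG stretches
#'
#' A stretch is a maximal run of at least `min_sites` sites on one chromosome
#' in which every consecutive gap is at most `max_gap` bp. Detected by a
#' single greedy pass over the sorted positions; strands are pooled.
#'
#' @param sites Tibble (`chrom`, `pos`).
#' @param max_gap Maximum gap between consecutive members in bp; default 2000.
#' @param min_sites Minimum member count; default 2.
#' @return Tibble, one row per stretch: `chrom`, `start`, `end`, `n_sites`,
#'   `span` (= end - start + 1), and member positions in the list column
#'   `positions`.
#' @export
find_stretches <- function(sites, max_gap = 2000, min_sites = 2) {
  if (max_gap < 1) md_abort("max_gap must be >= 1")
  if (min_sites < 2) md_abort("min_sites must be >= 2")
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    n_sites = integer(), span = integer(), positions = list()
  )
  if (nrow(sites) == 0) return(empty)
  runs <- sites %>%
    dplyr::distinct(.data$chrom, .data$pos) %>%
    dplyr::arrange(.data$chrom, .data$pos) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(.run = cumsum(c(TRUE, diff(.data$pos) > max_gap))) %>%
    dplyr::group_by(.data$chrom, .data$.run) %>%
    dplyr::filter(dplyr::n() >= min_sites)
  if (nrow(runs) == 0) return(empty)
  runs %>%
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_sites = dplyr::n(), span = max(.data$pos) - min(.data$pos) + 1L,
      positions = list(.data$pos),
      .groups = "drop"
    ) %>%
    dplyr::select(-".run") %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Stretch enrichment of DMCs versus control subsets
#'
#' The statistic is the number (and fraction) of sites belonging to some
#' stretch, computed within the DMC set and within each control subset, and
#' compared with [subset_ttest()]. Next-CpG distance-class fractions are also
#' reported per set.
#'
#' @param dmc_sites Tibble (`chrom`, `pos`) of DMC positions.
#' @param subsets A `subset_collection`.
#' @param max_gap,min_sites Stretch definition, see [find_stretches()].
#' @param var_adjust Passed to [subset_ttest()].
#' @return A list with components `enrichment` (an `enrich_tbl`, one row,
#'   statistic = in-stretch fraction), `dmc_stretches` (the stretch table for
#'   the DMCs), and `distance_classes` (per-set next-distance class
#'   fractions, `set` = "DMC" or "subset <i>").
#' @export
stretch_enrichment <- function(dmc_sites, subsets, max_gap = 2000,
                               min_sites = 2, var_adjust = TRUE) {
  in_stretch_frac <- function(s) {
    if (nrow(s) == 0) return(0)
    st <- find_stretches(s, max_gap, min_sites)
    sum(st$n_sites) / nrow(dplyr::distinct(s, .data$chrom, .data$pos))
  }
  obs <- in_stretch_frac(dmc_sites)
  sub_tbl <- tibble::as_tibble(subsets)
  sv <- vapply(split(sub_tbl, sub_tbl$subset), in_stretch_frac, numeric(1))
  tt <- subset_ttest(unname(sv), obs, var_adjust = var_adjust)
  enr <- new_enrich_tbl(
    tibble::tibble(
      statistic_name = "in_stretch_fraction",
      observed = obs,
      subset_mean = tt$subset_mean, subset_sd = tt$subset_sd,
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
      subset_values = list(unname(sv))
    ),
    kind = "stretch", key = "statistic_name"
  )
  classes <- dplyr::bind_rows(
    dplyr::mutate(next_distance_classes(dmc_sites, max_gap), set = "DMC"),
    purrr::imap_dfr(split(sub_tbl, sub_tbl$subset), function(s, i) {
      dplyr::mutate(next_distance_classes(s, max_gap),
                    set = paste("subset", i))
    })
  )
  list(
    enrichment = enr,
    dmc_stretches = find_stretches(dmc_sites, max_gap, min_sites),
    distance_classes = classes
  )
}
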