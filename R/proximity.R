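#' Distance to the nearest feature
#'
#' For each query site, the minimum absolute distance (bp) to any feature
#' position on the same chromosome; `Inf` when the chromosome carries no
#' features. Computed by a linear-time merge over the sorted feature list.
#' Distances are strand-agnostic.
#'
#' @param query Tibble (`chrom`, `pos`) of query sites (any order).
#' @param features Tibble (`chrom`, `pos`) of point features.
#' @return Numeric vector of distances, in the row order of `query`.
#' @export
nearest_distance <- function(query, features) {
  if (nrow(query) == 0) return(numeric(0))
  out <- rep(Inf, nrow(query))
  feats <- split(features$pos, features$chrom)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    f <- feats[[chr]]
    if (is.null(f) || length(f) == 0) next
    f <- sort(f)
    q <- query$pos[qi]
    i <- findInterval(q, f)
    left <- ifelse(i >= 1, q - f[pmax(i, 1)], Inf)
    right <- ifelse(i < length(f), f[pmin(i + 1, length(f))] - q, Inf)
    out[qi] <- pmin(left, right)
  }
  out
}

#' Cumulative proximity bins
#'
#' Fraction of query sites whose nearest-feature distance is less than or
#' equal to each threshold ("up to t bp" is inclusive). Infinite distances
#' (chromosomes without features) never count toward any bin; the
#' denominator is always the full number of query sites.
#'
#' @param distances Numeric distances, e.g. from [nearest_distance()].
#' @param thresholds Strictly increasing thresholds in bp;
#'   default `c(2, 10, 100, 2000)`.
#' @return Tibble (`threshold_bp`, `fraction`); fractions are monotone
#'   non-decreasing across thresholds.
#' @export
bin_cumulative <- function(distances, thresholds = c(2, 10, 100, 2000)) {
  if (length(distances) == 0) md_abort("empty query: fractions undefined")
  if (any(diff(thresholds) <= 0)) md_abort("thresholds must be strictly increasing")
  tibble::tibble(
    threshold_bp = thresholds,
    fraction = vapply(thresholds,
                      function(t) mean(is.finite(distances) & distances <= t),
                      numeric(1))
  )
}

#' Proximity enrichment of DMCs versus control subsets
#'
#' For each cumulative distance threshold, compares the fraction of DMCs
#' falling within that distance of a feature (SNPs, or a reference DMC list)
#' to the fractions observed in the k random control subsets, using
#' [subset_ttest()].
#'
#' @param dmc_sites Tibble (`chrom`, `pos`) of DMC positions.
#' @param subsets A `subset_collection` from [draw_subsets()].
#' @param features Tibble (`chrom`, `pos`) of point features.
#' @param thresholds Cumulative thresholds in bp; default `c(2, 10, 100, 2000)`.
#' @param var_adjust Passed to [subset_ttest()].
#' @return An `enrich_tbl` tibble, one row per threshold: `threshold_bp`,
#'   `observed` (DMC fraction), `subset_mean`, `subset_sd`, `statistic`,
#'   `df`, `p_value`, and the raw per-subset fractions in the list column
#'   `subset_values`.
#' @export
proximity_enrichment <- function(dmc_sites, subsets, features,
                                 thresholds = c(2, 10, 100, 2000),
                                 var_adjust = TRUE) {
  obs <- bin_cumulative(nearest_distance(dmc_sites, features), thresholds)
  sub_fracs <- subsets %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$subset) %>%
    dplyr::reframe(bin_cumulative(nearest_distance(dplyr::pick(dplyr::everything()),
                                                   features), thresholds))
  out <- purrr::map_dfr(seq_along(thresholds), function(j) {
    t <- thresholds[j]
    sv <- sub_fracs$fraction[sub_fracs$threshold_bp == t]
    tt <- subset_ttest(sv, obs$fraction[j], var_adjust = var_adjust)
    tibble::tibble(
      threshold_bp = t,
      observed = obs$fraction[j],
      subset_mean = tt$subset_mean, subset_sd = tt$subset_sd,
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
      subset_values = list(sv)
    )
  })
  stopifnot(!is.unsorted(out$observed))  # cumulative bins are monotone
  new_enrich_tbl(out, kind = "proximity", key = "threshold_bp")
}

new_enrich_tbl <- function(x, kind, key) {
  structure(x, kind = kind, key = key,
            class = c("enrich_tbl", class(tibble::tibble())))
}

#' @exportS3Method generics::tidy
tidy.enrich_tbl <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::mutate(subset = list(seq_along(.data$subset_values[[1]]))) %>%
    tidyr::unnest(c("subset", "subset_values")) %>%
    dplyr::rename(subset_value = "subset_values")
}

#' @exportS3Method generics::glance
glance.enrich_tbl <- function(x, ...) {
  tibble::tibble(
    kind = attr(x, "kind"),
    n_bins = nrow(x),
    k = length(x$subset_values[[1]]),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}
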