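#' Pool replicate counts within developmental stages
#'
#' Sums methylated/unmethylated counts site-wise across the replicates of
#' each stage; the site universe is the union over replicates (a site absent
#' from a replicate contributes (0, 0)).
#'
#' @param mat Long count table with columns `chrom`, `pos`, `sample`,
#'   `meth`, `unmeth` (e.g. from [build_matrix()] run on replicate records,
#'   or assembled directly).
#' @param stage_sheet Tibble (`sample`, `stage`) mapping each replicate to
#'   its stage; every stage needs at least one replicate.
#' @return Long tibble (`chrom`, `pos`, `stage`, `meth`, `unmeth`,
#'   `fraction`), `fraction = meth / (meth + unmeth)` (NA at zero coverage).
#' @export
pool_replicates <- function(mat, stage_sheet) {
  if (nrow(stage_sheet) == 0) md_abort("empty stage sheet")
  missing <- setdiff(stage_sheet$sample, unique(mat$sample))
  if (length(missing) > 0) {
    md_abort(paste0("stage sheet sample(s) with no records: ",
                    paste(missing, collapse = ", ")))
  }
  mat %>%
    dplyr::inner_join(stage_sheet, by = "sample") %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$stage) %>%
    dplyr::summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                     .groups = "drop") %>%
    tidyr::complete(
      tidyr::nesting(chrom, pos),
      stage = unique(stage_sheet$stage),
      fill = list(meth = 0L, unmeth = 0L)
    ) %>%
    dplyr::mutate(
      fraction = ifelse(.data$meth + .data$unmeth > 0,
                        .data$meth / (.data$meth + .data$unmeth), NA_real_)
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$stage)
}

#' Project DMC sites onto stage profiles with a coverage filter
#'
#' Restricts pooled stage profiles to the given sites and keeps a site only
#' when its pooled coverage reaches `min_cov` in every stage.
#'
#' @param profiles Pooled profiles from [pool_replicates()].
#' @param sites Tibble (`chrom`, `pos`) — normally DMC positions.
#' @param min_cov Minimum pooled coverage per stage; default 5.
#' @return Wide tibble: `chrom`, `pos`, one methylation-fraction column per
#'   stage.
#' @export
stage_filter <- function(profiles, sites, min_cov = 5) {
  if (min_cov < 1) md_abort("min_cov must be >= 1")
  profiles %>%
    dplyr::semi_join(sites, by = c("chrom", "pos")) %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::filter(min(.data$meth + .data$unmeth) >= min_cov) %>%
    dplyr::ungroup() %>%
    dplyr::select("chrom", "pos", "stage", "fraction") %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "fraction") %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Hierarchically cluster methylation profiles
#'
#' Clusters the numeric profile columns of a site-by-profile table using
#' `1 - Pearson correlation` (over pairwise-complete sites) and average
#' linkage by default. Columns constant across sites have no defined
#' correlation and are dropped with a warning.
#'
#' @param fractions Tibble with site columns (`chrom`, `pos`) and one numeric
#'   column per profile (stages, optionally external samples).
#' @param method Distance: `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()];
#'   default `"average"`.
#' @return A `stage_clust` list: `hclust` (the tree), `newick` (serialized),
#'   `order` (leaf labels in dendrogram order), `dropped` (removed columns).
#' @export
hierarchical_cluster <- function(fractions, method = c("correlation", "euclidean"),
                                 linkage = "average") {
  method <- match.arg(method)
  num_cols <- names(fractions)[vapply(fractions, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("pos", "start", "end"))
  m <- as.matrix(fractions[num_cols])
  if (nrow(m) < 2) md_abort("at least 2 sites required for clustering")
  const <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE)) == 0
  const[is.na(const)] <- TRUE
  dropped <- colnames(m)[const]
  if (length(dropped) > 0) {
    rlang::warn(paste0("constant profile column(s) dropped: ",
                       paste(dropped, collapse = ", ")),
                class = "methdmc_constant_profile")
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 2) md_abort("at least 2 non-constant profiles required")
  d <- if (method == "correlation") {
    stats::as.dist(1 - stats::cor(m, use = "pairwise.complete.obs"))
  } else {
    stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(
      hclust = hc,
      newick = ape::write.tree(ape::as.phylo(hc)),
      order = hc$labels[hc$order],
      dropped = dropped
    ),
    class = "stage_clust"
  )
}

#' @export
print.stage_clust <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$hclust$labels), "profiles\n")
  cat("Leaf order:", paste(x$order, collapse = ", "), "\n")
  cat("Newick:", x$newick, "\n")
  invisible(x)
}

#' @export
plot.stage_clust <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}
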