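#' Global methylation summary
#'
#' Per-sample and overall descriptive statistics of a methylation table:
#' the mean methylation fraction over covered sites, and the fraction of
#' sites called "methylated", i.e. whose pooled (all-sample) methylation
#' fraction is at least `meth_call_threshold`.
#'
#' @param mat Long methylation table.
#' @param meth_call_threshold Site-level pooled fraction at or above which a
#'   site counts as methylated; default 0.5.
#' @return List with `per_sample` (tibble: `sample`, `group`,
#'   `mean_fraction`, `mean_coverage`) and `overall` (one-row tibble:
#'   `n_sites`, `n_samples`, `mean_fraction`, `methylated_fraction`).
#' @export
global_methylation_stats <- function(mat, meth_call_threshold = 0.5) {
  if (nrow(mat) == 0) md_abort("empty methylation table")
  check_range(meth_call_threshold, 0, 1, "meth_call_threshold")
  per_sample <- mat %>%
    dplyr::group_by(.data$sample, .data$group) %>%
    dplyr::summarise(
      mean_fraction = mean((.data$meth / (.data$meth + .data$unmeth))[
        .data$meth + .data$unmeth > 0]),
      mean_coverage = mean(.data$meth + .data$unmeth),
      .groups = "drop"
    )
  site_pooled <- mat %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                     .groups = "drop") %>%
    dplyr::filter(.data$meth + .data$unmeth > 0) %>%
    dplyr::mutate(fraction = .data$meth / (.data$meth + .data$unmeth))
  overall <- tibble::tibble(
    n_sites = nrow(site_pooled),
    n_samples = dplyr::n_distinct(mat$sample),
    mean_fraction = mean(site_pooled$fraction),
    methylated_fraction = mean(site_pooled$fraction >= meth_call_threshold)
  )
  list(per_sample = per_sample, overall = overall)
}

#' Principal component analysis of samples
#'
#' PCA of samples in methylation-fraction space: per-site per-sample
#' fractions, centered per site, no unit-variance scaling. Component signs
#' follow a deterministic convention (the largest-magnitude site loading of
#' each component is positive).
#'
#' @param mat Long methylation table; at least 3 samples; sites must be
#'   covered in every sample (guaranteed after an all-sample coverage
#'   filter) — sites with any zero-coverage sample are excluded.
#' @return A `meth_pca` list: `scores` (tibble: `sample`, `group`, `PC1`,
#'   `PC2`, ...), `var_explained` (fraction per component, non-increasing),
#'   `n_sites`.
#' @export
pca_samples <- function(mat) {
  samples <- unique(mat$sample)
  if (length(samples) < 3) md_abort("at least 3 samples required for PCA")
  wide <- mat %>%
    dplyr::mutate(
      fraction = ifelse(.data$meth + .data$unmeth > 0,
                        .data$meth / (.data$meth + .data$unmeth), NA_real_)
    ) %>%
    dplyr::select("chrom", "pos", "strand", "sample", "fraction") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "fraction") %>%
    dplyr::filter(dplyr::if_all(dplyr::all_of(samples), ~ !is.na(.x)))
  x <- t(as.matrix(wide[samples]))  # samples x sites
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (total_var < .Machine$double.eps) {
    pc$x[] <- 0
    pc$sdev[] <- 0
  }
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  groups <- mat %>% dplyr::distinct(.data$sample, .data$group)
  scores <- tibble::as_tibble(pc$x, rownames = "sample") %>%
    dplyr::left_join(groups, by = "sample") %>%
    dplyr::relocate("group", .after = "sample")
  structure(
    list(
      scores = scores,
      var_explained = if (total_var < .Machine$double.eps) {
        rep(0, length(pc$sdev))
      } else {
        pc$sdev^2 / total_var
      },
      n_sites = ncol(x)
    ),
    class = "meth_pca"
  )
}

#' @exportS3Method generics::tidy
tidy.meth_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.meth_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_sites = x$n_sites,
    pc1_var = x$var_explained[1],
    pc2_var = x$var_explained[2]
  )
}
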