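#' Per-site two-group differential methylation test
#'
#' Tests whether the methylation proportion differs between two groups at one
#' CpG, using the likelihood-ratio test (1 df) of the group coefficient in a
#' binomial logistic regression of methylation state on group. On pooled
#' per-group counts this is exactly the G-test of independence on the 2x2
#' table of (methylated, unmethylated) x (group A, group B):
#' \deqn{G = 2 \sum_{cells} O \log(O/E), \quad p = P(\chi^2_1 \ge G).}
#'
#' @param counts_a,counts_b Length-2 numeric vectors `c(meth, unmeth)` of
#'   pooled counts for each group.
#' @return One-row tibble with `statistic` (G), `df` and `p_value`.
#' @examples
#' site_test(c(90, 10), c(10, 90))
#' @export
site_test <- function(counts_a, counts_b) {
  if (length(counts_a) != 2 || length(counts_b) != 2) {
    md_abort("counts_a and counts_b must each be c(meth, unmeth)")
  }
  if (any(c(counts_a, counts_b) < 0)) md_abort("counts must be non-negative")
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    md_abort("zero total reads in a group: test undefined",
             class = "methdmc_zero_coverage")
  }
  g <- g_statistic(counts_a[1], counts_a[2], counts_b[1], counts_b[2])
  tibble::tibble(
    statistic = g, df = 1,
    p_value = stats::pchisq(g, df = 1, lower.tail = FALSE)
  )
}

# Vectorized G statistic for 2x2 tables [ma ua; mb ub].
# Cells with O = 0 contribute 0 (lim x->0 of x log x).
g_statistic <- function(ma, ua, mb, ub) {
  na_ <- ma + ua
  nb_ <- mb + ub
  n <- na_ + nb_
  m <- ma + mb
  u <- ua + ub
  term <- function(o, e) {
    out <- rep(0, length(o))
    pos <- o > 0 & e > 0
    out[pos] <- o[pos] * log(o[pos] / e[pos])
    out
  }
  g <- 2 * (term(ma, na_ * m / n) + term(ua, na_ * u / n) +
              term(mb, nb_ * m / n) + term(ub, nb_ * u / n))
  pmax(g, 0)  # clamp tiny negative rounding
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement
#' (a thin validated wrapper around [stats::p.adjust()]); input order is
#' preserved in the output.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  check_range(p[!is.na(p)], 0, 1, "p-value")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated cytosines
#'
#' Pools counts per group at every site, applies [site_test()] (vectorized),
#' adjusts p-values with Benjamini-Hochberg over exactly the tested sites,
#' and flags sites with `q <= fdr_threshold` as DMCs. Sites where one group
#' has zero total coverage cannot be tested; they are dropped with a warning
#' (they cannot occur after a coverage-in-all-samples filter).
#'
#' @param mat Long methylation table (filtered and SNP-masked).
#' @param fdr_threshold FDR level; default 0.05.
#' @return A `dmc_tbl` tibble, one row per tested site, sorted by
#'   (chrom, pos): pooled counts `meth_a`, `unmeth_a`, `meth_b`, `unmeth_b`,
#'   group methylation fractions `p_a`, `p_b`, `delta = p_a - p_b`,
#'   `statistic`, `p_value`, `q_value`, `is_dmc`.
#' @export
call_dmcs <- function(mat, fdr_threshold = 0.05) {
  check_range(fdr_threshold, 0, 1, "fdr_threshold")
  groups <- sort(unique(mat$group))
  if (length(groups) != 2) md_abort("matrix must contain exactly two groups")
  pooled <- mat %>%
    dplyr::mutate(.grp = ifelse(.data$group == groups[1], "a", "b")) %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$.grp) %>%
    dplyr::summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                     .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = ".grp", values_from = c("meth", "unmeth"),
      values_fill = 0L
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  for (col in c("meth_a", "unmeth_a", "meth_b", "unmeth_b")) {
    if (!col %in% names(pooled)) pooled[[col]] <- 0L
  }
  untestable <- (pooled$meth_a + pooled$unmeth_a == 0) |
    (pooled$meth_b + pooled$unmeth_b == 0)
  if (any(untestable)) {
    rlang::warn(sprintf(
      "%d site(s) skipped: zero total coverage in one group", sum(untestable)
    ), class = "methdmc_zero_coverage")
    pooled <- pooled[!untestable, , drop = FALSE]
  }
  if (nrow(pooled) == 0) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      meth_a = integer(), unmeth_a = integer(),
      meth_b = integer(), unmeth_b = integer(),
      p_a = double(), p_b = double(), delta = double(),
      statistic = double(), p_value = double(), q_value = double(),
      is_dmc = logical()
    )
    return(new_dmc_tbl(out, fdr_threshold, groups))
  }
  out <- pooled %>%
    dplyr::mutate(
      p_a = .data$meth_a / (.data$meth_a + .data$unmeth_a),
      p_b = .data$meth_b / (.data$meth_b + .data$unmeth_b),
      delta = .data$p_a - .data$p_b,
      statistic = g_statistic(.data$meth_a, .data$unmeth_a,
                              .data$meth_b, .data$unmeth_b),
      p_value = stats::pchisq(.data$statistic, df = 1, lower.tail = FALSE),
      q_value = bh_fdr(.data$p_value),
      is_dmc = .data$q_value <= fdr_threshold
    )
  new_dmc_tbl(out, fdr_threshold, groups)
}

new_dmc_tbl <- function(x, fdr_threshold, groups) {
  structure(
    x,
    fdr_threshold = fdr_threshold,
    groups = groups,
    class = c("dmc_tbl", class(tibble::as_tibble(x)))
  )
}

#' @exportS3Method generics::glance
glance.dmc_tbl <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_dmc = sum(x$is_dmc),
    fdr_threshold = attr(x, "fdr_threshold"),
    group_a = attr(x, "groups")[1],
    group_b = attr(x, "groups")[2],
    mean_abs_delta_dmc = if (any(x$is_dmc)) mean(abs(x$delta[x$is_dmc])) else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.dmc_tbl <- function(x, ...) tibble::as_tibble(x)

#' Select high-confidence DMCs
#'
#' Restricts a DMC table to sites where the two groups differ most and where
#' genetic variation is an unlikely explanation: keeps DMC rows with
#' `|delta| > min_delta` and a nearest-SNP distance strictly greater than
#' `min_snp_dist` (sites at exactly `min_snp_dist` bp are excluded).
#'
#' @param dmc_table A `dmc_tbl` from [call_dmcs()].
#' @param snps SNP tibble (`chrom`, `pos`).
#' @param min_delta Minimum absolute group methylation difference
#'   (fraction); default 0.20.
#' @param min_snp_dist Minimum nearest-SNP distance in bp; default 100.
#' @return Tibble of retained rows with an added `snp_distance` column.
#' @export
select_high_confidence <- function(dmc_table, snps,
                                   min_delta = 0.20, min_snp_dist = 100) {
  dmcs <- dplyr::filter(tibble::as_tibble(dmc_table), .data$is_dmc)
  if (nrow(dmcs) == 0) {
    return(dplyr::mutate(dmcs, snp_distance = double()))
  }
  dmcs$snp_distance <- nearest_distance(dmcs, snps)
  dmcs %>%
    dplyr::filter(abs(.data$delta) > min_delta,
                  .data$snp_distance > min_snp_dist)
}
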