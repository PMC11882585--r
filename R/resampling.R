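#' Draw random control-cytosine subsets (r-Cs)
#'
#' Samples `k` subsets of `n` sites, each uniformly without replacement from
#' the universe of tested non-DMC cytosines. Subsets are drawn independently
#' of one another (they may overlap). Each subset `i` is drawn under child
#' seed `seed + i`, so enlarging `k` never changes earlier subsets.
#'
#' @param universe Tibble (`chrom`, `pos`, ...) of candidate sites — the
#'   tested sites with DMCs removed.
#' @param n Subset size (normally the number of DMCs).
#' @param k Number of subsets; default 10.
#' @param seed Master seed (integer).
#' @return A `subset_collection` tibble with columns `subset` (1..k) plus the
#'   site columns of `universe`; attributes `n`, `k`, `seed`.
#' @export
draw_subsets <- function(universe, n, k = 10, seed = 1) {
  if (k < 1) md_abort("k must be >= 1")
  if (n > nrow(universe)) {
    md_abort(sprintf("subset size n = %d exceeds universe size %d",
                     n, nrow(universe)))
  }
  out <- purrr::map_dfr(seq_len(k), function(i) {
    idx <- withr::with_seed(seed + i, sample.int(nrow(universe), n))
    dplyr::bind_cols(tibble::tibble(subset = i), universe[idx, , drop = FALSE])
  })
  structure(out, n = n, k = k, seed = seed,
            class = c("subset_collection", class(tibble::tibble())))
}

#' Compare an observed statistic to the subset distribution
#'
#' Two-sided t-test (df = k - 1) asking whether the observed DMC statistic is
#' consistent with the k control-subset statistics. Because the observed
#' value carries the same sampling noise as each subset value, the default
#' standard error is `s * sqrt(1 + 1/k)` (the prediction-interval form, which
#' has exact t size under normal exchangeability). `var_adjust = FALSE` gives
#' the plain one-sample t-test against the observed value as hypothesized
#' mean (`s / sqrt(k)`).
#'
#' @param subset_stats Numeric vector of k >= 2 subset statistics.
#' @param observed Observed DMC statistic.
#' @param var_adjust Use the prediction-variance standard error
#'   (default `TRUE`).
#' @return One-row tibble: `observed`, `subset_mean`, `subset_sd`,
#'   `statistic`, `df`, `p_value`.
#' @export
subset_ttest <- function(subset_stats, observed, var_adjust = TRUE) {
  k <- length(subset_stats)
  if (k < 2) md_abort("at least 2 subset statistics required for a t-test")
  m <- mean(subset_stats)
  s <- stats::sd(subset_stats)
  if (s == 0) {
    if (isTRUE(all.equal(observed, m))) {
      p <- 1
      tstat <- 0
    } else {
      rlang::warn("zero variance among subset statistics; p reported as 0",
                  class = "methdmc_degenerate_variance")
      p <- 0
      tstat <- Inf * sign(m - observed)
    }
  } else {
    se <- if (var_adjust) s * sqrt(1 + 1 / k) else s / sqrt(k)
    tstat <- (m - observed) / se
    p <- 2 * stats::pt(abs(tstat), df = k - 1, lower.tail = FALSE)
  }
  tibble::tibble(
    observed = observed, subset_mean = m, subset_sd = s,
    statistic = tstat, df = k - 1, p_value = p
  )
}

#' Check that subsets are representative of their universe
#'
#' For a per-site predicate (for example "within 100 bp of a SNP"), compares
#' each subset's predicate fraction to the universe-wide fraction and flags
#' subsets falling outside the central 99% binomial interval.
#'
#' @param subsets A `subset_collection` from [draw_subsets()].
#' @param universe The universe tibble the subsets were drawn from.
#' @param predicate Either a logical vector aligned with the rows of
#'   `universe`, or a function mapping a site tibble to a logical vector.
#' @return Tibble with one row per subset: `subset`, `fraction`,
#'   `universe_fraction`, `lower`, `upper`, `flagged`.
#' @export
subset_consistency_check <- function(subsets, universe, predicate) {
  pred_u <- if (is.function(predicate)) predicate(universe) else predicate
  if (length(pred_u) != nrow(universe)) {
    md_abort("predicate must yield one logical per universe site")
  }
  p0 <- mean(pred_u)
  n <- attr(subsets, "n")
  lower <- stats::qbinom(0.005, n, p0) / n
  upper <- stats::qbinom(0.995, n, p0) / n
  key_u <- site_key(universe$chrom, universe$pos)
  pred_map <- stats::setNames(pred_u, key_u)
  subsets %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$subset) %>%
    dplyr::summarise(
      fraction = mean(pred_map[site_key(.data$chrom, .data$pos)]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      universe_fraction = p0, lower = lower, upper = upper,
      flagged = .data$fraction < lower | .data$fraction > upper
    )
}
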