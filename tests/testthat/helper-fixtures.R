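# Small in-code fixtures shared across test files.

# A minimal per-sample record tibble.
make_records <- function(chrom, pos, meth, unmeth) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = "*",
                 meth = as.integer(meth), unmeth = as.integer(unmeth))
}

# Long methylation table for hand-built count configurations:
# counts is a list of per-sample tibbles (chrom, pos, meth, unmeth),
# groups a character vector aligned with counts.
make_matrix <- function(counts, groups) {
  samples <- paste0("s", seq_along(counts))
  purrr::imap_dfr(counts, function(x, i) {
    dplyr::mutate(x, strand = "*", sample = samples[as.integer(i)],
                  group = groups[as.integer(i)])
  }) %>%
    dplyr::select(chrom, pos, strand, sample, group, meth, unmeth)
}

# Two-group table at n sites where every sample has identical counts per group.
make_two_group_matrix <- function(pos, meth_a, unmeth_a, meth_b, unmeth_b,
                                  n_per_group = 1, chrom = "chr1") {
  counts <- c(
    replicate(n_per_group,
              make_records(chrom, pos, meth_a, unmeth_a), simplify = FALSE),
    replicate(n_per_group,
              make_records(chrom, pos, meth_b, unmeth_b), simplify = FALSE)
  )
  make_matrix(counts, rep(c("A", "B"), each = n_per_group))
}

# Independent G-test oracle on one pooled 2x2 table (meth/unmeth x group).
g_test_oracle <- function(ma, ua, mb, ub) {
  O <- matrix(c(ma, ua, mb, ub), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  g <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  stats::pchisq(g, df = 1, lower.tail = FALSE)
}

# Quadratic brute-force nearest distance.
nearest_oracle <- function(query, features) {
  vapply(seq_len(nrow(query)), function(i) {
    f <- features$pos[features$chrom == query$chrom[i]]
    if (length(f) == 0) Inf else min(abs(query$pos[i] - f))
  }, numeric(1))
}

# Quadratic brute-force stretch finder: all maximal runs with gaps <= max_gap.
stretch_oracle <- function(sites, max_gap, min_sites) {
  out <- list()
  for (chr in unique(sites$chrom)) {
    p <- sort(unique(sites$pos[sites$chrom == chr]))
    i <- 1
    while (i <= length(p)) {
      j <- i
      while (j < length(p) && p[j + 1] - p[j] <= max_gap) j <- j + 1
      if (j - i + 1 >= min_sites) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chr, start = p[i], end = p[j], n_sites = j - i + 1
        )
      }
      i <- j + 1
    }
  }
  if (length(out) == 0) {
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), n_sites = integer())
  } else {
    dplyr::arrange(dplyr::bind_rows(out), chrom, start)
  }
}

# Brute-force interval stabbing under the package boundary rule.
stab_oracle <- function(query, intervals) {
  vapply(seq_len(nrow(query)), function(i) {
    iv <- intervals[intervals$chrom == query$chrom[i], , drop = FALSE]
    any(iv$start < query$pos[i] & query$pos[i] < iv$end)
  }, logical(1))
}
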