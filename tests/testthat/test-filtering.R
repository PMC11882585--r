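test_that("build_matrix takes the union of sites with (0,0) fill", {
  recs <- list(
    s1 = make_records("chr1", c(100, 200), c(5, 3), c(5, 7)),
    s2 = make_records("chr1", 100, 8, 2)
  )
  sheet <- tibble::tibble(sample = c("s1", "s2"), group = c("A", "B"))
  mat <- build_matrix(recs, sheet)
  expect_equal(nrow(mat), 4)  # 2 sites x 2 samples
  missing <- mat[mat$pos == 200 & mat$sample == "s2", ]
  expect_equal(missing$meth, 0L)
  expect_equal(missing$unmeth, 0L)
})

test_that("build_matrix validates its sample sheet", {
  recs <- list(s1 = make_records("chr1", 1, 1, 1))
  expect_error(build_matrix(recs, tibble::tibble(sample = character(),
                                                 group = character())),
               "empty")
  sheet_dup <- tibble::tibble(sample = c("s1", "s1"), group = c("A", "B"))
  expect_error(build_matrix(recs, sheet_dup), "duplicate")
  sheet_missing <- tibble::tibble(sample = c("s1", "s2"), group = c("A", "B"))
  expect_error(build_matrix(recs, sheet_missing), "no records")
})

test_that("coverage filter applies the all-samples / any-sample rule", {
  mat <- make_matrix(
    list(make_records("chr1", c(1, 2), c(6, 6), c(6, 3)),    # cov 12, 9
         make_records("chr1", c(1, 2), c(5, 5), c(5, 6)),    # cov 10, 11
         make_records("chr1", c(1, 2), c(6, 6), c(5, 5))),   # cov 11, 11
    c("A", "A", "B")
  )
  kept_all <- matrix_sites(filter_coverage(mat, 10, require_all = TRUE))
  expect_equal(kept_all$pos, 1L)  # site 2 has a 9X sample
  kept_any <- matrix_sites(filter_coverage(mat, 10, require_all = FALSE))
  expect_equal(kept_any$pos, c(1L, 2L))
  # min_cov = 0 is the identity
  expect_equal(filter_coverage(mat, 0), mat)
})

test_that("SNP masking removes exact positions and (optionally) the dyad", {
  mat <- make_matrix(list(make_records("chr1", c(100, 300), 5, 5)), "A")
  mat$strand <- "+"
  snps_exact <- tibble::tibble(chrom = "chr1", pos = 100L)
  out <- mask_snp_positions(mat, snps_exact)
  expect_equal(out$pos, 300L)
  expect_equal(attr(out, "n_removed"), 1)

  snps_dyad <- tibble::tibble(chrom = "chr1", pos = 101L)
  expect_equal(mask_snp_positions(mat, snps_dyad, dyad_mode = FALSE)$pos,
               c(100L, 300L))
  expect_equal(mask_snp_positions(mat, snps_dyad, dyad_mode = TRUE)$pos, 300L)

  # SNPs on an absent chromosome are a no-op
  far <- tibble::tibble(chrom = "chr9", pos = 100L)
  expect_equal(mask_snp_positions(mat, far)$pos, c(100L, 300L))
})

test_that("filters commute, are idempotent, and account for removals", {
  withr::local_seed(5)
  pos <- sort(sample.int(10000, 200))
  mat <- make_matrix(
    list(make_records("chr1", pos, rpois(200, 8), rpois(200, 8)),
         make_records("chr1", pos, rpois(200, 8), rpois(200, 8))),
    c("A", "B")
  )
  snps <- tibble::tibble(chrom = "chr1", pos = sample(pos, 40))
  a <- mask_snp_positions(filter_coverage(mat, 10), snps)
  b <- filter_coverage(mask_snp_positions(mat, snps), 10)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b),
               ignore_attr = "n_removed")

  f1 <- filter_coverage(mat, 10)
  expect_equal(filter_coverage(f1, 10), f1)
  m1 <- mask_snp_positions(mat, snps)
  m2 <- mask_snp_positions(m1, snps)
  expect_equal(tibble::as_tibble(m2), tibble::as_tibble(m1),
               ignore_attr = "n_removed")
  expect_equal(attr(m2, "n_removed"), 0)

  # |kept sites| + |removed sites| = |input sites|
  expect_equal(nrow(matrix_sites(m1)) + attr(m1, "n_removed"),
               nrow(matrix_sites(mat)))
})
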