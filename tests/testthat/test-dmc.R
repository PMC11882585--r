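test_that("site_test reproduces hand-computed G-test values", {
  # identical groups: statistic 0, p = 1
  r <- site_test(c(50, 50), c(50, 50))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # no methylation anywhere: degenerate margin, p = 1
  expect_equal(site_test(c(0, 100), c(0, 100))$p_value, 1)
  # strongly opposed groups: all expected cells 50
  # G = 2 * (90 ln(90/50) + 10 ln(10/50)) * 2 = 147.23...
  r2 <- site_test(c(90, 10), c(10, 90))
  expect_equal(r2$statistic, 147.2343, tolerance = 1e-4)
  expect_lt(r2$p_value, 1e-33)
  # contract: zero total reads in one group
  expect_error(site_test(c(0, 0), c(5, 5)), class = "methdmc_zero_coverage")
})

test_that("site_test agrees with the brute-force G-test on random tables", {
  withr::local_seed(101)
  for (i in 1:1000) {
    tab <- sample(1:500, 4, replace = TRUE)
    p_pkg <- site_test(tab[1:2], tab[3:4])$p_value
    p_orc <- g_test_oracle(tab[1], tab[2], tab[3], tab[4])
    expect_lt(abs(p_pkg - p_orc), 1e-8)
  }
})

test_that("site_test matches the binomial-GLM likelihood-ratio route", {
  withr::local_seed(102)
  for (i in 1:40) {
    tab <- sample(1:300, 4, replace = TRUE)
    fit <- stats::glm(cbind(c(tab[1], tab[3]), c(tab[2], tab[4])) ~ c(0, 1),
                      family = stats::binomial())
    p_glm <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                           lower.tail = FALSE)
    expect_equal(site_test(tab[1:2], tab[3:4])$p_value, p_glm,
                 tolerance = 1e-6)
  }
})

test_that("site_test is symmetric in groups and in meth/unmeth labels", {
  withr::local_seed(103)
  for (i in 1:50) {
    tab <- sample(1:200, 4, replace = TRUE)
    p1 <- site_test(tab[1:2], tab[3:4])$p_value
    expect_equal(site_test(tab[3:4], tab[1:2])$p_value, p1)
    expect_equal(site_test(tab[2:1], tab[4:3])$p_value, p1)
  }
})

test_that("bh_fdr follows the step-up rule with ties and monotonicity", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(c(0.05, 0.05)), c(0.05, 0.05))
  # order preserved
  p <- c(0.9, 0.001, 0.5)
  q <- bh_fdr(p)
  expect_equal(order(q), order(p))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "methdmc_validation_error")
})

test_that("call_dmcs flags exactly a planted extreme site among nulls", {
  pos <- 1:40
  meth_a <- c(rep(10, 39), 48)   # site 40: pA = 0.96 vs pB = 0.04
  meth_b <- c(rep(10, 39), 2)
  mat <- make_two_group_matrix(pos, meth_a, 50 - meth_a, meth_b, 50 - meth_b)
  d <- call_dmcs(mat, fdr_threshold = 0.05)
  expect_equal(d$pos[d$is_dmc], 40L)
  expect_equal(sum(d$is_dmc), 1)
  # all-identical groups: zero DMCs
  d0 <- call_dmcs(make_two_group_matrix(1:10, 5, 5, 5, 5))
  expect_equal(sum(d0$is_dmc), 0)
  # degenerate threshold: every tested site flagged
  d1 <- call_dmcs(mat, fdr_threshold = 1.0)
  expect_true(all(d1$is_dmc))
})

test_that("DMC count is non-decreasing in the FDR threshold", {
  withr::local_seed(104)
  mat <- make_two_group_matrix(1:60, rbinom(60, 30, 0.4), rbinom(60, 30, 0.5),
                               rbinom(60, 30, 0.5), rbinom(60, 30, 0.4))
  counts <- vapply(c(0.01, 0.05, 0.1, 0.5, 1),
                   function(f) sum(call_dmcs(mat, f)$is_dmc), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("sites with zero coverage in one group are skipped with a warning", {
  mat <- make_matrix(
    list(make_records("chr1", c(1, 2), c(10, 0), c(10, 0)),
         make_records("chr1", c(1, 2), c(10, 5), c(10, 5))),
    c("A", "B")
  )
  expect_warning(d <- call_dmcs(mat), class = "methdmc_zero_coverage")
  expect_equal(d$pos, 1L)
})

test_that("high-confidence selection applies strict delta and SNP-distance rules", {
  # three clear DMCs at controlled SNP distances
  pos <- c(1000L, 5000L, 9000L)
  mat <- make_two_group_matrix(pos, c(190, 190, 120), c(10, 10, 80),
                               c(10, 10, 90), c(190, 190, 110))
  d <- call_dmcs(mat)
  expect_true(all(d$is_dmc))
  expect_equal(abs(d$delta), c(0.9, 0.9, 0.15), tolerance = 1e-9)
  snps <- tibble::tibble(chrom = "chr1", pos = c(1150L, 5100L, 14000L))
  hc <- select_high_confidence(d, snps, min_delta = 0.20, min_snp_dist = 100)
  # pos 1000: delta .9, snp at 150 bp -> kept
  # pos 5000: delta .9, snp at exactly 100 bp -> excluded (boundary strict)
  # pos 9000: delta .15 -> excluded by delta rule
  expect_equal(hc$pos, 1000L)
})

test_that("dmc_tbl tidiers summarise the fit", {
  mat <- make_two_group_matrix(1:5, 10, 10, 10, 10)
  d <- call_dmcs(mat)
  g <- glance(d)
  expect_equal(g$n_sites, 5)
  expect_equal(g$n_dmc, 0)
  expect_s3_class(tidy(d), "tbl_df")
})
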