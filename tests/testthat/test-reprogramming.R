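test_that("replicate pooling sums counts and fills absent sites", {
  mat <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 10L, 20L),
    sample = c("r1", "r2", "r1"),
    meth = c(3L, 2L, 4L), unmeth = c(7L, 8L, 6L)
  )
  sheet <- tibble::tibble(sample = c("r1", "r2"), stage = c("2C", "2C"))
  p <- pool_replicates(mat, sheet)
  expect_equal(p$meth[p$pos == 10], 5L)
  expect_equal(p$unmeth[p$pos == 10], 15L)
  expect_equal(p$fraction[p$pos == 10], 0.25)
  # site 20 absent in r2: treated as (0,0)
  expect_equal(p$meth[p$pos == 20], 4L)
  # single replicate is the identity on counts
  p1 <- pool_replicates(mat[mat$sample == "r1", ],
                        tibble::tibble(sample = "r1", stage = "2C"))
  expect_equal(p1$meth, c(3L, 4L))
  expect_error(pool_replicates(mat, tibble::tibble(sample = "r9", stage = "B")),
               "no records")
})

test_that("stage filter keeps sites covered in every stage", {
  mk <- function(stage, cov) {
    tibble::tibble(chrom = "chr1", pos = c(1L, 2L), stage = stage,
                   meth = as.integer(cov / 2), unmeth = as.integer(ceiling(cov / 2)),
                   fraction = 0.5)
  }
  profiles <- dplyr::bind_rows(
    mk("2C", c(6, 6)), mk("CM", c(5, 4)), mk("B", c(9, 9)), mk("S", c(12, 12))
  )
  sites <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L))
  f <- stage_filter(profiles, sites, min_cov = 5)
  expect_equal(f$pos, 1L)   # site 2 has a 4X stage
  expect_true(all(c("2C", "CM", "B", "S") %in% names(f)))
  # pooling then filtering equals filtering pre-summed counts
  f_all <- stage_filter(profiles, sites, min_cov = 1)
  expect_equal(f_all$pos, c(1L, 2L))
})

test_that("clustering joins identical profiles first and handles two columns", {
  withr::local_seed(51)
  a <- runif(50)
  fr <- tibble::tibble(chrom = "chr1", pos = 1:50,
                       A = a, B = a, C = 1 - a)
  hc <- hierarchical_cluster(fr)
  merged_first <- hc$hclust$merge[1, ]
  expect_setequal(hc$hclust$labels[-merged_first], c("A", "B"))
  expect_match(hc$newick, "A", fixed = TRUE)
  # two columns: a single merge
  hc2 <- hierarchical_cluster(fr[c("chrom", "pos", "A", "C")])
  expect_equal(nrow(hc2$hclust$merge), 1)
})

test_that("constant profiles are dropped with a warning", {
  withr::local_seed(52)
  fr <- tibble::tibble(chrom = "chr1", pos = 1:30,
                       A = runif(30), B = runif(30), K = 0.5)
  expect_warning(hc <- hierarchical_cluster(fr),
                 class = "methdmc_constant_profile")
  expect_equal(hc$dropped, "K")
  expect_setequal(hc$hclust$labels, c("A", "B"))
})

test_that("clustering recovers planted two-block stage structure", {
  withr::local_seed(53)
  ok <- replicate(20, {
    base1 <- runif(80)
    base2 <- runif(80)
    noise <- function(x) pmin(pmax(x + rnorm(80, 0, 0.05), 0), 1)
    fr <- tibble::tibble(chrom = "chr1", pos = 1:80,
                         s1 = noise(base1), s2 = noise(base1),
                         s3 = noise(base2), s4 = noise(base2))
    hc <- hierarchical_cluster(fr)
    m <- hc$hclust$merge
    pair1 <- sort(-m[1, ])
    pair2 <- sort(-m[2, ])
    setequal(pair1, c(1, 2)) && setequal(pair2, c(3, 4)) ||
      setequal(pair1, c(3, 4)) && setequal(pair2, c(1, 2))
  })
  expect_gte(mean(ok), 0.95)
})

test_that("clustering is invariant to site order", {
  withr::local_seed(54)
  fr <- tibble::tibble(chrom = "chr1", pos = 1:60,
                       A = runif(60), B = runif(60), C = runif(60))
  hc1 <- hierarchical_cluster(fr)
  hc2 <- hierarchical_cluster(fr[sample.int(60), ])
  expect_equal(hc1$newick, hc2$newick)
})
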