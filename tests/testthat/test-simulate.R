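test_that("truth generation honours count and coupling contracts", {
  cfg <- sim_config(seed = 3, n_cpg = 10000, n_dmc = 200, n_stretches = 0,
                    couple_fraction = 1.0, d_couple = 100)
  sim <- generate_truth(cfg)
  expect_equal(nrow(sim$truth), 10000)
  expect_equal(sum(sim$truth$is_planted_dmc), 200)
  # full coupling: every planted DMC has a SNP within 100 bp
  dmc_dist <- sim$truth$snp_distance[sim$truth$is_planted_dmc]
  expect_true(all(dmc_dist <= 100))
  # SNPs never collide with CpG positions (they would be masked away)
  expect_false(any(site_key(sim$snps$chrom, sim$snps$pos) %in%
                     site_key(sim$truth$chrom, sim$truth$pos)))
  # positions unique per chromosome
  expect_false(any(duplicated(sim$truth[c("chrom", "pos")])))
})

test_that("planted deltas have full magnitude and clipping is respected", {
  cfg <- sim_config(seed = 4, n_cpg = 5000, n_dmc = 300, n_stretches = 0)
  sim <- generate_truth(cfg)
  tr <- sim$truth
  expect_equal(abs(tr$delta_true[tr$is_planted_dmc]),
               rep(cfg$delta, sum(tr$is_planted_dmc)), tolerance = 1e-12)
  expect_true(all(tr$delta_true[!tr$is_planted_dmc] == 0))
  expect_true(all(tr$p_a >= 0.02 & tr$p_a <= 0.98))
  expect_true(all(tr$p_b >= 0.02 & tr$p_b <= 0.98))
})

test_that("stretch planting realizes runs of adjacent planted DMCs", {
  cfg <- sim_config(seed = 5, n_cpg = 5000, n_dmc = 100,
                    n_stretches = 4, stretch_sites = 10)
  sim <- generate_truth(cfg)
  planted <- sim$truth[!is.na(sim$truth$stretch_id), ]
  expect_equal(nrow(planted), 40)
  expect_true(all(planted$is_planted_dmc))
  st <- find_stretches(planted[c("chrom", "pos")], max_gap = 2000, min_sites = 2)
  expect_gte(sum(st$n_sites), 40)  # every planted member sits in a stretch
})

test_that("infeasible configurations fail before generation", {
  expect_error(sim_config(n_cpg = 100, n_dmc = 200), "more planted")
  expect_error(sim_config(n_dmc = 10, n_stretches = 3, stretch_sites = 12),
               "stretch members")
})

test_that("count sampling matches the configured laws", {
  cfg <- sim_config(seed = 6, n_cpg = 10000, n_dmc = 0, n_stretches = 0,
                    couple_fraction = 0)
  sim <- generate_truth(cfg)
  counts <- sample_counts(sim)
  expect_equal(length(counts$records), 18)
  expect_equal(sort(unique(counts$sample_sheet$group)), c("H", "M"))
  cov <- counts$records[[1]]$meth + counts$records[[1]]$unmeth
  expect_lt(abs(mean(cov) - 30) / 30, 0.05)
  # bimodality of pooled site fractions: sparse mid-range
  pooled <- purrr::reduce(counts$records, function(a, b) {
    a$meth <- a$meth + b$meth; a$unmeth <- a$unmeth + b$unmeth; a
  })
  fr <- pooled$meth / (pooled$meth + pooled$unmeth)
  h <- hist(fr, breaks = seq(0, 1, 0.1), plot = FALSE)$density
  expect_lt(min(h[5:6]), min(h[1], h[10]))  # dip between the modes
})

test_that("grouped counts concentrate around planted group means", {
  cfg <- sim_config(seed = 8, n_cpg = 2000, n_dmc = 50, n_stretches = 0)
  sim <- generate_truth(cfg)
  counts <- sample_counts(sim)
  b <- c(sim, counts)
  mat <- build_matrix(b$records, b$sample_sheet)
  pooled <- call_dmcs(mat, fdr_threshold = 0.05)
  truth_means <- dplyr::rename(sim$truth[c("chrom", "pos", "p_a", "p_b")],
                               p_a_true = p_a, p_b_true = p_b)
  tr <- dplyr::inner_join(tibble::as_tibble(pooled), truth_means,
                          by = c("chrom", "pos"))
  # pooled group fractions within 3 binomial sd of the planted means (~270 reads)
  sd3 <- 3 * sqrt(tr$p_a_true * (1 - tr$p_a_true) / (tr$meth_a + tr$unmeth_a))
  expect_gt(mean(abs(tr$p_a - tr$p_a_true) <= sd3 + 1e-9), 0.98)
})

test_that("simulation is deterministic and emitted files round-trip", {
  cfg <- sim_config(seed = 9, n_cpg = 500, n_dmc = 20, n_stretches = 0,
                    n_snps = 50)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$records, b2$records)

  outdir <- withr::local_tempdir()
  paths <- emit_files(b1, outdir)
  expect_equal(sum(endsWith(unname(paths), ".cov.tsv")), 18)
  rec_back <- read_coverage_table(paths[["H1"]])
  expect_equal(rec_back, dplyr::arrange(b1$records[["H1"]], chrom, pos))
  snps_back <- read_snp_table(paths[["snps"]], min_af = 0)
  expect_equal(snps_back[c("chrom", "pos")], b1$snps[c("chrom", "pos")])
  expect_equal(snps_back$af_a, b1$snps$af_a, tolerance = 1e-4)
  reps_back <- read_repeat_annotation(paths[["repeats"]])
  expect_equal(reps_back[c("chrom", "start", "end", "class")],
               dplyr::arrange(b1$repeats, chrom, start)[c("chrom", "start", "end", "class")])
  # truth nearest-SNP distances recomputable from emitted files
  snps_f <- read_snp_table(paths[["snps"]], min_af = 0.10)
  truth_back <- readr::read_tsv(paths[["truth"]], col_types = readr::cols(),
                                progress = FALSE)
  expect_equal(nearest_distance(truth_back, snps_f), truth_back$snp_distance)
})

test_that("stage simulation exercises the low-coverage filter path", {
  cfg <- sim_config(seed = 10, n_cpg = 2000, n_dmc = 100, n_stretches = 0)
  sim <- generate_truth(cfg)
  st <- simulate_stages(sim)
  expect_equal(nrow(st$stage_sheet), 8)  # 4 stages x 2 replicates
  pooled <- pool_replicates(st$mat, st$stage_sheet)
  dmc_sites <- sim$truth[sim$truth$is_planted_dmc, c("chrom", "pos")]
  fm <- stage_filter(pooled, dmc_sites, min_cov = 5)
  expect_gt(nrow(fm), 0)
  expect_lt(nrow(fm), nrow(dmc_sites))  # 6X mean coverage loses sites at 5X-in-all
})
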