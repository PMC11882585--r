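#' Simulation configuration
#'
#' Parameters of the synthetic two-group RRBS generator. Defaults emulate the
#' study conditions the pipeline targets: 9 + 9 samples, negative-binomial
#' coverage with mean 30X, bimodal baseline methylation (low mode Beta(1,10),
#' high mode Beta(10,1), high-mode weight 0.30), 20,000 CpGs on a 2 x 5 Mb
#' genome, 500 planted DMCs with a group shift of 0.4, 30% of planted DMCs
#' coupled to a SNP within 100 bp against a ~2% background near-SNP rate
#' (1,000 SNPs), four repeat classes with the first at 3x planted-DMC
#' density, and three planted stretches of 12 adjacent DMCs.
#'
#' @param seed Master seed.
#' @param n_chrom,chrom_length Genome shape (chromosome count, length in bp).
#' @param n_cpg Total CpG sites.
#' @param samples_per_group Integer length-2, samples in each group.
#' @param group_labels Character length-2 group names.
#' @param coverage_mean,coverage_size Negative-binomial coverage law
#'   (mean and dispersion `size`; variance = mu + mu^2/size).
#' @param meth_mix_weight_high Weight of the high-methylation mixture mode.
#' @param beta_low,beta_high Beta shape pairs of the two mixture modes.
#' @param n_dmc Planted DMC count (includes stretch members).
#' @param delta Group methylation shift at planted DMCs (shift direction is
#'   chosen away from the nearer clipping bound so the realized |delta| is
#'   preserved).
#' @param clip Lower/upper clipping bounds for methylation means.
#' @param couple_fraction Fraction of planted DMCs given a SNP within
#'   `d_couple` bp.
#' @param d_couple Coupling distance in bp.
#' @param n_snps Total SNP count (coupled + uniform background).
#' @param repeat_classes Tibble (`class`, `n_intervals`, `mean_length`,
#'   `dmc_multiplier`) describing the repeat annotation and per-class
#'   planted-DMC density multipliers.
#' @param n_stretches,stretch_sites,stretch_gap Planted stretch count, sites
#'   per stretch, and the uniform range of intra-stretch gaps in bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2,
                       chrom_length = 5e6,
                       n_cpg = 20000,
                       samples_per_group = c(9, 9),
                       group_labels = c("H", "M"),
                       coverage_mean = 30,
                       coverage_size = 20,
                       meth_mix_weight_high = 0.30,
                       beta_low = c(1, 10),
                       beta_high = c(10, 1),
                       n_dmc = 500,
                       delta = 0.4,
                       clip = c(0.02, 0.98),
                       couple_fraction = 0.30,
                       d_couple = 100,
                       n_snps = 1000,
                       repeat_classes = default_repeat_classes(),
                       n_stretches = 3,
                       stretch_sites = 12,
                       stretch_gap = c(10, 200)) {
  cfg <- as.list(environment())
  check_range(meth_mix_weight_high, 0, 1, "meth_mix_weight_high")
  check_range(couple_fraction, 0, 1, "couple_fraction")
  check_range(delta, 0, 1, "delta")
  if (n_dmc > n_cpg) md_abort("more planted DMCs than CpGs")
  if (n_stretches * stretch_sites > max(n_dmc, 0) && n_stretches > 0) {
    md_abort("stretch members exceed the planted DMC budget")
  }
  if (n_cpg > n_chrom * chrom_length / 2) {
    md_abort("CpG density infeasible for the configured genome size")
  }
  structure(cfg, class = "sim_config")
}

default_repeat_classes <- function() {
  tibble::tibble(
    class = c("LTR/ERV2", "rRNA/5S", "Satellite/BTSAT4", "LINE/L1"),
    n_intervals = c(600L, 600L, 600L, 600L),
    mean_length = c(400, 400, 400, 400),
    dmc_multiplier = c(3, 1, 1, 1)
  )
}

#' Generate simulation ground truth
#'
#' Realizes CpG positions (planted stretches first, remaining sites drawn
#' without collision), repeat intervals, per-site group methylation means
#' (planted DMCs get a shift of `delta`, clipped to `clip`), and SNP
#' positions (the configured fraction of planted DMCs receives a SNP within
#' `d_couple` bp; SNPs never collide with CpG positions). Fully seeded from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `truth` (per-site tibble: `chrom`, `pos`,
#'   `p_a`, `p_b`, `is_planted_dmc`, `delta_true`, `stretch_id`,
#'   `repeat_class`, `snp_distance`), `snps` (`chrom`, `pos`, `af_a`,
#'   `af_b`), `repeats` (half-open intervals with `class`, `name`), and the
#'   `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_truth_impl(config))
}

generate_truth_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))

  # planted stretches: runs of adjacent CpGs with small gaps
  stretch_tbl <- NULL
  if (cfg$n_stretches > 0) {
    stretch_tbl <- purrr::map_dfr(seq_len(cfg$n_stretches), function(i) {
      chr <- sample(chroms, 1)
      anchor <- sample.int(cfg$chrom_length - cfg$stretch_sites * cfg$stretch_gap[2] - 1, 1)
      gaps <- sample(seq(cfg$stretch_gap[1], cfg$stretch_gap[2]),
                     cfg$stretch_sites - 1, replace = TRUE)
      tibble::tibble(chrom = chr, pos = as.integer(anchor + cumsum(c(0, gaps))),
                     stretch_id = i)
    })
  }

  # repeat intervals (0-based half-open), uniform placement per class
  repeats <- purrr::pmap_dfr(cfg$repeat_classes, function(class, n_intervals,
                                                          mean_length, dmc_multiplier) {
    chr <- sample(chroms, n_intervals, replace = TRUE)
    len <- pmax(20L, as.integer(stats::rgamma(n_intervals, shape = 4,
                                              scale = mean_length / 4)))
    start <- vapply(len, function(l) sample.int(cfg$chrom_length - l - 1, 1),
                    integer(1))
    tibble::tibble(chrom = chr, start = start, end = start + len,
                   class = class,
                   name = paste0(sub(".*/", "", class), "_", seq_len(n_intervals)))
  }) %>% dplyr::arrange(.data$chrom, .data$start)

  # remaining CpG positions, collision-free with stretch members
  n_rest <- cfg$n_cpg - if (is.null(stretch_tbl)) 0L else nrow(stretch_tbl)
  per_chrom <- table(factor(sample(chroms, n_rest, replace = TRUE), levels = chroms))
  rest <- purrr::map_dfr(chroms, function(chr) {
    taken <- if (is.null(stretch_tbl)) integer(0) else
      stretch_tbl$pos[stretch_tbl$chrom == chr]
    pos <- sample.int(cfg$chrom_length, per_chrom[[chr]] + length(taken))
    pos <- setdiff(pos, taken)[seq_len(per_chrom[[chr]])]
    tibble::tibble(chrom = chr, pos = as.integer(pos), stretch_id = NA_integer_)
  })
  sites <- dplyr::bind_rows(stretch_tbl, rest) %>%
    dplyr::arrange(.data$chrom, .data$pos)

  # annotate containing repeat class (first by annotation order) + multiplier
  site_class <- rep(NA_character_, nrow(sites))
  site_mult <- rep(1, nrow(sites))
  for (cl in cfg$repeat_classes$class) {
    inside <- sites_in_intervals(sites, repeats[repeats$class == cl, ])
    mult <- cfg$repeat_classes$dmc_multiplier[cfg$repeat_classes$class == cl]
    site_mult[inside] <- site_mult[inside] * mult
    site_class[inside & is.na(site_class)] <- cl
  }

  # planted DMCs: stretch members first, remainder weighted by repeat multiplier
  is_dmc <- !is.na(sites$stretch_id)
  n_extra <- cfg$n_dmc - sum(is_dmc)
  if (n_extra > 0) {
    candidates <- which(!is_dmc)
    pick <- sample(candidates, n_extra, prob = site_mult[candidates])
    is_dmc[pick] <- TRUE
  }

  # methylation means: bimodal baseline, constant shift at planted DMCs
  n <- nrow(sites)
  high <- stats::runif(n) < cfg$meth_mix_weight_high
  p0 <- ifelse(high,
               stats::rbeta(n, cfg$beta_high[1], cfg$beta_high[2]),
               stats::rbeta(n, cfg$beta_low[1], cfg$beta_low[2]))
  p0 <- pmin(pmax(p0, cfg$clip[1]), cfg$clip[2])
  shift_dir <- ifelse(p0 <= 0.5, 1, -1)  # away from the nearer bound
  p_b <- ifelse(is_dmc,
                pmin(pmax(p0 + shift_dir * cfg$delta, cfg$clip[1]), cfg$clip[2]),
                p0)
  truth <- sites %>%
    dplyr::mutate(
      p_a = p0, p_b = p_b,
      is_planted_dmc = is_dmc,
      delta_true = .data$p_a - .data$p_b,
      repeat_class = site_class
    )

  # SNPs: coupled to a random subset of planted DMCs, remainder uniform
  dmc_idx <- which(is_dmc)
  n_couple <- round(cfg$couple_fraction * length(dmc_idx))
  snp_pos <- tibble::tibble(chrom = character(), pos = integer())
  taken_keys <- site_key(sites$chrom, sites$pos)
  if (n_couple > 0) {
    anchors <- sample(dmc_idx, n_couple)
    cpos <- purrr::map_dfr(anchors, function(i) {
      repeat {
        off <- sample(c(-1, 1), 1) * sample.int(cfg$d_couple, 1)
        p <- sites$pos[i] + off
        if (p >= 1 && p <= cfg$chrom_length &&
            !(site_key(sites$chrom[i], p) %in% taken_keys)) {
          return(tibble::tibble(chrom = sites$chrom[i], pos = as.integer(p)))
        }
      }
    })
    snp_pos <- dplyr::bind_rows(snp_pos, cpos)
  }
  n_bg <- cfg$n_snps - nrow(snp_pos)
  if (n_bg > 0) {
    bg_chr <- sample(chroms, n_bg, replace = TRUE)
    bg <- tibble::tibble(chrom = bg_chr,
                         pos = sample.int(cfg$chrom_length, n_bg))
    bg <- bg[!(site_key(bg$chrom, bg$pos) %in% taken_keys), , drop = FALSE]
    snp_pos <- dplyr::bind_rows(snp_pos, bg)
  }
  snps <- snp_pos %>%
    dplyr::distinct(.data$chrom, .data$pos) %>%
    dplyr::arrange(.data$chrom, .data$pos) %>%
    dplyr::mutate(
      af_a = stats::runif(dplyr::n(), 0.15, 0.95),
      af_b = stats::runif(dplyr::n(), 0, 0.95)
    )

  truth$snp_distance <- nearest_distance(truth, snps)
  structure(
    list(truth = truth, snps = snps, repeats = repeats, config = cfg),
    class = "sim_truth"
  )
}

#' Draw per-sample read counts from a simulation truth
#'
#' Per site and sample: coverage is negative binomial
#' (`mu = coverage_mean`, `size = coverage_size`); methylated reads are
#' binomial with the site's group-specific methylation mean. Counts are
#' independent across sites and samples given the seed
#' (`config$seed + 1`, so truth and counts use separate streams).
#'
#' @param sim A `sim_truth` from [generate_truth()].
#' @return List with `records` (named list of per-sample tibbles in
#'   [read_coverage_table()] layout) and `sample_sheet` (`sample`, `group`).
#' @export
sample_counts <- function(sim) {
  stopifnot(inherits(sim, "sim_truth"))
  cfg <- sim$config
  truth <- sim$truth
  sheet <- tibble::tibble(
    sample = c(paste0(cfg$group_labels[1], seq_len(cfg$samples_per_group[1])),
               paste0(cfg$group_labels[2], seq_len(cfg$samples_per_group[2]))),
    group = rep(cfg$group_labels, cfg$samples_per_group)
  )
  records <- withr::with_seed(cfg$seed + 1, {
    purrr::map(stats::setNames(seq_len(nrow(sheet)), sheet$sample), function(i) {
      p <- if (sheet$group[i] == cfg$group_labels[1]) truth$p_a else truth$p_b
      cov <- stats::rnbinom(nrow(truth), mu = cfg$coverage_mean,
                            size = cfg$coverage_size)
      meth <- stats::rbinom(nrow(truth), size = cov, prob = p)
      tibble::tibble(
        chrom = truth$chrom, pos = truth$pos, strand = "*",
        meth = meth, unmeth = cov - meth
      )
    })
  })
  list(records = records, sample_sheet = sheet)
}

#' Simulate a complete input bundle in memory
#'
#' Convenience wrapper: [generate_truth()] then [sample_counts()].
#'
#' @param config A [sim_config()].
#' @return List: `truth`, `snps`, `repeats`, `records`, `sample_sheet`,
#'   `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  sim <- generate_truth(config)
  counts <- sample_counts(sim)
  c(sim[c("truth", "snps", "repeats")], counts, list(config = config))
}

#' Write a simulated bundle to disk
#'
#' Emits per-sample coverage tables, a SNP VCF with per-group allele
#' frequencies (INFO keys `AFA`, `AFB`), a repeat BED (class in column 7),
#' the sample sheet, and the truth table — all in the formats the package's
#' readers consume.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_files <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (s in names(bundle$records)) {
    p <- file.path(outdir, paste0(s, ".cov.tsv"))
    write_coverage_table(bundle$records[[s]], p)
    paths[s] <- p
  }
  vcf_path <- file.path(outdir, "snps.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AFA,Number=1,Type=Float,Description=\"Alternate allele frequency, group A\">",
    "##INFO=<ID=AFB,Number=1,Type=Float,Description=\"Alternate allele frequency, group B\">",
    paste0("##contig=<ID=", unique(bundle$snps$chrom), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\tC\tT\t.\tPASS\tAFA=%.4f;AFB=%.4f",
            bundle$snps$chrom, bundle$snps$pos,
            bundle$snps$af_a, bundle$snps$af_b)
  ), vcf_path)
  paths["snps"] <- vcf_path
  bed_path <- file.path(outdir, "repeats.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t+\t%s",
                     bundle$repeats$chrom, bundle$repeats$start,
                     bundle$repeats$end, bundle$repeats$name,
                     bundle$repeats$class), bed_path)
  paths["repeats"] <- bed_path
  sheet_path <- file.path(outdir, "sample_sheet.tsv")
  sheet <- dplyr::mutate(bundle$sample_sheet,
                         file = paste0(.data$sample, ".cov.tsv"))
  readr::write_tsv(sheet, sheet_path, progress = FALSE)
  paths["sample_sheet"] <- sheet_path
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(bundle$truth, truth_path, progress = FALSE)
  paths["truth"] <- truth_path
  invisible(paths)
}

#' Simulate low-coverage multi-stage profiles at given sites
#'
#' Reuses the count generator at developmental-stage scale: each stage gets
#' `reps` replicates with negative-binomial coverage (default mean 6X, so a
#' 5X-in-all-stages pooled filter is exercised), and a stage-specific global
#' scaling of the methylation means emulating a demethylation /
#' remethylation wave (2-cell and morula hypomethylated, blastocyst and
#' sperm near the sperm baseline).
#'
#' @param sim A `sim_truth`.
#' @param stages Stage labels; default `c("2C", "CM", "B", "S")`.
#' @param stage_scale Multiplier on the site methylation mean per stage.
#' @param reps Replicates per stage; default 2.
#' @param coverage_mean,coverage_size Stage coverage law; defaults 6 and 5.
#' @param seed Seed; default `config$seed + 2`.
#' @return List: `mat` (long tibble `chrom`, `pos`, `sample`, `meth`,
#'   `unmeth`), `stage_sheet` (`sample`, `stage`).
#' @export
simulate_stages <- function(sim, stages = c("2C", "CM", "B", "S"),
                            stage_scale = c(0.3, 0.4, 0.8, 1.0),
                            reps = 2, coverage_mean = 6, coverage_size = 5,
                            seed = sim$config$seed + 2) {
  stopifnot(inherits(sim, "sim_truth"), length(stages) == length(stage_scale))
  truth <- sim$truth
  sheet <- tibble::tibble(
    sample = paste0(rep(stages, each = reps), "_r", rep(seq_len(reps), length(stages))),
    stage = rep(stages, each = reps)
  )
  mat <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
      sc <- stage_scale[match(sheet$stage[i], stages)]
      p <- pmin(pmax(truth$p_a * sc, 0.01), 0.99)
      cov <- stats::rnbinom(nrow(truth), mu = coverage_mean, size = coverage_size)
      meth <- stats::rbinom(nrow(truth), size = cov, prob = p)
      tibble::tibble(chrom = truth$chrom, pos = truth$pos,
                     sample = sheet$sample[i], meth = meth, unmeth = cov - meth)
    })
  })
  list(mat = mat, stage_sheet = sheet)
}
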