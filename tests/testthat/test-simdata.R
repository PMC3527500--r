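# The forward-time two-sex metapopulation simulator.

small_cfg <- function(...) {
  sim_config(n_demes = 3, n_f = 12, n_m = 12, generations = 30,
             seq_length = 60, n_loci = 4, sample_size = 8, ...)
}

test_that("configuration validation enforces rates and sizes", {
  expect_error(sim_config(m_f = 1.2), "rates")
  expect_error(sim_config(null_rate = -0.1), "rates")
  expect_error(sim_config(n_f = 2, n_m = 2, sample_size = 10),
               "sample_size")
})

test_that("a fixed seed reproduces the simulation bit for bit", {
  s1 <- simulate_metapopulation(small_cfg(seed = 11))
  s2 <- simulate_metapopulation(small_cfg(seed = 11))
  expect_equal(as.data.frame(s1$alignment), as.data.frame(s2$alignment))
  expect_equal(as.data.frame(s1$genotypes), as.data.frame(s2$genotypes))
  expect_equal(s1$truth$migrations, s2$truth$migrations)
  s3 <- simulate_metapopulation(small_cfg(seed = 12))
  expect_false(identical(as.data.frame(s1$genotypes),
                         as.data.frame(s3$genotypes)))
})

test_that("no migration and no mutation keeps demes fixed at founder states", {
  cfg <- sim_config(n_demes = 3, n_f = 8, n_m = 8, m_f = 0, m_m = 0,
                    generations = 15, mu_mt = 0, mu_ms = 0,
                    founder_private = 0, founder_alleles = c(1, 1),
                    founder_pool = "private", sample_size = 6,
                    n_loci = 3, seq_length = 50, seed = 21)
  sim <- simulate_metapopulation(cfg)
  # each deme monomorphic for its own haplotype and alleles
  expect_equal(nrow(collapse_haplotypes(sim$alignment)), 3L)
  expect_equal(wc_fstats(sim$genotypes, n_perm = 0, pairwise = FALSE)$estimate, 1)
  expect_equal(amova_phist(sim$alignment, n_perm = 0, pairwise = FALSE)$estimate, 1)
  expect_equal(sum(sim$truth$migrations), 0L)
})

test_that("a panmictic population carries no structure signal", {
  cfg <- sim_config(n_demes = 1, n_f = 30, n_m = 30, generations = 30,
                    seq_length = 60, n_loci = 5, sample_size = 24,
                    seed = 5)
  sim <- simulate_metapopulation(cfg)
  # split the single deme arbitrarily in two pseudo-populations
  gt <- sim$genotypes
  ids <- unique(gt$sample_id)
  fake <- setNames(rep(c("X", "Y"), length.out = length(ids)), ids)
  gt$population <- fake[gt$sample_id]
  gt <- genotype_table(gt, loci = loci_names(gt))
  expect_lt(abs(wc_fstats(gt, n_perm = 0, pairwise = FALSE)$estimate), 0.08)
  aln <- sim$alignment
  aln$population <- fake[aln$sample_id]
  aln <- aligned_sequences(aln)
  # the point estimate is noisy with few haplotypes; the split must carry
  # no significant signal
  phi <- amova_phist(aln, n_perm = 199, pairwise = FALSE, seed = 6)
  expect_gt(phi$p_value, 0.05)
})

test_that("mutation-free inheritance conserves the founder allele pool", {
  cfg <- small_cfg(mu_ms = 0, seed = 31)
  sim <- simulate_metapopulation(cfg)
  gt <- sim$truth$true_genotypes
  for (l in unique(gt$locus)) {
    alleles <- c(gt$a1[gt$locus == l], gt$a2[gt$locus == l])
    expect_true(all(alleles >= 10 & alleles <= 30 + 12)) # founder pool range
  }
})

test_that("founder null lineages depress observed heterozygosity only", {
  cfg0 <- small_cfg(null_rate = 0, seed = 41)
  cfg3 <- small_cfg(null_rate = 0.35, seed = 41)
  s0 <- simulate_metapopulation(cfg0)
  s3 <- simulate_metapopulation(cfg3)
  # identical underlying genotypes for the same seed
  expect_equal(as.data.frame(s0$truth$true_genotypes),
               as.data.frame(s3$truth$true_genotypes))
  h0 <- mean(allele_summary(s0$genotypes)$H_O, na.rm = TRUE)
  h3 <- mean(allele_summary(s3$genotypes)$H_O, na.rm = TRUE)
  expect_lt(h3, h0)
})

test_that("inject_null_alleles is identity at 0, blanks at 1, and depresses H_O", {
  set.seed(51)
  gt <- random_hwe_gt(n_per_pop = 30, n_pops = 1, n_loci = 5, k_alleles = 6)
  expect_identical(inject_null_alleles(gt, 0), gt)
  gone <- inject_null_alleles(gt, 1, seed = 1)
  expect_true(all(is.na(gone$a1)))
  masked <- inject_null_alleles(gt, 0.3, seed = 2)
  h_before <- mean(allele_summary(gt)$H_O)
  h_after <- mean(allele_summary(masked)$H_O, na.rm = TRUE)
  expect_lt(h_after, h_before)
  # masking shifts the allele-randomization deficit p downward
  p_before <- randomization_scan(gt, n_reps = 300, seed = 3)$p
  p_after <- randomization_scan(masked, n_reps = 300, seed = 3)$p
  expect_lt(median(p_after), median(p_before))
})

test_that("default study conditions give 15 loci within the observed richness range", {
  sim <- simulate_metapopulation(sim_config(seed = 7))
  gt <- sim$genotypes
  expect_equal(length(loci_names(gt)), 15L)
  richness <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(gt, !is.na(a1)), locus),
    k = dplyr::n_distinct(c(a1, a2)))$k
  expect_true(all(richness >= 4 & richness <= 13))
  expect_equal(aln_length(sim$alignment), 410L)
  expect_equal(nrow(sim$alignment), 4L * 12L)
  # sexes recorded on both outputs
  expect_true(all(sim$genotypes$sex %in% c("F", "M")))
})

test_that("simulated datasets round-trip through the on-disk formats", {
  sim <- simulate_metapopulation(small_cfg(seed = 61))
  dir <- withr::local_tempdir()
  write_sim_output(sim, dir)
  aln <- read_fasta_alignment(file.path(dir, "alignment.fasta"))
  expect_equal(as.data.frame(aln), as.data.frame(sim$alignment))
  gt <- read_genotype_table(file.path(dir, "genotypes.csv"))
  expect_equal(as.data.frame(gt), as.data.frame(sim$genotypes))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$seed, 61L)
  expect_equal(truth$config$n_demes, 3L)
})

test_that("male-biased gene flow separates the marker classes (small-scale)", {
  diffs <- vapply(1:3, function(s) {
    cfg <- sim_config(n_demes = 3, n_f = 25, n_m = 25, generations = 80,
                      sample_size = 10, n_loci = 8, seq_length = 200,
                      m_f = 0, m_m = 0.2, seed = 100 + s)
    sim <- simulate_metapopulation(cfg)
    phi <- amova_phist(sim$alignment, n_perm = 0, pairwise = FALSE)$estimate
    th <- wc_fstats(sim$genotypes, n_perm = 0, pairwise = FALSE)$estimate
    phi - th
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("raising male migration at fixed female migration lowers nuclear theta", {
  mean_theta <- function(mm) {
    mean(vapply(1:4, function(s) {
      cfg <- sim_config(n_demes = 3, n_f = 20, n_m = 20, generations = 60,
                        sample_size = 10, n_loci = 6, seq_length = 80,
                        m_f = 0, m_m = mm, founder_pool = "private",
                        founder_alleles = c(4, 6), seed = 300 + s)
      sim <- simulate_metapopulation(cfg)
      wc_fstats(sim$genotypes, n_perm = 0, pairwise = FALSE)$estimate
    }, numeric(1)))
  }
  grid <- c(0.01, 0.1, 0.4)
  thetas <- vapply(grid, mean_theta, numeric(1))
  expect_true(all(diff(thetas) < 0))
})
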