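# Allele summaries, HWE, LD, Bonferroni, Weir-Cockerham and AMOVA.

test_that("allele summaries give exact counts and unbiased gene diversity", {
  gt <- make_gt(list(c("1/2"), c("1/1")), populations = c("P", "P"))
  s <- allele_summary(gt)
  expect_equal(s$N_A, 2L)
  expect_equal(s$H_O, 0.5)
  expect_equal(s$H_E, (4 / 3) * (1 - (9 + 1) / 16)) # = 0.5
  # monomorphic locus
  gt2 <- make_gt(list(c("5/5"), c("5/5")), populations = c("P", "P"))
  s2 <- allele_summary(gt2)
  expect_equal(c(s2$N_A, s2$H_O, s2$H_E), c(1, 0, 0))
  # a fully missing cell is flagged, not fatal, and excluded from means
  gt3 <- make_gt(list(c("1/2", "?"), c("1/1", "?"), c("1/2", "3/4")),
                 populations = c("A", "A", "B"))
  s3 <- allele_summary(gt3)
  expect_equal(s3$n[s3$population == "A" & s3$locus == "L2"], 0L)
  m3 <- allele_summary_means(gt3)
  expect_equal(m3$n_loci[m3$population == "A"], 1L)
})

test_that("HWE chain agrees with full enumeration on biallelic samples", {
  # all-heterozygote sample: genotype counts (0, 5, 0), allele counts (5, 5)
  gt <- make_gt(as.list(rep("1/2", 5)), populations = rep("P", 5))
  oracle_p <- oracle_hwe_biallelic(5, 5)
  res <- hwe_exact_mcmc(gt, "L1", "P", chain = 30000, demem = 100, seed = 2)
  expect_lte(abs(res$p - oracle_p(5)), 3 * res$mc_se + 1e-9)
  # assorted biallelic cases with n <= 6
  cases <- list(
    list(calls = c("1/1", "1/2", "2/2", "1/2"), h = 2),
    list(calls = c("1/1", "1/1", "2/2", "2/2", "1/2", "1/2"), h = 2),
    list(calls = c("1/2", "1/2", "1/1", "1/1", "1/1"), h = 2))
  for (cs in cases) {
    gt <- make_gt(as.list(cs$calls), populations = rep("P", length(cs$calls)))
    n1 <- sum(2 * (cs$calls == "1/1")) + sum(cs$calls == "1/2")
    n2 <- 2 * length(cs$calls) - n1
    oracle_p <- oracle_hwe_biallelic(n1, n2)
    res <- hwe_exact_mcmc(gt, "L1", "P", chain = 30000, demem = 100,
                          seed = 7)
    expect_lte(abs(res$p - oracle_p(cs$h)), 3 * res$mc_se + 1e-9)
  }
})

test_that("HWE handles monomorphic loci and reproduces under a fixed seed", {
  gt <- make_gt(list("3/3", "3/3", "3/3"), populations = rep("P", 3))
  res <- hwe_exact_mcmc(gt, "L1", "P", seed = 1)
  expect_equal(res$p, 1)
  expect_match(res$note, "monomorphic")
  gt2 <- make_gt(list("1/2", "1/1", "2/2", "1/2"), populations = rep("P", 4))
  r1 <- hwe_exact_mcmc(gt2, "L1", "P", chain = 5000, seed = 9)
  r2 <- hwe_exact_mcmc(gt2, "L1", "P", chain = 5000, seed = 9)
  expect_equal(r1$p, r2$p)
})

test_that("LD permutation detects deterministic association and matches enumeration", {
  # locus B a relabeling of locus A -> smallest attainable p
  calls_a <- c("1/1", "1/2", "2/2", "1/1", "2/2", "1/2", "1/1", "2/2")
  calls_b <- c("7/7", "7/8", "8/8", "7/7", "8/8", "7/8", "7/7", "8/8")
  gt <- make_gt(purrr::map2(calls_a, calls_b, c), populations = rep("P", 8))
  res <- ld_permutation(gt, "L1", "L2", "P", n_perm = 500, seed = 1)
  expect_true(res$testable)
  expect_lte(res$p, 0.05)
  # 4 individuals with n_perm = 24: exhaustive enumeration, checked
  # against an independently coded permutation loop
  calls_a <- c("1/1", "1/2", "2/2", "1/2")
  calls_b <- c("7/8", "7/7", "8/8", "8/8")
  gt <- make_gt(purrr::map2(calls_a, calls_b, c), populations = rep("P", 4))
  res <- ld_permutation(gt, "L1", "L2", "P", n_perm = 24)
  expect_true(res$exhaustive)
  g_obs <- oracle_g_stat(calls_a, calls_b)
  g_null <- vapply(oracle_perms(4), function(ix) {
    oracle_g_stat(calls_a, calls_b[ix])
  }, numeric(1))
  expect_equal(res$p, mean(g_null >= g_obs - 1e-9))
  # insufficient data -> not testable
  gt3 <- make_gt(list(c("1/1", "2/2"), c("1/1", "2/3")),
                 populations = c("P", "P"))
  expect_false(ld_permutation(gt3, "L1", "L2", "P")$testable)
})

test_that("LD p-values are roughly uniform for independent loci", {
  # tie-randomized p-values (the standard device for testing uniformity of
  # a discrete permutation test) against a KS check
  set.seed(21)
  ps <- replicate(150, {
    gt <- random_hwe_gt(n_per_pop = 12, n_pops = 1, n_loci = 2,
                        k_alleles = 3)
    res <- ld_permutation(gt, "L1", "L2", "P1", n_perm = 99)
    if (!res$testable) return(NA_real_)
    tol <- 1e-9
    n_gt <- sum(res$null > res$statistic + tol)
    n_eq <- sum(abs(res$null - res$statistic) <= tol)
    (n_gt + runif(1) * (1 + n_eq)) / (res$n_perm + 1)
  })
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Bonferroni decisions use alpha over the number of tests", {
  d <- bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_equal(d$threshold, rep(0.025, 2))
  expect_equal(d$significant, c(TRUE, FALSE))
  expect_true(bonferroni(0.04)$significant) # k = 1 reduces to p <= alpha
  expect_false(any(bonferroni(rep(1, 5))$significant))
})

test_that("Weir-Cockerham components match the indicator-variable ANOVA oracle", {
  # 3 individuals x 2 demes toy
  gt <- make_gt(list("1/2", "1/1", "2/2", "2/2", "2/3", "3/3"),
                populations = rep(c("A", "B"), each = 3))
  res <- wc_fstats(gt, n_perm = 0, pairwise = FALSE)
  oc <- oracle_wc_anova(gt)
  expect_equal(unname(res$components), unname(oc), tolerance = 1e-12)
  expect_equal(res$estimate, oc[["a"]] / sum(oc))
  # larger random fixtures with missing data and >2 demes
  set.seed(13)
  for (i in 1:5) {
    gt <- random_hwe_gt(n_per_pop = 5, n_pops = 3, n_loci = 3, k_alleles = 4)
    gt$a1[sample(nrow(gt), 4)] <- NA
    gt$a2[is.na(gt$a1)] <- NA
    gt <- genotype_table(gt, loci = loci_names(gt))
    res <- wc_fstats(gt, n_perm = 0, pairwise = FALSE)
    oc <- oracle_wc_anova(gt)
    expect_equal(unname(res$components), unname(oc), tolerance = 1e-10)
  }
})

test_that("theta behaves at the boundaries and under relabeling", {
  # two demes fixed for different alleles -> theta = 1
  gt <- make_gt(as.list(rep(c("1/1", "2/2"), each = 3)),
                populations = rep(c("A", "B"), each = 3))
  expect_equal(wc_fstats(gt, n_perm = 0, pairwise = FALSE)$estimate, 1)
  # identical allele frequencies in HWE -> theta near 0, p clearly null
  set.seed(31)
  gt0 <- random_hwe_gt(n_per_pop = 40, n_pops = 2, n_loci = 5,
                       k_alleles = 5, common_freqs = TRUE)
  r0 <- wc_fstats(gt0, n_perm = 199, pairwise = FALSE, seed = 4)
  expect_lt(abs(r0$estimate), 0.05)
  expect_gt(r0$p_value, 0.05)
  # invariance under population and allele relabeling
  gt <- random_hwe_gt(n_per_pop = 8, n_pops = 2, n_loci = 2, k_alleles = 3)
  base <- wc_fstats(gt, n_perm = 0, pairwise = FALSE)$estimate
  relab <- gt
  relab$population <- c(P1 = "Zeta", P2 = "Alpha")[relab$population]
  expect_equal(wc_fstats(genotype_table(relab, loci_names(gt)),
                         n_perm = 0, pairwise = FALSE)$estimate, base)
  recode <- gt
  recode$a1 <- recode$a1 * 10L
  recode$a2 <- recode$a2 * 10L
  expect_equal(wc_fstats(genotype_table(recode, loci_names(gt)),
                         n_perm = 0, pairwise = FALSE)$estimate, base)
})

test_that("multilocus theta with one locus equals the single-locus value", {
  set.seed(17)
  gt <- random_hwe_gt(n_per_pop = 10, n_pops = 2, n_loci = 1, k_alleles = 4)
  multi <- wc_fstats(gt, n_perm = 0, pairwise = FALSE)$estimate
  single <- wc_fstats(genotype_table(gt[gt$locus == "L1", ], "L1"),
                      n_perm = 0, pairwise = FALSE)$estimate
  expect_equal(multi, single)
})

test_that("pairwise theta matrices are symmetric with reproducible p-values", {
  set.seed(19)
  gt <- random_hwe_gt(n_per_pop = 8, n_pops = 3, n_loci = 2, k_alleles = 3)
  r1 <- wc_fstats(gt, n_perm = 99, pairwise = TRUE, seed = 5)
  r2 <- wc_fstats(gt, n_perm = 99, pairwise = TRUE, seed = 5)
  pw <- r1$pairwise
  expect_equal(pw$estimate, t(pw$estimate))
  expect_equal(diag(pw$estimate), rep(0, 3), ignore_attr = TRUE)
  expect_equal(pw$p, r2$pairwise$p)
  expect_true(all(pw$p[lower.tri(pw$p)] >= 1 / 100))
})

test_that("AMOVA matches a brute-force SSD partition and its boundary cases", {
  # two pops of two, each fixed for its own haplotype, d = 1 apart
  aln <- aligned_sequences(tibble::tibble(
    sample_id = paste0("s", 1:4), population = rep(c("A", "B"), each = 2),
    sequence = c("AAAA", "AAAA", "AAAC", "AAAC")))
  r <- amova_phist(aln, n_perm = 0, pairwise = FALSE)
  expect_equal(r$estimate, 1)
  expect_equal(r$sigma_w, 0)
  # all identical -> Phi_ST defined as 0 with a note
  aln0 <- aligned_sequences(tibble::tibble(
    sample_id = paste0("s", 1:4), population = rep(c("A", "B"), each = 2),
    sequence = rep("AAAA", 4)))
  r0 <- amova_phist(aln0, n_perm = 0, pairwise = FALSE)
  expect_equal(r0$estimate, 0)
  expect_match(r0$note, "variance is 0")
  # 3-population toy with unequal sizes vs the brute-force oracle
  set.seed(23)
  aln3 <- random_alignment(n = 7, L = 20, n_pops = 1, p_mut = 0.2)
  aln3$population <- c("A", "A", "B", "B", "C", "C", "C")
  aln3 <- aligned_sequences(aln3)
  r3 <- amova_phist(aln3, n_perm = 0, pairwise = FALSE)
  m <- do.call(rbind, strsplit(aln3$sequence, ""))
  d2 <- matrix(0, 7, 7)
  for (i in 1:6) for (j in (i + 1):7) {
    d2[i, j] <- d2[j, i] <- sum(m[i, ] != m[j, ])
  }
  oc <- oracle_amova(d2, aln3$population)
  expect_equal(r3$estimate, oc$phi, tolerance = 1e-12)
  expect_equal(r3$sigma_a, oc$sigma_a, tolerance = 1e-12)
  expect_equal(r3$sigma_w, oc$sigma_w, tolerance = 1e-12)
})

test_that("AMOVA accepts a precomputed distance matrix and permutes reproducibly", {
  d2 <- matrix(c(0, 0, 3, 3,
                 0, 0, 3, 3,
                 3, 3, 0, 0,
                 3, 3, 0, 0), 4, 4,
               dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  pops <- rep(c("A", "B"), each = 2)
  r1 <- amova_phist(dist = d2, populations = pops, n_perm = 99, seed = 3,
                    pairwise = FALSE)
  r2 <- amova_phist(dist = d2, populations = pops, n_perm = 99, seed = 3,
                    pairwise = FALSE)
  expect_equal(r1$estimate, 1)
  expect_equal(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100) # add-one rule: never zero
})
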