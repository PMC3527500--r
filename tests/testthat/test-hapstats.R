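# Haplotype collapsing and Nei diversity indices.

test_that("collapsing merges identical sequences and windows can create redundancy", {
  # two sequences differing only at site 400: distinct over the full 410 bp,
  # one haplotype once the comparison window stops at 361 bp
  s1 <- strrep("A", 410)
  s2 <- paste0(strrep("A", 399), "C", strrep("A", 10))
  aln <- aligned_sequences(tibble::tibble(
    sample_id = c("x1", "x2"), population = "P", sequence = c(s1, s2)))
  expect_equal(nrow(collapse_haplotypes(aln)), 2L)
  expect_equal(nrow(collapse_haplotypes(aln, window = c(1, 361))), 1L)
  expect_error(collapse_haplotypes(aln, window = c(0, 361)), "window")

  # n identical sequences -> one haplotype of count n
  aln2 <- aligned_sequences(tibble::tibble(
    sample_id = paste0("s", 1:4), population = "P",
    sequence = strrep("ACGT", 5)))
  h2 <- collapse_haplotypes(aln2)
  expect_equal(h2$P, 4L)

  # 5 sequences, 4 distinct -> counts (2,1,1,1)
  seqs <- c("AAAA", "AAAA", "AAAC", "AACC", "ACCC")
  aln3 <- aligned_sequences(tibble::tibble(
    sample_id = paste0("s", 1:5), population = "P", sequence = seqs))
  h3 <- collapse_haplotypes(aln3)
  expect_equal(sort(h3$P, decreasing = TRUE), c(2L, 1L, 1L, 1L))
})

test_that("gapped or ambiguous columns are masked from haplotype identity", {
  aln <- aligned_sequences(tibble::tibble(
    sample_id = c("a", "b"), population = "P",
    sequence = c("ACGT", "ACG-")))   # differ only in a masked column
  expect_equal(nrow(collapse_haplotypes(aln)), 1L)
})

test_that("windowed collapse never increases the number of haplotypes", {
  set.seed(7)
  for (i in 1:20) {
    aln <- random_alignment(n = 8, L = 30, n_pops = 1, p_mut = 0.15)
    h_full <- nrow(collapse_haplotypes(aln))
    w <- sort(sample(30, 2))
    h_win <- nrow(collapse_haplotypes(aln, window = w))
    expect_lte(h_win, h_full)
  }
})

test_that("haplotype diversity matches the published estimator on forced counts", {
  # counts forced by n and h: (1,1), (2,1), (2,1,1,1)
  meta <- haplotype_diversity(c(1, 1))
  expect_equal(round(meta$value, 3), 1.000)
  expect_equal(round(meta$sd, 3), 0.500)
  orinoco <- haplotype_diversity(c(2, 1))
  expect_equal(round(orinoco$value, 3), 0.667)
  expect_equal(round(orinoco$sd, 3), 0.314)
  napo <- haplotype_diversity(c(2, 1, 1, 1))
  expect_equal(round(napo$value, 3), 0.900)
  expect_equal(round(napo$sd, 3), 0.161)
  # monomorphic sample and undefined estimator
  mono <- haplotype_diversity(c(7))
  expect_equal(mono$value, 0)
  expect_equal(mono$sd, 0)
  expect_error(haplotype_diversity(c(1)), "n >= 2")
})

test_that("Hd is label-invariant and maximal for all-singleton configurations", {
  expect_equal(haplotype_diversity(c(5, 3, 2))$value,
               haplotype_diversity(c(2, 5, 3))$value)
  # exhaustive over all count compositions for n <= 8
  compositions <- function(n) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (first in seq_len(n)) {
      for (rest in compositions(n - first)) {
        if (length(rest) == 0 || first >= rest[1]) {
          out[[length(out) + 1]] <- c(first, rest)
        }
      }
    }
    out
  }
  for (n in 2:8) {
    vals <- vapply(compositions(n),
                   function(cc) haplotype_diversity(cc)$value, numeric(1))
    singletons <- haplotype_diversity(rep(1, n))$value
    expect_equal(max(vals), singletons)
    expect_equal(singletons, 1) # n/(n-1) * (1 - n * (1/n)^2)
  }
})

test_that("nucleotide diversity matches direct pairwise counting and its variance", {
  # identical sequences
  aln0 <- aligned_sequences(tibble::tibble(
    sample_id = c("a", "b"), population = "P",
    sequence = strrep("A", 410)))
  expect_equal(nucleotide_diversity(aln0)$value, 0)
  # 2 sequences, 1 difference over 410 bp
  aln1 <- aligned_sequences(tibble::tibble(
    sample_id = c("a", "b"), population = "P",
    sequence = c(strrep("A", 410), paste0("C", strrep("A", 409)))))
  r1 <- nucleotide_diversity(aln1)
  expect_equal(round(r1$value, 4), 0.2439)
  expect_equal(round(r1$sd, 3), 0.345)
  # 3 sequences, two identical, third differing at 2 of 410 sites
  aln2 <- aligned_sequences(tibble::tibble(
    sample_id = c("a", "b", "c"), population = "P",
    sequence = c(strrep("A", 410), strrep("A", 410),
                 paste0("CC", strrep("A", 408)))))
  r2 <- nucleotide_diversity(aln2)
  expect_equal(round(r2$value, 4), 0.3252)
  expect_equal(round(r2$sd, 3), 0.334)
  expect_error(nucleotide_diversity(aln0[1, ]), "n >= 2")
})

test_that("pairwise pi equals the per-site frequency oracle on random alignments", {
  set.seed(11)
  for (i in 1:10) {
    aln <- random_alignment(n = sample(3:7, 1), L = 25, n_pops = 1,
                            p_mut = 0.2)
    n <- nrow(aln)
    m <- do.call(rbind, strsplit(aln$sequence, ""))
    # oracle: average over sites of the unequal-pair fraction
    per_site <- apply(m, 2, function(col) {
      cc <- table(col)
      (n^2 - sum(cc^2)) / (n * (n - 1))
    })
    expect_equal(nucleotide_diversity(aln)$value / 100, mean(per_site))
  }
})

test_that("the per-population diversity table assembles n, h, pi and Hd", {
  aln <- aligned_sequences(tibble::tibble(
    sample_id = paste0("s", 1:5),
    population = c("A", "A", "A", "B", "B"),
    sequence = c("AAAA", "AAAC", "AAAA", "CCCC", "CCCC")))
  tab <- diversity_table(aln)
  expect_equal(tab$n, c(3L, 2L))
  expect_equal(tab$h, c(2L, 1L))
  expect_equal(round(tab$Hd[1], 3), 0.667)
  expect_equal(tab$Hd[2], 0)
  expect_equal(tab$pi_pct[2], 0)
})
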