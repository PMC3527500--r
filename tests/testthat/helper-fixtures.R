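# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures.

# quick long-form genotype table: `calls` is a list of per-individual
# character vectors like c("1/2", "?", "3/3"), one element per locus
make_gt <- function(calls, populations, loci = NULL, sex = NULL) {
  n <- length(calls)
  loci <- loci %||% sprintf("L%d", seq_along(calls[[1]]))
  sex <- sex %||% rep(NA_character_, n)
  rows <- purrr::imap_dfr(calls, function(g, i) {
    parts <- strsplit(ifelse(g %in% c("?", ""), "NA/NA", g), "/")
    tibble::tibble(
      sample_id = sprintf("ind%02d", i),
      population = populations[i],
      sex = sex[i],
      locus = loci,
      a1 = suppressWarnings(as.integer(vapply(parts, `[`, "", 1))),
      a2 = suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    )
  })
  genotype_table(rows, loci = loci)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random genotype table under Hardy-Weinberg within each population:
# allele frequencies drawn per (population, locus)
random_hwe_gt <- function(n_per_pop, n_pops = 2, n_loci = 3, k_alleles = 4,
                          common_freqs = FALSE) {
  pops <- sprintf("P%d", seq_len(n_pops))
  shared <- lapply(seq_len(n_loci), function(l) {
    p <- stats::runif(k_alleles)
    p / sum(p)
  })
  ids <- sprintf("i%03d", seq_len(n_pops * n_per_pop))
  pop_of <- rep(pops, each = n_per_pop)
  gt <- tidyr::expand_grid(sample_id = ids,
                           locus = sprintf("L%d", seq_len(n_loci)))
  gt$population <- pop_of[match(gt$sample_id, ids)]
  gt$sex <- NA_character_
  gt$a1 <- NA_integer_
  gt$a2 <- NA_integer_
  # fill alleles: per population x locus frequencies (or shared)
  for (pp in pops) {
    for (l in sprintf("L%d", seq_len(n_loci))) {
      sel <- gt$population == pp & gt$locus == l
      n <- sum(sel)
      p <- if (common_freqs) shared[[match(l, sprintf("L%d", seq_len(n_loci)))]] else {
        q <- stats::runif(k_alleles); q / sum(q)
      }
      a <- matrix(sample.int(k_alleles, 2 * n, replace = TRUE, prob = p), n, 2)
      gt$a1[sel] <- pmin(a[, 1], a[, 2])
      gt$a2[sel] <- pmax(a[, 1], a[, 2])
    }
  }
  genotype_table(gt, loci = sprintf("L%d", seq_len(n_loci)))
}

# small random alignment over ACGT
random_alignment <- function(n, L, n_pops = 2, p_mut = 0.05) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    flip <- stats::runif(L) < p_mut
    s[flip] <- vapply(s[flip], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(s, collapse = "")
  }, character(1))
  aligned_sequences(tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    population = sprintf("P%d", rep_len(seq_len(n_pops), n)),
    sequence = seqs))
}
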