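# Independent oracles used to validate the analysis code: brute-force or
# closed-form routes that never share code with the implementation.

# Weir-Cockerham variance components via the nested ANOVA on allele
# indicator variables (one indicator per allele; gene copies nested in
# individuals nested in populations). Returns summed a, b, c.
oracle_wc_anova <- function(gt, pops = NULL) {
  gt <- genotype_table(gt, loci = loci_names(gt))
  pops <- pops %||% unique(gt$population)
  gt <- gt[gt$population %in% pops, ]
  total <- c(a = 0, b = 0, c = 0)
  for (l in loci_names(gt)) {
    sub <- gt[gt$locus == l & !is.na(gt$a1), ]
    if (nrow(sub) == 0) next
    alleles <- sort(unique(c(sub$a1, sub$a2)))
    if (length(alleles) < 2) next
    pop <- factor(sub$population, levels = pops)
    pop <- droplevels(pop)
    r <- nlevels(pop)
    n_i <- as.numeric(table(pop))
    if (any(n_i < 1) || mean(n_i) <= 1) next
    N <- sum(n_i)
    nc <- if (r >= 2) (N - sum(n_i^2) / N) / (r - 1) else 1
    for (A in alleles) {
      # gene-copy indicator matrix: rows = individuals, 2 copies each
      x <- cbind(as.numeric(sub$a1 == A), as.numeric(sub$a2 == A))
      ybar_ind <- rowMeans(x)
      ybar_pop <- tapply(ybar_ind, pop, mean)
      ybar <- mean(c(x))
      # sums of squares: among pops, among individuals within pops,
      # within individuals (each individual contributes 2 gene copies)
      ss_p <- sum(2 * n_i * (ybar_pop - ybar)^2)
      ss_i <- sum(2 * (ybar_ind - ybar_pop[as.integer(pop)])^2)
      ss_g <- sum((x - ybar_ind)^2)
      ms_p <- if (r >= 2) ss_p / (r - 1) else 0
      ms_i <- ss_i / (N - r)
      ms_g <- ss_g / N
      sigma_g <- ms_g
      sigma_i <- (ms_i - ms_g) / 2
      sigma_p <- if (r >= 2) (ms_p - ms_i) / (2 * nc) else 0
      total <- total + c(a = sigma_p, b = sigma_i, c = sigma_g)
    }
  }
  total
}

# AMOVA sums of squares by direct double loops over individuals.
oracle_amova <- function(d2, pop) {
  n <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ssd_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) ssd_tot <- ssd_tot + d2[i, j]
  ssd_tot <- ssd_tot / (2 * n)
  ssd_w <- 0
  for (g in pops) {
    rows <- which(pop == g)
    s <- 0
    for (i in rows) for (j in rows) s <- s + d2[i, j]
    ssd_w <- ssd_w + s / (2 * length(rows))
  }
  n_i <- as.numeric(table(factor(pop, levels = pops)))
  sigma_w <- ssd_w / (n - P)
  nbar <- (n - sum(n_i^2) / n) / (P - 1)
  sigma_a <- ((ssd_tot - ssd_w) / (P - 1) - sigma_w) / nbar
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phi = sigma_a / (sigma_a + sigma_w))
}

# Exact HWE p-value for a biallelic sample by full enumeration over
# heterozygote counts, under Levene's conditional distribution.
oracle_hwe_biallelic <- function(n1, n2) {
  n <- (n1 + n2) / 2
  hs <- seq(n1 %% 2, min(n1, n2), by = 2)
  logw <- vapply(hs, function(h) {
    naa <- (n1 - h) / 2
    nbb <- (n2 - h) / 2
    lfactorial(n) + h * log(2) -
      lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }, numeric(1))
  w <- exp(logw - max(logw))
  p_tab <- w / sum(w)
  function(h_obs) sum(p_tab[w <= w[hs == h_obs] * (1 + 1e-9)])
}

# Exact one-sided heterozygote-deficit p for re-pairing 2 individuals with
# allele pool {x, x, y, y}: of the 3 perfect pairings, 1 has 0 heterozygotes.
oracle_repair_p_2ind <- 1 / 3

# Spearman correlation of the lower triangles of two matrices (own route,
# via explicit average ranks).
oracle_spearman_lower <- function(m1, m2) {
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    })
  }
  r1 <- avg_rank(v1)
  r2 <- avg_rank(v2)
  sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
}

# all permutations of 1..n via recursion (independent of the package's)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# G statistic of a two-way contingency table, written independently
oracle_g_stat <- function(xa, xb) {
  tab <- table(xa, xb)
  n <- sum(tab)
  g <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      o <- tab[i, j]
      if (o > 0) {
        e <- sum(tab[i, ]) * sum(tab[, j]) / n
        g <- g + 2 * o * log(o / e)
      }
    }
  }
  g
}
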