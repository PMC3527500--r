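# Per-locus summaries, exact HWE Markov-chain test, LD permutation test,
# Weir-Cockerham F-statistics and AMOVA Phi-ST with permutation p-values.

#' Allele frequency and heterozygosity summary
#'
#' Per (population, locus): number of distinct alleles `N_A`, observed
#' heterozygosity `H_O` (fraction of non-missing individuals that are
#' heterozygous) and unbiased expected heterozygosity
#' \eqn{H_E = \frac{2n}{2n-1}(1 - \sum_i p_i^2)} computed over the `2n`
#' sampled gene copies. Cells with no genotyped individual are flagged
#' (`n = 0`) rather than dropped.
#'
#' @param gt A [genotype_table()].
#'
#' @return A tibble with columns `population`, `locus`, `n`, `N_A`, `H_O`,
#'   `H_E`.
#' @export
allele_summary <- function(gt) {
  gt <- genotype_table(gt, loci = loci_names(gt))
  pops <- unique(gt$population)
  grid <- tidyr::expand_grid(population = pops, locus = loci_names(gt))
  purrr::pmap_dfr(grid, function(population, locus) {
    sub <- gt[gt$population == population & gt$locus == locus &
                !is.na(gt$a1), , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) {
      return(tibble(population = population, locus = locus, n = 0L,
                    N_A = NA_integer_, H_O = NA_real_, H_E = NA_real_))
    }
    alleles <- c(sub$a1, sub$a2)
    p <- as.numeric(table(alleles)) / (2 * n)
    h_o <- mean(sub$a1 != sub$a2)
    h_e <- if (2 * n > 1) (2 * n) / (2 * n - 1) * (1 - sum(p^2)) else 0
    tibble(population = population, locus = locus, n = n,
           N_A = length(p), H_O = h_o, H_E = h_e)
  })
}

#' Per-population means of the per-locus summaries
#'
#' Means (with SDs) across loci of `N_A`, `H_O` and `H_E`, excluding cells
#' with no genotyped individuals.
#'
#' @param gt A [genotype_table()].
#'
#' @return A tibble, one row per population.
#' @export
allele_summary_means <- function(gt) {
  allele_summary(gt) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      mean_N_A = mean(.data$N_A), sd_N_A = sd(.data$N_A),
      mean_H_O = mean(.data$H_O), sd_H_O = sd(.data$H_O),
      mean_H_E = mean(.data$H_E), sd_H_E = sd(.data$H_E),
      .groups = "drop"
    )
}

# ---- exact HWE test -------------------------------------------------------

# log Levene weight of a genotype-count state, up to the constant shared by
# all tables with the same allele counts: H*log(2) - sum(lgamma(g_ij + 1)).
# Tracked incrementally along the chain.
hwe_log_weight <- function(gmat) {
  het <- sum(gmat[upper.tri(gmat)])
  het * log(2) - sum(lgamma(gmat + 1))
}

#' Exact Hardy-Weinberg test by Markov chain Monte Carlo
#'
#' Estimates the exact (Levene conditional) p-value for departure from
#' Hardy-Weinberg genotype proportions at one locus in one population. The
#' chain re-pairs the observed allele pool: its state is a perfect pairing
#' of the 2n sampled gene copies, a symmetric swap proposal leaves the
#' uniform distribution over pairings invariant, and uniform pairings
#' induce exactly Levene's conditional distribution on genotype tables.
#' The p-value is the chain frequency of tables no more probable than the
#' observed one.
#'
#' @param gt A [genotype_table()].
#' @param locus,population Which cell to test.
#' @param chain Markov chain length (post-dememorization samples).
#' @param demem Burn-in steps discarded before sampling.
#' @param seed Optional integer seed.
#'
#' @return A one-row tibble of class `hwe_result`: `locus`, `population`,
#'   `p`, `mc_se` (batch-means Monte Carlo standard error), `chain`,
#'   `demem`, `n`, `k` (allele count), `note`, `seed`.
#' @export
hwe_exact_mcmc <- function(gt, locus, population, chain = 100000,
                           demem = 100, seed = NULL) {
  stopifnot(chain > demem)
  gt <- genotype_table(gt, loci = loci_names(gt))
  sub <- gt[gt$locus == locus & gt$population == population &
              !is.na(gt$a1), , drop = FALSE]
  n <- nrow(sub)
  if (n < 2) abort("HWE test needs >= 2 genotyped individuals")
  alleles <- sort(unique(c(sub$a1, sub$a2)))
  k <- length(alleles)
  res <- function(p, se, note) {
    structure(tibble(locus = locus, population = population, p = p,
                     mc_se = se, chain = as.integer(chain),
                     demem = as.integer(demem), n = n, k = k, note = note,
                     seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
              class = c("hwe_result", class(tibble())))
  }
  if (k == 1) return(res(1, 0, "monomorphic locus: p = 1 by convention"))

  a1 <- match(sub$a1, alleles)
  a2 <- match(sub$a2, alleles)
  pool <- c(rbind(a1, a2)) # pairs at positions (2i-1, 2i)

  with_seed(seed, {
    g <- matrix(0L, k, k)
    for (i in seq_len(n)) {
      lo <- min(a1[i], a2[i]); hi <- max(a1[i], a2[i])
      g[lo, hi] <- g[lo, hi] + 1L
    }
    logw_obs <- hwe_log_weight(g)
    logw <- logw_obs
    state <- pool
    hits <- logical(chain)
    tol <- 1e-9
    total <- chain + demem
    # pre-draw proposal randomness in blocks for speed
    pick <- matrix(sample.int(n, 2L * total, replace = TRUE), ncol = 2)
    same <- pick[, 1] == pick[, 2]
    while (any(same)) {
      pick[same, 2] <- sample.int(n, sum(same), replace = TRUE)
      same <- pick[, 1] == pick[, 2]
    }
    side <- sample.int(2L, total, replace = TRUE)
    for (t in seq_len(total)) {
      i <- pick[t, 1]; j <- pick[t, 2]
      pi1 <- 2L * i - 1L; pi2 <- 2L * i
      pj1 <- 2L * j - 1L; pj2 <- 2L * j
      # genotypes before swap
      ia <- state[pi1]; ib <- state[pi2]
      ja <- state[pj1]; jb <- state[pj2]
      if (side[t] == 1L) { # swap second members
        na1 <- ia; na2 <- jb; nb1 <- ja; nb2 <- ib
      } else {             # swap crosswise
        na1 <- ia; na2 <- ja; nb1 <- ib; nb2 <- jb
      }
      # update table: remove (ia,ib),(ja,jb); add (na1,na2),(nb1,nb2)
      g[min(ia, ib), max(ia, ib)] <- g[min(ia, ib), max(ia, ib)] - 1L
      g[min(ja, jb), max(ja, jb)] <- g[min(ja, jb), max(ja, jb)] - 1L
      g[min(na1, na2), max(na1, na2)] <- g[min(na1, na2), max(na1, na2)] + 1L
      g[min(nb1, nb2), max(nb1, nb2)] <- g[min(nb1, nb2), max(nb1, nb2)] + 1L
      state[pi1] <- na1; state[pi2] <- na2
      state[pj1] <- nb1; state[pj2] <- nb2
      logw <- (n - sum(g[cbind(1:k, 1:k)])) * log(2) - sum(lgamma(g + 1))
      if (t > demem) hits[t - demem] <- logw <= logw_obs + tol
    }
    p_hat <- mean(hits)
    nb <- 50L
    bsize <- chain %/% nb
    bm <- vapply(seq_len(nb), function(b) {
      mean(hits[((b - 1) * bsize + 1):(b * bsize)])
    }, numeric(1))
    se <- sd(bm) / sqrt(nb)
    res(p_hat, se, NA_character_)
  })
}

# ---- LD permutation test --------------------------------------------------

g_statistic <- function(xa, xb) {
  tab <- table(xa, xb)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

#' Linkage-disequilibrium permutation test for a locus pair
#'
#' Tests association between the genotype classes of two loci within one
#' population with a log-likelihood-ratio (G) statistic on the two-locus
#' genotype contingency table. The null distribution permutes one locus's
#' genotypes among individuals; when all `n!` permutations number no more
#' than `n_perm` they are enumerated exactly, otherwise `n_perm` random
#' permutations are drawn and the add-one rule applied.
#'
#' @param gt A [genotype_table()].
#' @param locus_a,locus_b Locus names.
#' @param population Population to test within.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#'
#' @return A list of class `ld_result`: `statistic`, `p`, `n_perm`,
#'   `exhaustive`, `n`, `testable`, plus identifiers.
#' @export
ld_permutation <- function(gt, locus_a, locus_b, population,
                           n_perm = 10000, seed = NULL) {
  gt <- genotype_table(gt, loci = loci_names(gt))
  sub <- gt[gt$population == population &
              gt$locus %in% c(locus_a, locus_b), , drop = FALSE]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(sub, geno = paste0(.data$a1, "/", .data$a2)),
    id_cols = "sample_id", names_from = "locus", values_from = "geno")
  ok <- !is.na(wide[[locus_a]]) & wide[[locus_a]] != "NA/NA" &
    !is.na(wide[[locus_b]]) & wide[[locus_b]] != "NA/NA"
  xa <- wide[[locus_a]][ok]
  xb <- wide[[locus_b]][ok]
  n <- length(xa)
  base <- list(locus_a = locus_a, locus_b = locus_b,
               population = population, n = n,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (n < 3 || length(unique(xa)) < 2 || length(unique(xb)) < 2) {
    return(structure(c(base, list(statistic = NA_real_, p = NA_real_,
                                  n_perm = 0L, exhaustive = FALSE,
                                  testable = FALSE)),
                     class = "ld_result"))
  }
  g_obs <- g_statistic(xa, xb)
  tol <- 1e-9
  if (n <= 8 && factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    g_null <- apply(perms, 1, function(ix) g_statistic(xa, xb[ix]))
    p <- mean(g_null >= g_obs - tol)
    out <- list(statistic = g_obs, p = p, n_perm = nrow(perms),
                null = g_null, exhaustive = TRUE, testable = TRUE)
  } else {
    g_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      g_statistic(xa, xb[sample.int(n)])
    }, numeric(1)))
    p <- perm_pvalue(sum(g_null >= g_obs - tol), n_perm)
    out <- list(statistic = g_obs, p = p, n_perm = as.integer(n_perm),
                null = g_null, exhaustive = FALSE, testable = TRUE)
  }
  structure(c(base, out), class = "ld_result")
}

#' Bonferroni multiple-testing decisions
#'
#' Declares test `i` significant iff `p[i] <= alpha / k` with `k` the
#' number of tests.
#'
#' @param p Vector of p-values.
#' @param alpha Family-wise significance level.
#'
#' @return A tibble: `p`, `threshold`, `significant`, `k`.
#' @export
#' @examples
#' bonferroni(c(0.01, 0.04))
bonferroni <- function(p, alpha = 0.05) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  k <- length(p)
  tibble(p = p, threshold = alpha / k,
         significant = !is.na(p) & p <= alpha / k, k = k)
}
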