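# Weir-Cockerham variance-component F-statistics and AMOVA Phi-ST, with
# permutation tests. Core routines work on pre-extracted integer vectors so
# permutation loops stay cheap.

# Extract fast per-locus structures from a genotype table restricted to
# `pops`: for each locus, the indices of genotyped individuals and their
# recoded allele pair; plus the individual -> population map.
prep_loci <- function(gt, pops = NULL) {
  gt <- genotype_table(gt, loci = loci_names(gt))
  pops <- pops %||% unique(gt$population)
  gt <- gt[gt$population %in% pops, , drop = FALSE]
  if (nrow(gt) == 0) abort("no individuals in the requested populations")
  ids <- unique(gt$sample_id)
  ind_pop <- match(gt$population[match(ids, gt$sample_id)], pops)
  loci <- loci_names(gt)
  per_locus <- lapply(loci, function(l) {
    sub <- gt[gt$locus == l & !is.na(gt$a1), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    codes <- sort(unique(c(sub$a1, sub$a2)))
    list(idx = match(sub$sample_id, ids),
         al = cbind(match(sub$a1, codes), match(sub$a2, codes)),
         k = length(codes))
  })
  names(per_locus) <- loci
  list(pops = pops, ids = ids, ind_pop = ind_pop,
       loci = per_locus[!vapply(per_locus, is.null, logical(1))])
}

# Weir-Cockerham (1984) a, b, c sums over alleles for one locus.
# al: m x 2 matrix of recoded alleles; popl: population index per row;
# r: number of populations in the analysis.
wc_locus_components <- function(al, popl, r, k) {
  n_i <- tabulate(popl, r)
  present <- n_i > 0
  if (sum(present) < r) {
    # reindex to populations with data at this locus
    map <- cumsum(present)
    popl <- map[popl]
    n_i <- n_i[present]
    r <- length(n_i)
  }
  if (k < 2) return(c(a = 0, b = 0, c = 0))
  N <- sum(n_i)
  nbar <- N / r
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  counts <- matrix(
    tabulate(popl + r * (al[, 1] - 1L), r * k) +
      tabulate(popl + r * (al[, 2] - 1L), r * k), r, k)
  p <- counts / (2 * n_i)
  het <- al[, 1] != al[, 2]
  hcount <- matrix(
    tabulate(popl[het] + r * (al[het, 1] - 1L), r * k) +
      tabulate(popl[het] + r * (al[het, 2] - 1L), r * k), r, k)
  h <- hcount / n_i
  pbar <- colSums(n_i * p) / N
  hbar <- colSums(n_i * h) / N
  if (r >= 2) {
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    s2 <- colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  } else {
    nc <- 1
    s2 <- rep(0, k)
  }
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- if (r >= 2) nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1)) else rep(0, k)
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

# Multilocus component sums for a given individual -> population map.
wc_components <- function(prep, ind_pop = NULL, which_loci = NULL) {
  ind_pop <- ind_pop %||% prep$ind_pop
  r <- length(prep$pops)
  loci <- prep$loci
  if (!is.null(which_loci)) loci <- loci[which_loci]
  comp <- vapply(loci, function(ld) {
    wc_locus_components(ld$al, ind_pop[ld$idx], r, ld$k)
  }, numeric(3))
  comp <- comp[, !apply(is.na(comp), 2, any), drop = FALSE]
  rowSums(comp)
}

theta_from_components <- function(comp) {
  denom <- comp[["a"]] + comp[["b"]] + comp[["c"]]
  if (denom == 0) return(0)
  comp[["a"]] / denom
}

fis_from_components <- function(comp) {
  denom <- comp[["b"]] + comp[["c"]]
  if (denom == 0) return(0)
  1 - comp[["c"]] / denom
}

#' Weir-Cockerham F-statistics with permutation tests
#'
#' Multilocus theta (F_ST) and F_IS from Weir & Cockerham (1984) variance
#' components, summed over alleles and loci. The permutation p-value for
#' theta reassigns whole multilocus individuals among populations (keeping
#' within-individual disequilibrium intact); the p-value for F_IS re-pairs
#' alleles among individuals within each population at each locus.
#' Negative component estimates are retained, so estimates slightly below
#' zero are possible, as in the usual variance-component convention.
#'
#' @param gt A [genotype_table()].
#' @param populations Populations to include (default: all, input order).
#' @param n_perm Permutations for each test (0 skips the tests).
#' @param pairwise Also compute the pairwise theta matrix with per-pair
#'   permutation p-values?
#' @param seed Optional integer seed.
#'
#' @return An object of class `fstat_result`: estimates, per-statistic
#'   permutation p-values, component sums, and (optionally) a
#'   [pairwise_matrix()] of pairwise theta under `$pairwise`.
#' @export
wc_fstats <- function(gt, populations = NULL, n_perm = 999,
                      pairwise = TRUE, seed = NULL) {
  prep <- prep_loci(gt, populations)
  r <- length(prep$pops)
  comp <- wc_components(prep)
  theta <- if (r >= 2) theta_from_components(comp) else NA_real_
  fis <- fis_from_components(comp)
  fit <- {
    denom <- sum(comp)
    if (denom == 0) 0 else 1 - comp[["c"]] / denom
  }

  p_theta <- p_fis <- NA_real_
  if (n_perm > 0) {
    with_seed(seed, {
      if (r >= 2) {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          perm <- sample(prep$ind_pop)
          if (theta_from_components(wc_components(prep, perm)) >=
              theta - 1e-12) hits <- hits + 1L
        }
        p_theta <- perm_pvalue(hits, n_perm)
      }
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (fis_from_components(wc_components(shuffle_within_pops(prep))) >=
            fis - 1e-12) hits <- hits + 1L
      }
      p_fis <- perm_pvalue(hits, n_perm)
    })
  }

  pw <- NULL
  if (pairwise && r >= 2) {
    pw <- pairwise_theta(prep, n_perm = n_perm, seed = seed)
  }
  structure(
    list(statistic = "F_ST", estimate = theta, fis = fis, fit = fit,
         components = comp, p_value = p_theta, p_fis = p_fis,
         n_perm = as.integer(n_perm), populations = prep$pops,
         n_individuals = length(prep$ids), n_loci = length(prep$loci),
         pairwise = pw,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "fstat_result")
}

# Re-pair alleles uniformly within each (population, locus) cell; returns a
# prep whose allele pairs are permuted but whose allele pools per cell are
# conserved. Used by the F_IS permutation null.
shuffle_within_pops <- function(prep) {
  out <- prep
  for (l in seq_along(prep$loci)) {
    ld <- prep$loci[[l]]
    popl <- prep$ind_pop[ld$idx]
    al <- ld$al
    for (pp in unique(popl)) {
      rows <- which(popl == pp)
      pool <- sample(c(al[rows, 1], al[rows, 2]))
      al[rows, ] <- matrix(pool, ncol = 2)
    }
    out$loci[[l]]$al <- al
  }
  out
}

#' Pairwise population matrix of estimates and p-values
#'
#' Container for a symmetric matrix of pairwise structure estimates with a
#' companion matrix of permutation p-values.
#'
#' @param estimate Symmetric numeric matrix with population dimnames.
#' @param p Matrix of p-values, same shape (may be all `NA`).
#' @param statistic Name of the statistic (`"F_ST"`, `"Phi_ST"`, ...).
#' @param n_perm Number of permutations behind `p`.
#' @param seed Seed used, if any.
#'
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(estimate, p = NULL, statistic = "F_ST",
                            n_perm = NA_integer_, seed = NA_integer_) {
  stopifnot(is.matrix(estimate), nrow(estimate) == ncol(estimate))
  if (is.null(rownames(estimate))) {
    abort("estimate matrix needs population dimnames")
  }
  if (max(abs(estimate - t(estimate)), na.rm = TRUE) > 1e-8) {
    abort("estimate matrix must be symmetric")
  }
  diag(estimate) <- 0
  if (is.null(p)) p <- matrix(NA_real_, nrow(estimate), ncol(estimate),
                              dimnames = dimnames(estimate))
  structure(list(labels = rownames(estimate), estimate = estimate, p = p,
                 statistic = statistic, n_perm = n_perm, seed = seed),
            class = "pairwise_matrix")
}

#' Build a pairwise matrix from a long pair table
#'
#' Convenience constructor for published or externally computed pairwise
#' estimates: a long table with one row per population pair becomes a
#' symmetric [pairwise_matrix()].
#'
#' @param df Data frame with columns `pop1`, `pop2` and the value column.
#' @param value Name of the value column (default `"estimate"`).
#' @param p Optional name of a p-value column.
#' @param statistic Statistic label.
#' @param labels Optional population ordering; defaults to first
#'   appearance.
#'
#' @return A [pairwise_matrix()].
#' @export
pairwise_from_pairs <- function(df, value = "estimate", p = NULL,
                                statistic = value, labels = NULL) {
  df <- as_tibble(df)
  stopifnot(all(c("pop1", "pop2", value) %in% names(df)))
  labels <- labels %||% unique(c(rbind(df$pop1, df$pop2)))
  k <- length(labels)
  est <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(est) <- 0
  pm <- est
  diag(pm) <- NA_real_
  i <- match(df$pop1, labels)
  j <- match(df$pop2, labels)
  if (anyNA(i) || anyNA(j)) abort("pair labels not all present in `labels`")
  est[cbind(i, j)] <- est[cbind(j, i)] <- df[[value]]
  if (!is.null(p)) pm[cbind(i, j)] <- pm[cbind(j, i)] <- df[[p]]
  if (anyNA(est[lower.tri(est)])) abort("missing pairs: matrix incomplete")
  pairwise_matrix(est, pm, statistic = statistic)
}

# Pairwise multilocus theta over all population pairs of a prep.
pairwise_theta <- function(prep, n_perm = 999, seed = NULL) {
  pops <- prep$pops
  r <- length(pops)
  est <- p <- matrix(NA_real_, r, r, dimnames = list(pops, pops))
  diag(est) <- 0
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      keep <- prep$ind_pop %in% c(i, j)
      if (!any(prep$ind_pop == i) || !any(prep$ind_pop == j)) next
      sub <- subset_prep(prep, keep, c(i, j))
      comp <- wc_components(sub)
      th <- theta_from_components(comp)
      est[i, j] <- est[j, i] <- th
      if (n_perm > 0) {
        pv <- with_seed(seed, {
          hits <- 0L
          for (b in seq_len(n_perm)) {
            perm <- sample(sub$ind_pop)
            if (theta_from_components(wc_components(sub, perm)) >=
                th - 1e-12) hits <- hits + 1L
          }
          perm_pvalue(hits, n_perm)
        })
        p[i, j] <- p[j, i] <- pv
      }
    }
  }
  pairwise_matrix(est, p, statistic = "F_ST", n_perm = as.integer(n_perm),
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# Restrict a prep to a logical individual filter, renumbering populations.
subset_prep <- function(prep, keep, pop_sel) {
  new_ids <- which(keep)
  out <- list(pops = prep$pops[pop_sel], ids = prep$ids[keep],
              ind_pop = match(prep$ind_pop[keep], pop_sel))
  out$loci <- lapply(prep$loci, function(ld) {
    rows <- ld$idx %in% new_ids
    if (!any(rows)) return(NULL)
    list(idx = match(ld$idx[rows], new_ids),
         al = ld$al[rows, , drop = FALSE], k = ld$k)
  })
  out$loci <- out$loci[!vapply(out$loci, is.null, logical(1))]
  out
}

# ---- AMOVA ----------------------------------------------------------------

amova_from_d2 <- function(d2, pop_idx, P) {
  N <- length(pop_idx)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- 0
  n_i <- tabulate(pop_idx, P)
  for (g in seq_len(P)) {
    rows <- which(pop_idx == g)
    if (length(rows) >= 2) {
      sub <- d2[rows, rows, drop = FALSE]
      ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / length(rows)
    }
  }
  ssd_among <- ssd_total - ssd_within
  df_a <- P - 1
  df_w <- N - P
  sigma_w <- if (df_w > 0) ssd_within / df_w else 0
  nbar <- (N - sum(n_i^2) / N) / df_a
  ms_a <- ssd_among / df_a
  sigma_a <- (ms_a - sigma_w) / nbar
  phi <- if (sigma_a + sigma_w > 0) sigma_a / (sigma_a + sigma_w) else 0
  list(sigma_a = sigma_a, sigma_w = sigma_w, phi = phi,
       ssd_total = ssd_total, ssd_within = ssd_within,
       ssd_among = ssd_among)
}

#' AMOVA Phi-ST from sequence data or a distance matrix
#'
#' Partitions molecular variance among and within populations from squared
#' pairwise distances (here, counts of differing nucleotide sites under
#' complete deletion of gapped/ambiguous columns) and returns
#' \eqn{\Phi_{ST} = \sigma_a^2 / (\sigma_a^2 + \sigma_w^2)} with a
#' permutation p-value obtained by reassigning individuals to populations
#' with sample sizes held fixed. Negative variance components are retained.
#'
#' @param aln An [aligned_sequences()] table, or `NULL` if `dist` given.
#' @param dist Optional precomputed matrix of squared pairwise distances
#'   (row/col names are individual ids).
#' @param populations Population label per row of `dist` (required with
#'   `dist`; taken from `aln` otherwise).
#' @param window Optional `c(from, to)` site window (with `aln`).
#' @param n_perm Permutations for the p-value (0 skips).
#' @param pairwise Also compute the pairwise Phi-ST matrix?
#' @param seed Optional integer seed.
#'
#' @return An object of class `fstat_result` with `statistic = "Phi_ST"`,
#'   variance components `sigma_a`/`sigma_w`, permutation `p_value`, and
#'   optionally `$pairwise`, a [pairwise_matrix()].
#' @export
amova_phist <- function(aln = NULL, dist = NULL, populations = NULL,
                        window = NULL, n_perm = 999, pairwise = TRUE,
                        seed = NULL) {
  if (is.null(dist)) {
    aln <- aligned_sequences(aln)
    m <- seq_matrix(aln)
    if (!is.null(window)) m <- m[, window[1]:window[2], drop = FALSE]
    keep <- usable_sites(m)
    if (length(keep) == 0) abort("no usable sites after masking")
    dist <- pairwise_diff_matrix(m[, keep, drop = FALSE])
    populations <- aln$population
  } else {
    stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
    if (is.null(populations) || length(populations) != nrow(dist)) {
      abort("`populations` must label every row of `dist`")
    }
  }
  pops <- unique(populations)
  P <- length(pops)
  if (P < 2) abort("AMOVA needs >= 2 populations")
  pop_idx <- match(populations, pops)

  obs <- amova_from_d2(dist, pop_idx, P)
  note <- if (obs$sigma_a + obs$sigma_w <= 0) {
    "total molecular variance is 0; Phi_ST defined as 0"
  } else NA_character_

  p_val <- NA_real_
  if (n_perm > 0) {
    p_val <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (amova_from_d2(dist, sample(pop_idx), P)$phi >=
            obs$phi - 1e-12) hits <- hits + 1L
      }
      perm_pvalue(hits, n_perm)
    })
  }

  pw <- NULL
  if (pairwise && P >= 2) {
    est <- p <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
    diag(est) <- 0
    for (i in seq_len(P - 1)) {
      for (j in (i + 1):P) {
        rows <- which(pop_idx %in% c(i, j))
        sub_idx <- match(pop_idx[rows], c(i, j))
        sub_d <- dist[rows, rows, drop = FALSE]
        o <- amova_from_d2(sub_d, sub_idx, 2L)
        est[i, j] <- est[j, i] <- o$phi
        if (n_perm > 0) {
          pv <- with_seed(seed, {
            hits <- 0L
            for (b in seq_len(n_perm)) {
              if (amova_from_d2(sub_d, sample(sub_idx), 2L)$phi >=
                  o$phi - 1e-12) hits <- hits + 1L
            }
            perm_pvalue(hits, n_perm)
          })
          p[i, j] <- p[j, i] <- pv
        }
      }
    }
    pw <- pairwise_matrix(est, p, statistic = "Phi_ST",
                          n_perm = as.integer(n_perm),
                          seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  }

  structure(
    list(statistic = "Phi_ST", estimate = obs$phi,
         sigma_a = obs$sigma_a, sigma_w = obs$sigma_w,
         ssd = c(total = obs$ssd_total, among = obs$ssd_among,
                 within = obs$ssd_within),
         p_value = p_val, n_perm = as.integer(n_perm),
         populations = pops, n_individuals = length(pop_idx),
         note = note, pairwise = pw,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "fstat_result")
}
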