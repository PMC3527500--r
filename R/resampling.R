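# Resampling diagnostics: allele randomization within (population, locus)
# for homozygote excess, locus bootstrap for robustness of structure
# estimates, and population monophyly checks on genealogies.

#' Allele randomization test for homozygote excess
#'
#' Pools the `2n` observed alleles at one locus in one population and
#' re-pairs them uniformly at random into `n` diploids, `n_reps` times.
#' The statistic is the heterozygote count; the one-sided p-value asks
#' whether the observed count is low relative to the re-pairing null (a
#' heterozygote deficit, the signature of null alleles, inbreeding or
#' Wahlund substructure). The null conserves the allele multiset exactly.
#'
#' @param gt A [genotype_table()].
#' @param population,locus Which cell to test.
#' @param n_reps Number of random re-pairings.
#' @param seed Optional integer seed.
#'
#' @return An object of class `randomization_result`: `observed`
#'   (heterozygote count), `null` (vector of null counts), `p` (one-sided,
#'   add-one rule, direction "less"), `observed_het`, `null_mean_het`
#'   (frequencies for the expected-vs-observed comparison), `n`, `n_reps`,
#'   `seed`.
#' @export
allele_randomization <- function(gt, population, locus, n_reps = 10000,
                                 seed = NULL) {
  stopifnot(n_reps >= 1)
  gt <- genotype_table(gt, loci = loci_names(gt))
  sub <- gt[gt$population == population & gt$locus == locus &
              !is.na(gt$a1), , drop = FALSE]
  n <- nrow(sub)
  if (n < 2) abort("allele randomization needs >= 2 genotyped individuals")
  obs <- sum(sub$a1 != sub$a2)
  pool <- c(sub$a1, sub$a2)
  base <- list(population = population, locus = locus, n = n,
               n_reps = as.integer(n_reps), direction = "less",
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (length(unique(pool)) == 1L) {
    return(structure(c(base, list(observed = 0L,
                                  null = rep(0L, n_reps), p = 1,
                                  observed_het = 0, null_mean_het = 0,
                                  note = "monomorphic")),
                     class = "randomization_result"))
  }
  null <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    s <- sample(pool)
    sum(s[seq_len(n)] != s[n + seq_len(n)])
  }, numeric(1)))
  p <- perm_pvalue(sum(null <= obs), n_reps)
  structure(c(base, list(observed = obs, null = null, p = p,
                         observed_het = obs / n,
                         null_mean_het = mean(null) / n,
                         note = NA_character_)),
            class = "randomization_result")
}

#' Allele randomization across every (population, locus) cell
#'
#' Maps [allele_randomization()] over all testable cells and returns a
#' tidy table of observed vs null-expected heterozygosity with one-sided
#' deficit p-values -- the per-locus, per-population screen for homozygote
#' excess.
#'
#' @param gt A [genotype_table()].
#' @param n_reps Replicates per cell.
#' @param seed Optional integer seed; cell `i` uses `seed + i`.
#'
#' @return A tibble: `population`, `locus`, `n`, `observed_het`,
#'   `null_mean_het`, `p`.
#' @export
randomization_scan <- function(gt, n_reps = 10000, seed = NULL) {
  gt <- genotype_table(gt, loci = loci_names(gt))
  cells <- dplyr::count(gt[!is.na(gt$a1), ], .data$population, .data$locus)
  cells <- cells[cells$n >= 2, ]
  purrr::pmap_dfr(
    list(cells$population, cells$locus, seq_len(nrow(cells))),
    function(pop, loc, i) {
      r <- allele_randomization(gt, pop, loc, n_reps = n_reps,
                                seed = if (is.null(seed)) NULL else seed + i)
      tibble(population = pop, locus = loc, n = r$n,
             observed_het = r$observed_het,
             null_mean_het = r$null_mean_het, p = r$p)
    })
}

#' Locus bootstrap of a population-structure statistic
#'
#' Resamples the `L` loci with replacement `B` times and recomputes the
#' multilocus Weir-Cockerham theta per replicate. If structure is driven
#' by one locus (e.g. one carrying null alleles), replicates that omit it
#' show markedly lower structure; the per-locus influence table reports the
#' mean statistic among replicates excluding each locus, flagging a locus
#' as "driving" when that mean falls below the 2.5th percentile of the
#' replicates that include it.
#'
#' @param gt A [genotype_table()].
#' @param populations Populations to include (default all).
#' @param B Number of bootstrap replicates.
#' @param seed Optional integer seed.
#'
#' @return An object of class `bootstrap_dist`: `observed`, `values`
#'   (length `B`), `ci` (2.5/97.5 percentiles), `influence` tibble, `B`,
#'   `loci`, `seed`.
#' @export
locus_bootstrap <- function(gt, populations = NULL, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  prep <- prep_loci(gt, populations)
  L <- length(prep$loci)
  # per-locus component sums are fixed; a replicate is a resampled sum
  comp_l <- vapply(prep$loci, function(ld) {
    wc_locus_components(ld$al, prep$ind_pop[ld$idx],
                        length(prep$pops), ld$k)
  }, numeric(3))
  usable <- !apply(is.na(comp_l), 2, any)
  comp_l <- comp_l[, usable, drop = FALSE]
  L <- ncol(comp_l)
  if (L < 1) abort("no usable loci")
  theta_of <- function(cols) {
    cs <- rowSums(comp_l[, cols, drop = FALSE])
    theta_from_components(as.list(setNames(cs, c("a", "b", "c"))))
  }
  observed <- theta_of(seq_len(L))
  draws <- with_seed(seed,
                     matrix(sample.int(L, B * L, replace = TRUE), B, L))
  values <- vapply(seq_len(B), function(b) theta_of(draws[b, ]), numeric(1))
  ci <- quantile(values, c(0.025, 0.975), names = FALSE)
  influence <- purrr::map_dfr(seq_len(L), function(l) {
    excl <- !apply(draws == l, 1, any)
    m_ex <- if (any(excl)) mean(values[excl]) else NA_real_
    m_in <- if (any(!excl)) mean(values[!excl]) else NA_real_
    # the reference distribution is the replicates that carry the locus:
    # a locus drives the signal when dropping it pushes the statistic
    # below the low tail of what it supports
    lo <- if (any(!excl)) quantile(values[!excl], 0.025, names = FALSE) else NA_real_
    tibble(locus = colnames(comp_l)[l],
           n_excluding = sum(excl),
           mean_excluding = m_ex,
           mean_including = m_in,
           driving = !is.na(m_ex) && !is.na(lo) && m_ex < lo)
  })
  structure(list(statistic = "F_ST", observed = observed, values = values,
                 ci = ci, influence = influence, B = as.integer(B),
                 loci = colnames(comp_l), draws = draws,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "bootstrap_dist")
}

#' Population monophyly on a genealogy
#'
#' A population is monophyletic when the smallest clade (the MRCA subtree)
#' containing all its tips contains no tips from other populations;
#' singleton populations are monophyletic by convention. Offending alien
#' tips are listed for non-monophyletic populations.
#'
#' @param tree A `phylo` tree (see [read_newick()]).
#' @param assignment Either a data frame with columns `population` and
#'   `tip`, or a named list of tip-label vectors.
#'
#' @return A tibble of class `monophyly_report`: `population`, `n_tips`,
#'   `monophyletic`, `offending` (comma-separated alien tips, `""` if
#'   none).
#' @export
monophyly_check <- function(tree, assignment) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("population", "tip") %in% names(assignment)))
    assignment <- split(as.character(assignment$tip),
                        assignment$population)
  }
  all_tips <- unlist(assignment, use.names = FALSE)
  missing <- setdiff(all_tips, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("tips absent from tree: ",
                 paste(missing, collapse = ", ")))
  }
  out <- purrr::imap_dfr(assignment, function(tips, pop) {
    tips <- unique(tips)
    if (length(tips) <= 1) {
      return(tibble(population = pop, n_tips = length(tips),
                    monophyletic = TRUE, offending = ""))
    }
    mrca <- ape::getMRCA(tree, tips)
    clade_tips <- ape::extract.clade(tree, mrca)$tip.label
    alien <- setdiff(clade_tips, tips)
    tibble(population = pop, n_tips = length(tips),
           monophyletic = length(alien) == 0,
           offending = paste(alien, collapse = ","))
  })
  structure(out, class = c("monophyly_report", class(out)))
}

#' Write a monophyly report as a delimited table
#'
#' @param report A [monophyly_check()] result.
#' @param path Output file.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_monophyly_report <- function(report, path, delim = "\t") {
  readr::write_delim(as_tibble(report), path, delim = delim)
  invisible(path)
}
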