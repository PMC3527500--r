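# Haplotype collapsing and Nei diversity indices (per-population h, Hd, pi
# with sampling variances).

# Sites usable for haplotype identity / diversity within a set of
# sequences: complete deletion of any column holding '-' or 'N'.
usable_sites <- function(seq_mat) {
  bad <- apply(seq_mat == "-" | seq_mat == "N", 2, any)
  which(!bad)
}

seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$sample_id
  m
}

#' Collapse an alignment into haplotypes
#'
#' Sequences identical over the retained sites are merged into one
#' haplotype and tabulated per population. Sites containing a gap or `N`
#' in any sequence are masked (complete deletion) before comparison, and an
#' optional window restricts the comparison to a subrange of the alignment
#' -- the device used to reconcile datasets sequenced at different lengths
#' (e.g. 410 bp vs 361 bp control-region fragments, under which distinct
#' long haplotypes can become redundant).
#'
#' @param aln An [aligned_sequences()] table.
#' @param window Optional integer vector `c(from, to)` (1-based, inclusive)
#'   restricting the sites considered.
#' @param hap_names Optional character vector naming haplotypes; defaults
#'   to `H01`, `H02`, ... in first-seen order.
#'
#' @return A tibble of class `hap_tbl` with columns `hap_id`, `sequence`
#'   (the windowed, masked representative) and one count column per
#'   population; attributes `n_per_pop` and `mask` record sample sizes and
#'   the retained site indices.
#' @export
collapse_haplotypes <- function(aln, window = NULL, hap_names = NULL) {
  aln <- aligned_sequences(aln)
  L <- aln_length(aln)
  m <- seq_matrix(aln)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    if (window[1] < 1 || window[2] > L || window[1] > window[2]) {
      abort(sprintf("window [%d,%d] out of bounds for alignment of %d bp",
                    window[1], window[2], L))
    }
    m <- m[, window[1]:window[2], drop = FALSE]
  }
  keep <- usable_sites(m)
  key <- if (length(keep) > 0) {
    apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  } else rep("", nrow(m))

  first_seen <- !duplicated(key)
  uniq <- key[first_seen]
  hap_ids <- hap_names %||% sprintf("H%02d", seq_along(uniq))
  if (length(hap_ids) != length(uniq)) {
    abort("hap_names must have one name per distinct haplotype")
  }
  hap_of <- hap_ids[match(key, uniq)]

  pops <- unique(aln$population)
  counts <- table(factor(hap_of, levels = hap_ids),
                  factor(aln$population, levels = pops))
  out <- tibble(hap_id = hap_ids, sequence = uniq)
  for (p in pops) out[[p]] <- as.integer(counts[, p])
  structure(out,
            n_per_pop = setNames(as.integer(table(factor(aln$population, levels = pops))), pops),
            mask = keep,
            assignment = setNames(hap_of, aln$sample_id),
            class = c("hap_tbl", class(out)))
}

#' Populations of a haplotype table
#' @param haps A `hap_tbl` from [collapse_haplotypes()].
#' @return Character vector of population names.
#' @export
hap_populations <- function(haps) {
  setdiff(names(haps), c("hap_id", "sequence"))
}

#' Nei haplotype diversity with its sampling variance
#'
#' Unbiased gene (haplotype) diversity
#' \deqn{\hat H = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)}
#' with Nei's sampling variance
#' \deqn{V(\hat H) = \frac{2}{n(n-1)}\Bigl[2(n-2)\bigl(\sum p_i^3 -
#'   (\sum p_i^2)^2\bigr) + \sum p_i^2 - (\sum p_i^2)^2\Bigr].}
#' A monomorphic sample returns `Hd = 0` with `sd = 0`.
#'
#' @param counts Non-negative integer haplotype counts for one population.
#'
#' @return A one-row tibble: `kind`, `value`, `variance`, `sd`, `n`,
#'   `n_haplotypes`.
#' @export
#' @examples
#' haplotype_diversity(c(2, 1, 1, 1)) # 0.900 +/- 0.161
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) abort("haplotype diversity needs a sample of n >= 2")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  v <- max(v, 0)
  tibble(kind = "haplotype_diversity", value = hd, variance = v,
         sd = sqrt(v), n = n, n_haplotypes = length(counts))
}

# Pairwise difference count over the retained sites of a character matrix.
pairwise_diff_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sum(m[i, ] != m[j, ])
      d[i, j] <- dd
      d[j, i] <- dd
    }
  }
  d
}

#' Nucleotide diversity with Nei's total variance
#'
#' Mean proportion of sites differing between two sequences drawn from the
#' sample: \eqn{\pi = \sum_{i<j} d_{ij} / (\binom{n}{2} L)} over the
#' unmasked (complete-deletion) sites, reported as a percentage. The
#' variance is Nei's total variance (stochastic plus sampling):
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2.}
#'
#' @param aln An [aligned_sequences()] table, normally one population.
#' @param window Optional `c(from, to)` site window.
#'
#' @return A one-row tibble: `kind`, `value` (percent), `variance`, `sd`
#'   (both on the percent scale), `n`, `L` (usable sites).
#' @export
nucleotide_diversity <- function(aln, window = NULL) {
  aln <- aligned_sequences(aln)
  n <- nrow(aln)
  if (n < 2) abort("nucleotide diversity needs n >= 2 sequences")
  m <- seq_matrix(aln)
  if (!is.null(window)) m <- m[, window[1]:window[2], drop = FALSE]
  keep <- usable_sites(m)
  L <- length(keep)
  if (L == 0) abort("no usable sites after masking gaps/ambiguities")
  m <- m[, keep, drop = FALSE]
  d <- pairwise_diff_matrix(m)
  pi_hat <- sum(d[upper.tri(d)]) / (choose(n, 2) * L)
  v <- (n + 1) / (3 * (n - 1) * L) * pi_hat +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  tibble(kind = "nucleotide_diversity", value = 100 * pi_hat,
         variance = 1e4 * v, sd = 100 * sqrt(v), n = n, L = L)
}

#' Per-population mitochondrial diversity summary
#'
#' One row per population: sample size `n`, number of haplotypes `h`,
#' nucleotide diversity `pi_pct` (+/- `pi_sd`) and haplotype diversity
#' `Hd` (+/- `Hd_sd`).
#'
#' @param aln An [aligned_sequences()] table with population labels.
#' @param window Optional `c(from, to)` site window.
#'
#' @return A tibble, one row per population.
#' @export
diversity_table <- function(aln, window = NULL) {
  aln <- aligned_sequences(aln)
  haps <- collapse_haplotypes(aln, window = window)
  pops <- hap_populations(haps)
  purrr::map_dfr(pops, function(p) {
    counts <- haps[[p]]
    sub <- aln[aln$population == p, , drop = FALSE]
    n <- sum(counts)
    if (n < 2) {
      return(tibble(population = p, n = n, h = sum(counts > 0),
                    pi_pct = NA_real_, pi_sd = NA_real_,
                    Hd = NA_real_, Hd_sd = NA_real_))
    }
    hd <- haplotype_diversity(counts)
    pi <- nucleotide_diversity(aligned_sequences(sub), window = window)
    tibble(population = p, n = n, h = sum(counts > 0),
           pi_pct = pi$value, pi_sd = pi$sd,
           Hd = hd$value, Hd_sd = hd$sd)
  })
}
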