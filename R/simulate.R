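# Forward-time two-sex metapopulation simulator: maternally inherited
# mtDNA sequences plus biparental stepwise-mutating microsatellites under
# sex-specific migration, with optional null-allele scoring. Used to
# validate every pipeline stage under known dispersal asymmetry.

#' Simulation configuration
#'
#' Parameters of the two-sex island-model simulation. Defaults describe
#' the male-biased-dispersal study condition: four demes of 50 females and
#' 50 males, philopatric females (`m_f = 0`), dispersing males
#' (`m_m = 0.2` per generation), 200 non-overlapping generations, a 410 bp
#' maternally inherited sequence and 15 unlinked stepwise-mutating
#' microsatellite loci, with 12 individuals sampled per deme. The
#' equal-dispersal control raises `m_f` to the male rate and changes
#' nothing else.
#'
#' @param n_demes Number of demes (`P >= 1`).
#' @param n_f,n_m Female/male adults per deme (held constant).
#' @param m_f,m_m Per-generation migration probabilities by sex, in
#'   `[0, 1]`.
#' @param generations Number of non-overlapping generations.
#' @param seq_length mtDNA sequence length (bp).
#' @param mu_mt Per-site, per-generation mtDNA mutation probability.
#' @param n_loci Number of microsatellite loci.
#' @param mu_ms Per-allele, per-generation stepwise (+/-1 repeat) mutation
#'   probability, reflecting at repeat 1.
#' @param null_rate Probability that a founder allelic lineage is
#'   non-amplifying (a null allele).
#' @param sample_size Individuals sampled per deme at the end (`<= n_f +
#'   n_m`).
#' @param founder_divergence Mutational steps separating each deme's
#'   founding mtDNA lineage cluster from the common ancestor.
#' @param founder_private Mean (Poisson) private mutations per founder
#'   mtDNA lineage.
#' @param founder_alleles Distinct founder allele sizes per microsatellite
#'   locus (drawn `founder_alleles[1]:founder_alleles[2]`).
#' @param founder_pool `"shared"` (default): all demes found from one
#'   allele pool per locus, so nuclear structure starts at zero;
#'   `"private"`: each deme gets its own disjoint pool, modelling long-
#'   diverged demes (with pool size 1 each deme is fixed for a private
#'   allele).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 4, n_f = 50, n_m = 50,
                       m_f = 0, m_m = 0.2, generations = 200,
                       seq_length = 410, mu_mt = 2e-5,
                       n_loci = 15, mu_ms = 5e-4, null_rate = 0,
                       sample_size = 12,
                       founder_divergence = 8, founder_private = 1,
                       founder_alleles = c(6, 12),
                       founder_pool = c("shared", "private"), seed = 1L) {
  founder_pool <- match.arg(founder_pool)
  rates <- c(m_f = m_f, m_m = m_m, mu_mt = mu_mt, mu_ms = mu_ms,
             null_rate = null_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]")
  }
  stopifnot(n_demes >= 1, n_f >= 1, n_m >= 1, generations >= 1,
            seq_length >= 1, n_loci >= 1)
  if (sample_size > n_f + n_m) {
    abort("sample_size exceeds deme size")
  }
  structure(
    list(n_demes = as.integer(n_demes), n_f = as.integer(n_f),
         n_m = as.integer(n_m), m_f = m_f, m_m = m_m,
         generations = as.integer(generations),
         seq_length = as.integer(seq_length), mu_mt = mu_mt,
         n_loci = as.integer(n_loci), mu_ms = mu_ms,
         null_rate = null_rate, sample_size = as.integer(sample_size),
         founder_divergence = as.integer(founder_divergence),
         founder_private = founder_private,
         founder_alleles = as.integer(founder_alleles),
         founder_pool = founder_pool,
         seed = as.integer(seed)),
    class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# registry of mtDNA haplotypes: sequences stored once as integer vectors
new_registry <- function(first_seq) {
  env <- new.env(parent = emptyenv())
  env$seqs <- list(first_seq)
  env
}

registry_add <- function(reg, seq) {
  reg$seqs[[length(reg$seqs) + 1L]] <- seq
  length(reg$seqs)
}

mutate_sequence <- function(seq, n_mut) {
  sites <- sample.int(length(seq), n_mut, replace = FALSE)
  for (s in sites) {
    seq[s] <- sample(setdiff(1:4, seq[s]), 1)
  }
  seq
}

#' Simulate a two-sex metapopulation
#'
#' Discrete non-overlapping generations. Each generation: (1) migration --
#' every adult independently relocates to a uniformly chosen other deme
#' with probability `m_f` (females) or `m_m` (males); (2) reproduction --
#' each deme produces exactly `n_f` daughters and `n_m` sons, each drawing
#' its mother and father uniformly from the deme's post-migration adults
#' of the respective sex; (3) inheritance -- mtDNA is copied from the
#' mother with per-site mutation to a uniformly chosen different base, and
#' one microsatellite allele per locus comes from each parent, mutating by
#' +/-1 repeat with probability `mu_ms` (reflecting at 1). Deme sizes are
#' constant; if migration empties a deme of one sex, parents of that sex
#' are drawn from the whole metapopulation (counted in `truth$rescues`).
#' Founders start with deme-specific mtDNA lineage clusters and a shared
#' pool of microsatellite alleles; founder allele lineages are flagged as
#' null with probability `null_rate` and the flag is inherited with the
#' allele. After the final generation, `sample_size` individuals per deme
#' are scored: a carrier of one null copy is recorded as homozygous for
#' its visible allele, a carrier of two as missing.
#'
#' @param cfg A [sim_config()].
#'
#' @return An object of class `sim_output`: `alignment` (an
#'   [aligned_sequences()] tibble of sampled individuals), `genotypes` (a
#'   [genotype_table()] with sex labels), and `truth` (the configuration,
#'   realized migration counts per sex, rescue events, and the unscored
#'   true genotypes).
#' @export
simulate_metapopulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    P <- cfg$n_demes
    n_deme <- cfg$n_f + cfg$n_m
    n_tot <- P * n_deme
    L <- cfg$n_loci

    # founders -----------------------------------------------------------
    ancestor <- sample.int(4, cfg$seq_length, replace = TRUE)
    reg <- new_registry(ancestor)
    deme <- rep(seq_len(P), each = n_deme)
    sex <- rep(rep(c(1L, 2L), c(cfg$n_f, cfg$n_m)), P) # 1 = F, 2 = M
    hap <- integer(n_tot)
    for (d in seq_len(P)) {
      deme_anc <- if (cfg$founder_divergence > 0) {
        mutate_sequence(ancestor, cfg$founder_divergence)
      } else ancestor
      deme_anc_id <- registry_add(reg, deme_anc)
      rows <- which(deme == d)
      n_priv <- rpois(length(rows), cfg$founder_private)
      for (i in seq_along(rows)) {
        hap[rows[i]] <- if (n_priv[i] == 0) deme_anc_id else {
          registry_add(reg, mutate_sequence(deme_anc, n_priv[i]))
        }
      }
    }
    # founder allele pools per locus (shared across demes, or one disjoint
    # pool per deme)
    sample_vec <- function(x, n) { # sample() treats length-1 x as 1:x
      if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
    }
    pool_sizes <- sample_vec(cfg$founder_alleles[1]:cfg$founder_alleles[2], L)
    alleles <- matrix(0L, n_tot, 2L * L)
    for (l in seq_len(L)) {
      k <- pool_sizes[l]
      base <- sample(10:30, 1)
      if (cfg$founder_pool == "shared") {
        pool <- base:(base + k - 1L)
        alleles[, 2L * l - 1L] <- sample_vec(pool, n_tot)
        alleles[, 2L * l] <- sample_vec(pool, n_tot)
      } else {
        for (d in seq_len(P)) {
          pool <- (base + (d - 1L) * k):(base + d * k - 1L)
          rows <- which(deme == d)
          alleles[rows, 2L * l - 1L] <- sample_vec(pool, length(rows))
          alleles[rows, 2L * l] <- sample_vec(pool, length(rows))
        }
      }
    }
    nullf <- matrix(runif(n_tot * 2L * L) < cfg$null_rate, n_tot, 2L * L)

    migrations <- c(F = 0L, M = 0L)
    rescues <- 0L

    for (g in seq_len(cfg$generations)) {
      # 1. migration
      m_rate <- ifelse(sex == 1L, cfg$m_f, cfg$m_m)
      mig <- runif(n_tot) < m_rate
      if (P > 1 && any(mig)) {
        shift <- sample.int(P - 1L, sum(mig), replace = TRUE)
        deme[mig] <- 1L + (deme[mig] - 1L + shift) %% P
        migrations["F"] <- migrations["F"] + sum(mig & sex == 1L)
        migrations["M"] <- migrations["M"] + sum(mig & sex == 2L)
      }
      # 2. reproduction
      mothers <- fathers <- integer(n_tot)
      off_deme <- rep(seq_len(P), each = n_deme)
      for (d in seq_len(P)) {
        fem <- which(deme == d & sex == 1L)
        mal <- which(deme == d & sex == 2L)
        if (length(fem) == 0) { fem <- which(sex == 1L); rescues <- rescues + 1L }
        if (length(mal) == 0) { mal <- which(sex == 2L); rescues <- rescues + 1L }
        rows <- which(off_deme == d)
        mothers[rows] <- fem[sample.int(length(fem), n_deme, replace = TRUE)]
        fathers[rows] <- mal[sample.int(length(mal), n_deme, replace = TRUE)]
      }
      off_sex <- rep(rep(c(1L, 2L), c(cfg$n_f, cfg$n_m)), P)
      # 3a. mtDNA inheritance + mutation
      off_hap <- hap[mothers]
      n_events <- rbinom(1L, n_tot * cfg$seq_length, cfg$mu_mt)
      if (n_events > 0) {
        who <- sample.int(n_tot, n_events, replace = TRUE)
        for (w in unique(who)) {
          k <- sum(who == w)
          off_hap[w] <- registry_add(
            reg, mutate_sequence(reg$seqs[[off_hap[w]]], k))
        }
      }
      # 3b. microsatellite inheritance
      mat_choice <- matrix(sample.int(2L, n_tot * L, replace = TRUE), n_tot, L)
      pat_choice <- matrix(sample.int(2L, n_tot * L, replace = TRUE), n_tot, L)
      col_base <- rep(2L * seq_len(L) - 2L, each = n_tot)
      mat_idx <- cbind(rep(mothers, L), col_base + as.vector(mat_choice))
      pat_idx <- cbind(rep(fathers, L), col_base + as.vector(pat_choice))
      off_alleles <- matrix(0L, n_tot, 2L * L)
      off_null <- matrix(FALSE, n_tot, 2L * L)
      odd <- 2L * seq_len(L) - 1L
      off_alleles[, odd] <- alleles[mat_idx]
      off_alleles[, odd + 1L] <- alleles[pat_idx]
      off_null[, odd] <- nullf[mat_idx]
      off_null[, odd + 1L] <- nullf[pat_idx]
      n_mut <- rbinom(1L, n_tot * 2L * L, cfg$mu_ms)
      if (n_mut > 0) {
        slots <- sample.int(n_tot * 2L * L, n_mut, replace = FALSE)
        step <- sample(c(-1L, 1L), n_mut, replace = TRUE)
        newval <- off_alleles[slots] + step
        newval[newval < 1L] <- 2L # reflect at repeat 1
        off_alleles[slots] <- newval
      }
      deme <- off_deme
      sex <- off_sex
      hap <- off_hap
      alleles <- off_alleles
      nullf <- off_null
    }

    # sampling ------------------------------------------------------------
    samp <- unlist(lapply(seq_len(P), function(d) {
      rows <- which(deme == d)
      rows[sample.int(length(rows), cfg$sample_size)]
    }))
    ids <- sprintf("d%d_i%02d", deme[samp],
                   unlist(lapply(seq_len(P), function(d) seq_len(cfg$sample_size))))
    pop <- paste0("deme", deme[samp])
    sex_chr <- c("F", "M")[sex[samp]]

    seqs <- vapply(hap[samp], function(h) {
      paste(BASES[reg$seqs[[h]]], collapse = "")
    }, character(1))
    alignment <- aligned_sequences(tibble(
      sample_id = ids, population = pop, sex = sex_chr, sequence = seqs))

    locus_names <- sprintf("L%02d", seq_len(L))
    long <- tidyr::expand_grid(i = seq_along(samp), l = seq_len(L))
    a1 <- alleles[cbind(samp[long$i], 2L * long$l - 1L)]
    a2 <- alleles[cbind(samp[long$i], 2L * long$l)]
    f1 <- nullf[cbind(samp[long$i], 2L * long$l - 1L)]
    f2 <- nullf[cbind(samp[long$i], 2L * long$l)]
    scored <- score_null(a1, a2, f1, f2)
    gt <- genotype_table(tibble(
      sample_id = ids[long$i], population = pop[long$i],
      sex = sex_chr[long$i], locus = locus_names[long$l],
      a1 = scored$a1, a2 = scored$a2), loci = locus_names)
    truth_gt <- tibble(
      sample_id = ids[long$i], population = pop[long$i],
      sex = sex_chr[long$i], locus = locus_names[long$l],
      a1 = pmin(a1, a2), a2 = pmax(a1, a2))

    structure(
      list(alignment = alignment, genotypes = gt,
           truth = list(config = cfg, migrations = migrations,
                        rescues = rescues, n_haplotypes_total = length(reg$seqs),
                        true_genotypes = truth_gt)),
      class = "sim_output")
  })
}

# apply null-allele scoring to parallel allele/flag vectors
score_null <- function(a1, a2, f1, f2) {
  out1 <- ifelse(f1 & f2, NA_integer_, ifelse(f1, a2, a1))
  out2 <- ifelse(f1 & f2, NA_integer_, ifelse(f2, out1, a2))
  # one null copy -> homozygote for the visible allele
  out2 <- ifelse(!is.na(out1) & f1 & !f2, a2, out2)
  list(a1 = as.integer(pmin(out1, out2)), a2 = as.integer(pmax(out1, out2)))
}

#' Write a simulated dataset to disk
#'
#' Emits the sampled alignment as FASTA (headers `id|population|sex`), the
#' scored genotypes as a delimited table, and the ground truth
#' (configuration, realized migration counts, rescue events) as JSON.
#'
#' @param sim A [simulate_metapopulation()] result.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  write_genotype_table(sim$genotypes, file.path(dir, "genotypes.csv"))
  truth <- sim$truth
  truth$true_genotypes <- NULL
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Inject null alleles into a genotype table
#'
#' Masks each allele occurrence independently with probability `rate`: an
#' individual with one masked copy is scored homozygous for the visible
#' allele, with both masked as missing. Models non-amplifying
#' (null) microsatellite alleles in already-collected data.
#'
#' @param gt A [genotype_table()].
#' @param rate Masking probability in `[0, 1]`.
#' @param seed Optional integer seed.
#'
#' @return A genotype table with the same shape (individuals left with no
#'   genotyped locus are retained; validation is relaxed accordingly).
#' @export
inject_null_alleles <- function(gt, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  gt <- genotype_table(gt, loci = loci_names(gt))
  if (rate == 0) return(gt)
  with_seed(seed, {
    nr <- nrow(gt)
    f1 <- runif(nr) < rate
    f2 <- runif(nr) < rate
    miss <- is.na(gt$a1)
    scored <- score_null(gt$a1, gt$a2, f1 & !miss, f2 & !miss)
    out <- gt
    out$a1 <- scored$a1
    out$a2 <- scored$a2
    structure(out, loci = loci_names(gt), class = class(gt))
  })
}
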