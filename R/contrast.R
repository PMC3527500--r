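# Marker-class contrast: Spearman Mantel correlation between pairwise
# structure matrices, Bayes-factor ranking of migration models, and the
# male-biased-dispersal contrast report.

as_square_matrix <- function(m, arg = "matrix") {
  if (inherits(m, "pairwise_matrix")) m <- m$estimate
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0(arg, " must be a square matrix or pairwise_matrix"))
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("P", seq_len(nrow(m)))
  m
}

spearman_lower <- function(m1, m2) {
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  cor(rank(v1), rank(v2))
}

#' Spearman Mantel test between two pairwise matrices
#'
#' Correlates the off-diagonal entries of two symmetric population-pair
#' matrices using Spearman rank correlation (midranks for ties) and
#' assesses significance by simultaneously permuting the rows and columns
#' of the second matrix. When all `n!` label permutations number no more
#' than `n_perm` they are enumerated exactly; otherwise `n_perm` random
#' permutations are sampled and the add-one rule applied. The p-value is
#' two-sided.
#'
#' @param m1,m2 Symmetric matrices with matching population labels, or
#'   [pairwise_matrix()] objects.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#'
#' @return An object of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `exhaustive`, `method`, `n` (matrix dimension), `seed`.
#' @export
mantel_spearman <- function(m1, m2, n_perm = 100000, seed = NULL) {
  m1 <- as_square_matrix(m1, "m1")
  m2 <- as_square_matrix(m2, "m2")
  if (!setequal(rownames(m1), rownames(m2))) {
    abort("matrices must share population labels")
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  n <- nrow(m1)
  if (n < 3) abort("Mantel test needs matrices of dimension >= 3")
  if (max(abs(m1 - t(m1)), na.rm = TRUE) > 1e-8 ||
      max(abs(m2 - t(m2)), na.rm = TRUE) > 1e-8) {
    abort("matrices must be symmetric")
  }
  r_obs <- spearman_lower(m1, m2)
  tol <- 1e-12
  if (n <= 7 && factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    r_null <- apply(perms, 1, function(ix) {
      spearman_lower(m1, m2[ix, ix])
    })
    p <- mean(abs(r_null) >= abs(r_obs) - tol)
    exhaustive <- TRUE
    n_used <- nrow(perms)
  } else {
    r_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n)
      spearman_lower(m1, m2[ix, ix])
    }, numeric(1)))
    p <- perm_pvalue(sum(abs(r_null) >= abs(r_obs) - tol), n_perm)
    exhaustive <- FALSE
    n_used <- as.integer(n_perm)
  }
  structure(list(r = r_obs, p = p, n_perm = n_used,
                 exhaustive = exhaustive, method = "spearman", n = n,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "mantel_result")
}

#' Rank migration models by harmonic-mean likelihood and Bayes factors
#'
#' Ranks models by their harmonic-mean log-likelihood (a marginal
#' likelihood approximation from MCMC output) and computes each model's
#' log-Bayes factor against the best model as
#' \eqn{LBF_i = 2(\ln L_{best} - \ln L_i)}.
#'
#' @param models A data frame with columns `model` and `lnL`, or a named
#'   numeric vector of harmonic-mean log-likelihoods.
#'
#' @return A tibble of class `model_ranking`: `model`, `lnL`, `rank`,
#'   `LBF` (0 for the best model).
#' @export
#' @examples
#' bayes_factor_ranking(c(M2 = -12874, M3 = -14620))
bayes_factor_ranking <- function(models) {
  if (is.numeric(models)) {
    models <- tibble(model = names(models) %||%
                       paste0("M", seq_along(models)),
                     lnL = unname(models))
  }
  models <- as_tibble(models)
  stopifnot(all(c("model", "lnL") %in% names(models)))
  if (nrow(models) < 2) abort("model ranking needs >= 2 models")
  if (any(!is.finite(models$lnL))) abort("all lnL values must be finite")
  best <- max(models$lnL)
  if (sum(models$lnL == best) > 1) {
    warn("tie for the best model; all tied models get LBF = 0 and rank 1")
  }
  out <- models |>
    dplyr::mutate(LBF = 2 * (best - .data$lnL),
                  rank = dplyr::min_rank(-.data$lnL)) |>
    dplyr::arrange(.data$rank) |>
    dplyr::select("model", "lnL", "rank", "LBF")
  structure(out, class = c("model_ranking", class(out)))
}

#' Read harmonic-mean model likelihoods from delimited text
#'
#' Two columns: model name and harmonic-mean log-likelihood.
#'
#' @param path Delimited file with columns `model`, `lnL` (header
#'   optional).
#' @return A tibble with columns `model`, `lnL`.
#' @export
read_model_likelihoods <- function(path) {
  x <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE,
                         col_names = FALSE)
  if (ncol(x) < 2) abort("expected two columns: model, lnL")
  x <- x[, 1:2]
  names(x) <- c("model", "lnL")
  suppressWarnings(first_lnl <- as.numeric(x$lnL[1]))
  if (is.na(first_lnl)) x <- x[-1, ] # header row
  tibble(model = as.character(x$model), lnL = as.numeric(x$lnL))
}

#' Male-biased dispersal contrast report
#'
#' Confronts mitochondrial and nuclear pairwise structure. For each
#' population pair, the discordance flag marks the male-biased-dispersal
#' (MBD) signature: significant mitochondrial structure accompanied by
#' absent *or markedly lesser* nuclear structure -- nuclear p above the
#' threshold, or a nuclear estimate no more than `ratio_max` times the
#' mitochondrial one (male gene flow dilutes, and need not erase, nuclear
#' differentiation). The report classifies the dataset as consistent with
#' MBD when (i) at least `min_mt_frac` of all pairs show significant
#' mitochondrial structure and (ii) at least `discordant_frac` of those
#' mitochondrially structured pairs are discordant. Pair-level
#' significance uses `alpha`, Bonferroni-corrected across pairs by default
#' (set `p_adjust = "none"` to use raw `alpha`).
#'
#' @param phist_mt [pairwise_matrix()] of mitochondrial Phi-ST with
#'   p-values.
#' @param theta_nuc [pairwise_matrix()] of nuclear theta with p-values.
#' @param mantel Optional [mantel_spearman()] result to embed.
#' @param alpha Significance level.
#' @param p_adjust `"bonferroni"` (default) or `"none"`.
#' @param min_mt_frac Minimum fraction of pairs with significant
#'   mitochondrial structure required before MBD is considered.
#' @param discordant_frac Minimum fraction of mitochondrially significant
#'   pairs that must be discordant.
#' @param ratio_max A mitochondrially significant pair with significant
#'   nuclear structure still counts as discordant when
#'   `theta_nuc <= ratio_max * phist_mt` (default 0.5: nuclear structure
#'   under half the mitochondrial level).
#'
#' @return An object of class `contrast_report`: `pairs` tibble, counts,
#'   `classification` text, thresholds, and the embedded Mantel result.
#' @export
contrast_report <- function(phist_mt, theta_nuc, mantel = NULL,
                            alpha = 0.05,
                            p_adjust = c("bonferroni", "none"),
                            min_mt_frac = 0.5, discordant_frac = 0.5,
                            ratio_max = 0.5) {
  p_adjust <- match.arg(p_adjust)
  if (!inherits(phist_mt, "pairwise_matrix") ||
      !inherits(theta_nuc, "pairwise_matrix")) {
    abort("phist_mt and theta_nuc must be pairwise_matrix objects")
  }
  labs <- phist_mt$labels
  if (!setequal(labs, theta_nuc$labels)) {
    abort("pairwise matrices must share population labels")
  }
  ord <- match(labs, theta_nuc$labels)
  est_n <- theta_nuc$estimate[ord, ord]
  p_n <- theta_nuc$p[ord, ord]

  idx <- which(lower.tri(phist_mt$estimate), arr.ind = TRUE)
  n_pairs <- nrow(idx)
  thr <- if (p_adjust == "bonferroni") alpha / n_pairs else alpha
  est_mt <- phist_mt$estimate[idx]
  p_mt <- phist_mt$p[idx]
  pairs <- tibble(
    pop1 = labs[idx[, 2]], pop2 = labs[idx[, 1]],
    phist_mt = est_mt, p_mt = p_mt,
    theta_nuc = est_n[idx], p_nuc = p_n[idx]
  ) |>
    dplyr::mutate(
      mt_significant = !is.na(.data$p_mt) & .data$p_mt <= thr,
      nuc_significant = !is.na(.data$p_nuc) & .data$p_nuc <= thr,
      lesser_nuclear = .data$phist_mt > 0 &
        .data$theta_nuc <= ratio_max * .data$phist_mt,
      discordant = .data$mt_significant &
        (!.data$nuc_significant | .data$lesser_nuclear)
    )
  n_mt <- sum(pairs$mt_significant)
  n_disc <- sum(pairs$discordant)
  n_conc <- sum(pairs$mt_significant & pairs$nuc_significant)
  positive <- n_mt >= min_mt_frac * n_pairs &&
    n_disc >= discordant_frac * n_mt && n_mt > 0
  classification <- if (positive) {
    "consistent with male-biased dispersal"
  } else {
    "not consistent with male-biased dispersal"
  }
  structure(
    list(pairs = pairs, n_pairs = n_pairs,
         n_mt_significant = n_mt, n_discordant = n_disc,
         n_concordant = n_conc,
         alpha = alpha, p_adjust = p_adjust, threshold = thr,
         min_mt_frac = min_mt_frac, discordant_frac = discordant_frac,
         ratio_max = ratio_max,
         mantel = mantel, classification = classification),
    class = "contrast_report")
}
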