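# broom-style tidiers, glance summaries, autoplot methods and printers for
# the package's result objects.

#' @export
tidy.fstat_result <- function(x, ...) {
  if (x$statistic == "Phi_ST") {
    tibble(statistic = c("Phi_ST", "sigma_a", "sigma_w"),
           estimate = c(x$estimate, x$sigma_a, x$sigma_w),
           p_value = c(x$p_value, NA, NA))
  } else {
    tibble(statistic = c("F_ST", "F_IS", "F_IT"),
           estimate = c(x$estimate, x$fis, x$fit),
           p_value = c(x$p_value, x$p_fis, NA))
  }
}

#' @export
glance.fstat_result <- function(x, ...) {
  tibble(statistic = x$statistic, estimate = x$estimate,
         p_value = x$p_value, n_perm = x$n_perm,
         n_populations = length(x$populations),
         n_individuals = x$n_individuals, seed = x$seed)
}

#' @export
tidy.pairwise_matrix <- function(x, ...) {
  idx <- which(lower.tri(x$estimate), arr.ind = TRUE)
  tibble(pop1 = x$labels[idx[, 2]], pop2 = x$labels[idx[, 1]],
         statistic = x$statistic,
         estimate = x$estimate[idx], p_value = x$p[idx])
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(r = x$r, p_value = x$p, method = x$method, n = x$n,
         n_perm = x$n_perm, exhaustive = x$exhaustive)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' @export
tidy.randomization_result <- function(x, ...) {
  tibble(population = x$population, locus = x$locus, n = x$n,
         observed = x$observed, null_mean = mean(x$null),
         null_sd = sd(x$null), observed_het = x$observed_het,
         null_mean_het = x$null_mean_het, p_value = x$p,
         n_reps = x$n_reps)
}

#' @export
tidy.bootstrap_dist <- function(x, ...) x$influence

#' @export
glance.bootstrap_dist <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         boot_mean = mean(x$values), boot_sd = sd(x$values),
         ci_lower = x$ci[1], ci_upper = x$ci[2], B = x$B,
         n_loci = length(x$loci), seed = x$seed)
}

#' @export
tidy.contrast_report <- function(x, ...) x$pairs

#' @export
glance.contrast_report <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_mt_significant = x$n_mt_significant,
         n_discordant = x$n_discordant, n_concordant = x$n_concordant,
         threshold = x$threshold,
         mantel_r = if (!is.null(x$mantel)) x$mantel$r else NA_real_,
         mantel_p = if (!is.null(x$mantel)) x$mantel$p else NA_real_,
         classification = x$classification)
}

#' @export
tidy.hap_network <- function(x, ...) x$edges

#' @export
glance.hap_network <- function(x, ...) {
  tibble(n_observed = sum(x$nodes$type == "observed"),
         n_median = sum(x$nodes$type == "median"),
         n_edges = nrow(x$edges), total_cost = x$total_cost,
         epsilon = x$epsilon)
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic, x$estimate))
  if (!is.na(x$p_value)) {
    cat(sprintf("  (permutation p = %.4g, %d permutations)",
                x$p_value, x$n_perm))
  }
  cat("\n")
  if (x$statistic == "F_ST") {
    cat(sprintf("F_IS = %.4f", x$fis))
    if (!is.na(x$p_fis)) cat(sprintf("  (p = %.4g)", x$p_fis))
    cat("\n")
  }
  cat(sprintf("%d populations, %d individuals\n",
              length(x$populations), x$n_individuals))
  if (!is.null(x$pairwise)) cat("pairwise matrix in $pairwise\n")
  invisible(x)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise %s (lower triangle), p-values (upper triangle)\n",
              x$statistic))
  m <- x$estimate
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, 4))
  invisible(x)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test (Spearman): r = %.4f, %s p = %.4g (%s%d permutations)\n",
    x$r, if (x$exhaustive) "exact" else "permutation", x$p,
    if (x$exhaustive) "all " else "", x$n_perm))
  invisible(x)
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Marker-contrast dispersal report\n")
  cat(sprintf(
    "  %d population pairs; mtDNA-significant: %d; discordant: %d; concordant: %d\n",
    x$n_pairs, x$n_mt_significant, x$n_discordant, x$n_concordant))
  cat(sprintf("  pair-level threshold: p <= %.4g (%s)\n",
              x$threshold, x$p_adjust))
  if (!is.null(x$mantel)) {
    cat(sprintf("  Mantel (Spearman): r = %.3f, p = %.3g\n",
                x$mantel$r, x$mantel$p))
  }
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf(
    "median-joining network: %d observed, %d median vectors, %d edges, total cost %d (epsilon = %d)\n",
    sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
    nrow(x$edges), x$total_cost, x$epsilon))
  invisible(x)
}

#' @export
print.sim_output <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "simulated metapopulation: %d demes, %d+%d adults/deme, %d generations\n",
    cfg$n_demes, cfg$n_f, cfg$n_m, cfg$generations))
  cat(sprintf("  m_f = %.3g, m_m = %.3g; sampled %d/deme; seed %d\n",
              cfg$m_f, cfg$m_m, cfg$sample_size, cfg$seed))
  cat(sprintf("  realized migrations: %d female, %d male\n",
              x$truth$migrations[["F"]], x$truth$migrations[["M"]]))
  invisible(x)
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "allele randomization (%s, %s): observed %d heterozygotes of %d (%.3f), null mean %.3f, one-sided p = %.4g\n",
    x$population, x$locus, x$observed, x$n, x$observed_het,
    x$null_mean_het, x$p))
  invisible(x)
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(sprintf(
    "locus bootstrap of %s: observed %.4f, B = %d, 95%% CI [%.4f, %.4f]\n",
    x$statistic, x$observed, x$B, x$ci[1], x$ci[2]))
  drv <- x$influence$locus[x$influence$driving]
  if (length(drv) > 0) cat("  driving loci:", paste(drv, collapse = ", "), "\n")
  invisible(x)
}

# ---- autoplot methods -------------------------------------------------------

#' Plot a median-joining haplotype network
#'
#' Fruchterman-Reingold layout; observed haplotypes are sized by total
#' count, median vectors drawn as small squares, edges labelled with their
#' mutational weight when larger than 1.
#'
#' @param object A `hap_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_network <- function(object, seed = 1, ...) {
  g <- network_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  pops <- setdiff(names(nodes), c("node_id", "type", "sequence", "x", "y"))
  nodes$count <- if (length(pops) > 0) {
    rowSums(as.matrix(nodes[, pops, drop = FALSE]))
  } else 1
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$node_id)]
  edges$y <- nodes$y[match(edges$from, nodes$node_id)]
  edges$xend <- nodes$x[match(edges$to, nodes$node_id)]
  edges$yend <- nodes$y[match(edges$to, nodes$node_id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey40") +
    ggplot2::geom_text(
      data = edges[edges$weight > 1, ],
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2,
                   label = .data$weight), size = 3, colour = "grey30") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   size = .data$count, shape = .data$type,
                   colour = .data$type)) +
    ggplot2::geom_text(
      data = nodes[nodes$type == "observed", ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node_id),
      vjust = -1.2, size = 3) +
    ggplot2::scale_shape_manual(values = c(observed = 16, median = 15)) +
    ggplot2::scale_colour_manual(values = c(observed = "steelblue",
                                            median = "grey55")) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "count", shape = NULL, colour = NULL)
}

#' Plot a locus-bootstrap distribution
#' @param object A `bootstrap_dist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_dist <- function(object, ...) {
  df <- tibble(value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = 2) +
    ggplot2::labs(x = paste("bootstrap", object$statistic), y = "replicates")
}

#' Plot an allele-randomization null distribution
#' @param object A `randomization_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.randomization_result <- function(object, ...) {
  df <- tibble(het = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$het)) +
    ggplot2::geom_bar(fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "null heterozygote count", y = "replicates",
                  title = sprintf("%s / %s: observed %d, p = %.3g",
                                  object$population, object$locus,
                                  object$observed, object$p))
}

#' Heatmap of a pairwise structure matrix
#' @param object A `pairwise_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pairwise_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop1, y = .data$pop2,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f\np=%.3g", .data$estimate, .data$p_value)),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = object$statistic)
}

#' Mitochondrial vs nuclear structure per population pair
#' @param object A `contrast_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contrast_report <- function(object, ...) {
  df <- object$pairs
  df$pair <- paste(df$pop1, df$pop2, sep = " - ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_nuc,
                                   y = .data$phist_mt,
                                   colour = .data$discordant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(x = "nuclear theta", y = "mitochondrial Phi_ST",
                  colour = "discordant",
                  subtitle = object$classification)
}
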