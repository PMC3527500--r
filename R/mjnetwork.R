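# Median-joining haplotype networks (Bandelt-style): iterate between an
# epsilon-relaxed minimum spanning network over the current node set and
# the addition of cost-reducing quasi-median (majority-state) vectors, then
# prune median vectors of degree <= 2.

hamming <- function(a, b) sum(a != b)

dist_mat <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- hamming(seqs[[i]], seqs[[j]])
      }
    }
  }
  d
}

# Prim MST on a dense distance matrix; returns edge list (i, j, w).
# Deterministic: ties broken by lowest node index.
mst_edges <- function(d) {
  n <- nrow(d)
  if (n < 2) return(matrix(numeric(0), 0, 3))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_w <- d[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    edges[k, ] <- c(min(best_from[v], v), max(best_from[v], v), best_w[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best_w
    best_from[upd] <- v
    best_w[upd] <- d[v, upd]
  }
  edges
}

# Minimax edge weight between all node pairs, from the MST: the largest
# edge on the unique MST path. Used to build the epsilon-relaxed MSN.
minimax_from_mst <- function(edges, n) {
  mm <- matrix(Inf, n, n)
  diag(mm) <- 0
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]; w <- edges[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, w))
      adj[[j]] <- rbind(adj[[j]], c(i, w))
    }
  }
  for (src in seq_len(n)) {
    # DFS from src along the tree
    stack <- list(c(src, 0))
    visited <- rep(FALSE, n)
    visited[src] <- TRUE
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- top[1]; wmax <- top[2]
      mm[src, v] <- wmax
      nb <- adj[[v]]
      if (!is.null(nb)) {
        for (k in seq_len(nrow(nb))) {
          u <- nb[k, 1]
          if (!visited[u]) {
            visited[u] <- TRUE
            stack[[length(stack) + 1]] <- c(u, max(wmax, nb[k, 2]))
          }
        }
      }
    }
  }
  mm
}

# Epsilon-relaxed minimum spanning network: edge (u,v) kept iff
# d(u,v) <= minimax(u,v) + eps. With eps = 0 this is the union of all MSTs.
msn_edges <- function(d, eps = 0) {
  n <- nrow(d)
  mm <- minimax_from_mst(mst_edges(d), n)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= mm[i, j] + eps) out <- rbind(out, c(i, j, d[i, j]))
    }
  }
  if (is.null(out)) matrix(numeric(0), 0, 3) else out
}

# Majority-state quasi-median of three sequences, lexicographic ('A' <
# 'C' < 'G' < 'T') tie-break when all three states differ at a site.
quasi_median <- function(s1, s2, s3) {
  m <- s1
  diff2 <- s2 == s3 & s1 != s2
  m[diff2] <- s2[diff2]
  all_diff <- s1 != s2 & s2 != s3 & s1 != s3
  if (any(all_diff)) {
    m[all_diff] <- pmin(s1[all_diff], s2[all_diff], s3[all_diff])
  }
  m
}

#' Median-joining haplotype network
#'
#' Builds a haplotype network by iterating between an epsilon-relaxed
#' minimum spanning network over the current node set and the addition of
#' quasi-median vectors (per-site majority state of three mutually linked
#' nodes, lexicographic tie-break) whenever a median shortens the total
#' connection of its triple. Median vectors of degree two or less are
#' pruned, and the final network is the relaxed minimum spanning network
#' over observed haplotypes plus retained medians. Distances are Hamming
#' distances over the haplotype table's retained (unmasked) sites.
#'
#' @param haps A `hap_tbl` from [collapse_haplotypes()], or a named
#'   character vector of aligned haplotype sequences.
#' @param epsilon Non-negative integer relaxation; 0 (default) keeps only
#'   edges that occur in some minimum spanning tree.
#' @param max_iter Safety cap on median-addition rounds.
#'
#' @return An object of class `hap_network`: `nodes` (tibble: `node_id`,
#'   `type` observed/median, `sequence`, per-population counts), `edges`
#'   (tibble: `from`, `to`, `weight`), `epsilon`, `total_cost`.
#' @export
median_joining <- function(haps, epsilon = 0, max_iter = 25) {
  stopifnot(epsilon >= 0)
  if (inherits(haps, "hap_tbl")) {
    seq_str <- setNames(haps$sequence, haps$hap_id)
    pops <- hap_populations(haps)
    counts <- as.matrix(haps[, pops, drop = FALSE])
    rownames(counts) <- haps$hap_id
  } else {
    seq_str <- haps
    if (is.null(names(seq_str))) {
      names(seq_str) <- sprintf("H%02d", seq_along(seq_str))
    }
    pops <- character(0)
    counts <- matrix(integer(0), length(seq_str), 0,
                     dimnames = list(names(seq_str), NULL))
  }
  if (length(unique(nchar(seq_str))) > 1) {
    abort("haplotype sequences must share one length")
  }
  # canonical processing order: sort observed nodes by sequence so the
  # result is invariant to input order
  ord <- order(seq_str, names(seq_str))
  seq_str <- seq_str[ord]
  counts <- counts[ord, , drop = FALSE]
  seqs <- lapply(seq_str, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  n_obs <- length(seqs)
  if (n_obs == 1) {
    warn("single haplotype: degenerate one-node network")
    nodes <- tibble(node_id = names(seq_str), type = "observed",
                    sequence = unname(seq_str))
    for (p in pops) nodes[[p]] <- as.integer(counts[, p])
    return(structure(list(nodes = nodes,
                          edges = tibble(from = character(0),
                                         to = character(0),
                                         weight = integer(0)),
                          epsilon = epsilon, total_cost = 0),
                     class = "hap_network"))
  }

  node_seqs <- seqs
  node_type <- rep("observed", n_obs)
  mv_count <- 0L
  node_ids <- names(seq_str)

  for (iter in seq_len(max_iter)) {
    d <- dist_mat(node_seqs)
    edges <- msn_edges(d, epsilon)
    # adjacency for triple enumeration
    n <- length(node_seqs)
    adj <- matrix(FALSE, n, n)
    if (nrow(edges) > 0) {
      adj[edges[, 1:2, drop = FALSE]] <- TRUE
      adj[edges[, 2:1, drop = FALSE]] <- TRUE
    }
    cand_seqs <- list()
    cand_cost <- numeric(0)
    seen <- character(0)
    existing <- vapply(node_seqs, paste, character(1), collapse = "")
    for (u in seq_len(n)) {
      nb <- which(adj[u, ])
      if (length(nb) < 2) next
      prs <- combn(nb, 2)
      for (cidx in seq_len(ncol(prs))) {
        v <- prs[1, cidx]; w <- prs[2, cidx]
        m <- quasi_median(node_seqs[[u]], node_seqs[[v]], node_seqs[[w]])
        key <- paste(m, collapse = "")
        if (key %in% existing || key %in% seen) next
        cost_with <- hamming(m, node_seqs[[u]]) +
          hamming(m, node_seqs[[v]]) + hamming(m, node_seqs[[w]])
        trip <- c(d[u, v], d[u, w], d[v, w])
        cost_without <- sum(trip) - max(trip)
        if (cost_with < cost_without) {
          seen <- c(seen, key)
          cand_seqs[[length(cand_seqs) + 1]] <- m
          cand_cost <- c(cand_cost, cost_with)
        }
      }
    }
    if (length(cand_seqs) == 0) break
    # add the best medians this round (all achieving the minimal cost),
    # in lexicographic order for determinism
    best <- which(cand_cost == min(cand_cost))
    keys <- vapply(cand_seqs[best], paste, character(1), collapse = "")
    for (key_i in order(keys)) {
      mv_count <- mv_count + 1L
      node_seqs[[length(node_seqs) + 1]] <- cand_seqs[[best[key_i]]]
      node_type <- c(node_type, "median")
      node_ids <- c(node_ids, paste0("mv", mv_count))
    }
    if (iter == max_iter) {
      warn("median addition stopped at max_iter without convergence")
    }
  }

  # prune median vectors of degree <= 2, rebuilding the MSN after each pass
  repeat {
    d <- dist_mat(node_seqs)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges[, 1], edges[, 2]), length(node_seqs))
    drop <- which(node_type == "median" & deg <= 2)
    if (length(drop) == 0) break
    node_seqs <- node_seqs[-drop]
    node_type <- node_type[-drop]
    node_ids <- node_ids[-drop]
  }

  nodes <- tibble(node_id = node_ids, type = node_type,
                  sequence = vapply(node_seqs, paste, character(1),
                                    collapse = ""))
  for (p in pops) {
    nodes[[p]] <- ifelse(nodes$type == "observed",
                         as.integer(counts[match(nodes$node_id,
                                                 rownames(counts)), p]),
                         0L)
  }
  edge_tbl <- tibble(from = node_ids[edges[, 1]],
                     to = node_ids[edges[, 2]],
                     weight = as.integer(edges[, 3]))
  structure(list(nodes = nodes, edges = edge_tbl, epsilon = epsilon,
                 total_cost = sum(edge_tbl$weight)),
            class = "hap_network")
}

#' Convert a haplotype network to an igraph graph
#'
#' @param net A [median_joining()] network.
#' @return A weighted undirected `igraph` graph with node attributes.
#' @export
network_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a haplotype network as GML
#' @param net A [median_joining()] network.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_gml <- function(net, path) {
  igraph::write_graph(network_igraph(net), path, format = "gml")
  invisible(path)
}

#' Write a haplotype network as a tab-separated edge list
#' @param net A [median_joining()] network.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}
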