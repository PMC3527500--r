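# Shared internal helpers: seeding, permutation p-values, result plumbing.

# Run `expr` under a locally seeded RNG without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Empirical p-value with the add-one rule: never 0, never above 1.
perm_pvalue <- function(n_as_extreme, n_perm) {
  (1 + n_as_extreme) / (1 + n_perm)
}

#' Run configuration for reproducible analyses
#'
#' Bundles the random seed, replicate counts and significance level that
#' every stochastic step of the pipeline records in its output, so a rerun
#' with the same configuration is bit-reproducible.
#'
#' @param seed Integer random seed.
#' @param n_perm Default number of permutations for permutation tests.
#' @param n_reps Default number of replicates for randomization tests.
#' @param alpha Significance level used for decisions.
#' @param out_dir Directory where [write_result_json()] places files.
#'
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 1, n_perm = 999)
run_config <- function(seed = 1L, n_perm = 999L, n_reps = 1000L,
                       alpha = 0.05, out_dir = ".") {
  stopifnot(n_perm >= 1, n_reps >= 1, alpha > 0, alpha < 1)
  structure(
    list(seed = as.integer(seed), n_perm = as.integer(n_perm),
         n_reps = as.integer(n_reps), alpha = alpha, out_dir = out_dir),
    class = "run_config"
  )
}

#' Write a result object to JSON with its provenance
#'
#' Serialises any of the package's result objects to JSON, embedding the
#' seed and test multiplicities stored on the object so results are
#' traceable to their run configuration.
#'
#' @param x A result object (e.g. from [wc_fstats()], [mantel_spearman()]).
#' @param path Output file path.
#' @param config Optional [run_config()] echoed into the file.
#'
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, config = NULL) {
  payload <- if (is.data.frame(x)) list(table = x) else unclass(x)
  payload$config <- if (!is.null(config)) unclass(config) else NULL
  payload$class <- class(x)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# Enumerate all permutations of 1..n (n small). Returns a matrix with one
# permutation per row.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}
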