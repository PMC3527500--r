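# Input/output: FASTA alignments with population metadata, delimited
# diploid genotype tables, newick genealogies.

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct an aligned-sequences table
#'
#' An alignment is a tibble with one row per sampled individual and columns
#' `sample_id`, `population`, `sex` (`"F"`, `"M"` or `NA`) and `sequence`
#' (uppercase over `A C G T - N`). All sequences must have identical length
#' and `sample_id` must be unique.
#'
#' @param df A data frame with at least `sample_id`, `population`,
#'   `sequence`; `sex` is optional.
#'
#' @return A tibble of class `aln_tbl` with an `aln_length` attribute.
#' @export
#' @examples
#' aligned_sequences(data.frame(
#'   sample_id = c("a", "b"), population = "P1",
#'   sequence = c("ACGT", "ACGA")
#' ))
aligned_sequences <- function(df) {
  df <- as_tibble(df)
  need <- c("sample_id", "population", "sequence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("alignment is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("alignment has no records")
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df <- df[, c("sample_id", "population", "sex", "sequence")]
  df$sample_id <- as.character(df$sample_id)
  df$population <- as.character(df$population)
  df$sex <- toupper(as.character(df$sex))
  df$sex[!df$sex %in% c("F", "M")] <- NA_character_
  df$sequence <- toupper(as.character(df$sequence))

  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")))
  }
  no_pop <- is.na(df$population) | df$population == ""
  if (any(no_pop)) {
    abort(paste0("records lacking a population label: ",
                 paste(df$sample_id[no_pop], collapse = ", ")))
  }
  lens <- nchar(df$sequence)
  if (length(unique(lens)) != 1L) {
    abort(sprintf(
      "ragged alignment: sequence lengths range %d-%d; all must be equal",
      min(lens), max(lens)))
  }
  bad <- grepl("[^ACGTN-]", df$sequence)
  if (any(bad)) {
    abort(paste0("sequences with characters outside {A,C,G,T,-,N}: ",
                 paste(df$sample_id[bad], collapse = ", ")))
  }
  structure(df, aln_length = lens[1],
            class = c("aln_tbl", class(df)))
}

#' Alignment length in base pairs
#' @param aln An [aligned_sequences()] table.
#' @return Integer alignment length.
#' @export
aln_length <- function(aln) attr(aln, "aln_length")

#' Read a FASTA alignment with population metadata
#'
#' Population (and optionally sex) labels are taken from FASTA headers of
#' the form `id|population` or `id|population|sex`, or from a sidecar
#' delimited file with columns `sample_id`, `population` and optionally
#' `sex`. When both are present, the sidecar wins.
#'
#' @param path FASTA file.
#' @param sidecar Optional path to a delimited metadata table.
#' @param sep Field separator inside FASTA headers (default `"|"`).
#'
#' @return An [aligned_sequences()] tibble.
#' @export
read_fasta_alignment <- function(path, sidecar = NULL, sep = "|") {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort(paste0("no FASTA records in ", path))
  seqs <- vapply(as.character(dna), function(x) paste(x, collapse = ""),
                 character(1))
  headers <- names(dna)
  parts <- stringr::str_split(headers, stringr::fixed(sep))
  df <- tibble(
    sample_id  = vapply(parts, `[`, character(1), 1),
    population = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1)),
    sex        = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, character(1)),
    sequence   = unname(seqs)
  )
  if (!is.null(sidecar)) {
    meta <- readr::read_delim(sidecar, show_col_types = FALSE,
                              trim_ws = TRUE)
    names(meta) <- tolower(names(meta))
    if (!all(c("sample_id", "population") %in% names(meta))) {
      abort("sidecar must have columns sample_id and population")
    }
    idx <- match(df$sample_id, meta$sample_id)
    hit <- !is.na(idx)
    df$population[hit] <- as.character(meta$population)[idx[hit]]
    if ("sex" %in% names(meta)) df$sex[hit] <- as.character(meta$sex)[idx[hit]]
  }
  no_pop <- is.na(df$population) | df$population == ""
  if (any(no_pop)) {
    abort(paste0(
      "no population label (header or sidecar) for: ",
      paste(df$sample_id[no_pop], collapse = ", ")))
  }
  aligned_sequences(df)
}

#' Write a FASTA alignment
#'
#' Headers encode metadata as `id|population` or `id|population|sex`, the
#' convention [read_fasta_alignment()] parses, so write/read round-trips.
#'
#' @param aln An [aligned_sequences()] table.
#' @param path Output file.
#' @param sep Header field separator.
#'
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, sep = "|") {
  aln <- aligned_sequences(aln)
  hdr <- ifelse(is.na(aln$sex),
                paste(aln$sample_id, aln$population, sep = sep),
                paste(aln$sample_id, aln$population, aln$sex, sep = sep))
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- aln$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Construct a diploid genotype table
#'
#' Genotypes live in a long tibble with one row per individual x locus:
#' columns `sample_id`, `population`, `sex`, `locus`, `a1`, `a2` (positive
#' integer allele codes, stored smaller-first; both `NA` when missing).
#' Every individual must be genotyped at one locus at least.
#'
#' @param df A long data frame as above (`sex` optional).
#' @param loci Optional character vector fixing locus order; defaults to
#'   first-appearance order.
#'
#' @return A tibble of class `geno_tbl` with a `loci` attribute.
#' @export
#' @examples
#' genotype_table(data.frame(
#'   sample_id = "ind1", population = "PopA", locus = "L1",
#'   a1 = 186, a2 = 182
#' ))
genotype_table <- function(df, loci = NULL) {
  df <- as_tibble(df)
  need <- c("sample_id", "population", "locus", "a1", "a2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df <- df[, c("sample_id", "population", "sex", "locus", "a1", "a2")]
  df$sample_id <- as.character(df$sample_id)
  df$population <- as.character(df$population)
  df$sex <- toupper(as.character(df$sex))
  df$sex[!df$sex %in% c("F", "M")] <- NA_character_
  df$locus <- as.character(df$locus)

  for (col in c("a1", "a2")) {
    v <- df[[col]]
    if (!is.numeric(v)) abort(paste0("allele column ", col, " is not numeric"))
    if (any(!is.na(v) & (v <= 0 | v != round(v)))) {
      abort("allele codes must be positive integers")
    }
    df[[col]] <- as.integer(v)
  }
  half <- xor(is.na(df$a1), is.na(df$a2))
  if (any(half)) {
    abort(paste0("half-missing genotypes (one allele NA) for: ",
                 paste(df$sample_id[half], collapse = ", ")))
  }
  # canonical order: smaller allele first
  swap <- !is.na(df$a1) & df$a1 > df$a2
  tmp <- df$a1[swap]; df$a1[swap] <- df$a2[swap]; df$a2[swap] <- tmp

  if (anyDuplicated(df[, c("sample_id", "locus")])) {
    abort("duplicate (sample_id, locus) rows")
  }
  typed <- tapply(!is.na(df$a1), df$sample_id, any)
  if (any(!typed)) {
    abort(paste0("individuals with all loci missing: ",
                 paste(names(typed)[!typed], collapse = ", ")))
  }
  loci <- loci %||% unique(df$locus)
  if (!setequal(loci, unique(df$locus))) {
    abort("`loci` must list exactly the loci present in `df`")
  }
  df <- df[order(match(df$locus, loci), df$sample_id), ]
  structure(df, loci = loci, class = c("geno_tbl", class(as_tibble(df))))
}

#' Loci of a genotype table, in canonical order
#' @param gt A [genotype_table()].
#' @return Character vector of locus names.
#' @export
loci_names <- function(gt) attr(gt, "loci")

#' Read a delimited diploid genotype table
#'
#' Expects columns `sample_id`, `population`, optionally `sex`, then one
#' column per locus with genotypes written `a/b` (integer allele codes).
#' Missing genotypes may be coded `?`, `-9` or an empty field.
#'
#' @param path Delimited text file (comma, tab or semicolon separated).
#'
#' @return A [genotype_table()] in long form.
#' @export
read_genotype_table <- function(path) {
  wide <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE,
                            col_types = readr::cols(.default = "c"))
  names(wide)[1:2] <- tolower(names(wide)[1:2])
  if (!all(c("sample_id", "population") %in% names(wide)[1:2])) {
    abort("first two columns must be sample_id and population")
  }
  has_sex <- length(names(wide)) >= 3 && tolower(names(wide)[3]) == "sex"
  if (has_sex) names(wide)[3] <- "sex"
  loci <- names(wide)[(if (has_sex) 4 else 3):ncol(wide)]
  if (length(loci) == 0) abort("no locus columns found")

  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(loci),
                              names_to = "locus", values_to = "geno")
  g <- long$geno
  missing <- is.na(g) | g %in% c("?", "-9", "-9/-9", "")
  parts <- stringr::str_split_fixed(ifelse(missing, "NA/NA", g), "/", 2)
  suppressWarnings({
    a1 <- as.integer(parts[, 1])
    a2 <- as.integer(parts[, 2])
  })
  bad <- !missing & (is.na(a1) | is.na(a2))
  if (any(bad)) {
    abort(paste0(
      "unparseable genotype(s): ",
      paste(sprintf("%s at %s ('%s')", long$sample_id[bad],
                    long$locus[bad], g[bad]), collapse = "; ")))
  }
  long$a1 <- a1
  long$a2 <- a2
  if (!has_sex) long$sex <- NA_character_
  genotype_table(long[, c("sample_id", "population", "sex", "locus",
                          "a1", "a2")], loci = loci)
}

#' Write a genotype table as delimited text
#'
#' Emits the wide layout [read_genotype_table()] reads: one column per
#' locus, genotypes `a/b`, missing as `?`.
#'
#' @param gt A [genotype_table()].
#' @param path Output file.
#' @param delim Field delimiter (default `","`).
#'
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path, delim = ",") {
  gt <- genotype_table(gt, loci = loci_names(gt))
  gt$geno <- ifelse(is.na(gt$a1), "?", paste0(gt$a1, "/", gt$a2))
  wide <- tidyr::pivot_wider(
    gt[, c("sample_id", "population", "sex", "locus", "geno")],
    names_from = "locus", values_from = "geno")
  wide <- wide[, c("sample_id", "population", "sex", loci_names(gt))]
  readr::write_delim(wide, path, delim = delim, na = "")
  invisible(path)
}

#' Read a newick genealogy
#'
#' Thin validating wrapper: multifurcations are allowed, duplicate tip
#' labels are not.
#'
#' @param path Newick file (or a literal newick string).
#'
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  open <- stringr::str_count(txt, stringr::fixed("("))
  close <- stringr::str_count(txt, stringr::fixed(")"))
  if (open != close) {
    abort(sprintf("unbalanced parentheses in newick input (%d '(' vs %d ')')",
                  open, close))
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) NULL)
  if (is.null(tr)) abort(paste0("could not parse newick input: ", path))
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  tr
}
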