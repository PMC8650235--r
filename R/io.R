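#' Expression tables
#'
#' An expression table is a wide tibble with one row per gene: a `gene_id`
#' column, a `gene_type` column (`"lncRNA"` or `"mRNA"`), and one numeric
#' column per sample, holding log2-scale expression after preprocessing.
#' This mirrors the on-disk TSV layout, so [read_expression_tsv()] and
#' [write_expression_tsv()] round-trip it exactly.
#'
#' @param expr An expression table.
#' @return `expr_values()` returns the numeric gene x sample matrix with
#'   gene ids as row names; `expr_samples()` the sample ids;
#'   `expr_gene_types()` the named gene-type vector.
#' @name expression-table
NULL

check_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) {
    abort(sprintf("`%s` must be a data frame (wide expression table).", arg))
  }
  if (!all(c("gene_id", "gene_type") %in% names(expr))) {
    abort(sprintf("`%s` must have `gene_id` and `gene_type` columns.", arg))
  }
  if (anyDuplicated(expr$gene_id)) {
    abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  bad <- setdiff(unique(expr$gene_type), c("lncRNA", "mRNA"))
  if (length(bad)) {
    abort(sprintf("Unknown gene_type value(s): %s", toString(bad)))
  }
  invisible(expr)
}

#' @rdname expression-table
#' @export
expr_values <- function(expr) {
  check_expression(expr)
  m <- as.matrix(expr[, setdiff(names(expr), c("gene_id", "gene_type")), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' @rdname expression-table
#' @export
expr_samples <- function(expr) {
  setdiff(names(expr), c("gene_id", "gene_type"))
}

#' @rdname expression-table
#' @export
expr_gene_types <- function(expr) {
  check_expression(expr)
  setNames(expr$gene_type, expr$gene_id)
}

#' Drop genes with excessive missingness
#'
#' Removes genes whose fraction of missing values across samples is strictly
#' greater than `max_na_frac`; a gene missing in exactly that fraction of
#' samples is retained. Row order is preserved and the operation is
#' idempotent.
#'
#' @param expr Expression table (possibly with `NA` entries).
#' @param max_na_frac Maximum tolerated missing fraction per gene
#'   (default 0.20).
#' @return The filtered expression table.
#' @export
#' @examples
#' x <- tibble::tibble(gene_id = c("g1", "g2"), gene_type = "mRNA",
#'                     s1 = c(1, NA), s2 = c(2, NA), s3 = c(3, NA),
#'                     s4 = c(4, 5), s5 = c(5, 6))
#' filter_genes(x) # g2 is 60% missing and is dropped
filter_genes <- function(expr, max_na_frac = 0.20) {
  check_expression(expr)
  m <- expr_values(expr)
  if (ncol(m) == 0L) abort("`expr` has no sample columns.")
  na_frac <- rowMeans(is.na(m))
  keep <- na_frac <= max_na_frac
  if (!any(keep)) warn("All genes exceeded the missingness threshold; returning an empty table.")
  as_tibble(expr[keep, , drop = FALSE])
}

#' Fill missing values and log2-transform
#'
#' Remaining `NA` entries are replaced by 0, then every value is mapped to
#' `log2(x + 1)`. The pseudocount keeps filled zeros finite and maps 0 to 0,
#' so the transform is monotone and non-negative for non-negative input.
#'
#' @param expr Expression table on the raw (FPKM-like, non-negative) scale.
#' @return Expression table on the log2 scale with no missing values.
#' @export
fill_and_log <- function(expr) {
  check_expression(expr)
  samp <- expr_samples(expr)
  m <- expr_values(expr)
  m[is.na(m)] <- 0
  if (any(m < 0)) abort("Expression values must be non-negative before log2 transform.")
  m <- log2(m + 1)
  out <- expr
  out[samp] <- as_tibble(m)
  as_tibble(out)
}

#' Read and write expression TSV files
#'
#' The on-disk format has one row per gene with columns
#' `gene_id`, `gene_type`, then one column per sample. Gzip-compressed files
#' are read transparently.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @param expr Expression table to write.
#' @return `read_expression_tsv()` returns an expression table.
#' @export
read_expression_tsv <- function(path) {
  expr <- read_tsv_exact(path)
  check_expression(expr)
  expr
}

# base-R parser: strtod is correctly rounded, so doubles written with 17
# significant digits round-trip bit-exactly
read_tsv_exact <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  as_tibble(utils::read.delim(con, sep = "\t", check.names = FALSE,
                              stringsAsFactors = FALSE))
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  readr::write_tsv(format_full_precision(expr), path)
  invisible(path)
}

# 17 significant digits round-trip IEEE doubles exactly through text
format_full_precision <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' Normalise TNM stage labels
#'
#' Maps free-text stage strings such as `"Stage IIIA"` or `"iiib"` to the
#' main stages `"I"`--`"IV"`, dropping sub-stage letters. Unrecognised or
#' missing values become `NA`.
#'
#' @param stage Character vector of stage labels.
#' @return Character vector with values in `c("I","II","III","IV")` or `NA`.
#' @export
normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("^(IV|III|II|I).*$", "\\1", s)
  s[!s %in% c("I", "II", "III", "IV")] <- NA_character_
  s
}

#' Read and write clinical TSV files
#'
#' Expected columns: `sample_id`, `os_time`, `os_event`, `pfs_time`,
#' `pfs_event`, `age`, `stage` (and optionally `tissue`). Stage labels are
#' normalised to I--IV with [normalize_stage()]; event indicators must be
#' 0/1 and times positive.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @param clinical Clinical table to write.
#' @return A tibble, one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  cl <- read_tsv_exact(path)
  check_clinical(cl)
  cl$stage <- normalize_stage(cl$stage)
  cl
}

#' @rdname read_clinical_tsv
#' @export
write_clinical_tsv <- function(clinical, path) {
  check_clinical(clinical)
  readr::write_tsv(clinical, path)
  invisible(path)
}

check_clinical <- function(clinical) {
  need <- c("sample_id", "os_time", "os_event", "pfs_time", "pfs_event", "age", "stage")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) abort(sprintf("Clinical table is missing column(s): %s", toString(miss)))
  for (ev in c("os_event", "pfs_event")) {
    v <- clinical[[ev]]
    if (!all(v %in% c(0, 1))) abort(sprintf("`%s` must be 0/1.", ev))
  }
  for (tm in c("os_time", "pfs_time")) {
    v <- clinical[[tm]]
    if (any(!is.na(v) & v <= 0)) abort(sprintf("`%s` must be positive.", tm))
  }
  invisible(clinical)
}

#' Read gene sets in GMT format
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are removed. Gzip input is supported.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of gene ids, with a
#'   `description` attribute carrying the per-set description column.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- list()
    attr(out, "description") <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT parse error: line %d has fewer than 3 tab-separated fields.", short[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) abort("GMT file contains duplicated set names.")
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  sets
}
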