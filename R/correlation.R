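#' Spearman correlation between lncRNAs and mRNAs
#'
#' Computes the full lncRNA x mRNA matrix of Spearman rank correlations
#' across samples. Ties receive average ranks (the classic
#' `1 - 6*sum(d^2)/(n(n^2-1))` shortcut is recovered exactly in the tie-free
#' case). Genes with zero rank variance (constant expression) cannot be
#' correlated; their entries are set to 0 and a warning lists how many genes
#' were affected, so downstream mutual ranks stay defined.
#'
#' @param expr Expression table containing both lncRNA and mRNA rows (see
#'   [read_expression_tsv()] for the layout).
#' @return A numeric matrix with one row per lncRNA and one column per mRNA,
#'   entries in `[-1, 1]`.
#' @export
spearman_matrix <- function(expr) {
  check_expression(expr)
  m <- expr_values(expr)
  types <- expr_gene_types(expr)
  if (ncol(m) < 3L) abort("At least 3 samples are required for rank correlation.")
  lnc <- m[types == "lncRNA", , drop = FALSE]
  mrna <- m[types == "mRNA", , drop = FALSE]
  if (nrow(lnc) == 0L || nrow(mrna) == 0L) {
    abort("Both lncRNA and mRNA rows must be present.")
  }
  # rank rows once, then Pearson on ranks == Spearman with average ranks
  rl <- t(apply(lnc, 1, rank))
  rm_ <- t(apply(mrna, 1, rank))
  const_l <- apply(rl, 1, function(r) all(r == r[1]))
  const_m <- apply(rm_, 1, function(r) all(r == r[1]))
  scc <- suppressWarnings(cor(t(rl), t(rm_), method = "pearson"))
  n_const <- sum(const_l) + sum(const_m)
  if (n_const > 0) {
    warn(sprintf("%d constant gene(s): their correlations are set to 0.", n_const))
    scc[const_l, ] <- 0
    scc[, const_m] <- 0
  }
  scc[is.na(scc)] <- 0
  scc
}

#' Mutual ranks of a correlation matrix
#'
#' For a lncRNA `X` and mRNA `Y`, the mutual rank is the geometric mean of
#' the rank of `scc[X, Y]` within row `X` (over all mRNAs) and within column
#' `Y` (over all lncRNAs). Under the `"positive"` orientation rank 1 is the
#' largest correlation, so strongly positively correlated pairs get small
#' mutual ranks; under `"negative"` rank 1 is the most negative correlation.
#' Ties get average ranks.
#'
#' @param scc lncRNA x mRNA correlation matrix from [spearman_matrix()].
#' @param orientation `"positive"` or `"negative"`.
#' @return Matrix of mutual ranks (same dimnames as `scc`), all entries
#'   >= 1 and <= `sqrt(nrow * ncol)` cannot be exceeded jointly by both
#'   directional ranks.
#' @export
mutual_rank <- function(scc, orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  s <- if (orientation == "positive") -scc else scc
  row_rank <- t(apply(s, 1, rank))
  col_rank <- apply(s, 2, rank)
  mr <- sqrt(row_rank * col_rank)
  dimnames(mr) <- dimnames(scc)
  attr(mr, "orientation") <- orientation
  mr
}

#' Mutual-rank cutoff for correlated-mRNA selection
#'
#' The cutoff retaining a fraction of the lncRNA-mRNA search space:
#' `sqrt(n_lnc * n_mrna) * fraction`. With 4342 lncRNAs, 16619 mRNAs and
#' fraction 0.001 this evaluates to about 8.49.
#'
#' @param n_lnc,n_mrna Numbers of lncRNAs and mRNAs.
#' @param fraction Fraction of the geometric-mean dimension retained,
#'   strictly between 0 and 1.
#' @return The numeric cutoff.
#' @export
#' @examples
#' mr_cutoff(4342, 16619, 0.001)
mr_cutoff <- function(n_lnc, n_mrna, fraction = 0.001) {
  if (n_lnc < 1 || n_mrna < 1) abort("Gene counts must be >= 1.")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.")
  }
  sqrt(n_lnc * n_mrna) * fraction
}

#' Select each lncRNA's correlated mRNA sets
#'
#' An mRNA belongs to a lncRNA's positively (negatively) correlated set when
#' its positive- (negative-) orientation mutual rank is less than or equal
#' to the cutoff. Sets may legitimately be empty.
#'
#' @param mr_pos,mr_neg Mutual-rank matrices from [mutual_rank()] under the
#'   two orientations; they must share dimnames.
#' @param cutoff Mutual-rank cutoff, usually from [mr_cutoff()].
#' @return A tibble with one row per lncRNA: `lnc_id`, and list-columns
#'   `pos_set` and `neg_set` of mRNA ids. The cutoff is stored in the
#'   `cutoff` attribute.
#' @export
select_correlated_sets <- function(mr_pos, mr_neg, cutoff) {
  if (!identical(dimnames(mr_pos), dimnames(mr_neg))) {
    abort("`mr_pos` and `mr_neg` must share the same gene index.")
  }
  mrna_ids <- colnames(mr_pos)
  out <- tibble(
    lnc_id = rownames(mr_pos),
    pos_set = lapply(seq_len(nrow(mr_pos)), function(i) mrna_ids[mr_pos[i, ] <= cutoff]),
    neg_set = lapply(seq_len(nrow(mr_neg)), function(i) mrna_ids[mr_neg[i, ] <= cutoff])
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "mrna_universe") <- mrna_ids
  out
}
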