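#' Set-overlap association index between two lncRNAs
#'
#' Given the correlated-mRNA sets of two lncRNAs and the size of the mRNA
#' universe, returns
#' `(|X ∩ Y| * n - |X| * |Y|) / sqrt(|X| |Y| (n - |X|) (n - |Y|))`,
#' which equals the Pearson correlation (phi coefficient) of the two 0/1
#' membership indicator vectors over the universe. Values lie in `[-1, 1]`;
#' identical sets give 1.
#'
#' @param set_x,set_y Character vectors of mRNA ids.
#' @param n_universe Total number of mRNAs the sets were drawn from.
#' @return The association index, a single number.
#' @export
#' @examples
#' association_pcc(paste0("g", 1:10), paste0("g", 6:15), 100)
association_pcc <- function(set_x, set_y, n_universe) {
  a <- length(unique(set_x))
  b <- length(unique(set_y))
  if (a == 0L || b == 0L || a >= n_universe || b >= n_universe) {
    abort("Association index is undefined for empty or universe-sized sets.")
  }
  ov <- length(intersect(set_x, set_y))
  (ov * n_universe - a * b) / sqrt(a * b * (n_universe - a) * (n_universe - b))
}

#' Build the thresholded lncRNA association edge list
#'
#' Computes the association index between every pair of lncRNAs from their
#' positively (orientation `"positive"`, yielding the positive lncRNA
#' association network, PLAN) or negatively (`"negative"`, NLAN) correlated
#' mRNA sets, and keeps pairs whose index is strictly greater than the
#' threshold. lncRNAs whose set is empty or covers the whole universe have
#' an undefined index and are skipped with a warning. The pairwise indices
#' are computed in one shot from the indicator matrix (cross-products), so
#' the result is exact and fast.
#'
#' @param sets Correlated sets tibble from [select_correlated_sets()].
#' @param orientation `"positive"` or `"negative"`.
#' @param threshold Association-index threshold; edges require `pcc >
#'   threshold` (strict). Default 0.7.
#' @param n_universe mRNA universe size; defaults to the universe recorded
#'   by [select_correlated_sets()].
#' @return A tibble with columns `lnc_a`, `lnc_b` (with `lnc_a < lnc_b`),
#'   `pcc` and `orientation`, sorted by decreasing `pcc`. The full pairwise
#'   index matrix over participating lncRNAs is attached as attribute
#'   `pcc_matrix` (used by [intra_inter_comparison()]).
#' @export
build_edge_list <- function(sets, orientation = c("positive", "negative"),
                            threshold = 0.7, n_universe = NULL) {
  orientation <- match.arg(orientation)
  if (threshold <= -1 || threshold >= 1) abort("`threshold` must lie in (-1, 1).")
  universe <- attr(sets, "mrna_universe")
  n_universe <- n_universe %||% length(universe)
  if (is.null(n_universe) || n_universe < 2) abort("`n_universe` must be supplied (>= 2).")
  col <- if (orientation == "positive") "pos_set" else "neg_set"
  sz <- lengths(sets[[col]])
  ok <- sz > 0L & sz < n_universe
  if (any(!ok)) {
    warn(sprintf(
      "%d lncRNA(s) with empty or universe-sized %s sets were skipped.",
      sum(!ok), orientation))
  }
  ids <- sets$lnc_id[ok]
  empty <- tibble(lnc_a = character(), lnc_b = character(),
                  pcc = numeric(), orientation = character())
  if (length(ids) < 2L) return(empty)
  if (is.null(universe)) universe <- unique(unlist(sets[[col]][ok]))
  ind <- matrix(0L, length(ids), n_universe, dimnames = list(ids, NULL))
  pos_of <- setNames(seq_along(universe), universe)
  for (i in seq_along(ids)) {
    ind[i, pos_of[sets[[col]][ok][[i]]]] <- 1L
  }
  s <- rowSums(ind)
  ov <- tcrossprod(ind)
  num <- ov * n_universe - outer(s, s)
  den <- sqrt(outer(s * (n_universe - s), s * (n_universe - s)))
  pcc <- num / den
  keep <- upper.tri(pcc) & pcc > threshold
  if (!any(keep)) {
    out <- empty
  } else {
    idx <- which(keep, arr.ind = TRUE)
    out <- tibble(
      lnc_a = pmin(ids[idx[, 1]], ids[idx[, 2]]),
      lnc_b = pmax(ids[idx[, 1]], ids[idx[, 2]]),
      pcc = pcc[keep],
      orientation = orientation
    ) |> arrange(desc(.data$pcc))
  }
  attr(out, "pcc_matrix") <- pcc
  out
}
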