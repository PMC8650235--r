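#' Module-level mutual-rank ordering of mRNAs
#'
#' Ranks all mRNAs by their mutual rank with a module's lncRNAs, using the
#' ordering convention in which the mRNAs of interest score HIGH: for a
#' positive-network (PLAN) module the Spearman correlations are ranked
#' ascending, so positively correlated mRNAs get large mutual ranks; for a
#' negative-network (NLAN) module they are ranked descending, putting the
#' negatively correlated mRNAs on top. Per-mRNA scores are aggregated over
#' the module's lncRNAs by the mean mutual rank (or the minimum, as an
#' alternative).
#'
#' @param scc lncRNA x mRNA Spearman matrix from [spearman_matrix()].
#' @param members Character vector of the module's lncRNA ids.
#' @param orientation Network orientation of the module: `"positive"`
#'   (PLAN) or `"negative"` (NLAN).
#' @param aggregate `"mean"` (default) or `"min"`.
#' @return A tibble `mrna_id`, `score`, sorted by decreasing score.
#' @export
module_rank <- function(scc, members, orientation = c("positive", "negative"),
                        aggregate = c("mean", "min")) {
  orientation <- match.arg(orientation)
  aggregate <- match.arg(aggregate)
  if (!length(members)) abort("`members` must contain at least one lncRNA.")
  missing <- setdiff(members, rownames(scc))
  if (length(missing)) abort(sprintf("lncRNA(s) not in the correlation matrix: %s", toString(missing)))
  # flip the ranking orientation so the module's correlated mRNAs score high
  flip <- if (orientation == "positive") "negative" else "positive"
  mr <- mutual_rank(scc, orientation = flip)
  sub <- mr[members, , drop = FALSE]
  score <- if (aggregate == "mean") colMeans(sub) else apply(sub, 2, min)
  tibble(mrna_id = colnames(scc), score = unname(score)) |>
    arrange(desc(.data$score))
}

# Weighted Kolmogorov-Smirnov-like enrichment score from sorted hit
# positions. `stats_abs_p` is |score|^p of the full ranked list.
gsea_es_from_positions <- function(pos, stats_abs_p, n_total) {
  k <- length(pos)
  if (k == 0L || k >= n_total) return(list(es = NA_real_, arg = NA_integer_))
  pos <- sort(pos)
  w <- stats_abs_p[pos]
  nr <- sum(w)
  h <- if (nr > 0) cumsum(w) / nr else seq_len(k) / k
  miss <- 1 / (n_total - k)
  offs <- (pos - seq_len(k)) * miss
  at_hit <- h - offs
  before_hit <- c(0, h[-k]) - offs
  i_max <- which.max(at_hit)
  i_min <- which.min(before_hit)
  if (at_hit[i_max] >= -before_hit[i_min]) {
    list(es = at_hit[i_max], arg = i_max)
  } else {
    list(es = before_hit[i_min], arg = i_min)
  }
}

#' Enrichment score of one gene set in a ranked list
#'
#' Running-sum enrichment score: walking down the ranked list, hitting a set
#' member increments the sum proportionally to `|score|^weight_p`
#' (normalised so the increments total 1), and every miss decrements it by
#' `1/(N - set size)`. The score is the maximal deviation from zero, in
#' `[-1, 1]`.
#'
#' @param ranked Tibble `mrna_id`, `score` sorted by decreasing score (as
#'   from [module_rank()]), or a named numeric vector.
#' @param set Character vector of member gene ids.
#' @param weight_p Weighting exponent (default 1; 0 gives the classic
#'   unweighted Kolmogorov-Smirnov statistic).
#' @return List with `es` and `leading_edge` (gene ids up to the extremum).
#' @export
gsea_es <- function(ranked, set, weight_p = 1) {
  r <- as_ranked(ranked)
  pos <- sort(which(r$ids %in% set))
  n <- length(r$ids)
  if (length(pos) == 0L) abort("The set has no members in the ranked list.")
  if (length(pos) >= n) abort("A set covering the whole ranked list has an undefined score.")
  res <- gsea_es_from_positions(pos, abs(r$scores)^weight_p, n)
  le <- if (res$es >= 0) r$ids[pos[seq_len(res$arg)]] else r$ids[pos[res$arg:length(pos)]]
  list(es = res$es, leading_edge = le)
}

as_ranked <- function(ranked) {
  if (inherits(ranked, "lncmod_ranked")) return(ranked)
  if (is.data.frame(ranked)) {
    ids <- ranked$mrna_id %||% ranked[[1]]
    scores <- ranked$score %||% ranked[[2]]
  } else {
    ids <- names(ranked)
    scores <- unname(ranked)
  }
  if (anyDuplicated(ids)) abort("Ranked list contains duplicate ids.")
  ord <- order(scores, decreasing = TRUE)
  structure(list(ids = ids[ord], scores = scores[ord]), class = "lncmod_ranked")
}

#' Preranked gene set enrichment analysis
#'
#' Computes the running-sum enrichment score of each gene set against a
#' ranked list, then calibrates it with `n_perm` random gene sets of the
#' same size drawn from the list (the only valid null for an externally
#' ranked list). The normalised enrichment score (NES) divides the score by
#' the mean magnitude of same-sign permutation scores; the nominal p-value
#' is the same-sign permutation tail fraction; FDR q compares each NES with
#' the pooled permutation NES distribution, positive and negative sides
#' separately.
#'
#' @param ranked Ranked list (see [gsea_es()]).
#' @param sets Named list of gene-id vectors, e.g. from [read_gmt()].
#' @param n_perm Number of random-set permutations (default 1000; fewer
#'   than 100 triggers a warning).
#' @param weight_p Hit-weighting exponent (default 1).
#' @param min_size,max_size Size window; sets with fewer/more members
#'   present in the ranked list are skipped.
#' @param seed Optional integer seed for the permutations.
#' @return A tibble `set_name`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`,
#'   `leading_edge` (list-column), sorted by decreasing NES.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight_p = 1,
                           min_size = 15, max_size = 500, seed = NULL) {
  if (n_perm < 100) warn("Fewer than 100 permutations give unstable p-values and FDR.")
  if (!is.null(seed)) set.seed(seed)
  r <- as_ranked(ranked)
  n <- length(r$ids)
  wts <- abs(r$scores)^weight_p
  sizes <- vapply(sets, function(s) sum(r$ids %in% s), integer(1))
  keep <- sizes >= max(min_size, 1L) & sizes <= min(max_size, n - 1L)
  skipped <- names(sets)[!keep]
  if (length(skipped)) {
    inform(sprintf("%d set(s) outside the size window were skipped.", length(skipped)))
  }
  sets <- sets[keep]
  if (!length(sets)) {
    return(tibble(set_name = character(), size = integer(), es = numeric(),
                  nes = numeric(), nominal_p = numeric(), fdr_q = numeric(),
                  leading_edge = list()))
  }
  obs <- lapply(sets, function(s) gsea_es(r, s, weight_p))
  es <- vapply(obs, `[[`, numeric(1), "es")
  size <- sizes[keep]

  nes <- numeric(length(sets))
  nominal_p <- numeric(length(sets))
  perm_nes_all <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    k <- size[i]
    perm_es <- vapply(seq_len(n_perm), function(j) {
      gsea_es_from_positions(sample.int(n, k), wts, n)$es
    }, numeric(1))
    pos_mean <- mean(perm_es[perm_es >= 0])
    neg_mean <- mean(abs(perm_es[perm_es < 0]))
    perm_nes <- ifelse(perm_es >= 0,
                       perm_es / pos_mean,
                       perm_es / neg_mean)
    if (es[i] >= 0) {
      same <- perm_es[perm_es >= 0]
      nes[i] <- if (is.finite(pos_mean) && pos_mean > 0) es[i] / pos_mean else NA_real_
      nominal_p[i] <- if (length(same)) mean(same >= es[i]) else NA_real_
    } else {
      same <- perm_es[perm_es < 0]
      nes[i] <- if (is.finite(neg_mean) && neg_mean > 0) es[i] / neg_mean else NA_real_
      nominal_p[i] <- if (length(same)) mean(same <= es[i]) else NA_real_
    }
    perm_nes_all[[i]] <- perm_nes[is.finite(perm_nes)]
  }
  pool <- unlist(perm_nes_all)
  fdr_q <- vapply(seq_along(sets), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      top <- mean(pool[pool >= 0] >= nes[i])
      denom <- mean(nes[nes >= 0 & is.finite(nes)] >= nes[i])
    } else {
      top <- mean(pool[pool < 0] <= nes[i])
      denom <- mean(nes[nes < 0 & is.finite(nes)] <= nes[i])
    }
    if (!is.finite(denom) || denom == 0) return(NA_real_)
    min(1, top / denom)
  }, numeric(1))

  tibble(
    set_name = names(sets),
    size = as.integer(size),
    es = unname(es),
    nes = unname(nes),
    nominal_p = unname(nominal_p),
    fdr_q = unname(fdr_q),
    leading_edge = lapply(obs, `[[`, "leading_edge")
  ) |> arrange(desc(.data$nes))
}
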