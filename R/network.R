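#' Build an lncRNA association network from an edge list
#'
#' Nodes are the union of edge endpoints (isolated lncRNAs are not carried);
#' duplicate edges (in either order) are collapsed and self-loops are
#' rejected. The result is a simple undirected igraph graph with a `pcc`
#' edge attribute and an `orientation` graph attribute.
#'
#' @param edges Edge tibble from [build_edge_list()] (columns `lnc_a`,
#'   `lnc_b`, `pcc`, `orientation`).
#' @return An `igraph` object.
#' @export
build_network <- function(edges) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::graph_attr(g, "orientation") <- if (nrow(edges)) edges$orientation[1] else NA_character_
    return(g)
  }
  if (any(edges$lnc_a == edges$lnc_b)) abort("Self-loops are not allowed in the edge list.")
  ori <- unique(edges$orientation)
  if (length(ori) > 1L) abort("Edges must share a single orientation.")
  key <- paste(pmin(edges$lnc_a, edges$lnc_b), pmax(edges$lnc_a, edges$lnc_b))
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("lnc_a", "lnc_b", "pcc")], directed = FALSE)
  igraph::graph_attr(g, "orientation") <- ori
  g
}

#' Extract size-filtered lncRNA modules
#'
#' Modules are the connected components of the association network with at
#' least `min_size` nodes, labelled `P1, P2, ...` (positive orientation) or
#' `N1, N2, ...` (negative) in decreasing size order; ties are broken by the
#' lexicographically smallest member id. Connected components are the
#' minimal clustering assumption for a sparsely thresholded graph; a custom
#' `community_fun` (taking the graph, returning a membership vector named by
#' node) can be plugged in without changing downstream stages.
#'
#' @param net Network from [build_network()].
#' @param min_size Minimum module size (default 12).
#' @param community_fun Optional alternative community-detection function.
#' @return A tibble `lnc_id`, `module_id`, `orientation`; one row per member
#'   of a qualifying module.
#' @export
extract_modules <- function(net, min_size = 12, community_fun = NULL) {
  ori <- igraph::graph_attr(net, "orientation")
  prefix <- if (identical(ori, "negative")) "N" else "P"
  empty <- tibble(lnc_id = character(), module_id = character(),
                  orientation = character())
  if (igraph::vcount(net) == 0L) return(empty)
  memb <- if (is.null(community_fun)) {
    igraph::components(net)$membership
  } else {
    community_fun(net)
  }
  groups <- split(names(memb), memb)
  groups <- groups[lengths(groups) >= min_size]
  if (!length(groups)) return(empty)
  first_id <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-lengths(groups), first_id)
  groups <- groups[ord]
  bind_rows(lapply(seq_along(groups), function(i) {
    tibble(lnc_id = sort(groups[[i]]),
           module_id = paste0(prefix, i),
           orientation = ori %||% NA_character_)
  }))
}

#' Degree density of a network
#'
#' For each observed degree `k`, `pk` is the fraction of nodes with that
#' degree; the densities sum to 1.
#'
#' @param net Network from [build_network()].
#' @return A tibble `k`, `pk` sorted by `k`.
#' @export
degree_density <- function(net) {
  if (igraph::vcount(net) == 0L) abort("Network is empty.")
  deg <- igraph::degree(net)
  tb <- table(deg)
  tibble(k = as.numeric(names(tb)), pk = as.numeric(tb) / length(deg))
}

#' Log-log power-law fit of the degree distribution
#'
#' Ordinary least squares of `log10(pk)` on `log10(k)` over points with
#' positive density, as a scale-free diagnostic. No binning is applied;
#' unobserved degrees are simply absent.
#'
#' @param k,pk Degrees and densities, e.g. from [degree_density()].
#' @return An object of class `lncmod_topology_fit` with elements `slope`,
#'   `intercept`, `p_value` (two-sided, for the slope), `r_squared`, and the
#'   fitted points. Use [tidy()]/[glance()] or [autoplot()] on it.
#' @export
power_law_fit <- function(k, pk) {
  if (is.data.frame(k)) { pk <- k$pk; k <- k$k }
  keep <- pk > 0
  k <- k[keep]; pk <- pk[keep]
  if (length(unique(k)) < 3L) abort("At least 3 distinct degrees with positive density are required.")
  x <- log10(k); y <- log10(pk)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # exact fits trigger a harmless warning
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = unname(sm$coefficients[2, 4]),
    r_squared = sm$r.squared,
    points = tibble(k = k, pk = pk)
  )
  class(out) <- "lncmod_topology_fit"
  out
}

#' @export
#' @method print lncmod_topology_fit
print.lncmod_topology_fit <- function(x, ...) {
  cat(sprintf("Power-law degree fit: log10(pk) = %.3f %+.3f log10(k)\n",
              x$intercept, x$slope))
  cat(sprintf("  slope p-value = %.3g, r^2 = %.3f, %d degree points\n",
              x$p_value, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
#' @method tidy lncmod_topology_fit
tidy.lncmod_topology_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
#' @method glance lncmod_topology_fit
glance.lncmod_topology_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         p_value = x$p_value, r_squared = x$r_squared,
         n_points = nrow(x$points))
}

#' Per-node topology metrics
#'
#' Degree, local clustering coefficient (fraction of closed triples; 0 for
#' degree < 2) and betweenness centrality normalised by `(n-1)(n-2)/2`,
#' joined with module membership.
#'
#' @param net Network from [build_network()].
#' @param modules Module tibble from [extract_modules()]; nodes outside any
#'   qualifying module get `NA`.
#' @return A tibble `lnc_id`, `degree`, `clustering`, `betweenness`,
#'   `module_id`.
#' @export
node_metrics <- function(net, modules = NULL) {
  ids <- igraph::V(net)$name
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  deg <- igraph::degree(net)
  cl[deg < 2] <- 0
  btw <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  out <- tibble(lnc_id = ids, degree = as.numeric(deg),
                clustering = as.numeric(cl), betweenness = as.numeric(btw))
  if (!is.null(modules)) {
    out <- left_join(out, modules[, c("lnc_id", "module_id")], by = "lnc_id")
  } else {
    out$module_id <- NA_character_
  }
  out
}

#' Compare intra- versus inter-module association
#'
#' Splits all pairwise association values among module members into pairs
#' within one module and pairs spanning two different modules, and compares
#' the two groups with a two-sided Wilcoxon rank-sum test. Pairs involving
#' lncRNAs outside every module are ignored.
#'
#' @param pcc_matrix Symmetric all-pairs association matrix (attribute
#'   `pcc_matrix` of [build_edge_list()] output).
#' @param modules Module tibble from [extract_modules()]; at least two
#'   modules are required for inter-module pairs to exist.
#' @return A list with `intra`, `inter` (numeric vectors) and `wilcoxon_p`.
#' @export
intra_inter_comparison <- function(pcc_matrix, modules) {
  if (length(unique(modules$module_id)) < 2L) {
    abort("At least two modules are required for inter-module pairs.")
  }
  memb <- setNames(modules$module_id, modules$lnc_id)
  ids <- intersect(rownames(pcc_matrix), names(memb))
  if (length(ids) < 3L) abort("Too few module members found in the association matrix.")
  m <- pcc_matrix[ids, ids, drop = FALSE]
  grp <- memb[ids]
  same <- outer(grp, grp, "==")
  ut <- upper.tri(m)
  intra <- m[ut & same]
  inter <- m[ut & !same]
  p <- if (length(unique(c(intra, inter))) == 1L) {
    1 # identical constant distributions: no evidence either way
  } else {
    wilcox.test(intra, inter, exact = FALSE)$p.value
  }
  list(intra = intra, inter = inter, wilcoxon_p = p)
}

#' Export a network for external viewers
#'
#' Writes GraphML (Cytoscape-loadable) or SIF.
#'
#' @param net Network from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return The path, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    readr::write_lines(paste(el[, 1], "assoc", el[, 2], sep = "\t"), path)
  }
  invisible(path)
}
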