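#' Pipeline configuration
#'
#' Bundles the data (in-memory tables or file paths) and every tunable
#' threshold of the module-discovery flow. Paths are read with the package
#' readers; in-memory tables are used as-is.
#'
#' @param tumour,normal Expression tables or TSV paths (see
#'   [read_expression_tsv()]); `normal` is required for the
#'   differential-expression screen step.
#' @param clinical Clinical tibble or TSV path.
#' @param gene_sets Named list of gene sets, a GMT path, or `NULL` to skip
#'   enrichment.
#' @param out_dir Output directory for artifacts and the manifest; `NULL`
#'   keeps everything in memory.
#' @param preprocess Apply [filter_genes()] and [fill_and_log()] to the
#'   expression inputs (default `TRUE`).
#' @param mr_fraction Mutual-rank cutoff fraction (see [mr_cutoff()]).
#' @param pcc_threshold Association-index threshold for edges (default 0.7).
#' @param min_module_size Minimum module size (default 12).
#' @param alphas Four screening thresholds (default 0.05 each).
#' @param eval_days Evaluation times (days) for time-dependent AUC.
#' @param n_perm GSEA permutations.
#' @param gsea_min_size,gsea_max_size GSEA set-size window.
#' @param seed Seed for every stochastic stage (GSEA permutations).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tumour, normal, clinical, gene_sets = NULL,
                            out_dir = NULL, preprocess = TRUE,
                            mr_fraction = 0.001, pcc_threshold = 0.7,
                            min_module_size = 12,
                            alphas = c(0.05, 0.05, 0.05, 0.05),
                            eval_days = c(336, 672, 1008, 1344, 1680),
                            n_perm = 1000, gsea_min_size = 15,
                            gsea_max_size = 500, seed = 1L) {
  if (mr_fraction <= 0 || mr_fraction >= 1) abort("`mr_fraction` must lie in (0, 1).")
  if (pcc_threshold <= -1 || pcc_threshold >= 1) abort("`pcc_threshold` must lie in (-1, 1).")
  if (min_module_size < 2) abort("`min_module_size` must be at least 2.")
  if (length(alphas) != 4 || any(alphas <= 0 | alphas > 1)) {
    abort("`alphas` must be four values in (0, 1].")
  }
  structure(list(tumour = tumour, normal = normal, clinical = clinical,
                 gene_sets = gene_sets, out_dir = out_dir,
                 preprocess = preprocess, mr_fraction = mr_fraction,
                 pcc_threshold = pcc_threshold,
                 min_module_size = min_module_size, alphas = alphas,
                 eval_days = eval_days, n_perm = n_perm,
                 gsea_min_size = gsea_min_size, gsea_max_size = gsea_max_size,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Validate pipeline inputs
#'
#' Schema checks for the expression, clinical and gene-set inputs. The
#' function never errors: every violation found is one row of the report.
#'
#' @param tumour,clinical,normal,gene_sets Inputs as in [pipeline_config()]
#'   (`normal` and `gene_sets` optional).
#' @return A tibble `check`, `detail`; zero rows means all checks passed.
#' @export
validate_inputs <- function(tumour, clinical, normal = NULL, gene_sets = NULL) {
  issues <- list()
  note <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- tibble(check = check, detail = detail)
  }
  check_expr_tbl <- function(x, label) {
    if (!is.data.frame(x)) { note(label, "not a data frame"); return(FALSE) }
    for (col in c("gene_id", "gene_type")) {
      if (!col %in% names(x)) note(label, sprintf("missing column `%s`", col))
    }
    if ("gene_id" %in% names(x) && anyDuplicated(x$gene_id)) {
      note(label, "duplicated gene ids")
    }
    if ("gene_type" %in% names(x)) {
      bad <- setdiff(unique(x$gene_type), c("lncRNA", "mRNA"))
      if (length(bad)) note(label, sprintf("unknown gene_type value(s): %s", toString(bad)))
    }
    TRUE
  }
  ok_t <- check_expr_tbl(tumour, "tumour expression")
  if (!is.null(normal)) check_expr_tbl(normal, "normal expression")
  if (!is.data.frame(clinical)) {
    note("clinical", "not a data frame")
  } else {
    need <- c("sample_id", "os_time", "os_event", "pfs_time", "pfs_event", "age", "stage")
    for (col in setdiff(need, names(clinical))) {
      note("clinical", sprintf("missing column `%s`", col))
    }
    for (ev in intersect(c("os_event", "pfs_event"), names(clinical))) {
      if (!all(clinical[[ev]] %in% c(0, 1))) note("clinical", sprintf("`%s` not 0/1", ev))
    }
    for (tm in intersect(c("os_time", "pfs_time"), names(clinical))) {
      if (any(!is.na(clinical[[tm]]) & clinical[[tm]] <= 0)) {
        note("clinical", sprintf("`%s` has non-positive times", tm))
      }
    }
    if (ok_t && "sample_id" %in% names(clinical)) {
      samp <- expr_samples(tumour)
      extra <- setdiff(clinical$sample_id, samp)
      miss <- setdiff(samp, clinical$sample_id)
      if (length(extra)) {
        note("concordance", sprintf("clinical sample(s) absent from expression: %s",
                                    toString(head(extra, 5))))
      }
      if (length(miss)) {
        note("concordance", sprintf("expression sample(s) absent from clinical: %s",
                                    toString(head(miss, 5))))
      }
    }
  }
  if (!is.null(gene_sets)) {
    if (!is.list(gene_sets) || is.null(names(gene_sets))) {
      note("gene sets", "not a named list")
    } else if (any(lengths(gene_sets) == 0L)) {
      note("gene sets", "empty set(s) present")
    }
  }
  if (!length(issues)) {
    tibble(check = character(), detail = character())
  } else {
    bind_rows(issues)
  }
}

#' Run the full module-discovery pipeline
#'
#' Executes, for both orientations: preprocessing, Spearman correlation,
#' mutual ranks and correlated-set selection, association edge lists,
#' network construction and module extraction, topology diagnostics, the
#' three-step prognostic screen, per-module and pooled signatures, and
#' preranked GSEA of each prognostic module. When `out_dir` is set, every
#' tabular artifact is written as TSV (networks as GraphML, summaries as
#' JSON) and checksummed into `manifest.tsv`; a rerun with the same config
#' and seed reproduces every checksum.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `lncmod_run`: a list with the preprocessed
#'   inputs, correlation/mutual-rank products, `edges`, `networks`,
#'   `modules`, `topology`, `node_metrics`, `intra_inter`, `screen`,
#'   `signatures` (per prognostic module plus `"pooled"`), `enrichment`,
#'   stage `counts` and the output `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  tumour <- resolve_input(config$tumour, read_expression_tsv)
  normal <- resolve_input(config$normal, read_expression_tsv)
  clinical <- resolve_input(config$clinical, read_clinical_tsv)
  gene_sets <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets) else config$gene_sets

  report <- validate_inputs(tumour, clinical, normal, gene_sets)
  if (nrow(report)) {
    abort(paste0("Input validation failed:\n",
                 paste(sprintf("- [%s] %s", report$check, report$detail), collapse = "\n")))
  }

  if (config$preprocess) {
    tumour <- fill_and_log(filter_genes(tumour))
    normal <- fill_and_log(filter_genes(normal))
  }
  n_lnc <- sum(tumour$gene_type == "lncRNA")
  n_mrna <- sum(tumour$gene_type == "mRNA")
  inform(sprintf("Preprocessed: %d lncRNAs, %d mRNAs, %d tumour samples.",
                 n_lnc, n_mrna, length(expr_samples(tumour))))

  scc <- spearman_matrix(tumour)
  cutoff <- mr_cutoff(n_lnc, n_mrna, config$mr_fraction)
  mr_pos <- mutual_rank(scc, "positive")
  mr_neg <- mutual_rank(scc, "negative")
  sets <- select_correlated_sets(mr_pos, mr_neg, cutoff)
  inform(sprintf("MR cutoff %.3f: median set sizes %g (positive), %g (negative).",
                 cutoff, median(lengths(sets$pos_set)), median(lengths(sets$neg_set))))

  edges <- list(); networks <- list(); modules <- list()
  topology <- list(); metrics <- list(); intra_inter <- list()
  for (ori in c("positive", "negative")) {
    e <- suppressWarnings(build_edge_list(sets, ori, config$pcc_threshold))
    net <- build_network(e)
    igraph::graph_attr(net, "orientation") <- ori
    mods <- extract_modules(net, config$min_module_size)
    inform(sprintf("%s network: %d nodes, %d edges, %d module(s) of size >= %d.",
                   ori, igraph::vcount(net), igraph::ecount(net),
                   length(unique(mods$module_id)), config$min_module_size))
    edges[[ori]] <- e
    networks[[ori]] <- net
    modules[[ori]] <- mods
    topology[[ori]] <- tryCatch(power_law_fit(degree_density(net)), error = function(e) NULL)
    metrics[[ori]] <- if (igraph::vcount(net)) node_metrics(net, mods) else NULL
    intra_inter[[ori]] <- tryCatch(
      intra_inter_comparison(attr(e, "pcc_matrix"), mods),
      error = function(e) NULL)
  }
  all_modules <- bind_rows(modules)

  screen <- NULL; signatures <- list(); enrichment <- list()
  if (nrow(all_modules)) {
    screen <- screen_lncrnas(tumour, normal, clinical, all_modules, config$alphas)
    inform(sprintf("Screen: %d of %d module lncRNA(s) prognostic.",
                   sum(screen$passed), nrow(screen)))
    prog_modules <- unique(screen$module_id[screen$passed])
    for (mid in prog_modules) {
      signatures[[mid]] <- module_score(tumour, screen, clinical, mid,
                                        eval_times = config$eval_days)
    }
    if (length(prog_modules) >= 2L) {
      signatures[["pooled"]] <- pooled_signature(tumour, screen, clinical,
                                                 prog_modules,
                                                 eval_times = config$eval_days)
    }
    if (!is.null(gene_sets) && length(prog_modules)) {
      for (mid in prog_modules) {
        ori <- all_modules$orientation[all_modules$module_id == mid][1]
        members <- all_modules$lnc_id[all_modules$module_id == mid]
        ranked <- module_rank(scc, members, orientation = ori)
        enrichment[[mid]] <- gsea_preranked(
          ranked, gene_sets, n_perm = config$n_perm,
          min_size = config$gsea_min_size, max_size = config$gsea_max_size)
      }
    }
  } else {
    inform("No modules passed the size filter; survival and enrichment stages skipped.")
  }

  run <- structure(list(
    config = config, tumour = tumour, normal = normal, clinical = clinical,
    scc = scc, mr_cutoff = cutoff, sets = sets, edges = edges,
    networks = networks, modules = all_modules, topology = topology,
    node_metrics = metrics, intra_inter = intra_inter, screen = screen,
    signatures = signatures, enrichment = enrichment,
    counts = tibble(
      stage = c("lncRNAs", "mRNAs", "edges_positive", "edges_negative",
                "modules", "screened", "prognostic"),
      n = c(n_lnc, n_mrna, nrow(edges$positive), nrow(edges$negative),
            length(unique(all_modules$module_id)),
            if (is.null(screen)) 0L else nrow(screen),
            if (is.null(screen)) 0L else sum(screen$passed)))
  ), class = "lncmod_run")
  if (!is.null(config$out_dir)) {
    run$manifest <- write_run(run, config$out_dir)
  }
  run
}

#' @export
#' @method print lncmod_run
print.lncmod_run <- function(x, ...) {
  cat("lncRNA module-discovery run\n")
  print(x$counts, n = Inf)
  invisible(x)
}

# Serialize run artifacts and checksum them.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put_tsv <- function(tbl, name) {
    p <- file.path(dir, name)
    readr::write_tsv(tbl, p)
    paths <<- c(paths, p)
  }
  for (ori in names(run$edges)) {
    if (nrow(run$edges[[ori]])) put_tsv(run$edges[[ori]], sprintf("edges_%s.tsv", ori))
    net <- run$networks[[ori]]
    if (igraph::vcount(net)) {
      p <- file.path(dir, sprintf("network_%s.graphml", ori))
      export_network(net, p, "graphml")
      paths <- c(paths, p)
    }
    if (!is.null(run$node_metrics[[ori]])) {
      put_tsv(run$node_metrics[[ori]], sprintf("node_metrics_%s.tsv", ori))
    }
  }
  if (nrow(run$modules)) put_tsv(run$modules, "modules.tsv")
  if (!is.null(run$screen)) put_tsv(run$screen, "screen.tsv")
  if (length(run$signatures)) {
    put_tsv(bind_rows(lapply(run$signatures, function(s) {
      mutate(s$scores, signature_id = s$signature_id)
    })), "signature_scores.tsv")
    summaries <- lapply(run$signatures, function(s) {
      list(hr = s$os$hr, ci_low = s$os$ci_low, ci_high = s$os$ci_high,
           cox_p = s$os$cox_p, os_logrank_p = s$os$logrank_p,
           pfs_logrank_p = s$pfs_logrank_p,
           auc = as.list(setNames(s$auc$auc, s$auc$time)),
           weights = as.list(s$weights))
    })
    p <- file.path(dir, "signatures.json")
    jsonlite::write_json(summaries, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  for (mid in names(run$enrichment)) {
    tbl <- run$enrichment[[mid]]
    tbl$leading_edge <- vapply(tbl$leading_edge, paste, character(1), collapse = ",")
    put_tsv(tbl, sprintf("enrichment_%s.tsv", mid))
  }
  manifest <- tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  ) |> arrange(.data$file)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}
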