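# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Cohort with two prognostic planted modules and one null module; the
# standard substrate for screening / signature / end-to-end tests.
fixture_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    cfg <- synthetic_config(
      n_tumour_samples = 200, n_normal_samples = 50,
      modules = list(
        planted_module(survival_beta = -0.6, tumour_shift = 1.5),
        planted_module(survival_beta = -0.5, tumour_shift = 1.2),
        planted_module(survival_beta = 0, tumour_shift = 0)),
      stage_link = 0.8, seed = 42)
    .fixture_cache$cohort <- simulate_cohort(cfg)
  }
  .fixture_cache$cohort
}

# Full pipeline run on the fixture cohort (no enrichment), cached.
fixture_run <- function() {
  if (is.null(.fixture_cache$run)) {
    coh <- fixture_cohort()
    cfg <- pipeline_config(coh$tumour, coh$normal, coh$clinical,
                           mr_fraction = 0.2, eval_days = c(336, 672),
                           seed = 7)
    .fixture_cache$run <- suppressMessages(run_pipeline(cfg))
  }
  .fixture_cache$run
}

# Tiny expression table builder.
make_expr <- function(values, gene_type, gene_id = NULL) {
  values <- as.matrix(values)
  gene_id <- gene_id %||% sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  dplyr::bind_cols(
    tibble::tibble(gene_id = gene_id, gene_type = gene_type),
    tibble::as_tibble(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index between two labelings over the same elements.
fixture_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Membership recovered by the pipeline for the planted lncRNAs, aligned with
# ground truth; uses the positive-orientation modules.
recovered_vs_truth <- function(run, truth, orientation = "positive") {
  mods <- run$modules[run$modules$orientation == orientation, , drop = FALSE]
  planted <- names(truth$module_membership)
  rec <- mods$module_id[match(planted, mods$lnc_id)]
  rec[is.na(rec)] <- "unassigned"
  list(recovered = rec, truth = unname(truth$module_membership))
}
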