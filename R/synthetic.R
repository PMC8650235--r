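#' Specify a planted co-regulated lncRNA module
#'
#' A planted module is driven by one latent Gaussian factor per tumour
#' sample. Member lncRNAs and the positively co-regulated mRNA block load on
#' the factor with `+latent_loading`; the negatively co-regulated block with
#' `-latent_loading`. The factor also enters the survival hazard
#' (`survival_beta`, log-hazard per standard-deviation of module activity)
#' and planted lncRNAs are shifted down by `tumour_shift` log2 units in
#' normal tissue.
#'
#' @param n_lnc_members Number of member lncRNAs (>= 2).
#' @param n_mrna_pos,n_mrna_neg Sizes of the positively / negatively
#'   co-regulated mRNA blocks.
#' @param latent_loading Loading of every planted gene on the module factor,
#'   in (0, 1].
#' @param survival_beta Log-hazard per unit of module factor.
#' @param tumour_shift Mean log2 expression difference of member lncRNAs
#'   between tumour and normal tissue.
#' @return A `planted_module` list.
#' @export
planted_module <- function(n_lnc_members = 15, n_mrna_pos = 60, n_mrna_neg = 60,
                           latent_loading = 0.9, survival_beta = 0,
                           tumour_shift = 0) {
  if (n_lnc_members < 2) abort("A planted module needs at least 2 lncRNA members.")
  if (latent_loading <= 0 || latent_loading > 1) abort("`latent_loading` must lie in (0, 1].")
  structure(list(n_lnc_members = n_lnc_members, n_mrna_pos = n_mrna_pos,
                 n_mrna_neg = n_mrna_neg, latent_loading = latent_loading,
                 survival_beta = survival_beta, tumour_shift = tumour_shift),
            class = "planted_module")
}

#' Configuration of the synthetic cohort generator
#'
#' Collects the cohort dimensions, the planted modules, the noise level and
#' the survival-model parameters used by [simulate_expression()] and
#' [simulate_clinical()]. Defaults emulate a small tumour cohort with three
#' co-regulated lncRNA modules against a background of unstructured genes.
#'
#' @param n_tumour_samples,n_normal_samples Cohort sizes.
#' @param n_lnc,n_mrna Total numbers of lncRNAs and mRNAs (planted blocks
#'   must fit inside these totals; the remainder is background noise).
#' @param modules List of [planted_module()] specifications.
#' @param noise_sd Standard deviation of the iid Gaussian noise added to
#'   every gene (log2 units).
#' @param baseline_hazard_scale Scale of the exponential baseline survival
#'   time, in days.
#' @param censoring_rate Target fraction of censored tumour samples, in
#'   `[0, 1]`.
#' @param age_beta,stage_beta Log-hazard per year of age (centred at 60) and
#'   per stage step (I=1 ... IV=4).
#' @param age_range Range of the uniform age-at-diagnosis distribution.
#' @param stage_probs Marginal probabilities of stages I--IV.
#' @param stage_link Coupling of stage to module activity: the stage latent
#'   variable is `rnorm(n) + stage_link * mean module factor`, cut so the
#'   marginal stage probabilities are preserved. 0 (default) makes stage
#'   independent of the planted modules.
#' @param pfs_factor Progression-free survival time as a fraction of overall
#'   survival time.
#' @param seed Integer seed making generation reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_tumour_samples = 400, n_normal_samples = 60,
                             n_lnc = 60, n_mrna = 500,
                             modules = list(planted_module(), planted_module(), planted_module()),
                             noise_sd = 0.3, baseline_hazard_scale = 1500,
                             censoring_rate = 0.4, age_beta = 0.02,
                             stage_beta = 0.35, age_range = c(40, 85),
                             stage_probs = c(0.5, 0.25, 0.17, 0.08),
                             stage_link = 0, pfs_factor = 0.7, seed = 1L) {
  cfg <- list(n_tumour_samples = n_tumour_samples, n_normal_samples = n_normal_samples,
              n_lnc = n_lnc, n_mrna = n_mrna, modules = modules,
              noise_sd = noise_sd, baseline_hazard_scale = baseline_hazard_scale,
              censoring_rate = censoring_rate, age_beta = age_beta,
              stage_beta = stage_beta, age_range = age_range,
              stage_probs = stage_probs / sum(stage_probs),
              stage_link = stage_link, pfs_factor = pfs_factor,
              seed = as.integer(seed))
  if (sum(vapply(modules, `[[`, 0, "n_lnc_members")) > n_lnc) {
    abort("Planted lncRNA members exceed `n_lnc`.")
  }
  n_blk <- sum(vapply(modules, function(m) m$n_mrna_pos + m$n_mrna_neg, 0))
  if (n_blk > n_mrna) abort("Planted mRNA blocks exceed `n_mrna`.")
  if (censoring_rate < 0 || censoring_rate > 1) abort("`censoring_rate` must lie in [0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(cfg, class = "synthetic_config")
}

#' Simulate tumour and normal expression with planted modules
#'
#' Every gene gets a baseline log2 expression drawn uniformly from
#' `[2, 8]`. Per planted module one latent standard-normal factor per tumour
#' sample drives its member lncRNAs and positive mRNA block with
#' `+latent_loading` and its negative block with `-latent_loading`; iid
#' Gaussian noise (`noise_sd`) is added everywhere and values are floored at
#' 0 so the matrices look like log2(FPKM+1) data. Normal samples carry no
#' module factors, and planted lncRNAs lose `tumour_shift` from their
#' baseline. Generation is fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `tumour` and `normal` expression tables and `truth`,
#'   a ground-truth list: `module_membership` (named lncRNA -> module id),
#'   `correlated_mrna_sets` (per module, `pos`/`neg` id vectors),
#'   `survival_betas`, and `factors` (tumour sample x module latent factor
#'   matrix).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ns <- config$n_tumour_samples; nn <- config$n_normal_samples
  nl <- config$n_lnc; nm <- config$n_mrna
  lnc_ids <- sprintf("LNC%04d", seq_len(nl))
  mrna_ids <- sprintf("MRNA%05d", seq_len(nm))
  tum_ids <- sprintf("T%03d", seq_len(ns))
  nor_ids <- sprintf("C%03d", seq_len(nn))

  base_l <- runif(nl, 2, 8)
  base_m <- runif(nm, 2, 8)
  tum_l <- matrix(rnorm(nl * ns, 0, config$noise_sd), nl, ns)
  tum_m <- matrix(rnorm(nm * ns, 0, config$noise_sd), nm, ns)
  nor_l <- matrix(rnorm(nl * nn, 0, config$noise_sd), nl, nn)
  nor_m <- matrix(rnorm(nm * nn, 0, config$noise_sd), nm, nn)

  n_mod <- length(config$modules)
  factors <- matrix(0, ns, max(n_mod, 1),
                    dimnames = list(tum_ids, if (n_mod) paste0("M", seq_len(n_mod)) else "M1"))
  membership <- character(0)
  sets <- list()
  betas <- numeric(0)
  li <- 1L; mi <- 1L
  shift_l <- numeric(nl)
  for (k in seq_len(n_mod)) {
    m <- config$modules[[k]]
    f <- rnorm(ns)
    factors[, k] <- f
    il <- li:(li + m$n_lnc_members - 1L)
    ip <- mi:(mi + m$n_mrna_pos - 1L)
    im <- if (m$n_mrna_neg > 0) (mi + m$n_mrna_pos):(mi + m$n_mrna_pos + m$n_mrna_neg - 1L) else integer(0)
    tum_l[il, ] <- tum_l[il, ] + m$latent_loading * matrix(f, length(il), ns, byrow = TRUE)
    tum_m[ip, ] <- tum_m[ip, ] + m$latent_loading * matrix(f, length(ip), ns, byrow = TRUE)
    if (length(im)) {
      tum_m[im, ] <- tum_m[im, ] - m$latent_loading * matrix(f, length(im), ns, byrow = TRUE)
    }
    shift_l[il] <- m$tumour_shift
    mod_id <- paste0("M", k)
    membership[lnc_ids[il]] <- mod_id
    sets[[mod_id]] <- list(pos = mrna_ids[ip], neg = mrna_ids[im])
    betas[mod_id] <- m$survival_beta
    li <- li + m$n_lnc_members
    mi <- mi + m$n_mrna_pos + m$n_mrna_neg
  }

  tum_l <- pmax(tum_l + base_l, 0)
  tum_m <- pmax(tum_m + base_m, 0)
  nor_l <- pmax(nor_l + base_l - shift_l, 0)
  nor_m <- pmax(nor_m + base_m, 0)

  as_expr <- function(lm, mm, samp) {
    vals <- rbind(lm, mm)
    colnames(vals) <- samp
    dplyr::bind_cols(
      tibble(gene_id = c(lnc_ids, mrna_ids),
             gene_type = rep(c("lncRNA", "mRNA"), c(nl, nm))),
      as_tibble(vals)
    )
  }
  list(
    tumour = as_expr(tum_l, tum_m, tum_ids),
    normal = as_expr(nor_l, nor_m, nor_ids),
    truth = list(module_membership = membership,
                 correlated_mrna_sets = sets,
                 survival_betas = betas,
                 factors = factors[, seq_len(max(n_mod, 1)), drop = FALSE])
  )
}

# Censoring-time rate achieving the target mean censoring probability for
# exponential event times with per-sample rates `rates`.
censoring_exp_rate <- function(rates, target) {
  if (target <= 0) return(0)
  if (target >= 1) return(Inf)
  f <- function(rc) mean(rc / (rc + rates)) - target
  uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-10)$root
}

#' Simulate clinical data tied to planted module activity
#'
#' Overall survival times are exponential with per-sample hazard
#' `exp(sum_m beta_m f_m + age_beta (age - 60) + stage_beta (stage - 1)) /
#' baseline_hazard_scale`, where `f_m` are the module latent factors from
#' [simulate_expression()]. Censoring is by an independent exponential time
#' whose rate is solved numerically so the expected censored fraction
#' matches `censoring_rate`. Ages are uniform over `age_range`; stage is
#' drawn with the configured marginal probabilities, optionally coupled to
#' module activity through `stage_link`. Progression-free survival is a
#' deterministic scaling of overall survival by `pfs_factor`.
#'
#' @param config A [synthetic_config()].
#' @param tumour Tumour expression table from [simulate_expression()] (used
#'   for its sample ids).
#' @param truth Ground-truth list from [simulate_expression()].
#' @return A clinical tibble: `sample_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`, `age`, `stage`, `tissue`.
#' @export
simulate_clinical <- function(config, tumour, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  samp <- expr_samples(tumour)
  fac <- truth$factors
  if (!identical(rownames(fac), samp)) {
    abort("Sample ids of `tumour` do not match the ground-truth factors.")
  }
  set.seed(config$seed + 1L)
  n <- length(samp)
  age <- runif(n, config$age_range[1], config$age_range[2])
  mean_f <- rowMeans(fac)
  z <- rnorm(n) + config$stage_link * mean_f
  cuts <- quantile(z, probs = cumsum(config$stage_probs)[-length(config$stage_probs)])
  stage_num <- findInterval(z, cuts) + 1L
  stage <- c("I", "II", "III", "IV")[stage_num]

  betas <- truth$survival_betas
  lp <- as.numeric(fac[, names(betas), drop = FALSE] %*% betas) +
    config$age_beta * (age - 60) + config$stage_beta * (stage_num - 1)
  rate <- exp(lp) / config$baseline_hazard_scale
  t_event <- rexp(n, rate)
  rc <- censoring_exp_rate(rate, config$censoring_rate)
  t_cens <- if (rc == 0) rep(Inf, n) else rexp(n, rc)
  os_time <- pmax(pmin(t_event, t_cens), 1e-8)
  os_event <- as.integer(t_event <= t_cens)
  tibble(
    sample_id = samp,
    os_time = os_time,
    os_event = os_event,
    pfs_time = os_time * config$pfs_factor,
    pfs_event = os_event,
    age = age,
    stage = stage,
    tissue = "tumour"
  )
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_expression()] then
#' [simulate_clinical()].
#'
#' @param config A [synthetic_config()].
#' @return List with `tumour`, `normal`, `clinical`, `truth`.
#' @export
simulate_cohort <- function(config) {
  ex <- simulate_expression(config)
  clin <- simulate_clinical(config, ex$tumour, ex$truth)
  c(ex[c("tumour", "normal")], list(clinical = clin, truth = ex$truth))
}

#' Write a synthetic cohort to disk
#'
#' Writes `tumour_expression.tsv`, `normal_expression.tsv`, `clinical.tsv`
#' and `ground_truth.json` under `dir`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tumour = file.path(dir, "tumour_expression.tsv"),
    normal = file.path(dir, "normal_expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expression_tsv(cohort$tumour, paths["tumour"])
  write_expression_tsv(cohort$normal, paths["normal"])
  write_clinical_tsv(cohort$clinical, paths["clinical"])
  truth <- cohort$truth
  truth$factors <- NULL
  # named atomic vectors lose their names in JSON; store them as objects
  truth$module_membership <- as.list(truth$module_membership)
  truth$survival_betas <- as.list(truth$survival_betas)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
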