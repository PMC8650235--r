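#' Split samples at the median
#'
#' Values strictly above the median go to `"high"`, values at or below it to
#' `"low"`; with an odd number of samples the median-valued sample therefore
#' lands in the low group. An all-constant vector (or any split leaving a
#' group empty) is rejected as degenerate.
#'
#' @param values Named (or unnamed) numeric vector, length >= 4 recommended.
#' @return Character vector of `"high"`/`"low"`, same names as `values`.
#' @export
median_split <- function(values) {
  med <- median(values)
  grp <- ifelse(values > med, "high", "low")
  if (length(unique(grp)) < 2L) {
    abort("Degenerate median split: all samples fall in one group.")
  }
  names(grp) <- names(values)
  grp
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic and two-sided p-value for
#' comparing the survival of two groups.
#'
#' @param groups Factor-like vector with exactly two levels.
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) abort("`groups` must contain exactly two groups.")
  if (any(table(groups) == 0L)) abort("Both groups must be non-empty.")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- sd$chisq
  list(statistic = unname(stat), p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood (Efron tie handling) and reports the
#' coefficient, hazard ratio, Wald 95% confidence interval and p-value per
#' covariate.
#'
#' @param covariates Data frame of covariates, one row per sample. Character
#'   or factor columns are allowed (treatment contrasts).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return A tibble: `term`, `beta`, `hr`, `ci_low`, `ci_high`, `p_value`.
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) < 2L, TRUE))) {
    abort("Constant covariates cannot be fitted.")
  }
  dat <- cbind(covariates, .time = times, .event = events)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ .,
                         data = dat, ties = "efron")
  if (any(!is.finite(coef(fit)))) abort("Cox fit did not converge (non-finite coefficient).")
  sm <- summary(fit)
  tibble(
    term = rownames(sm$coefficients),
    beta = unname(sm$coefficients[, "coef"]),
    hr = unname(sm$coefficients[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, "lower .95"]),
    ci_high = unname(sm$conf.int[, "upper .95"]),
    p_value = unname(sm$coefficients[, "Pr(>|z|)"])
  )
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function: starts at `S(0) = 1`,
#' drops at event times and uses censored subjects only to shrink the risk
#' set.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return A tibble `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   including the `time = 0` row.
#' @export
km_curve <- function(times, events) {
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble(
    time = c(0, sf$time),
    n_risk = c(sf$n, sf$n.risk),
    n_event = c(0, sf$n.event),
    n_censor = c(0, sf$n.censor),
    surv = c(1, sf$surv)
  )
}

# Left-continuous Kaplan-Meier estimate of the censoring survival G(t-),
# evaluated at `at`. Used as IPCW weight denominator.
censor_km <- function(times, events) {
  sf <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  list(times = sf$time, surv = sf$surv)
}

censor_surv_at <- function(g, at, left = FALSE) {
  vapply(at, function(t0) {
    idx <- if (left) which(g$times < t0) else which(g$times <= t0)
    if (!length(idx)) 1 else g$surv[max(idx)]
  }, numeric(1))
}

#' Time-dependent AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC of a risk score at each evaluation
#' time: cases are subjects with an event at or before `t`, controls are
#' subjects still event-free beyond `t`. Censoring is handled by inverse
#' probability-of-censoring weights from the Kaplan-Meier estimate of the
#' censoring distribution; with no censoring the estimate reduces exactly to
#' Mann-Whitney pair counting. Higher scores are treated as higher risk;
#' tied scores count one half.
#'
#' @param scores Per-sample risk score.
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param eval_times Times (same units as `times`) at which to evaluate.
#' @return A tibble `time`, `auc`, `n_case`, `n_control`; `auc` is `NA`
#'   where no case or no control exists.
#' @export
time_auc <- function(scores, times, events, eval_times) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  g <- censor_km(times, events)
  purrr::map_dfr(eval_times, function(t0) {
    is_case <- times <= t0 & events == 1
    is_ctrl <- times > t0
    if (!any(is_case) || !any(is_ctrl)) {
      return(tibble(time = t0, auc = NA_real_,
                    n_case = sum(is_case), n_control = sum(is_ctrl)))
    }
    w_case <- 1 / censor_surv_at(g, times[is_case], left = TRUE)
    sc <- scores[is_case]
    st <- scores[is_ctrl]
    # control IPCW weight 1/G(t0) is constant and cancels in the ratio
    conc <- vapply(sc, function(s) sum(s > st) + 0.5 * sum(s == st), numeric(1))
    auc <- sum(w_case * conc) / (sum(w_case) * length(st))
    tibble(time = t0, auc = auc, n_case = sum(is_case), n_control = sum(is_ctrl))
  })
}

stage_to_numeric <- function(stage) {
  match(normalize_stage(stage), c("I", "II", "III", "IV"))
}

#' Three-step prognostic screen of module lncRNAs
#'
#' For every lncRNA belonging to a module, the screen applies:
#' \enumerate{
#'   \item median-split of tumour expression and a log-rank test on overall
#'     survival (`p < alpha1`);
#'   \item a multivariable Cox model of the high/low indicator adjusted for
#'     age and stage (`p < alpha2`);
#'   \item a Kruskal-Wallis test of expression across stages I--IV
#'     (`p < alpha3`) and a Wilcoxon rank-sum test of tumour versus normal
#'     expression (`p < alpha4`): stage-independent or
#'     non-differentially-expressed lncRNAs are excluded.
#' }
#' All four p-values are reported for every lncRNA; `passed` requires all
#' four. `direction` is `"favourable"` when the adjusted hazard ratio of the
#' high-expression group is below 1.
#'
#' @param tumour,normal Expression tables (log2 scale).
#' @param clinical Clinical tibble matching the tumour samples (see
#'   [read_clinical_tsv()]).
#' @param modules Module membership tibble from [extract_modules()] (or any
#'   tibble with `lnc_id`, `module_id`).
#' @param alphas Numeric vector of the four significance thresholds
#'   (default all 0.05); no multiple-testing correction is applied.
#' @return A tibble, one row per screened lncRNA: `lnc_id`, `module_id`,
#'   `logrank_p`, `cox_hr`, `cox_ci_low`, `cox_ci_high`, `cox_p`, `kw_p`,
#'   `de_p`, `passed`, `direction`.
#' @export
screen_lncrnas <- function(tumour, normal, clinical, modules,
                           alphas = c(0.05, 0.05, 0.05, 0.05)) {
  stopifnot(length(alphas) == 4L)
  check_clinical(clinical)
  samp <- expr_samples(tumour)
  clinical <- clinical[match(samp, clinical$sample_id), , drop = FALSE]
  if (anyNA(clinical$sample_id)) abort("Tumour samples missing from the clinical table.")
  tum <- expr_values(tumour)
  nor <- expr_values(normal)
  stage_num <- stage_to_numeric(clinical$stage)
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    id <- modules$lnc_id[i]
    if (!id %in% rownames(tum)) abort(sprintf("Module lncRNA %s absent from tumour expression.", id))
    x <- tum[id, ]
    res <- tibble(lnc_id = id, module_id = modules$module_id[i],
                  logrank_p = NA_real_, cox_hr = NA_real_,
                  cox_ci_low = NA_real_, cox_ci_high = NA_real_,
                  cox_p = NA_real_, kw_p = NA_real_, de_p = NA_real_,
                  passed = FALSE, direction = NA_character_)
    grp <- tryCatch(median_split(x), error = function(e) NULL)
    if (is.null(grp)) return(res)
    lr <- logrank_test(grp, clinical$os_time, clinical$os_event)
    res$logrank_p <- lr$p_value
    cx <- tryCatch(
      cox_fit(data.frame(group = factor(grp, levels = c("low", "high")),
                         age = clinical$age, stage = stage_num),
              clinical$os_time, clinical$os_event),
      error = function(e) NULL)
    if (is.null(cx)) return(res)
    row <- cx[cx$term == "grouphigh", ]
    res$cox_hr <- row$hr
    res$cox_ci_low <- row$ci_low
    res$cox_ci_high <- row$ci_high
    res$cox_p <- row$p_value
    ok_stage <- !is.na(stage_num)
    res$kw_p <- tryCatch(
      kruskal.test(x[ok_stage], factor(stage_num[ok_stage]))$p.value,
      error = function(e) NA_real_)
    res$de_p <- if (id %in% rownames(nor)) {
      suppressWarnings(wilcox.test(x, nor[id, ], exact = FALSE)$p.value)
    } else NA_real_
    res$direction <- if (row$hr < 1) "favourable" else "unfavourable"
    res$passed <- isTRUE(res$logrank_p < alphas[1] && res$cox_p < alphas[2] &&
                           res$kw_p < alphas[3] && res$de_p < alphas[4])
    res
  })
}

signature_result <- function(signature_id, weights, scores_tbl, os, pfs_logrank_p, auc) {
  structure(list(signature_id = signature_id, weights = weights,
                 scores = scores_tbl, os = os,
                 pfs_logrank_p = pfs_logrank_p, auc = auc),
            class = "lncmod_signature")
}

#' @export
#' @method print lncmod_signature
print.lncmod_signature <- function(x, ...) {
  cat(sprintf("Signature '%s': %d lncRNA(s)\n", x$signature_id, length(x$weights)))
  cat(sprintf("  OS: HR = %.3f (95%% CI %.3f-%.3f), Cox p = %.3g, log-rank p = %.3g\n",
              x$os$hr, x$os$ci_low, x$os$ci_high, x$os$cox_p, x$os$logrank_p))
  cat(sprintf("  PFS log-rank p = %.3g\n", x$pfs_logrank_p))
  if (nrow(x$auc)) {
    cat("  time-AUC:",
        paste(sprintf("%g d: %.3f", x$auc$time, x$auc$auc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @method tidy lncmod_signature
tidy.lncmod_signature <- function(x, ...) {
  tibble(signature_id = x$signature_id,
         lnc_id = names(x$weights), weight = unname(x$weights))
}

#' @export
#' @method glance lncmod_signature
glance.lncmod_signature <- function(x, ...) {
  tibble(signature_id = x$signature_id, n_lncrnas = length(x$weights),
         hr = x$os$hr, ci_low = x$os$ci_low, ci_high = x$os$ci_high,
         cox_p = x$os$cox_p, os_logrank_p = x$os$logrank_p,
         pfs_logrank_p = x$pfs_logrank_p)
}

signature_weights <- function(tum, clinical, stage_num, lnc_ids) {
  vapply(lnc_ids, function(id) {
    cox_fit(data.frame(expr = tum[id, ], age = clinical$age, stage = stage_num),
            clinical$os_time, clinical$os_event)$beta[1]
  }, numeric(1))
}

evaluate_signature <- function(signature_id, weights, tum, clinical, stage_num,
                               eval_times) {
  score <- as.numeric(crossprod(tum[names(weights), , drop = FALSE], weights))
  names(score) <- colnames(tum)
  grp <- median_split(score)
  lr_os <- logrank_test(grp, clinical$os_time, clinical$os_event)
  lr_pfs <- logrank_test(grp, clinical$pfs_time, clinical$pfs_event)
  cx <- cox_fit(data.frame(group = factor(grp, levels = c("low", "high")),
                           age = clinical$age, stage = stage_num),
                clinical$os_time, clinical$os_event)
  row <- cx[cx$term == "grouphigh", ]
  auc <- if (length(eval_times)) {
    time_auc(score, clinical$os_time, clinical$os_event, eval_times)
  } else {
    tibble(time = numeric(), auc = numeric(), n_case = integer(), n_control = integer())
  }
  signature_result(
    signature_id, weights,
    tibble(sample_id = names(score), score = unname(score), group = unname(grp)),
    os = list(hr = row$hr, ci_low = row$ci_low, ci_high = row$ci_high,
              cox_p = row$p_value, beta = row$beta, logrank_p = lr_os$p_value),
    pfs_logrank_p = lr_pfs$p_value,
    auc = auc
  )
}

#' Coefficient-weighted module risk score and its evaluation
#'
#' For one module's screened lncRNAs, each weight is the Cox coefficient of
#' the lncRNA's continuous expression in a multivariable fit adjusted for
#' age and stage; the per-sample score is the weighted sum of expression
#' over those lncRNAs (so high score means high modelled hazard). The score
#' is then median-split and evaluated with log-rank tests on overall and
#' progression-free survival, an adjusted Cox model of the high/low
#' indicator, and time-dependent AUC.
#'
#' @param tumour Tumour expression table.
#' @param screen Screen tibble from [screen_lncrnas()]; only `passed` rows
#'   of `module_id` are used.
#' @param clinical Clinical tibble.
#' @param module_id Module to score.
#' @param eval_times Evaluation days for [time_auc()] (may be empty).
#' @return An object of class `lncmod_signature` (see [tidy()], [glance()]),
#'   or `NULL` with a warning when no lncRNA of the module passed.
#' @export
module_score <- function(tumour, screen, clinical, module_id,
                         eval_times = numeric()) {
  check_clinical(clinical)
  samp <- expr_samples(tumour)
  clinical <- clinical[match(samp, clinical$sample_id), , drop = FALSE]
  tum <- expr_values(tumour)
  stage_num <- stage_to_numeric(clinical$stage)
  ids <- screen$lnc_id[screen$passed & screen$module_id == module_id]
  if (!length(ids)) {
    warn(sprintf("Module %s has no prognostic lncRNAs; dropped.", module_id))
    return(NULL)
  }
  w <- signature_weights(tum, clinical, stage_num, ids)
  evaluate_signature(module_id, w, tum, clinical, stage_num, eval_times)
}

#' Pooled multi-module signature
#'
#' Pools the prognostic lncRNAs of several modules into one signature: the
#' pooled score is the coefficient-weighted sum over the union of passed
#' lncRNAs, evaluated exactly like a single module. With disjoint modules
#' the pooled score equals the sum of the module scores.
#'
#' @param tumour Tumour expression table.
#' @param screen Screen tibble from [screen_lncrnas()].
#' @param clinical Clinical tibble.
#' @param module_ids Modules to pool; default every module with at least one
#'   passed lncRNA.
#' @param eval_times Evaluation days for [time_auc()].
#' @return An `lncmod_signature` with `signature_id = "pooled"`.
#' @export
pooled_signature <- function(tumour, screen, clinical, module_ids = NULL,
                             eval_times = numeric()) {
  check_clinical(clinical)
  passed <- screen[screen$passed, , drop = FALSE]
  module_ids <- module_ids %||% unique(passed$module_id)
  ids <- passed$lnc_id[passed$module_id %in% module_ids]
  if (!length(ids)) abort("No prognostic lncRNAs to pool.")
  samp <- expr_samples(tumour)
  clinical <- clinical[match(samp, clinical$sample_id), , drop = FALSE]
  tum <- expr_values(tumour)
  stage_num <- stage_to_numeric(clinical$stage)
  w <- signature_weights(tum, clinical, stage_num, unique(ids))
  evaluate_signature("pooled", w, tum, clinical, stage_num, eval_times)
}
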