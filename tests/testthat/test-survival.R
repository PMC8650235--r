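test_that("median split sends the median-valued sample to the low group", {
  expect_identical(unname(median_split(c(1, 2, 3, 4))), c("low", "low", "high", "high"))
  expect_identical(unname(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_error(median_split(rep(2, 5)), "Degenerate")
  expect_error(median_split(c(1, 5, 5, 5)), "Degenerate")
})

test_that("log-rank test is null on duplicated groups and matches the O-E oracle", {
  tm <- c(3, 5, 8, 10, 3, 5, 8, 10)
  ev <- c(1, 0, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 4)
  res <- logrank_test(grp, tm, ev)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  tm2 <- c(1, 2, 10, 20); ev2 <- c(1, 1, 1, 1); g2 <- c("A", "A", "B", "B")
  res2 <- logrank_test(g2, tm2, ev2)
  expect_equal(res2$statistic, bf_logrank(g2, tm2, ev2), tolerance = 1e-10)
  # invariance to swapping group labels
  res3 <- logrank_test(rev(g2)[c(3, 4, 1, 2)], tm2, ev2)
  expect_equal(res3$statistic, res2$statistic, tolerance = 1e-12)
})

test_that("log-rank has power against a strong simulated effect", {
  set.seed(101)
  n <- 400
  grp <- rep(c("low", "high"), each = n / 2)
  rate <- ifelse(grp == "high", 3, 1) / 1000
  tm <- rexp(n, rate)
  res <- logrank_test(grp, tm, rep(1, n))
  expect_lt(res$p_value, 1e-10)
})

test_that("Cox fit is near-null for an independent covariate", {
  set.seed(55)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 1 / 1000)
  fit <- cox_fit(data.frame(x = x), tm, rep(1, n))
  expect_lt(abs(fit$beta), 0.2)
  expect_true(fit$ci_low < 1 && fit$ci_high > 1)
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  cases <- list(
    list(x = c(0, 1, 0, 1, 0, 1), tm = c(2, 1, 5, 3, 9, 4), ev = c(1, 1, 1, 1, 1, 1)),
    list(x = c(0, 1, 1, 0, 1), tm = c(4, 2, 3, 8, 6), ev = c(1, 1, 0, 1, 1)),
    list(x = c(1, 0, 1, 0), tm = c(1, 3, 6, 10), ev = c(1, 1, 1, 0))
  )
  for (cs in cases) {
    fit <- cox_fit(data.frame(x = cs$x), cs$tm, cs$ev)
    beta_bf <- bf_cox_grid(cs$x, cs$tm, cs$ev)
    expect_equal(fit$beta, beta_bf, tolerance = 1e-4)
  }
})

test_that("Cox fit rejects constant covariates and reports all terms", {
  set.seed(1)
  expect_error(cox_fit(data.frame(x = rep(1, 10)), rexp(10), rep(1, 10)),
               "Constant")
  n <- 200
  dat <- data.frame(x = rnorm(n), age = runif(n, 40, 80))
  fit <- cox_fit(dat, rexp(n, 1 / 500), rbinom(n, 1, 0.8))
  expect_identical(fit$term, c("x", "age"))
  expect_true(all(fit$ci_low <= fit$hr & fit$hr <= fit$ci_high))
})

test_that("Kaplan-Meier curve matches the product-limit computation", {
  km0 <- km_curve(c(4, 9, 13), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  km <- km_curve(c(5, 8, 12), c(1, 0, 1))
  expect_equal(km$surv[km$time == 5], 2 / 3)
  expect_equal(km$surv[km$time == 12], 0)
  expect_equal(km$surv[km$time == 0], 1)
  expect_true(all(diff(km$surv) <= 0))

  # all events, no censoring: complement of the ECDF
  set.seed(8)
  tm <- sort(sample(1:100, 10))
  km2 <- km_curve(tm, rep(1, 10))
  expect_equal(km2$surv[-1], 1 - seq_len(10) / 10)
  # agreement with the hand product-limit oracle at arbitrary times
  tm3 <- c(2, 2, 5, 7, 7, 11); ev3 <- c(1, 0, 1, 1, 0, 1)
  km3 <- km_curve(tm3, ev3)
  for (at in c(2, 5, 7, 11)) {
    expect_equal(km3$surv[km3$time == at], bf_km(tm3, ev3, at))
  }
})

test_that("time-AUC equals pair counting without censoring and is 1 for a perfect marker", {
  set.seed(33)
  n <- 120
  tm <- rexp(n, 1 / 500)
  sc <- -tm # perfect risk ranking: earlier events get higher scores
  res <- time_auc(sc, tm, rep(1, n), quantile(tm, c(0.25, 0.5, 0.75)))
  expect_true(all(res$auc == 1))

  sc2 <- rnorm(n)
  eval_t <- quantile(tm, c(0.2, 0.5, 0.8))
  res2 <- time_auc(sc2, tm, rep(1, n), eval_t)
  want <- vapply(eval_t, function(t0) bf_pair_auc(sc2, tm, rep(1, n), t0), numeric(1))
  expect_equal(res2$auc, unname(want), tolerance = 1e-10)
})

test_that("time-AUC reports NA when no case or control exists at a time", {
  tm <- c(10, 20, 30); ev <- c(0, 1, 0)
  res <- time_auc(c(1, 2, 3), tm, ev, c(5, 25))
  expect_true(is.na(res$auc[res$time == 5]))   # no case yet
  expect_false(is.na(res$auc[res$time == 25])) # one case (censored before don't count)
})

test_that("time-AUC IPCW weighting reduces bias under heavy censoring", {
  # sanity: with independent censoring the IPCW estimate stays near the
  # censoring-free pair-count value computed from the latent event times
  set.seed(77)
  n <- 800
  sc <- rnorm(n)
  t_event <- rexp(n, exp(0.8 * sc) / 1000)
  t_cens <- rexp(n, 1 / 800)
  tm <- pmin(t_event, t_cens); ev <- as.integer(t_event <= t_cens)
  t0 <- unname(quantile(tm, 0.5))
  full <- bf_pair_auc(sc, t_event, rep(1, n), t0)
  ipcw <- time_auc(sc, tm, ev, t0)$auc
  expect_lt(abs(ipcw - full), 0.05)
})

test_that("the three-step screen keeps planted prognostic lncRNAs and drops null ones", {
  run <- fixture_run()
  coh <- fixture_cohort()
  truth <- coh$truth$module_membership
  screen <- run$screen
  planted <- screen[screen$lnc_id %in% names(truth), ]
  planted$true_module <- truth[planted$lnc_id]
  pass_rate <- tapply(planted$passed, planted$true_module, mean)
  expect_gt(pass_rate[["M1"]], 0.6) # survival_beta -0.6, shifted, stage-linked
  expect_gt(pass_rate[["M2"]], 0.6)
  expect_lt(pass_rate[["M3"]], 0.2) # null module
  # all reported p-values are valid probabilities, HRs positive with ordered CIs
  ok <- !is.na(screen$cox_hr)
  expect_true(all(screen$cox_hr[ok] > 0))
  expect_true(all(screen$cox_ci_low[ok] <= screen$cox_hr[ok] &
                    screen$cox_hr[ok] <= screen$cox_ci_high[ok]))
})

test_that("a stage-independent lncRNA is excluded even when survival-related", {
  set.seed(202)
  # survival depends on the lncRNA, but expression is independent of stage
  # and identical in tumour and normal: steps 1-2 pass, step 3 fails
  cfg <- synthetic_config(
    n_tumour_samples = 300, n_normal_samples = 60, n_lnc = 10, n_mrna = 50,
    modules = list(planted_module(n_lnc_members = 2, n_mrna_pos = 5, n_mrna_neg = 5,
                                  survival_beta = -1, tumour_shift = 0)),
    stage_link = 0, seed = 202)
  coh <- simulate_cohort(cfg)
  mods <- tibble::tibble(lnc_id = names(coh$truth$module_membership),
                         module_id = "M1", orientation = "positive")
  sc <- screen_lncrnas(coh$tumour, coh$normal, coh$clinical, mods)
  strong <- sc[sc$logrank_p < 0.05 & sc$cox_p < 0.05, ]
  expect_gt(nrow(strong), 0)
  expect_false(any(strong$passed))
})

test_that("screen errors name missing clinical fields and absent lncRNAs", {
  coh <- fixture_cohort()
  mods <- tibble::tibble(lnc_id = "LNC0001", module_id = "M1", orientation = "positive")
  broken <- coh$clinical[, setdiff(names(coh$clinical), "stage")]
  expect_error(screen_lncrnas(coh$tumour, coh$normal, broken, mods), "stage")
  ghost <- tibble::tibble(lnc_id = "NOPE", module_id = "M1", orientation = "positive")
  expect_error(screen_lncrnas(coh$tumour, coh$normal, coh$clinical, ghost), "NOPE")
})

test_that("module scores are the coefficient-weighted expression sums", {
  run <- fixture_run()
  coh <- fixture_cohort()
  sig <- run$signatures[[1]]
  w <- setNames(tidy(sig)$weight, tidy(sig)$lnc_id)
  tum <- expr_values(run$tumour)
  manual <- as.numeric(crossprod(tum[names(w), , drop = FALSE], w))
  expect_equal(sig$scores$score, manual, tolerance = 1e-12)
  # grouping is the median split of the score
  expect_identical(sig$scores$group, unname(median_split(manual)))
})

test_that("a single-lncRNA signature groups samples like the lncRNA itself", {
  coh <- fixture_cohort()
  screen <- fixture_run()$screen
  one <- screen[screen$passed, ][1, ]
  fake <- screen[screen$lnc_id == one$lnc_id & screen$module_id == one$module_id, ]
  fake$module_id <- "SOLO"
  sig <- module_score(coh$tumour, fake, coh$clinical, "SOLO")
  x <- expr_values(coh$tumour)[one$lnc_id, ]
  w <- sig$weights[[1]]
  expect_identical(
    sig$scores$group,
    unname(median_split(if (w > 0) x else -x)))
})

test_that("pooling disjoint modules sums their scores and beats them individually", {
  run <- fixture_run()
  sigs <- run$signatures
  expect_true("pooled" %in% names(sigs))
  pooled <- sigs$pooled
  mods <- setdiff(names(sigs), "pooled")
  # P and N orientations contain the same planted modules; restrict to a
  # disjoint pair for the linearity check
  disjoint <- character()
  for (m in mods) {
    if (!length(intersect(names(sigs[[m]]$weights),
                          unlist(lapply(disjoint, function(d) names(sigs[[d]]$weights)))))) {
      disjoint <- c(disjoint, m)
    }
  }
  expect_gte(length(disjoint), 2)
  manual <- Reduce(`+`, lapply(disjoint, function(m) sigs[[m]]$scores$score))
  pool2 <- pooled_signature(run$tumour, run$screen, run$clinical, disjoint)
  expect_equal(pool2$scores$score, manual, tolerance = 1e-10)
  # pooled signature at least matches the strongest single module
  expect_gte(abs(log(pooled$os$hr)) + 0.25,
             max(vapply(mods, function(m) abs(log(sigs[[m]]$os$hr)), numeric(1))))
})

test_that("pooled effect exceeds single-module effects across replicates", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(
      n_tumour_samples = 250, n_normal_samples = 40, n_lnc = 30, n_mrna = 200,
      modules = list(
        planted_module(n_lnc_members = 8, n_mrna_pos = 30, n_mrna_neg = 30,
                       survival_beta = -0.5, tumour_shift = 1),
        planted_module(n_lnc_members = 8, n_mrna_pos = 30, n_mrna_neg = 30,
                       survival_beta = -0.5, tumour_shift = 1)),
      stage_link = 0.8, seed = 1000 + s)
    coh <- simulate_cohort(cfg)
    mods <- tibble::tibble(lnc_id = names(coh$truth$module_membership),
                           module_id = unname(coh$truth$module_membership),
                           orientation = "positive")
    screen <- screen_lncrnas(coh$tumour, coh$normal, coh$clinical, mods)
    if (length(unique(screen$module_id[screen$passed])) < 2) next
    s1 <- module_score(coh$tumour, screen, coh$clinical, "M1")
    s2 <- module_score(coh$tumour, screen, coh$clinical, "M2")
    pl <- pooled_signature(coh$tumour, screen, coh$clinical)
    if (abs(log(pl$os$hr)) >= max(abs(log(s1$os$hr)), abs(log(s2$os$hr)))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 8L)
})
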