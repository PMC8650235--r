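test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_tumour_samples = 30, n_normal_samples = 10,
                          n_lnc = 12, n_mrna = 40,
                          modules = list(planted_module(n_lnc_members = 4,
                                                        n_mrna_pos = 10, n_mrna_neg = 10)),
                          seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tumour, b$tumour)
  expect_identical(a$normal, b$normal)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("zero noise and unit loading make module members perfectly rank-correlated", {
  cfg <- synthetic_config(n_tumour_samples = 50, n_normal_samples = 5,
                          n_lnc = 4, n_mrna = 20,
                          modules = list(planted_module(n_lnc_members = 2,
                                                        n_mrna_pos = 5, n_mrna_neg = 5,
                                                        latent_loading = 1)),
                          noise_sd = 0, seed = 3)
  coh <- simulate_cohort(cfg)
  tum <- expr_values(coh$tumour)
  expect_equal(cor(tum["LNC0001", ], tum["LNC0002", ], method = "spearman"), 1)
  # negative-block mRNAs are perfectly anti-correlated with the members
  neg <- coh$truth$correlated_mrna_sets$M1$neg[1]
  expect_equal(cor(tum["LNC0001", ], tum[neg, ], method = "spearman"), -1)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_lnc = 5, modules = list(planted_module(n_lnc_members = 10))),
               "exceed")
  expect_error(synthetic_config(n_mrna = 10, modules = list(planted_module())),
               "exceed")
  expect_error(synthetic_config(censoring_rate = 1.2), "censoring_rate")
  expect_error(planted_module(n_lnc_members = 1), "at least 2")
  expect_error(planted_module(latent_loading = 0), "latent_loading")
})

test_that("ground truth partitions the planted lncRNAs with disjoint mRNA blocks", {
  coh <- fixture_cohort()
  truth <- coh$truth
  expect_equal(length(truth$module_membership), 45)
  expect_false(anyDuplicated(names(truth$module_membership)) > 0)
  for (m in names(truth$correlated_mrna_sets)) {
    s <- truth$correlated_mrna_sets[[m]]
    expect_length(intersect(s$pos, s$neg), 0)
  }
  all_blocks <- unlist(truth$correlated_mrna_sets, use.names = FALSE)
  expect_false(anyDuplicated(all_blocks) > 0)
})

test_that("zero censoring gives all events; the target censoring rate is approached", {
  cfg0 <- synthetic_config(n_tumour_samples = 150, censoring_rate = 0, seed = 9)
  coh0 <- simulate_cohort(cfg0)
  expect_true(all(coh0$clinical$os_event == 1))

  cfg4 <- synthetic_config(n_tumour_samples = 800, censoring_rate = 0.4, seed = 9)
  coh4 <- simulate_cohort(cfg4)
  expect_lt(abs(mean(1 - coh4$clinical$os_event) - 0.4), 0.08)
})

test_that("clinical table is schema-valid with PFS a fixed scaling of OS", {
  coh <- fixture_cohort()
  cl <- coh$clinical
  expect_identical(cl$sample_id, expr_samples(coh$tumour))
  expect_true(all(cl$os_time > 0))
  expect_true(all(cl$stage %in% c("I", "II", "III", "IV")))
  expect_equal(cl$pfs_time, cl$os_time * 0.7)
  truncated <- coh$tumour[, 1:30] # drops most sample columns
  expect_error(simulate_clinical(synthetic_config(n_tumour_samples = 200, seed = 42),
                                 truncated, coh$truth),
               "do not match")
})

test_that("a negative planted survival effect yields a protective expression HR", {
  cfg <- synthetic_config(
    n_tumour_samples = 600, n_normal_samples = 20, n_lnc = 10, n_mrna = 60,
    modules = list(planted_module(n_lnc_members = 4, n_mrna_pos = 15, n_mrna_neg = 15,
                                  survival_beta = -1)),
    censoring_rate = 0.2, seed = 31)
  coh <- simulate_cohort(cfg)
  score <- colMeans(expr_values(coh$tumour)[names(coh$truth$module_membership), ])
  grp <- median_split(score)
  fit <- cox_fit(data.frame(high = as.integer(grp == "high")),
                 coh$clinical$os_time, coh$clinical$os_event)
  expect_lt(fit$hr, 1)
})

test_that("tumour-vs-normal shift appears only in planted lncRNAs", {
  coh <- fixture_cohort()
  tum <- expr_values(coh$tumour); nor <- expr_values(coh$normal)
  truth <- coh$truth$module_membership
  shifted <- names(truth)[truth %in% c("M1", "M2")]
  null_mod <- names(truth)[truth == "M3"]
  d_shift <- rowMeans(tum[shifted, ]) - rowMeans(nor[shifted, ])
  d_null <- rowMeans(tum[null_mod, ]) - rowMeans(nor[null_mod, ])
  expect_gt(min(d_shift), 0.8)
  expect_lt(max(abs(d_null)), 0.4)
})

test_that("stage coupling links stage to module activity only when requested", {
  base <- list(n_tumour_samples = 500, n_normal_samples = 20, n_lnc = 10, n_mrna = 60,
               modules = list(planted_module(n_lnc_members = 4, n_mrna_pos = 15,
                                             n_mrna_neg = 15)))
  linked <- simulate_cohort(do.call(synthetic_config,
                                    c(base, list(stage_link = 1.5, seed = 77))))
  indep <- simulate_cohort(do.call(synthetic_config,
                                   c(base, list(stage_link = 0, seed = 77))))
  p_link <- kruskal.test(linked$truth$factors[, 1],
                         factor(linked$clinical$stage))$p.value
  p_indep <- kruskal.test(indep$truth$factors[, 1],
                          factor(indep$clinical$stage))$p.value
  expect_lt(p_link, 1e-6)
  expect_gt(p_indep, 0.001)
})

test_that("written cohorts round-trip through the readers", {
  coh <- fixture_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  tum <- read_expression_tsv(paths["tumour"])
  expect_equal(expr_values(tum), expr_values(coh$tumour))
  cl <- read_clinical_tsv(paths["clinical"])
  expect_equal(cl$os_time, coh$clinical$os_time)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  memb <- unlist(truth$module_membership)
  expect_setequal(names(memb), names(coh$truth$module_membership))
  expect_identical(unname(memb[names(coh$truth$module_membership)]),
                   unname(coh$truth$module_membership))
})
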