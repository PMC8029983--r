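small_cfg <- function(...) {
  do.call(cohort_config,
          modifyList(list(n_tumor = 10, n_normal = 10, n_genes = 60,
                          seed = 7),
                     list(...)))
}

test_that("cohort generation is a pure function of config and seed", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$expression$array, b$expression$array)
  expect_identical(a$methylation$beta, b$methylation$beta)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$genomic$mutations, b$genomic$mutations)
  expect_identical(a$mirna$lists, b$mirna$lists)
  c <- simulate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$expression$counts, c$expression$counts))
})

test_that("config validation rejects out-of-range values by name", {
  expect_error(cohort_config(de_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(n_genes = 0))
  expect_error(cohort_config(libsize_range = c(2e6, 1e6)), "increasing")
  expect_error(cohort_config(nonsense = 1), "nonsense")
})

test_that("planted expression truth matches construction", {
  ex <- simulate_expression_pair(cohort_config(
    n_tumor = 30, n_normal = 30, n_genes = 400, de_fraction = 0.1,
    discordant_fraction = 0.1, seed = 3))
  tr <- ex$truth
  expect_equal(sum(tr$planted), 40)
  expect_true(all(tr$dir_array[!tr$planted] == 0))
  expect_true(all(abs(tr$dir_array[tr$planted]) == 1))
  # discordant genes flip only the count-platform direction
  disc <- tr$planted & tr$dir_array != tr$dir_seq
  expect_equal(sum(disc), 4)
  expect_true(all(tr$dir_seq[disc] == -tr$dir_array[disc]))
  expect_true(all(ex$counts >= 0))
  expect_identical(colnames(ex$array), colnames(ex$counts))
})

test_that("null expression cohorts produce calibrated p-values", {
  ex <- simulate_expression_pair(cohort_config(
    n_tumor = 20, n_normal = 20, n_genes = 600, de_fraction = 0, seed = 21))
  de <- array_ttest_de(ex$array, ex$groups)
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.08)
})

test_that("methylation truth matches construction and NA handling", {
  mm <- simulate_methylation(cohort_config(
    n_tumor = 10, n_normal = 10, n_genes = 80, meth_na_rate = 0, seed = 5))
  expect_false(anyNA(mm$beta))
  expect_true(all(mm$beta >= 0 & mm$beta <= 1))
  expect_setequal(mm$map$cpg, rownames(mm$beta))

  mm2 <- simulate_methylation(cohort_config(
    n_tumor = 10, n_normal = 10, n_genes = 80, meth_na_rate = 0.1, seed = 5))
  expect_gt(sum(is.na(mm2$beta)), 0)
  # an all-CpG shifted gene carries a directional truth label
  expect_true(all(mm$truth$meth_truth %in% c("hyper", "hypo", "mixed", "none")))
  expect_gt(sum(mm$truth$meth_truth %in% c("hyper", "hypo")), 0)
})

test_that("survival generator recovers null and planted hazard ratios", {
  cfg <- cohort_config(n_tumor = 300, n_normal = 5, n_genes = 210,
                       hr_genes = c(g0200 = log(2)), censor_rate = 0.25,
                       seed = 9)
  ex <- simulate_expression_pair(cfg)
  cl <- simulate_clinical_survival(cfg, ex$array)
  tum <- cl[cl$group == "tumor", ]
  x <- as.numeric(scale(ex$array["g0200", tum$sample_id]))
  fit <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "g")),
                 tum$os_time, tum$os_event)
  expect_gt(fit$hr, 1.6)
  expect_lt(fit$hr, 2.5)

  # null genes: 95% CI covers HR = 1 at roughly the nominal rate
  null_genes <- setdiff(rownames(ex$array), "g0200")[1:200]
  covered <- vapply(null_genes, function(g) {
    z <- as.numeric(scale(ex$array[g, tum$sample_id]))
    f <- cox_fit(matrix(z, ncol = 1, dimnames = list(NULL, "g")),
                 tum$os_time, tum$os_event)
    f$lower <= 1 && f$upper >= 1
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("degenerate censoring configurations warn", {
  cfg <- cohort_config(n_tumor = 20, n_normal = 5, n_genes = 20,
                       censor_rate = 1, seed = 2)
  ex <- simulate_expression_pair(cfg)
  expect_warning(cl <- simulate_clinical_survival(cfg, ex$array),
                 "censored")
  expect_true(all(cl$os_event[cl$group == "tumor"] == 0))
})

test_that("genomic alteration frequencies track their configured rates", {
  cfg <- cohort_config(n_tumor = 1000, n_normal = 2, n_genes = 20,
                       mutation_rate = 0.05, cnv_del_prob = 0.4,
                       cnv_amp_prob = 0.05, seed = 13)
  ga <- simulate_genomic_alterations(cfg, genes = c("CALM1", "RORA"))
  freq <- alteration_frequencies(ga$mutations, ga$cnv, ga$samples)
  expect_true(all(abs(freq$mut_freq - 5) < 1.5))
  expect_true(all(abs(freq$del_freq + 40) < 5))

  cfg0 <- cohort_config(n_tumor = 50, n_normal = 2, n_genes = 20,
                        mutation_rate = 0, seed = 13)
  ga0 <- simulate_genomic_alterations(cfg0)
  expect_equal(nrow(ga0$mutations), 0L)
})

test_that("miRNA lists, consensus truth and anticorrelation are as planted", {
  cfg <- cohort_config(n_tumor = 40, n_normal = 40, n_genes = 20,
                       anticor_strength = 0.8, seed = 17)
  mi <- simulate_mirna_targets(cfg)
  mi2 <- simulate_mirna_targets(cfg)
  expect_identical(mi$lists, mi2$lists)
  expect_identical(mi$counts, mi2$counts)

  tr <- mi$truth
  expect_true(all(tr$n_lists[tr$consensus] >= 2))
  expect_true(all(tr$n_lists[!tr$consensus] <= 1))

  # planted regulators anticorrelate with a supplied target on log scale
  samples <- c(sprintf("T%03d", 1:40), sprintf("N%03d", 1:40))
  set.seed(99)
  target <- setNames(rnorm(80), samples)
  mi3 <- simulate_mirna_targets(
    cohort_config(n_tumor = 40, n_normal = 40, n_genes = 20,
                  anticor_strength = 0.8, mirna_shift = 0, seed = 17),
    target = target)
  lc <- log_cpm(mi3$counts)
  reg <- mi3$truth$mirna[mi3$truth$regulatory]
  rs <- apply(lc[reg, ], 1, function(v) cor(v, target[colnames(lc)]))
  expect_true(all(rs < -0.5))
})
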