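two_group <- function(n1, n2, first = "tumor", second = "normal") {
  factor(rep(c(first, second), c(n1, n2)), levels = c(first, second))
}

test_that("pooled-variance t matches the closed form", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(5, 5.1, 4.9, 5, 5.1, 4.9))
  colnames(m) <- paste0("s", 1:6)
  de <- array_ttest_de(m, two_group(3, 3))
  # x=(1,2,3) vs y=(4,5,6): t = -3/sqrt(2/3) = -3.674, df 4
  expect_equal(de$statistic[1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(de$p[1], 2 * pt(-abs(-3 / sqrt(2 / 3)), 4), tolerance = 1e-12)
  expect_equal(de$p[1], 0.02131164, tolerance = 1e-6)
  expect_equal(de$direction[1], -1)
  # near-identical group means: t ~ 0, p ~ 1
  expect_gt(de$p[2], 0.9)

  # permuting samples within groups changes nothing
  perm <- m[, c(2, 3, 1, 6, 4, 5)]
  expect_equal(array_ttest_de(perm, two_group(3, 3))$statistic,
               de$statistic, tolerance = 1e-12)
})

test_that("antisymmetry: swapping group labels negates t, log2FC and S", {
  set.seed(4)
  cfg <- cohort_config(n_tumor = 8, n_normal = 8, n_genes = 40,
                       de_fraction = 0.2, seed = 4)
  ex <- simulate_expression_pair(cfg)
  nf <- tmm_factors(ex$counts)
  swapped <- factor(ifelse(ex$groups == "tumor", "normal", "tumor"),
                    levels = c("tumor", "normal"))
  de_a <- array_ttest_de(ex$array, ex$groups)
  de_a2 <- array_ttest_de(ex$array, swapped)
  expect_equal(de_a2$statistic, -de_a$statistic, tolerance = 1e-9)
  de_s <- count_nb_de(ex$counts, nf, ex$groups, dispersion = 0.1)
  de_s2 <- count_nb_de(ex$counts, nf, swapped, dispersion = 0.1)
  expect_equal(de_s2$statistic, -de_s$statistic, tolerance = 1e-9)
  expect_equal(de_s2$p, de_s$p, tolerance = 1e-9)
  s1 <- status_table(de_a, de_s)
  s2 <- status_table(de_a2, de_s2)
  expect_equal(s2$S, -s1$S)
})

test_that("the NB exact test reduces to the binomial split at zero dispersion", {
  counts <- rbind(g1 = c(30L, 25L, 3L, 2L),
                  g2 = c(11L, 12L, 10L, 13L),
                  g3 = c(0L, 1L, 25L, 30L))
  colnames(counts) <- paste0("s", 1:4)
  # equal library sizes so equalization is a no-op
  counts <- rbind(counts, filler = 500L - colSums(counts))
  de <- count_nb_de(counts, factors = NULL, groups = two_group(2, 2),
                    dispersion = 0)
  for (i in 1:3) {
    ya <- sum(counts[i, 1:2]); y <- sum(counts[i, ])
    expect_equal(de$p[i], binom.test(ya, y, 0.5)$p.value, tolerance = 1e-9)
  }
  expect_equal(de$direction[1], 1)
  expect_equal(de$direction[3], -1)
})

test_that("the NB exact test is calibrated under the null and powered when planted", {
  ex <- simulate_expression_pair(cohort_config(
    n_tumor = 10, n_normal = 10, n_genes = 2000, de_fraction = 0,
    nb_dispersion = 0.1, seed = 31))
  nf <- tmm_factors(ex$counts)
  de <- count_nb_de(ex$counts, nf, ex$groups)
  expect_gt(mean(de$p < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(de$p < 0.05, na.rm = TRUE), 0.07)
  # recovered common dispersion near the generating value
  expect_lt(abs(attr(de, "dispersion") - 0.1), 0.05)

  # a planted 4-fold gene at n=10/10, phi=0.1 clears FDR < 0.05
  ex2 <- simulate_expression_pair(cohort_config(
    n_tumor = 10, n_normal = 10, n_genes = 400, de_fraction = 0.05,
    effect_size = 2, discordant_fraction = 0, nb_dispersion = 0.1,
    seed = 32))
  nf2 <- tmm_factors(ex2$counts)
  de2 <- count_nb_de(ex2$counts, nf2, ex2$groups)
  planted <- ex2$truth$gene[ex2$truth$planted]
  expect_gt(mean(de2$fdr[match(planted, de2$gene)] < 0.05), 0.8)
})

test_that("the NB exact test tracks an established exact-test implementation", {
  ex <- simulate_expression_pair(cohort_config(
    n_tumor = 8, n_normal = 8, n_genes = 200, de_fraction = 0.1,
    nb_dispersion = 0.15, seed = 41))
  nf <- tmm_factors(ex$counts)
  de <- count_nb_de(ex$counts, nf, ex$groups, dispersion = 0.15)
  dge <- edgeR::DGEList(ex$counts, group = ex$groups)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  et <- edgeR::exactTest(dge, dispersion = 0.15,
                         pair = c("normal", "tumor"))
  expect_gt(cor(-log10(de$p), -log10(et$table$PValue),
                method = "spearman"), 0.95)
  expect_gt(cor(de$statistic, et$table$logFC), 0.98)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
  o <- sample(50)
  expect_equal(bh_adjust(p[o]), bh_adjust(p)[o])
  expect_true(all(bh_adjust(p) >= p))
})

test_that("platform status assignment follows the significance/direction rule", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   fdr = c(0.01, 0.2, 0.01, 0.2, 0.03),
                   direction = c(1, 1, -1, -1, NA))
  expect_equal(assign_platform_status(de), c(1, 0.5, -1, -0.5, NA))
  expect_equal(assign_platform_status(0.2, direction = -1), -0.5)
})

test_that("status integration gates the sum on sign agreement", {
  expect_equal(integrate_status(0.5, 1), 1.5)
  expect_equal(integrate_status(-0.5, 1), 0)
  expect_equal(integrate_status(-1, -1), -2)
  expect_error(integrate_status(0.7, 1), "alphabet")

  # over all 16 combinations: S stays in the alphabet, antisymmetric,
  # |S| = 2 exactly when both platforms are significant and concordant
  alphabet <- c(-1, -0.5, 0.5, 1)
  for (sa in alphabet) for (ss in alphabet) {
    S <- integrate_status(sa, ss)
    expect_true(S %in% c(-2, -1.5, -1, 0, 1, 1.5, 2))
    expect_equal(integrate_status(-sa, -ss), -S)
    expect_equal(abs(S) == 2, abs(sa) == 1 && abs(ss) == 1 &&
                   sign(sa) == sign(ss))
  }
})

test_that("status_table joins platforms and reports requested genes", {
  de_a <- data.frame(gene = c("x", "y"), statistic = c(2, -1),
                     p = c(0.001, 0.3), fdr = c(0.002, 0.3),
                     direction = c(1, -1))
  de_s <- data.frame(gene = c("x", "y"), statistic = c(1.5, 0.2),
                     p = c(0.001, 0.4), fdr = c(0.002, 0.4),
                     direction = c(1, 1))
  st <- status_table(de_a, de_s)
  expect_equal(st$S, c(2, 0))
  expect_error(status_table(de_a, de_s, genes = "z"), "absent")
})
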