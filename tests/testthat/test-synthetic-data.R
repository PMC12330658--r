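# Synthetic cohort generators: label fractions, covariate structure,
# determinism, and the deterministic hidden-label rule.

test_that("cohort_config validates its inputs", {
  expect_error(cohort_config(denovo_fraction_risk = 0.02,
                             denovo_fraction_nonrisk = 0.6),
               "must exceed")
  expect_error(cohort_config(n_genes = 0), "positive")
  expect_error(cohort_config(score_model = list(mean_denovo = 0.6,
                                                mean_inherited = 0.2,
                                                variance = 0)),
               "variance")
})

test_that("degenerate de novo fraction of zero yields all-inherited tables", {
  cfg <- cohort_config(n_genes = 50, n_variants_total = 500,
                       denovo_fraction_nonrisk = 0,
                       risk_gene_fraction = 0, rng_seed = 4)
  fam <- simulate_family_variants(cfg)
  expect_true(all(fam$label == 0L))
})

test_that("family label counts match the binomial imbalance model", {
  # 30:1 inherited:de novo imbalance over 31,000 variants
  cfg <- cohort_config(n_genes = 1000, n_variants_total = 31000,
                       denovo_fraction_nonrisk = 1 / 31,
                       risk_gene_fraction = 0, rng_seed = 9)
  fam <- simulate_family_variants(cfg)
  n <- nrow(fam)
  expected <- n / 31
  sd3 <- 3 * sqrt(n * (1 / 31) * (30 / 31))
  expect_gt(sum(fam$label), expected - sd3)
  expect_lt(sum(fam$label), expected + sd3)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- cohort_config(n_genes = 40, n_variants_total = 400, rng_seed = 21)
  expect_identical(simulate_family_variants(cfg),
                   simulate_family_variants(cfg))
  cs1 <- simulate_case_variants(cfg)
  cs2 <- simulate_case_variants(cfg)
  expect_identical(cs1, cs2)
  genes <- simulate_genes(30, 0, rng_seed = 5)
  expect_identical(simulate_null_variants(200, gene_table = genes,
                                          rng_seed = 8),
                   simulate_null_variants(200, gene_table = genes,
                                          rng_seed = 8))
})

test_that("covariates respect their legal ranges and class directions", {
  cfg <- cohort_config(n_genes = 200, n_variants_total = 20000,
                       denovo_fraction_risk = 0.5,
                       denovo_fraction_nonrisk = 0.49,
                       risk_gene_fraction = 1, rng_seed = 2)
  fam <- simulate_family_variants(cfg)
  expect_true(all(fam$AF >= 0 & fam$AF <= 0.001))
  expect_true(all(fam$CCR >= 0 & fam$CCR <= 100))
  expect_true(all(fam$FDR_TADA_DD >= 0 & fam$FDR_TADA_DD <= 1))
  expect_true(all(fam$obs_lof >= 0))
  expect_true(all(fam$exp_lof > 0))
  expect_false(anyNA(fam[, c("AF", "LOEUF", "CCR", "FDR_TADA_DD",
                             "obs_lof", "exp_lof")]))
  dn <- fam[fam$label == 1L, ]
  inh <- fam[fam$label == 0L, ]
  # de novo variants: rarer, more constrained, less DD-excluded
  expect_lt(mean(dn$AF), mean(inh$AF))
  expect_lt(mean(dn$LOEUF), mean(inh$LOEUF))
  expect_gt(mean(dn$CCR), mean(inh$CCR))
  expect_lt(mean(dn$FDR_TADA_DD), mean(inh$FDR_TADA_DD))
  expect_lt(mean(dn$obs_lof), mean(inh$obs_lof))
  expect_gt(mean(dn$exp_lof), mean(inh$exp_lof))
})

test_that("hidden de novo counts follow the deterministic rounding rule", {
  genes <- data.frame(gene_id = c("A", "B"), mu = c(5e-6, 5e-6),
                      risk = c(1L, 0L), n_case = c(5L, 5L))
  cfg <- cohort_config(n_genes = 2, n_variants_total = 10, rng_seed = 3)
  cs <- simulate_case_variants(cfg, gene_table = genes)
  dn <- tapply(cs$truth$label, cs$truth$gene_id, sum)
  expect_equal(unname(dn[["A"]]), 3)  # round(0.603 * 5) = 3
  expect_equal(unname(dn[["B"]]), 0)  # round(0.026 * 5) = 0
  expect_equal(nrow(cs$variants), 10L)
  expect_false("label" %in% names(cs$variants))
})

test_that("case de novo scores are Gaussian around the class means", {
  genes <- data.frame(gene_id = "A", mu = 5e-6, risk = 1L, n_case = 4000L)
  cfg <- cohort_config(n_genes = 1, n_variants_total = 4000,
                       denovo_fraction_risk = 1,
                       denovo_fraction_nonrisk = 0.5, rng_seed = 6)
  cs <- simulate_case_variants(cfg, gene_table = genes)
  # all variants de novo; about half their scores exceed the 0.6 mean
  expect_equal(mean(cs$truth$label), 1)
  expect_equal(mean(cs$variants$score > 0.6), 0.5, tolerance = 0.05)
  expect_equal(sd(cs$variants$score), sqrt(0.1), tolerance = 0.05)
})

test_that("null case tables carry no signal and respect gene weights", {
  genes <- simulate_genes(100, 0, rng_seed = 13)
  expect_true(all(genes$risk == 0L))
  tab <- simulate_null_variants(5000, gene_table = genes, rng_seed = 13)
  expect_equal(nrow(tab), 5000L)
  # gene usage tracks mutation-opportunity weights
  counts <- table(factor(tab$gene_id, levels = genes$gene_id))
  expect_gt(cor(as.numeric(counts), genes$mu, method = "spearman"), 0.7)
  # scores come from the inherited component
  expect_lt(abs(mean(tab$score) - 0.2), 0.03)
  expect_error(simulate_null_variants(0), "positive")
})

test_that("child seed streams are reproducible and within integer range", {
  expect_identical(derive_seed(1, "labels"), derive_seed(1, "labels"))
  expect_false(derive_seed(1, "labels") == derive_seed(1, "scores"))
  big <- derive_seed(2147483600, "x")
  expect_true(is.integer(big) && big >= 0L)
})
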