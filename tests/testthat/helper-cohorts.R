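# Shared fixtures, built in code.

# Small labeled family-style cohort for classifier tests.
make_family_cohort <- function(seed, n_genes = 200, n_variants = 3000) {
  cfg <- cohort_config(n_genes = n_genes, n_variants_total = n_variants,
                       risk_gene_fraction = 0.05, rng_seed = seed)
  simulate_family_variants(cfg)
}

# Family-with-signal gene table + family BFs + null case counts, the
# configuration used by the error-control study.
make_study_genes <- function(seed, n_genes = 800, n_case = 600,
                             n_trios = 8000) {
  genes <- simulate_genes(n_genes, 0.05, rng_seed = seed)
  gnull <- genes
  gnull$risk <- 0L  # null case data: no risk-gene enrichment
  gnull <- simulate_case_counts(gnull, n_case, rng_seed = seed)
  genes$n_case <- gnull$n_case
  fam <- simulate_family_counts(genes, n_trios = n_trios, rng_seed = seed)
  fam$bf_family <- denovo_bayes_factor(fam$dn_count, n_trios, fam$mu)
  list(genes = genes, family = fam, n_trios = n_trios)
}

# Monte-Carlo oracle for the Beta-prior Random Draw marginal likelihood.
mc_rd_bayes_factor <- function(xd, xh, w1, w2, priors, n_draws, seed) {
  set.seed(seed)
  marg <- function(spec) {
    p <- if (spec$type == "point") rep(spec$value, n_draws)
         else rbeta(n_draws, spec$shape1, spec$shape2)
    q <- w1 * p + (1 - w2) * (1 - p)
    mean(dbinom(xd, xd + xh, q))
  }
  marg(priors$p1) / marg(priors$p0)
}
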