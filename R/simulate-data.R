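# Synthetic cohort generators.  These emulate the statistical structure the
# classifier and the Random Draw model assume -- label-conditional covariate
# separation, per-gene de novo fractions that differ between risk and
# non-risk genes, and a Gaussian de novo score model -- without attempting to
# reproduce any real cohort's joint covariate distribution.

#' Configuration for a simulated cohort
#'
#' Defaults are the study conditions of the power-simulation design: the de
#' novo fraction is 0.603 among variants in risk genes and 0.026 otherwise
#' (the fractions observed in family-based data for the two gene classes),
#' and de novo scores are Gaussian with mean 0.6 (de novo) or 0.2
#' (inherited) and variance 0.1.
#'
#' @param n_genes number of genes in the cohort.
#' @param n_variants_total expected total variant count across genes.
#' @param denovo_fraction_risk probability a variant in a risk gene is de
#'   novo.
#' @param denovo_fraction_nonrisk probability a variant in a non-risk gene is
#'   de novo; must be smaller than `denovo_fraction_risk`.
#' @param risk_gene_fraction fraction of genes flagged as risk genes.
#' @param score_model list with `mean_denovo`, `mean_inherited`, `variance`
#'   of the Gaussian de novo score model.
#' @param count_dispersion extra-Poisson dispersion of per-gene variant
#'   counts given the gene's mutation rate (negative-binomial size; the
#'   default `Inf` means Poisson sampling, in which case the marginal count
#'   distribution across genes is still negative binomial because mutation
#'   rates are Gamma-distributed).
#' @param rng_seed integer root seed.
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_genes = 100, n_variants_total = 1000)
#' @export
cohort_config <- function(n_genes = 500,
                          n_variants_total = 10000,
                          denovo_fraction_risk = 0.603,
                          denovo_fraction_nonrisk = 0.026,
                          risk_gene_fraction = 0.05,
                          score_model = list(mean_denovo = 0.6,
                                             mean_inherited = 0.2,
                                             variance = 0.1),
                          count_dispersion = Inf,
                          rng_seed = 1L) {
  if (n_genes < 1 || n_variants_total < 1)
    stop("n_genes and n_variants_total must be positive")
  for (f in c(denovo_fraction_risk, denovo_fraction_nonrisk,
              risk_gene_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (denovo_fraction_risk <= denovo_fraction_nonrisk)
    stop("denovo_fraction_risk must exceed denovo_fraction_nonrisk")
  if (score_model$variance <= 0) stop("score variance must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_variants_total = as.integer(n_variants_total),
                 denovo_fraction_risk = denovo_fraction_risk,
                 denovo_fraction_nonrisk = denovo_fraction_nonrisk,
                 risk_gene_fraction = risk_gene_fraction,
                 score_model = score_model,
                 count_dispersion = count_dispersion,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

#' Simulate a gene table
#'
#' Draws per-gene de novo mutation rates (mutational opportunity) from a
#' Gamma distribution and flags a fixed fraction of genes as risk genes.
#' Mutation rates average 5e-6 expected de novo protein-truncating events per
#' chromosome per generation, a realistic exome-wide scale.
#'
#' @param n_genes number of genes.
#' @param risk_gene_fraction fraction flagged as risk (exact count,
#'   `round(n_genes * fraction)`, assigned at random).
#' @param mean_mu mean per-gene mutation rate.
#' @param rng_seed integer seed.
#' @return data.frame with `gene_id`, `mu`, `risk` (0/1).
#' @examples
#' genes <- simulate_genes(50, 0.1, rng_seed = 1)
#' sum(genes$risk)
#' @export
simulate_genes <- function(n_genes, risk_gene_fraction = 0.05,
                           mean_mu = 5e-6, rng_seed = 1L) {
  stopifnot(n_genes >= 1)
  with_seed(derive_seed(rng_seed, "genes"), {
    mu <- rgamma(n_genes, shape = 1.5, rate = 1.5 / mean_mu)
    n_risk <- round_half_up(n_genes * risk_gene_fraction)
    risk <- integer(n_genes)
    if (n_risk > 0) risk[sample.int(n_genes, n_risk)] <- 1L
    data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
               mu = mu, risk = risk, stringsAsFactors = FALSE)
  })
}

#' Add case variant counts to a gene table
#'
#' Per-gene counts of rare variants observed in the case sample.  The
#' inherited background is proportional to the gene's mutation-opportunity
#' weight `mu`; on top of it, affected individuals carry excess de novo
#' variants in risk genes, so when the gene table has a `risk` column the
#' expected count is scaled by `1 / (1 - fraction)` with the gene's de novo
#' fraction — the enrichment implied by the fractions themselves (a gene in
#' which 60.3% of case variants are de novo must hold its inherited
#' background times `1/0.397`).  Counts are Poisson given the mean, with
#' optional extra negative-binomial dispersion.
#'
#' @param gene_table data.frame with `gene_id`, `mu` and optionally `risk`.
#' @param n_variants_total expected total count over all genes.
#' @param dispersion extra-Poisson negative-binomial size (`Inf` = Poisson).
#' @param rng_seed integer seed.
#' @param denovo_fraction_risk,denovo_fraction_nonrisk de novo fractions
#'   used for the risk-gene enrichment (ignored without a `risk` column).
#' @return `gene_table` with an added `n_case` column.
#' @export
simulate_case_counts <- function(gene_table, n_variants_total,
                                 dispersion = Inf, rng_seed = 1L,
                                 denovo_fraction_risk = 0.603,
                                 denovo_fraction_nonrisk = 0.026) {
  stopifnot(all(c("gene_id", "mu") %in% names(gene_table)))
  w <- gene_table$mu
  if ("risk" %in% names(gene_table)) {
    frac <- ifelse(gene_table$risk == 1L, denovo_fraction_risk,
                   denovo_fraction_nonrisk)
    w <- w / (1 - frac)
  }
  with_seed(derive_seed(rng_seed, "case_counts"), {
    m <- n_variants_total * w / sum(w)
    gene_table$n_case <- draw_counts(m, dispersion)
    gene_table
  })
}

draw_counts <- function(m, dispersion) {
  if (is.infinite(dispersion)) rpois(length(m), m)
  else rnbinom(length(m), mu = m, size = dispersion)
}

#' Simulate a labeled family-style variant table
#'
#' Emulates family-based (trio) data in which the inheritance class of every
#' offspring variant is known: per-gene variant counts are negative-binomial
#' with mean proportional to mutation rate, each variant is independently de
#' novo with the gene's configured fraction, and the six covariates are drawn
#' from the label-conditional profile distributions.
#'
#' @param config a `cohort_config`.
#' @param profiles covariate profiles covering all six covariates (default
#'   [covariate_profiles()]).
#' @param gene_table optional gene table from [simulate_genes()]; generated
#'   from `config` when missing.
#' @return data.frame with `gene_id`, the six covariates, and `label`
#'   (1 = de novo, 0 = inherited); the gene table is attached as attribute
#'   `genes`.
#' @examples
#' cfg <- cohort_config(n_genes = 50, n_variants_total = 500, rng_seed = 7)
#' fam <- simulate_family_variants(cfg)
#' table(fam$label)
#' @export
simulate_family_variants <- function(config, profiles = covariate_profiles(),
                                     gene_table = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(profiles) == 0) stop("profiles must not be empty")
  if (is.null(gene_table))
    gene_table <- simulate_genes(config$n_genes, config$risk_gene_fraction,
                                 rng_seed = config$rng_seed)
  counts <- with_seed(derive_seed(config$rng_seed, "family_counts"), {
    m <- config$n_variants_total * gene_table$mu / sum(gene_table$mu)
    draw_counts(m, config$count_dispersion)
  })
  gene_idx <- rep(seq_len(nrow(gene_table)), counts)
  frac <- ifelse(gene_table$risk[gene_idx] == 1L,
                 config$denovo_fraction_risk,
                 config$denovo_fraction_nonrisk)
  labels <- with_seed(derive_seed(config$rng_seed, "family_labels"),
                      rbinom(length(gene_idx), 1L, frac))
  covs <- with_seed(derive_seed(config$rng_seed, "family_covariates"),
                    sample_covariates(labels, profiles))
  out <- cbind(data.frame(gene_id = gene_table$gene_id[gene_idx],
                          stringsAsFactors = FALSE),
               covs, data.frame(label = labels))
  attr(out, "genes") <- gene_table
  out
}

#' Simulate an unlabeled case-only variant table with hidden truth
#'
#' Emulates case-only data: per gene, the number of de novo variants is the
#' gene's de novo fraction times its case variant count, rounded to the
#' nearest integer (half away from zero) and floored at zero; the remaining
#' variants are inherited.  Each variant receives covariates drawn
#' conditional on its hidden label and a de novo score drawn from the
#' Gaussian score model.  The true labels are returned separately and are
#' meant for evaluation only.
#'
#' @inheritParams simulate_family_variants
#' @return list with `variants` (gene_id, covariates, score; no label) and
#'   `truth` (per-variant `gene_id`, `label`); gene table attached to
#'   `variants` as attribute `genes`.
#' @examples
#' cfg <- cohort_config(n_genes = 20, n_variants_total = 200, rng_seed = 3)
#' cs <- simulate_case_variants(cfg)
#' head(cs$variants)
#' @export
simulate_case_variants <- function(config, profiles = covariate_profiles(),
                                   gene_table = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_variants_total < 1) stop("n_variants_total must be positive")
  if (is.null(gene_table))
    gene_table <- simulate_genes(config$n_genes, config$risk_gene_fraction,
                                 rng_seed = config$rng_seed)
  if (!"n_case" %in% names(gene_table))
    gene_table <- simulate_case_counts(gene_table, config$n_variants_total,
                                       config$count_dispersion,
                                       config$rng_seed)
  labels <- hidden_labels(gene_table$n_case,
                          ifelse(gene_table$risk == 1L,
                                 config$denovo_fraction_risk,
                                 config$denovo_fraction_nonrisk),
                          derive_seed(config$rng_seed, "case_label_order"))
  gene_idx <- rep(seq_len(nrow(gene_table)), gene_table$n_case)
  covs <- with_seed(derive_seed(config$rng_seed, "case_covariates"),
                    sample_covariates(labels, profiles))
  scores <- draw_scores(labels, config$score_model,
                        derive_seed(config$rng_seed, "case_scores"))
  variants <- cbind(data.frame(gene_id = gene_table$gene_id[gene_idx],
                               stringsAsFactors = FALSE),
                    covs, data.frame(score = scores))
  attr(variants, "genes") <- gene_table
  list(variants = variants,
       truth = data.frame(gene_id = gene_table$gene_id[gene_idx],
                          label = labels, stringsAsFactors = FALSE))
}

# Deterministic per-gene de novo counts (round half away from zero, floored
# at 0), randomly positioned within each gene's variants.
hidden_labels <- function(n_case, frac, seed) {
  n_dn <- pmax(0, round_half_up(frac * n_case))
  n_dn <- pmin(n_dn, n_case)
  with_seed(seed, {
    unlist(lapply(seq_along(n_case), function(i) {
      lab <- integer(n_case[i])
      if (n_dn[i] > 0) lab[sample.int(n_case[i], n_dn[i])] <- 1L
      lab
    }), use.names = FALSE)
  })
}

draw_scores <- function(labels, score_model, seed) {
  mu <- ifelse(labels == 1L, score_model$mean_denovo,
               score_model$mean_inherited)
  with_seed(seed, rnorm(length(labels), mu, sqrt(score_model$variance)))
}

#' Simulate a fully null case-only table
#'
#' All variants are drawn from the inherited/background covariate and score
#' distributions with no gene-level enrichment; variants are assigned to
#' genes with probability proportional to each gene's mutation-opportunity
#' weight.  Used for error-control (per-family error rate) simulations; the
#' truth set of risk genes is empty by construction.
#'
#' @param n_variants number of variants to draw.
#' @param profiles covariate profiles.
#' @param gene_table gene table with `gene_id` and `mu` weights.
#' @param score_model Gaussian score model (only the inherited component is
#'   used).
#' @param rng_seed integer seed.
#' @return data.frame with `gene_id`, covariates, `score`.
#' @export
simulate_null_variants <- function(n_variants, profiles = covariate_profiles(),
                                   gene_table = NULL,
                                   score_model = list(mean_denovo = 0.6,
                                                      mean_inherited = 0.2,
                                                      variance = 0.1),
                                   rng_seed = 1L) {
  if (n_variants < 1) stop("n_variants must be positive")
  if (is.null(gene_table))
    gene_table <- simulate_genes(500, 0, rng_seed = rng_seed)
  gene_idx <- with_seed(derive_seed(rng_seed, "null_genes"),
                        sample.int(nrow(gene_table), n_variants,
                                   replace = TRUE, prob = gene_table$mu))
  labels <- integer(n_variants)
  covs <- with_seed(derive_seed(rng_seed, "null_covariates"),
                    sample_covariates(labels, profiles))
  scores <- draw_scores(labels, score_model,
                        derive_seed(rng_seed, "null_scores"))
  out <- cbind(data.frame(gene_id = gene_table$gene_id[gene_idx],
                          stringsAsFactors = FALSE),
               covs, data.frame(score = scores))
  attr(out, "genes") <- gene_table
  out
}

#' Simulate per-gene family de novo counts
#'
#' Draws observed de novo counts for a trio cohort: `x ~ Poisson(2 N mu)`
#' for non-risk genes and `x ~ Poisson(2 N mu gamma)` with a
#' Gamma-distributed relative risk for risk genes (the generative model the
#' family de novo Bayes factor tests against).
#'
#' @param gene_table data.frame with `gene_id`, `mu`, `risk`.
#' @param n_trios number of trios.
#' @param gamma_mean,beta relative-risk prior: `gamma ~ Gamma(gamma_mean *
#'   beta, rate = beta)` for risk genes.
#' @param rng_seed integer seed.
#' @return `gene_table` with an added `dn_count` column.
#' @export
simulate_family_counts <- function(gene_table, n_trios,
                                   gamma_mean = 20, beta = 1,
                                   rng_seed = 1L) {
  stopifnot(all(c("gene_id", "mu", "risk") %in% names(gene_table)))
  with_seed(derive_seed(rng_seed, "family_dn_counts"), {
    lambda <- 2 * n_trios * gene_table$mu
    gam <- ifelse(gene_table$risk == 1L,
                  rgamma(nrow(gene_table), shape = gamma_mean * beta,
                         rate = beta),
                  1)
    gene_table$dn_count <- rpois(nrow(gene_table), lambda * gam)
    gene_table
  })
}
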