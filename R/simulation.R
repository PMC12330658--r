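# Error-control (per-family error rate) and power simulations for the
# combined family + Random Draw gene test, under the Gaussian de novo score
# model: scores ~ N(0.6, 0.1) for de novo variants and N(0.2, 0.1) for
# inherited variants, so at any threshold c the classifier's sensitivity
# and specificity follow in closed form from the normal CDF.

#' Analytic sensitivity and specificity under the Gaussian score model
#'
#' With de novo scores `N(mean_denovo, variance)` and inherited scores
#' `N(mean_inherited, variance)`, thresholding at c gives
#' `w1 = 1 - Phi((c - mean_denovo) / sd)` and
#' `w2 = Phi((c - mean_inherited) / sd)`.
#'
#' @param threshold threshold c (vectorised).
#' @param score_model list with `mean_denovo`, `mean_inherited`,
#'   `variance`; defaults 0.6 / 0.2 / 0.1.
#' @return data.frame with columns `threshold`, `w1`, `w2`.
#' @examples
#' gaussian_threshold_performance(c(0.3, 0.5, 0.7, 0.9))
#' @export
gaussian_threshold_performance <- function(threshold,
                                           score_model = list(
                                             mean_denovo = 0.6,
                                             mean_inherited = 0.2,
                                             variance = 0.1)) {
  stopifnot(score_model$variance > 0)
  s <- sqrt(score_model$variance)
  data.frame(threshold = threshold,
             w1 = 1 - pnorm((threshold - score_model$mean_denovo) / s),
             w2 = pnorm((threshold - score_model$mean_inherited) / s))
}

#' Configuration for the null and power simulations
#'
#' Defaults are the study conditions of the simulation design: thresholds
#' 0.3/0.5/0.7/0.9, the Gaussian score model N(0.6, 0.1) vs N(0.2, 0.1),
#' de novo fractions 0.603 (risk genes) and 0.026 (non-risk), FDR cutoff
#' 0.05 and prior risk-gene proportion 0.06.
#'
#' @param thresholds score thresholds to sweep.
#' @param n_replicates number of simulation replicates.
#' @param score_model Gaussian score model (see
#'   [gaussian_threshold_performance()]).
#' @param denovo_fraction_risk,denovo_fraction_nonrisk de novo fractions.
#' @param pi_risk prior proportion of risk genes.
#' @param q_cutoff FDR selection cutoff.
#' @param alpha Bonferroni family-wise level.
#' @param priors [rd_priors()] for the Random Draw model.
#' @param rng_seed integer root seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(thresholds = c(0.3, 0.5, 0.7, 0.9),
                       n_replicates = 100L,
                       score_model = list(mean_denovo = 0.6,
                                          mean_inherited = 0.2,
                                          variance = 0.1),
                       denovo_fraction_risk = 0.603,
                       denovo_fraction_nonrisk = 0.026,
                       pi_risk = 0.06, q_cutoff = 0.05, alpha = 0.05,
                       priors = rd_priors(), rng_seed = 1L) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1),
            score_model$variance > 0, n_replicates >= 1,
            denovo_fraction_risk > denovo_fraction_nonrisk)
  structure(list(thresholds = thresholds,
                 n_replicates = as.integer(n_replicates),
                 score_model = score_model,
                 denovo_fraction_risk = denovo_fraction_risk,
                 denovo_fraction_nonrisk = denovo_fraction_nonrisk,
                 pi_risk = pi_risk, q_cutoff = q_cutoff, alpha = alpha,
                 priors = priors, rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# One pass of the gene test at one threshold: counts -> RD BF -> combine
# with family BFs (floored) -> q-values -> selections.
rd_test_once <- function(counts, family, perf, config) {
  params <- rd_params(perf$w1, perf$w2, perf$threshold)
  counts <- rd_bayes_factor_table(counts, params, config$priors)
  res <- merge(family[, c("gene_id", "bf_family")], counts,
               by = "gene_id", all.x = TRUE)
  # genes with no case variants contribute a neutral RD factor
  res$bf_rd[is.na(res$bf_rd)] <- 1
  res$bf_final <- combine_bfs(res$bf_family, res$bf_rd)
  res <- bayesian_fdr(res, "bf_final", config$pi_risk)
  select_genes(res, "bf_final", config$q_cutoff, config$alpha)
}

#' Power simulation for the combined family + Random Draw test
#'
#' Per replicate and threshold: hidden de novo labels are planted per gene
#' as `round(fraction x n_case)` (fraction 0.603 for risk genes, 0.026
#' otherwise), Gaussian de novo scores are drawn per label, thresholding
#' yields per-gene `(xd, xh)` counts, Random Draw Bayes factors are
#' computed with the analytic (w1, w2) of the threshold, combined with the
#' family Bayes factors under the flooring rule and converted to q-values;
#' genes with q below the cutoff are discoveries.  The family-only baseline
#' (Random Draw factor fixed at 1) is computed on the same gene table.
#'
#' @param gene_table data.frame with `gene_id`, `risk` (0/1), `n_case`
#'   (case variant count per gene).
#' @param family data.frame with `gene_id` and `bf_family` (e.g. from
#'   [denovo_bayes_factor()] on trio counts).
#' @param config a [sim_config()].
#' @return Object of class `simulation_report`: per-threshold `w1`, `w2`,
#'   mean discovery count and mean true-positive count, with the
#'   family-only baseline in attribute `baseline`.
#' @export
run_power_simulation <- function(gene_table, family, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"),
            all(c("gene_id", "risk", "n_case") %in% names(gene_table)),
            all(c("gene_id", "bf_family") %in% names(family)))
  if (nrow(gene_table) == 0L) stop("gene_table must be non-empty")
  frac <- ifelse(gene_table$risk == 1L, config$denovo_fraction_risk,
                 config$denovo_fraction_nonrisk)
  perf <- gaussian_threshold_performance(config$thresholds,
                                         config$score_model)
  risk_genes <- gene_table$gene_id[gene_table$risk == 1L]

  # family-only baseline: same selection machinery, no case contribution
  base <- bayesian_fdr(family, "bf_family", config$pi_risk)
  base <- select_genes(base, "bf_family", config$q_cutoff, config$alpha)
  baseline <- c(discoveries = sum(base$selected_fdr),
                true_positives = sum(base$selected_fdr &
                                       base$gene_id %in% risk_genes))

  acc <- array(0, dim = c(length(config$thresholds), 2),
               dimnames = list(NULL, c("discoveries", "true_positives")))
  for (r in seq_len(config$n_replicates)) {
    seed_r <- derive_seed(config$rng_seed, paste0("power_rep_", r))
    labels <- hidden_labels(gene_table$n_case, frac,
                            derive_seed(seed_r, "labels"))
    scores <- draw_scores(labels, config$score_model,
                          derive_seed(seed_r, "scores"))
    gene_idx <- rep(seq_len(nrow(gene_table)), gene_table$n_case)
    scored <- data.frame(gene_id = gene_table$gene_id[gene_idx],
                         score = scores, stringsAsFactors = FALSE)
    for (k in seq_along(config$thresholds)) {
      counts <- aggregate_counts(scored, config$thresholds[k])
      res <- rd_test_once(counts, family, perf[k, ], config)
      acc[k, "discoveries"] <- acc[k, "discoveries"] + sum(res$selected_fdr)
      acc[k, "true_positives"] <- acc[k, "true_positives"] +
        sum(res$selected_fdr & res$gene_id %in% risk_genes)
    }
  }
  out <- data.frame(threshold = config$thresholds,
                    w1 = perf$w1, w2 = perf$w2,
                    mean_discoveries = acc[, "discoveries"] /
                      config$n_replicates,
                    mean_true_positives = acc[, "true_positives"] /
                      config$n_replicates)
  structure(out, class = c("simulation_report", "data.frame"),
            mode = "power", baseline = baseline)
}

#' Null simulation: per-family error rate of the combined test
#'
#' Generates null case replicates — every case variant is inherited, with
#' scores drawn from the inherited score distribution — and reports the
#' per-family error rate: the mean number of selected genes outside the
#' designated true set, under both the Bonferroni and the q-value rule, per
#' threshold.  The true set is the gene table's `risk` flags; in a fully
#' synthetic null (no flags, or all zero) every selection counts as false.
#' Mirroring the observed-data design, the family Bayes factors are held
#' fixed across replicates and may carry signal; only the case data are
#' null.
#'
#' @param gene_table data.frame with `gene_id`, `mu`, `n_case` and
#'   optionally `risk` (0/1 true-set flags).
#' @param family data.frame with `gene_id`, `bf_family`.
#' @param config a [sim_config()].
#' @return Object of class `simulation_report`: per-threshold `w1`, `w2`,
#'   `pfer_bonferroni`, `pfer_qvalue`.
#' @export
run_null_simulation <- function(gene_table, family, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"),
            all(c("gene_id", "n_case") %in% names(gene_table)),
            all(c("gene_id", "bf_family") %in% names(family)))
  if (nrow(gene_table) == 0L) stop("gene_table must be non-empty")
  perf <- gaussian_threshold_performance(config$thresholds,
                                         config$score_model)
  acc <- array(0, dim = c(length(config$thresholds), 2),
               dimnames = list(NULL, c("bonf", "qval")))
  true_set <- if ("risk" %in% names(gene_table))
    gene_table$gene_id[gene_table$risk == 1L] else character(0)
  gene_idx <- rep(seq_len(nrow(gene_table)), gene_table$n_case)
  for (r in seq_len(config$n_replicates)) {
    seed_r <- derive_seed(config$rng_seed, paste0("null_rep_", r))
    labels <- integer(length(gene_idx))
    scores <- draw_scores(labels, config$score_model,
                          derive_seed(seed_r, "scores"))
    scored <- data.frame(gene_id = gene_table$gene_id[gene_idx],
                         score = scores, stringsAsFactors = FALSE)
    for (k in seq_along(config$thresholds)) {
      counts <- aggregate_counts(scored, config$thresholds[k])
      res <- rd_test_once(counts, family, perf[k, ], config)
      false_sel <- !res$gene_id %in% true_set
      acc[k, "bonf"] <- acc[k, "bonf"] +
        sum(res$selected_bonferroni & false_sel)
      acc[k, "qval"] <- acc[k, "qval"] + sum(res$selected_fdr & false_sel)
    }
  }
  out <- data.frame(threshold = config$thresholds,
                    w1 = perf$w1, w2 = perf$w2,
                    pfer_bonferroni = acc[, "bonf"] / config$n_replicates,
                    pfer_qvalue = acc[, "qval"] / config$n_replicates)
  structure(out, class = c("simulation_report", "data.frame"),
            mode = "null")
}

#' @export
print.simulation_report <- function(x, ...) {
  mode <- attr(x, "mode")
  cat("Simulation report (", if (is.null(mode)) "?" else mode, " mode, ",
      nrow(x), " thresholds)\n", sep = "")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4, ...)
  b <- attr(x, "baseline")
  if (!is.null(b))
    cat("family-only baseline: ", b["discoveries"], " discoveries (",
        b["true_positives"], " true positives)\n", sep = "")
  invisible(x)
}
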