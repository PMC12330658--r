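# End-to-end gene identification: family Bayes factors + Random Draw Bayes
# factors from scored case-only variants, combined under the flooring rule,
# ranked by Bayesian FDR.

#' Combined family + Random Draw gene association test
#'
#' Runs the gene-identification stage of the framework: aggregates scored
#' case-only variants into per-gene likely-de-novo / likely-inherited
#' counts at the chosen threshold, computes Random Draw Bayes factors with
#' the supplied classifier accuracy `(w1, w2)`, combines them with the
#' family-based de novo Bayes factors (each floored at 1), converts the
#' products to Bayesian FDR q-values with prior risk proportion `pi_risk`,
#' and flags selections under the FDR and Bonferroni rules.
#'
#' @param family data.frame with `gene_id` and either `bf_family`
#'   (precomputed family Bayes factors) or `dn_count` plus `mu` (de novo
#'   counts and mutation rates, from which Bayes factors are computed via
#'   [denovo_bayes_factor()] with `n_trios`, `gamma_mean`, `beta`).
#' @param case_scored data.frame of case-only variants with `gene_id` and
#'   `score` columns (e.g. scored by [predict.classdn()]).  Genes in
#'   `family` without case variants receive a neutral Random Draw factor
#'   of 1.
#' @param params an [rd_params()] object: classifier sensitivity and
#'   specificity at the threshold.
#' @param threshold score threshold c used to split likely de novo from
#'   likely inherited.
#' @param priors an [rd_priors()] object.
#' @param pi_risk prior proportion of risk genes (default 0.06).
#' @param q_cutoff FDR selection cutoff (default 0.05).
#' @param alpha Bonferroni family-wise level (default 0.05).
#' @param n_trios,gamma_mean,beta family Bayes factor hyperparameters, used
#'   only when `family` carries counts rather than `bf_family`.
#' @return Object of class `tada_rd`: a list with `results` (per-gene
#'   `gene_id`, `bf_family`, `bf_rd`, `bf_final`, `posterior_p1`,
#'   `qvalue`, `pvalue`, `selected_fdr`, `selected_bonferroni`), the call
#'   parameters, and a stage log.
#' @examples
#' fam <- data.frame(gene_id = c("A", "B"), bf_family = c(30, 0.8))
#' case <- data.frame(gene_id = c("A", "A", "B"), score = c(0.9, 0.1, 0.2))
#' fit <- tada_rd(fam, case, rd_params(0.376, 0.943), threshold = 0.7)
#' summary(fit)
#' @export
tada_rd <- function(family, case_scored, params, threshold = 0.7,
                    priors = rd_priors(), pi_risk = 0.06, q_cutoff = 0.05,
                    alpha = 0.05, n_trios = NULL, gamma_mean = 20,
                    beta = 1) {
  stopifnot(inherits(params, "rd_params"), "gene_id" %in% names(family))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  if (!"bf_family" %in% names(family)) {
    if (!all(c("dn_count", "mu") %in% names(family)) || is.null(n_trios))
      stop("family table must carry bf_family, or dn_count + mu with n_trios")
    family$bf_family <- denovo_bayes_factor(family$dn_count, n_trios,
                                            family$mu, gamma_mean, beta)
    say("family BFs computed from de novo counts (", n_trios, " trios)")
  }
  counts <- aggregate_counts(case_scored, threshold)
  frac_dn <- sum(counts$xd) / max(1, sum(counts$xd + counts$xh))
  say(sum(counts$xd + counts$xh), " case variants in ", nrow(counts),
      " genes; ", sprintf("%.1f%%", 100 * frac_dn),
      " classified likely de novo at c = ", threshold)
  say("classifier accuracy: w1 = ", signif(params$w1, 4), ", w2 = ",
      signif(params$w2, 4))
  res <- rd_test_once(counts, family,
                      list(w1 = params$w1, w2 = params$w2,
                           threshold = threshold),
                      list(priors = priors, pi_risk = pi_risk,
                           q_cutoff = q_cutoff, alpha = alpha))
  say(sum(res$selected_fdr), " gene(s) selected at q < ", q_cutoff, "; ",
      sum(res$selected_bonferroni), " under Bonferroni")
  res <- res[order(-res$bf_final, res$gene_id), ]
  rownames(res) <- NULL
  structure(list(results = res,
                 params = params, threshold = threshold, priors = priors,
                 pi_risk = pi_risk, q_cutoff = q_cutoff, alpha = alpha,
                 log = log),
            class = "tada_rd")
}

#' @export
print.tada_rd <- function(x, ...) {
  cat("TADA-RD gene association results\n")
  cat("  threshold c = ", x$threshold, ", w1 = ", signif(x$params$w1, 4),
      ", w2 = ", signif(x$params$w2, 4), ", pi = ", x$pi_risk, "\n",
      sep = "")
  cat("  ", nrow(x$results), " genes; ", sum(x$results$selected_fdr),
      " selected at q < ", x$q_cutoff, "\n", sep = "")
  cat("Top genes:\n")
  print.data.frame(head(x$results, 8), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.tada_rd <- function(object, ...) {
  r <- object$results
  out <- list(n_genes = nrow(r),
              n_selected_fdr = sum(r$selected_fdr),
              n_selected_bonferroni = sum(r$selected_bonferroni),
              top = head(r[, c("gene_id", "bf_family", "bf_rd", "bf_final",
                               "qvalue")], 10),
              log = object$log)
  class(out) <- "summary.tada_rd"
  out
}

#' @export
print.summary.tada_rd <- function(x, ...) {
  cat("TADA-RD summary: ", x$n_genes, " genes, ", x$n_selected_fdr,
      " FDR selections, ", x$n_selected_bonferroni,
      " Bonferroni selections\n", sep = "")
  print.data.frame(x$top, row.names = FALSE, digits = 4)
  cat("Run log:\n")
  for (l in x$log) cat("  - ", l, "\n", sep = "")
  invisible(x)
}

#' Plot the evidence decomposition of a TADA-RD fit
#'
#' Log Bayes factor of each selected gene, split into the family and
#' Random Draw contributions (after flooring at 1).
#'
#' @param x a `tada_rd` object.
#' @param n_genes number of top genes to show.
#' @param ... passed to `barplot`.
#' @export
plot.tada_rd <- function(x, n_genes = 20, ...) {
  r <- head(x$results, n_genes)
  m <- rbind(family = log10(pmax(r$bf_family, 1)),
             random_draw = log10(pmax(r$bf_rd, 1)))
  graphics::barplot(m, names.arg = r$gene_id, las = 2,
                    col = c("grey35", "goldenrod"),
                    ylab = "log10 Bayes factor", ...)
  graphics::legend("topright", rownames(m), fill = c("grey35", "goldenrod"),
                   bty = "n")
  invisible(x)
}

#' Run the full two-pipeline workflow on variant tables
#'
#' Pipeline 1 trains ClassDn on labeled family-style training data and
#' estimates its sensitivity/specificity on labeled test data at the chosen
#' threshold.  Pipeline 2 scores the unlabeled case-only variants, and runs
#' the combined family + Random Draw gene test via [tada_rd()].
#'
#' @param train,test labeled variant tables (six covariates + `label`).
#' @param case unlabeled case-only variant table (six covariates).
#' @param family per-gene family table (see [tada_rd()]).
#' @param algorithm,n_estimators,max_depth,rng_seed passed to [classdn()].
#' @param threshold score threshold c.
#' @param ... further arguments passed to [tada_rd()].
#' @return A `tada_rd` object whose log also records the training stages;
#'   the fitted classifier is attached as `$classifier` and the estimated
#'   accuracy as `$params`.
#' @export
run_tadard_pipeline <- function(train, test, case, family,
                                algorithm = "rusboost",
                                n_estimators = 100L, max_depth = 3L,
                                threshold = 0.7, rng_seed = 1L, ...) {
  covs <- paste(COVARIATE_NAMES, collapse = " + ")
  fml <- stats::as.formula(paste("label ~", covs))
  fit <- classdn(fml, train, algorithm = algorithm,
                 n_estimators = n_estimators, max_depth = max_depth,
                 rng_seed = rng_seed)
  test_scores <- predict(fit, test)
  perf <- estimate_performance(test$label,
                               classify_at_threshold(test_scores, threshold))
  params <- rd_params(perf["w1"], perf["w2"], threshold)
  case$score <- predict(fit, case)
  out <- tada_rd(family, case, params, threshold = threshold, ...)
  out$classifier <- fit
  out$log <- c(paste0("trained ", algorithm, " on ", fit$n_train,
                      " labeled variants (", fit$n_dropped, " dropped)"),
               paste0("test performance at c = ", threshold, ": w1 = ",
                      signif(perf["w1"], 4), ", w2 = ",
                      signif(perf["w2"], 4)),
               out$log)
  out
}
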