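# Family-based de novo Bayes factors (Poisson-Gamma), combination with the
# Random Draw Bayes factor under the flooring rule, Bayesian FDR q-values
# and gene selection.

#' Family-based de novo Bayes factor
#'
#' Evidence of association from observed de novo counts in trio data.  Under
#' the null the count is `x ~ Poisson(2 N mu)` (`N` trios, per-gene de novo
#' mutation rate `mu`); under the alternative the rate is inflated by a
#' relative risk `gamma ~ Gamma(gamma_mean * beta, rate = beta)`, so the
#' marginal of `x` is negative binomial and the Bayes factor has closed
#' form:
#' `BF(x) = NB(x; a, b / (b + lambda)) / Poisson(x; lambda)` with
#' `lambda = 2 N mu`, `a = gamma_mean * beta`, `b = beta`.
#'
#' @param x observed de novo count(s), non-negative integer (vectorised).
#' @param n_trios number of trios.
#' @param mu per-gene de novo mutation rate (expected events per chromosome
#'   per generation); recycled against `x`.
#' @param gamma_mean mean relative risk under the alternative (> 1 for a
#'   risk-conferring model).
#' @param beta rate hyperparameter of the Gamma relative-risk prior.
#' @return Positive Bayes factor(s).
#' @examples
#' denovo_bayes_factor(2, n_trios = 5000, mu = 5e-6)
#' @export
denovo_bayes_factor <- function(x, n_trios, mu, gamma_mean = 20, beta = 1) {
  if (any(x < 0) || any(x != round(x)))
    stop("x must be a non-negative integer count")
  stopifnot(n_trios >= 1, all(mu > 0), gamma_mean > 0, beta > 0)
  lambda <- 2 * n_trios * mu
  a <- gamma_mean * beta
  log_bf <- dnbinom(x, size = a, prob = beta / (beta + lambda), log = TRUE) -
    dpois(x, lambda, log = TRUE)
  exp(log_bf)
}

#' Combine family and Random Draw Bayes factors
#'
#' Each component Bayes factor is floored at 1 before multiplication so that
#' weak evidence from one data source never down-weights strong evidence
#' from the other: `bf_final = max(bf_family, 1) * max(bf_rd, 1)`.
#'
#' @param bf_family,bf_rd positive Bayes factors (vectorised).
#' @return Combined Bayes factor(s), always >= 1.
#' @examples
#' combine_bfs(0.5, 2)  # 2
#' combine_bfs(3, 4)    # 12
#' @export
combine_bfs <- function(bf_family, bf_rd) {
  if (any(bf_family <= 0) || any(bf_rd <= 0))
    stop("Bayes factors must be positive")
  pmax(bf_family, 1) * pmax(bf_rd, 1)
}

#' Bayesian FDR q-values from Bayes factors
#'
#' Converts per-gene Bayes factors into posterior risk probabilities,
#' `P(D = 1 | data) = pi * BF / (pi * BF + 1 - pi)` with `pi` the prior
#' proportion of risk genes, ranks genes by decreasing Bayes factor (ties
#' broken by gene id for determinism) and reports the q-value of each gene
#' as the cumulative mean of the posterior null probabilities over the
#' top-ranked genes, made monotone non-decreasing down the ranking.
#'
#' @param genes data.frame with `gene_id` and a Bayes factor column.
#' @param bf_col name of the Bayes factor column (default `"bf_final"`).
#' @param pi_risk prior proportion of risk genes in (0, 1); default 0.06.
#' @return `genes` with added `posterior_p1` and `qvalue` columns, in the
#'   original row order.
#' @examples
#' g <- data.frame(gene_id = c("A", "B", "C"), bf_final = c(100, 10, 1))
#' bayesian_fdr(g)
#' @export
bayesian_fdr <- function(genes, bf_col = "bf_final", pi_risk = 0.06) {
  stopifnot("gene_id" %in% names(genes), bf_col %in% names(genes),
            pi_risk > 0, pi_risk < 1)
  if (nrow(genes) == 0L) {
    genes$posterior_p1 <- numeric(0)
    genes$qvalue <- numeric(0)
    return(genes)
  }
  bf <- genes[[bf_col]]
  if (any(bf <= 0)) stop("Bayes factors must be positive")
  post <- pi_risk * bf / (pi_risk * bf + 1 - pi_risk)
  ord <- order(-bf, genes$gene_id)
  q_sorted <- cumsum(1 - post[ord]) / seq_along(ord)
  q_sorted <- cummax(q_sorted)  # enforce monotonicity down the ranking
  q <- numeric(length(bf))
  q[ord] <- q_sorted
  genes$posterior_p1 <- post
  genes$qvalue <- q
  genes
}

#' Select risk genes by FDR and Bonferroni rules
#'
#' Two selection rules: `selected_fdr` flags genes with q-value below
#' `q_cutoff`; `selected_bonferroni` converts q-values back to p-values by
#' inverting the Benjamini-Hochberg relation (`p_i = q_i * rank_i / m`,
#' evaluated on the monotone q sequence — a convention, since the q-to-p
#' conversion is not unique) and flags `p_i < alpha / m`.
#'
#' @param genes data.frame with `gene_id` and `qvalue` (from
#'   [bayesian_fdr()]), plus the Bayes factor column used for ranking.
#' @param bf_col Bayes factor column name used for ranking.
#' @param q_cutoff FDR cutoff (default 0.05).
#' @param alpha family-wise error level for the Bonferroni rule (default
#'   0.05).
#' @return `genes` with added `pvalue`, `selected_fdr`,
#'   `selected_bonferroni` columns.
#' @export
select_genes <- function(genes, bf_col = "bf_final", q_cutoff = 0.05,
                         alpha = 0.05) {
  stopifnot(all(c("gene_id", "qvalue") %in% names(genes)))
  m <- nrow(genes)
  if (m == 0L) {
    genes$pvalue <- numeric(0)
    genes$selected_fdr <- logical(0)
    genes$selected_bonferroni <- logical(0)
    return(genes)
  }
  ord <- order(-genes[[bf_col]], genes$gene_id)
  rank_i <- integer(m)
  rank_i[ord] <- seq_len(m)
  genes$pvalue <- pmin(genes$qvalue * rank_i / m, 1)
  genes$selected_fdr <- genes$qvalue < q_cutoff
  genes$selected_bonferroni <- genes$pvalue < alpha / m
  genes
}
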