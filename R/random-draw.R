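# The Random Draw model.  Each case-only variant in a gene is treated as an
# independent Bernoulli draw of de novo status, with draw probability p1
# (risk gene) or p0 (non-risk gene), p1 > p0.  Because only the classifier's
# prediction X of de novo status I is observed, the Bernoulli parameter is
# adjusted through the classifier's sensitivity w1 = P(X=1|I=1) and
# specificity w2 = P(X=0|I=0):
#
#   P(X = 1 | D) = w1 * p + (1 - w2) * (1 - p),   p = p1 or p0.
#
# Evidence for risk status is the Bayes factor of the binomial likelihoods
# of the observed (xd, xh) counts under the two scenarios, marginalised over
# prior distributions on p1 and p0.

BF_FLOOR <- 1e-12
BF_CAP <- 1e12

#' Classifier accuracy parameters for the Random Draw model
#'
#' @param w1 sensitivity `P(X = 1 | I = 1)` in \[0, 1\].
#' @param w2 specificity `P(X = 0 | I = 0)` in \[0, 1\].
#' @param threshold the score threshold c at which (w1, w2) were measured
#'   (recorded for provenance; not used in computation).
#' @return A list of class `rd_params`.  A warning is raised for a
#'   degenerate classifier (`w1 == 1 - w2`), whose predictions are
#'   independent of the truth and carry no information.
#' @examples
#' rd_params(0.376, 0.943, threshold = 0.7)
#' @export
rd_params <- function(w1, w2, threshold = NA_real_) {
  w1 <- unname(w1); w2 <- unname(w2)
  stopifnot(w1 >= 0, w1 <= 1, w2 >= 0, w2 <= 1)
  if (isTRUE(all.equal(w1, 1 - w2)))
    warning("degenerate classifier: w1 = 1 - w2; ",
            "predictions are independent of true inheritance class ",
            "and all Bayes factors will equal 1")
  structure(list(w1 = w1, w2 = w2, threshold = threshold),
            class = "rd_params")
}

#' Prior distributions on the de novo draw probabilities
#'
#' Each prior is either a point mass or a Beta distribution on \[0, 1\].
#' Defaults anchor the prior means at the de novo fractions observed in
#' family-based data — 0.603 among variants in risk genes and 0.026 in
#' non-risk genes — with a total Beta concentration of 10 encoding
#' uncertainty about the fractions.
#'
#' @param p1 either a single number (point mass) or `c(shape1, shape2)` of a
#'   Beta prior for the risk-gene de novo probability.
#' @param p0 same, for non-risk genes.
#' @return A list of class `rd_priors`.  The mean of `p1` must exceed the
#'   mean of `p0`.
#' @examples
#' rd_priors()                        # default Beta priors
#' rd_priors(p1 = 0.603, p0 = 0.026)  # point masses
#' @export
rd_priors <- function(p1 = c(0.603 * 10, (1 - 0.603) * 10),
                      p0 = c(0.026 * 10, (1 - 0.026) * 10)) {
  sp1 <- as_prior_spec(p1, "p1")
  sp0 <- as_prior_spec(p0, "p0")
  if (prior_mean(sp1) < prior_mean(sp0))
    stop("mean of the p1 prior must not be below the mean of the p0 prior")
  if (prior_mean(sp1) == prior_mean(sp0))
    warning("p1 and p0 priors have equal means: the two risk scenarios ",
            "are indistinguishable and Bayes factors will be uninformative")
  structure(list(p1 = sp1, p0 = sp0), class = "rd_priors")
}

as_prior_spec <- function(x, what) {
  if (length(x) == 1L) {
    if (x < 0 || x > 1) stop(what, " point mass must lie in [0, 1]")
    list(type = "point", value = as.numeric(x))
  } else if (length(x) == 2L) {
    if (any(x <= 0)) stop(what, " Beta shapes must be positive")
    list(type = "beta", shape1 = x[[1]], shape2 = x[[2]])
  } else stop(what, " must be a point mass (length 1) or Beta shapes (length 2)")
}

prior_mean <- function(spec) {
  if (spec$type == "point") spec$value
  else spec$shape1 / (spec$shape1 + spec$shape2)
}

#' Misclassification-adjusted de novo call rate
#'
#' Probability that a variant is *called* de novo given the gene's true de
#' novo probability `p` and the classifier accuracy:
#' `w1 * p + (1 - w2) * (1 - p)`.
#'
#' @param p true de novo probability in \[0, 1\] (vectorised).
#' @param params an [rd_params()] object.
#' @return Adjusted rate(s) in `[min(w1, 1 - w2), max(w1, 1 - w2)]`.
#' @examples
#' misclassification_adjusted_rate(0.603, rd_params(0.376, 0.943))
#' @export
misclassification_adjusted_rate <- function(p, params) {
  stopifnot(inherits(params, "rd_params"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  params$w1 * p + (1 - params$w2) * (1 - p)
}

#' Binomial likelihood of per-gene classified counts
#'
#' `P(xd, xh | q) = choose(xd + xh, xd) q^xd (1 - q)^xh`, the probability of
#' observing `xd` likely-de-novo and `xh` likely-inherited variants when
#' each variant is called de novo independently with probability `q`.
#'
#' @param xd,xh non-negative integer counts (vectorised).
#' @param q de novo call probability in \[0, 1\].
#' @param log return the log likelihood.
#' @return Likelihood (or log likelihood).
#' @examples
#' rd_likelihood(1, 1, 0.5)  # 0.5
#' @export
rd_likelihood <- function(xd, xh, q, log = FALSE) {
  stopifnot(all(xd >= 0), all(xh >= 0), all(q >= 0), all(q <= 1))
  dbinom(xd, xd + xh, q, log = log)
}

# log integrated likelihood of (xd, xh) under one scenario's prior.
# Beta priors are integrated by 128-node Gauss-Legendre quadrature in
# prior-CDF space (substitution p = qbeta(t, a, b)), which stays accurate
# even when a shape parameter < 1 makes the Beta density unbounded at an
# endpoint.
rd_log_marginal <- function(xd, xh, params, spec, n_nodes = 128L) {
  if (spec$type == "point") {
    q <- misclassification_adjusted_rate(spec$value, params)
    return(rd_likelihood(xd, xh, q, log = TRUE))
  }
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  p <- qbeta(gl$x, spec$shape1, spec$shape2)
  q <- misclassification_adjusted_rate(p, params)
  # matrix of log-likelihoods: genes x nodes
  ll <- outer(seq_along(xd), seq_along(q),
              function(i, j) dbinom(xd[i], xd[i] + xh[i], q[j], log = TRUE))
  lw <- log(gl$w)
  apply(ll, 1, function(row) logsumexp(row + lw))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Random Draw Bayes factor for one gene
#'
#' Evidence for risk status (`D = 1` vs `D = 0`) given the gene's counts of
#' likely-de-novo (`xd`) and likely-inherited (`xh`) variants:
#' the ratio of binomial likelihoods at the misclassification-adjusted call
#' rates, marginalised over the priors on p1 and p0.  Under point priors the
#' integrals reduce to single binomial evaluations.
#'
#' @param xd,xh non-negative integer counts for the gene.
#' @param params an [rd_params()] object (classifier sensitivity and
#'   specificity).
#' @param priors an [rd_priors()] object.
#' @param n_nodes Gauss-Legendre node count for Beta priors.
#' @return A positive Bayes factor, clamped to `[1e-12, 1e12]` (a warning is
#'   raised when clamping occurs).
#' @examples
#' # perfect classifier, point priors: ratio of Bernoulli pmfs
#' rd_bayes_factor(1, 0, rd_params(1, 1), rd_priors(p1 = 0.603, p0 = 0.026))
#' @export
rd_bayes_factor <- function(xd, xh, params, priors, n_nodes = 128L) {
  stopifnot(length(xd) == 1L, length(xh) == 1L)
  rd_bayes_factor_vec(xd, xh, params, priors, n_nodes)
}

rd_bayes_factor_vec <- function(xd, xh, params, priors, n_nodes = 128L) {
  stopifnot(inherits(params, "rd_params"), inherits(priors, "rd_priors"))
  if (any(xd < 0) || any(xh < 0) || any(xd != round(xd)) || any(xh != round(xh)))
    stop("xd and xh must be non-negative integers")
  log_bf <- rd_log_marginal(xd, xh, params, priors$p1, n_nodes) -
    rd_log_marginal(xd, xh, params, priors$p0, n_nodes)
  bf <- exp(log_bf)
  if (any(bf < BF_FLOOR | bf > BF_CAP, na.rm = TRUE))
    warning("Random Draw Bayes factor clamped to [", BF_FLOOR, ", ", BF_CAP,
            "] for ", sum(bf < BF_FLOOR | bf > BF_CAP), " gene(s)")
  pmin(pmax(bf, BF_FLOOR), BF_CAP)
}

#' Random Draw Bayes factors for a gene-count table
#'
#' Vectorised [rd_bayes_factor()] over a table of per-gene counts.
#'
#' @param counts data.frame with columns `gene_id`, `xd`, `xh`; gene ids
#'   must be unique.
#' @inheritParams rd_bayes_factor
#' @return `counts` with an added `bf_rd` column.
#' @export
rd_bayes_factor_table <- function(counts, params, priors, n_nodes = 128L) {
  stopifnot(all(c("gene_id", "xd", "xh") %in% names(counts)))
  if (anyDuplicated(counts$gene_id))
    stop("duplicate gene_id in counts table")
  counts$bf_rd <- if (nrow(counts) == 0L) numeric(0)
    else rd_bayes_factor_vec(counts$xd, counts$xh, params, priors, n_nodes)
  counts
}
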