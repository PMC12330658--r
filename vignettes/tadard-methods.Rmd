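---
title: "Inferring de novo variants without parental genotypes: the ClassDn + Random Draw framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring de novo variants without parental genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadard)
```

## The problem

De novo protein-truncating variants (PTVs) carry most of the rare-variant
association signal for developmental disorders such as autism spectrum
disorder. Calling a variant de novo normally requires sequencing the
affected offspring *and* both parents; in case-only cohorts the inheritance
class is hidden, and the case–control contrast recovers only a fraction of
the information. This package implements a two-stage framework that (i)
infers the de novo status of case-only variants with an imbalanced-data
classifier and (ii) converts those inferences into a gene-level Bayesian
association score that explicitly corrects for classification error.

## Stage 1: ClassDn, an imbalanced-data inheritance classifier

A typical proband carries one or two de novo exonic variants but roughly
thirty times as many rare inherited ones, so the two classes are heavily
imbalanced and an unweighted classifier would ignore the minority class.
`classdn()` therefore implements two resampling ensembles over shallow
decision trees (rpart):

* **rusboost** — AdaBoost-style boosting in which, before each round, the
  majority class is randomly undersampled (weighted by the current boosting
  weights) down to the minority size, so every weak learner sees a 1:1
  class ratio;
* **underbagging** — bagging in which each bag pairs a bootstrap of the
  minority class with an equal-sized undersample of the majority class.

Six covariates drive the classification: allele frequency (AF; de novo
variants are rarer), the gene constraint score LOEUF together with its
components obs_lof and exp_lof (constrained genes, i.e. low LOEUF, are
enriched for de novo PTVs), the regional constraint percentile CCR (0–100;
higher for de novo), and FDR_TADA_DD, a published per-gene FDR for
developmental-delay association (lower in de novo carriers). AF is
log10-transformed with a 1e-9 pseudo-count before fitting because it spans
orders of magnitude.

Hyperparameter defaults — 100 estimators, depth-3 trees, learning rate 0.5
for boosting — are conventional weak-learner settings; they are exposed as
arguments and the fits are deterministic under `rng_seed`. The ensemble
score is the (boosting-weighted) mean of the members' de novo class
probabilities, so it always lies in [0, 1].

A variant is called *likely de novo* when its score strictly exceeds a
threshold c ("exceeds" is strict: a score equal to c is likely inherited).
Performance at a threshold is summarised by the sensitivity
`w1 = P(X = 1 | I = 1)` and specificity `w2 = P(X = 0 | I = 0)`, estimated
on labeled held-out data with `estimate_performance()`; raising c trades
sensitivity for specificity, and `performance_curve()` is monotone in both
by construction.

## Stage 2: the Random Draw gene test

For a gene with `xd` likely-de-novo and `xh` likely-inherited case
variants, the Random Draw model treats each variant as an independent
Bernoulli draw of de novo status with probability `p1` if the gene is a
risk gene (`D = 1`) and `p0 < p1` otherwise. Because only the classifier's
call X is observed, the draw probability is adjusted for classification
error:

$$P(X=1 \mid D) = w_1\,p + (1-w_2)\,(1-p), \qquad p \in \{p_1, p_0\},$$

and the likelihood of `(xd, xh)` under either scenario is binomial in the
adjusted rate. The evidence for risk status is the Bayes factor

$$\mathrm{BF}_{RD} = \frac{\int \mathrm{Bin}(x_d;\, x_d{+}x_h,\, q(p_1))\, dP_1(p_1)}
                          {\int \mathrm{Bin}(x_d;\, x_d{+}x_h,\, q(p_0))\, dP_0(p_0)}.$$

Two structural properties follow immediately and are tested: a *degenerate*
classifier (`w1 = 1 - w2`, predictions independent of truth) gives BF = 1
for any counts, and a *perfect* classifier (`w1 = w2 = 1`) recovers the
unadjusted binomial contrast. With prior mean of `p1` above that of `p0`,
the BF is non-decreasing in `xd` and non-increasing in `xh` — each
additional inherited variant is evidence against risk status, the model's
defining difference from a case–control contrast.

**Priors.** The priors on `p1` and `p0` default to Beta distributions with
means 0.603 and 0.026 — the de novo fractions observed in family data for
risk and non-risk genes — and total concentration 10 each, encoding honest
uncertainty about the fractions; point masses and other shapes are
accepted (`rd_priors()`). The dependence of the fractions on the mutation
rate is not modelled: the defaults are constant fractions (the power-study
design itself uses constant fractions), and per-gene priors can be supplied
by calling `rd_bayes_factor()` gene by gene.

**Numerics.** Beta-prior integrals use 128-node Gauss–Legendre quadrature
evaluated in prior-CDF space (substituting `p = qbeta(t, a, b)`), which
remains accurate when a shape parameter below 1 makes the Beta density
unbounded at an endpoint — the default `p0` prior, Beta(0.26, 9.74), is
exactly such a case. Likelihoods are combined in log space, and Bayes
factors are clamped to [1e-12, 1e12] with a warning. Quadrature agrees with
a 1e6-draw Monte-Carlo oracle to well under 1%.

## Integration with family-based evidence

Family (trio) data provide a per-gene de novo count `x` whose Bayes factor
follows the classical Poisson–Gamma contrast: `x ~ Poisson(2 N mu)` under
the null and `x ~ Poisson(2 N mu gamma)` with
`gamma ~ Gamma(gamma_mean * beta, rate = beta)` under the alternative, so
the marginal is negative binomial and `denovo_bayes_factor()` is closed
form. The hyperparameter defaults (`gamma_mean = 20`, `beta = 1`) are
conventional for PTVs and must be chosen by the analyst for real data.

The two Bayes factors are combined with a flooring rule,
`bf_final = max(bf_family, 1) * max(bf_rd, 1)`, so weak evidence in one
data source never cancels strong evidence in the other. Final BFs are
converted to Bayesian FDR q-values: with prior risk-gene proportion
`pi = 0.06`, the posterior risk probability is
`pi BF / (pi BF + 1 - pi)`; genes are ranked by decreasing BF (ties broken
lexicographically by gene id for determinism) and the q-value of rank i is
the running mean of the posterior null probabilities over the top i genes,
made monotone down the ranking. Selection uses `q < 0.05` and, as a
stricter alternative, a Bonferroni rule on p-values obtained by inverting
the Benjamini–Hochberg relation, `p_i = q_i * rank_i / m` — the q-to-p
conversion is not unique, and this convention is order-preserving and
guarantees the Bonferroni set is nested inside the FDR set when
`alpha = q_cutoff`.

`tada_rd()` runs counts → RD BFs → flooring → q-values → selection and
returns a classed object with print/summary/plot methods;
`run_tadard_pipeline()` prepends classifier training and performance
estimation.

## The synthetic-data module

No cohort data ship with the package; `simulate_family_variants()`,
`simulate_case_variants()` and `simulate_null_variants()` generate tables
with the statistical structure the method assumes:

* **Genes.** Per-gene mutation rates are Gamma(shape 1.5) with mean 5e-6
  expected de novo PTV events per chromosome per generation — a realistic
  exome-wide scale — and a configurable fraction of genes (default 5%) are
  flagged as risk genes.
* **Counts.** Given its rate, a gene's variant count is Poisson with mean
  proportional to the rate; across genes the marginal is therefore negative
  binomial through the Gamma mixing. An extra overdispersion knob exists
  but defaults off: coupling gene size to mutational opportunity is what
  real cohorts show, and it is what makes the Random Draw and family-based
  scores rank genes consistently. In case cohorts, a risk gene's expected
  count is additionally scaled by `1/(1 - fraction)`: a gene in which
  60.3% of case variants are de novo must hold its inherited background
  divided by 0.397 — the enrichment is implied by the fraction itself.
* **Labels.** Family-style tables draw each variant's inheritance class
  Bernoulli with the gene's de novo fraction (defaults 0.603 risk / 0.026
  non-risk, the fractions observed in family data). Case tables instead
  plant exactly `round(fraction * n_case)` de novo variants per gene
  (half-away-from-zero rounding, floored at zero) — the deterministic rule
  of the power-study design — and return the truth separately.
* **Covariates** are drawn from label-conditional distributions chosen to
  respect each covariate's legal range and to separate the classes by
  roughly one standardized mean difference in the directions seen in
  family data (truncated log-normal AF, scaled Beta LOEUF and FDR,
  truncated normal CCR, Poisson obs_lof, Gamma exp_lof). No attempt is
  made to match any real cohort's joint distribution — passing classifier
  tests here shows the machinery works on separable data, not that real
  data are this separable (published real-data operating points, e.g.
  sensitivity 0.164 at c = 0.7 for boosting, are far more conservative).
* **Scores.** Simulated de novo scores are Gaussian: N(0.6, 0.1) for de
  novo and N(0.2, 0.1) for inherited variants, unclipped, so for any
  threshold the implied `(w1, w2)` follow from the normal CDF
  (`gaussian_threshold_performance()`); at c = 0.3/0.5/0.7/0.9 these are
  (0.829, 0.624), (0.624, 0.829), (0.376, 0.943), (0.171, 0.987).
* **Seeding.** Every generator takes one root seed and derives named child
  streams (`derive_seed()`), so replicates are independent but the whole
  study is reproducible bit for bit.

## The simulation studies

`run_power_simulation()` plants hidden labels by the deterministic rule,
draws Gaussian scores, thresholds them, computes RD BFs with the analytic
`(w1, w2)`, combines with family BFs and counts q < 0.05 discoveries,
against a family-only baseline (RD factor fixed at 1).
`run_null_simulation()` mirrors the error-control design: the family Bayes
factors are held fixed (they may carry signal, as the real family data do),
every case variant is inherited with scores from the inherited component,
and the per-family error rate (PFER) is the mean number of selected genes
outside the designated true set — the generator's risk flags.

Choices worth stating explicitly:

* The null design keeps family signal because false-discovery inflation by
  the Random Draw stage is only observable against genes with appreciable
  family evidence; in a fully null cohort the Bonferroni PFER is dominated
  by rare joint flukes and has no systematic threshold dependence (we
  measured a flat ~0.03–0.07 across thresholds), whereas in the
  family-signal design the Bonferroni PFER is 0 at every threshold and the
  q-value PFER decreases as the threshold rises.
* The family-based test in the consistency check uses a trio count that is
  self-consistent with the cohort: `2 N mean(mu)` equals the cohort's mean
  per-gene de novo count. With a mismatched trio count the two models rank
  genes by different noise and their agreement is artificially low.
* Problem sizes: simulation studies in the tests and the reproduction
  script use cohorts of 800 genes with ~600 case variants (the per-gene
  case density of published cohorts, below one variant per gene), family
  cohorts of 500 genes with ~10,000 labeled variants, and 50 replicates.
  These sizes give stable Monte-Carlo summaries while keeping a full run
  in the tens of seconds.

## Known limitations

* Covariate distributions are marginal and label-conditional only; real
  covariates are correlated (LOEUF with obs_lof/exp_lof by construction),
  so synthetic separability overstates real separability.
* The priors on the de novo fractions and their possible stratification by
  mutation rate are design choices, not estimates; analyses of real data
  should re-derive them from labeled family data.
* The Bonferroni p-values come from a documented q-to-p convention, not
  from a sampling distribution.
* The case–control contrast of the original TADA framework is not
  implemented; the Random Draw factor replaces it by design, and the
  family-only reduction (`bf_rd = 1`) is the supported comparison
  baseline.

## A minimal run

```{r example, eval = FALSE}
genes <- simulate_genes(800, risk_gene_fraction = 0.05, rng_seed = 1)
genes <- simulate_case_counts(genes, 600, rng_seed = 1)
family <- simulate_family_counts(genes, n_trios = 8000, rng_seed = 1)
family$bf_family <- denovo_bayes_factor(family$dn_count, 8000, family$mu)

cfg <- cohort_config(n_genes = 800, n_variants_total = 600, rng_seed = 1)
case <- simulate_case_variants(cfg, gene_table = genes)

perf <- gaussian_threshold_performance(0.7)
fit <- tada_rd(family, case$variants,
               rd_params(perf$w1, perf$w2, threshold = 0.7))
summary(fit)
```
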