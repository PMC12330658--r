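# Family de novo Bayes factor, flooring/combination, Bayesian FDR and
# selection rules.

test_that("family Bayes factor matches numerical integration over gamma", {
  cases <- expand.grid(x = c(0, 1, 3), mu = c(2e-6, 1e-5),
                       gamma_mean = c(5, 20), beta = c(1, 0.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    lam <- 2 * 6000 * cs$mu
    num <- integrate(function(g) dpois(cs$x, lam * g) *
                       dgamma(g, shape = cs$gamma_mean * cs$beta,
                              rate = cs$beta),
                     0, Inf, rel.tol = 1e-10)$value
    oracle <- num / dpois(cs$x, lam)
    expect_equal(denovo_bayes_factor(cs$x, 6000, cs$mu, cs$gamma_mean,
                                     cs$beta),
                 oracle, tolerance = 1e-3)
  }
})

test_that("family Bayes factor limits and monotonicity behave", {
  # relative-risk prior collapsing to a point mass at 1 gives BF -> 1
  expect_equal(denovo_bayes_factor(2, 5000, 5e-6, gamma_mean = 1,
                                   beta = 1e8), 1, tolerance = 1e-4)
  # zero counts favour the null
  expect_lt(denovo_bayes_factor(0, 5000, 5e-6, gamma_mean = 20), 1)
  # non-decreasing in the observed count
  bf <- denovo_bayes_factor(0:6, 5000, 5e-6, gamma_mean = 20)
  expect_true(all(diff(bf) > 0))
  expect_error(denovo_bayes_factor(-1, 5000, 5e-6), "non-negative")
  expect_error(denovo_bayes_factor(1.5, 5000, 5e-6), "non-negative")
})

test_that("combine_bfs floors each component at 1", {
  expect_equal(combine_bfs(0.5, 2), 2)
  expect_equal(combine_bfs(3, 4), 12)
  expect_equal(combine_bfs(0.2, 0.3), 1)
  # exhaustive small grid: floored product, always >= 1, monotone
  vals <- c(0.1, 0.5, 1, 2, 10)
  for (a in vals) for (b in vals) {
    expect_equal(combine_bfs(a, b), max(a, 1) * max(b, 1))
    expect_gte(combine_bfs(a, b), 1)
  }
  expect_error(combine_bfs(0, 1), "positive")
})

test_that("q-values follow the cumulative posterior-null mean", {
  pi0 <- 0.06
  # single gene at the break-even Bayes factor
  g1 <- bayesian_fdr(data.frame(gene_id = "A",
                                bf_final = (1 - pi0) / pi0), pi_risk = pi0)
  expect_equal(g1$posterior_p1, 0.5)
  expect_equal(g1$qvalue, 0.5)
  # overwhelming evidence drives q to 0
  g2 <- bayesian_fdr(data.frame(gene_id = "A", bf_final = 1e10))
  expect_lt(g2$qvalue, 1e-6)
  # three-gene hand computation at pi = 0.06
  g3 <- bayesian_fdr(data.frame(gene_id = c("A", "B", "C"),
                                bf_final = c(100, 10, 1)))
  expect_equal(g3$posterior_p1, c(0.8645533, 0.3896104, 0.06),
               tolerance = 1e-6)
  expect_equal(g3$qvalue, c(0.1354467, 0.3729181, 0.5619454),
               tolerance = 1e-6)
  # empty input passes through
  empty <- bayesian_fdr(data.frame(gene_id = character(0),
                                   bf_final = numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("q-values are monotone along the ranking with deterministic ties", {
  set.seed(3)
  g <- data.frame(gene_id = sprintf("g%02d", 1:40),
                  bf_final = sample(c(rexp(30, 0.1), rep(2, 10))))
  out <- bayesian_fdr(g)
  ord <- order(-out$bf_final, out$gene_id)
  expect_true(all(diff(out$qvalue[ord]) >= 0))
  expect_true(all(out$qvalue >= 0 & out$qvalue <= 1))
  # top-ranked gene's q equals its posterior null probability
  top <- ord[1]
  expect_equal(out$qvalue[top], 1 - out$posterior_p1[top])
})

test_that("selection rules behave and Bonferroni is nested within FDR", {
  g <- data.frame(gene_id = c("A", "B"), bf_final = c(5, 2),
                  qvalue = c(1, 1))
  s <- select_genes(g)
  expect_false(any(s$selected_fdr))
  expect_false(any(s$selected_bonferroni))
  g2 <- select_genes(data.frame(gene_id = "A", bf_final = 100,
                                qvalue = 0.01))
  expect_true(g2$selected_fdr)
  # property: at alpha = q_cutoff the Bonferroni set is inside the FDR set
  for (seed in 1:5) {
    set.seed(seed)
    tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      bf_final = rexp(200, 0.05))
    tab <- select_genes(bayesian_fdr(tab))
    expect_true(all(tab$selected_fdr[tab$selected_bonferroni]))
  }
})
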