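# Random Draw model: adjusted rates, binomial likelihood, Bayes factors
# under point and Beta priors, degeneracies and monotonicity.

test_that("misclassification-adjusted rate follows w1*p + (1-w2)*(1-p)", {
  expect_equal(misclassification_adjusted_rate(0.5, rd_params(1, 1)), 0.5)
  expect_equal(misclassification_adjusted_rate(1, rd_params(0.376, 0.943)),
               0.376)
  expect_equal(misclassification_adjusted_rate(0.603,
                                               rd_params(0.376, 0.943)),
               0.249357)
  p <- rd_params(0.3, 0.8)
  r <- misclassification_adjusted_rate(seq(0, 1, 0.1), p)
  expect_true(all(r >= 0.2 - 1e-12 & r <= 0.3 + 1e-12))
  expect_error(misclassification_adjusted_rate(1.2, p), "\\[0, 1\\]")
})

test_that("rd_likelihood is the binomial pmf in the de novo count", {
  expect_equal(rd_likelihood(0, 0, 0.37), 1)
  expect_equal(rd_likelihood(1, 1, 0.5), 0.5)
  expect_equal(sum(rd_likelihood(0:5, 5:0, 0.3)), 1)
})

test_that("point-prior Bayes factors equal hand-computed binomial ratios", {
  pp <- rd_priors(p1 = 0.603, p0 = 0.026)
  expect_equal(rd_bayes_factor(1, 0, rd_params(1, 1), pp), 0.603 / 0.026)
  # perfect-classifier reduction: unadjusted binomial contrast, any counts
  for (cnt in list(c(2, 3), c(0, 4), c(5, 0))) {
    expect_equal(rd_bayes_factor(cnt[1], cnt[2], rd_params(1, 1), pp),
                 dbinom(cnt[1], sum(cnt), 0.603) /
                   dbinom(cnt[1], sum(cnt), 0.026))
  }
  # identical scenarios carry no evidence
  eq <- suppressWarnings(rd_priors(p1 = 0.3, p0 = 0.3))
  expect_equal(rd_bayes_factor(4, 7, rd_params(0.376, 0.943), eq), 1)
})

test_that("a degenerate classifier yields Bayes factor 1 for any counts", {
  prs <- rd_priors()
  for (w1 in c(0.2, 0.5, 0.9)) {
    params <- suppressWarnings(rd_params(w1, 1 - w1))
    for (cnt in list(c(0, 0), c(3, 1), c(0, 10), c(7, 7)))
      expect_equal(rd_bayes_factor(cnt[1], cnt[2], params, prs), 1)
  }
})

test_that("Beta-prior quadrature agrees with a Monte-Carlo oracle", {
  prs <- rd_priors()
  cases <- list(c(0, 3), c(1, 0), c(2, 5), c(4, 20))
  for (cnt in cases) {
    bf <- rd_bayes_factor(cnt[1], cnt[2], rd_params(0.376, 0.943), prs)
    mc <- mc_rd_bayes_factor(cnt[1], cnt[2], 0.376, 0.943, prs,
                             n_draws = 2e5, seed = 42)
    expect_equal(bf, mc, tolerance = 0.02)
  }
})

test_that("Bayes factors are monotone in the classified counts", {
  prs <- rd_priors()
  params <- rd_params(0.376, 0.943)
  grid <- expand.grid(gene_id = NA, xd = 0:12, xh = 0:12)
  grid$gene_id <- sprintf("g%03d", seq_len(nrow(grid)))
  bf <- rd_bayes_factor_table(grid, params, prs)
  m <- matrix(bf$bf_rd, nrow = 13)  # rows: xd, cols: xh
  expect_true(all(diff(m) > 0))          # increasing in xd at fixed xh
  expect_true(all(t(diff(t(m))) < 0))    # decreasing in xh at fixed xd
})

test_that("the table operation matches the scalar operation elementwise", {
  prs <- rd_priors()
  params <- rd_params(0.62, 0.83)
  expect_equal(nrow(rd_bayes_factor_table(
    data.frame(gene_id = character(0), xd = integer(0), xh = integer(0)),
    params, prs)), 0L)
  set.seed(8)
  counts <- data.frame(gene_id = sprintf("g%03d", 1:100),
                       xd = rpois(100, 1), xh = rpois(100, 4))
  tab <- rd_bayes_factor_table(counts, params, prs)
  for (i in c(1, 17, 50, 100))
    expect_identical(tab$bf_rd[i],
                     rd_bayes_factor(counts$xd[i], counts$xh[i], params, prs))
  dup <- counts
  dup$gene_id[2] <- dup$gene_id[1]
  expect_error(rd_bayes_factor_table(dup, params, prs), "duplicate")
})

test_that("prior and parameter constructors validate their inputs", {
  expect_error(rd_priors(p1 = 0.1, p0 = 0.5), "not be below")
  expect_warning(rd_priors(p1 = 0.3, p0 = 0.3), "equal means")
  expect_error(rd_priors(p1 = c(-1, 2)), "positive")
  expect_warning(rd_params(0.4, 0.6), "degenerate")
  expect_error(rd_params(1.4, 0.6))
  expect_error(rd_bayes_factor(-1, 2, rd_params(0.5, 0.9), rd_priors()),
               "non-negative")
})
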