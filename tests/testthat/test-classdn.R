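# ClassDn: imbalanced ensemble training, scoring, thresholding and
# performance estimation.

fml <- label ~ AF + LOEUF + CCR + FDR_TADA_DD + obs_lof + exp_lof

test_that("both algorithms separate the classes on synthetic data", {
  train <- make_family_cohort(31)
  test <- make_family_cohort(95)
  for (alg in c("rusboost", "underbagging")) {
    fit <- classdn(fml, train, algorithm = alg, n_estimators = 25)
    s <- predict(fit, test)
    expect_true(all(s >= 0 & s <= 1))
    expect_gt(auc_score(test$label, s), 0.95)
    # scores on de novo rows stochastically larger than on inherited rows
    wt <- wilcox.test(s[test$label == 1], s[test$label == 0],
                      alternative = "greater")
    expect_lt(wt$p.value, 1e-6)
  }
})

test_that("permuted labels give chance-level performance", {
  cohort <- make_family_cohort(31, n_genes = 300, n_variants = 12000)
  set.seed(77)
  cohort$label <- sample(cohort$label)  # break any label-covariate link
  idx <- sample(nrow(cohort), nrow(cohort) / 2)
  fit <- classdn(fml, cohort[idx, ], algorithm = "underbagging",
                 n_estimators = 20)
  held <- cohort[-idx, ]
  auc <- auc_score(held$label, predict(fit, held))
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("fits and scores are deterministic under a fixed seed", {
  train <- make_family_cohort(31, n_genes = 100, n_variants = 1200)
  f1 <- classdn(fml, train, n_estimators = 10, rng_seed = 3)
  f2 <- classdn(fml, train, n_estimators = 10, rng_seed = 3)
  expect_identical(predict(f1, train), predict(f2, train))
  # duplicated row gets a duplicated score
  two <- rbind(train[1, ], train[1, ])
  expect_equal(predict(f1, two)[1], predict(f1, two)[2])
  # empty input gives empty output
  expect_identical(predict(f1, train[0, ]), numeric(0))
})

test_that("every base learner trains on a class-balanced subsample", {
  train <- make_family_cohort(31, n_genes = 100, n_variants = 1500)
  for (alg in c("rusboost", "underbagging")) {
    fit <- classdn(fml, train, algorithm = alg, n_estimators = 8)
    expect_true(all(fit$balance[, "minority"] == fit$balance[, "majority"]))
  }
})

test_that("training and prediction validate their inputs", {
  train <- make_family_cohort(31, n_genes = 50, n_variants = 600)
  one_class <- train[train$label == 0L, ]
  expect_error(classdn(fml, one_class, n_estimators = 5),
               "both inheritance classes")
  fit <- classdn(fml, train, n_estimators = 5)
  expect_error(predict(fit, train[, setdiff(names(train), "CCR")]), "CCR")
  # rows with missing covariates are dropped and counted
  train2 <- train
  train2$LOEUF[1:7] <- NA
  fit2 <- classdn(fml, train2, n_estimators = 5)
  expect_equal(fit2$n_dropped, 7L)
})

test_that("thresholding uses a strict 'exceeds' rule", {
  expect_identical(classify_at_threshold(c(0.7, 0.71, 0.69), 0.7),
                   c(0L, 1L, 0L))
  expect_identical(classify_at_threshold(c(0.2, 0.9, 1), 1), c(0L, 0L, 0L))
  expect_error(classify_at_threshold(0.5, 1.2))
})

test_that("estimate_performance counts classification rates per class", {
  expect_equal(estimate_performance(c(1, 0), c(1, 0)), c(w1 = 1, w2 = 1))
  expect_equal(estimate_performance(c(1, 1, 0, 0), c(0, 0, 0, 0)),
               c(w1 = 0, w2 = 1))
  expect_equal(estimate_performance(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               c(w1 = 0.5, w2 = 0.5))
  expect_error(estimate_performance(c(1, 1), c(1, 0)), "specificity")
  expect_error(estimate_performance(c(0, 0), c(1, 0)), "sensitivity")
})

test_that("performance curves are monotone and match pointwise estimates", {
  set.seed(10)
  labels <- rbinom(400, 1, 0.3)
  scores <- rnorm(400, 0.3 + 0.3 * labels, 0.2)
  scores <- pmin(pmax(scores, 0), 1)
  grid <- seq(0, 1, 0.05)
  pc <- performance_curve(labels, scores, grid)
  expect_true(all(diff(pc$sensitivity) <= 0))
  expect_true(all(diff(pc$specificity) >= 0))
  # compositional oracle: curve = estimate_performance o classify_at_threshold
  for (i in seq_along(grid)) {
    ref <- estimate_performance(labels, classify_at_threshold(scores, grid[i]))
    expect_equal(pc$sensitivity[i], unname(ref["w1"]))
    expect_equal(pc$specificity[i], unname(ref["w2"]))
  }
  # boundary grids
  pos <- performance_curve(labels, pmax(scores, 0.01), c(0))
  expect_equal(pos$sensitivity, 1)
  top <- performance_curve(labels, scores, c(1))
  expect_equal(top$sensitivity, 0)
  expect_equal(top$specificity, 1)
})
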