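# ClassDn: imbalanced-data ensemble classifiers for inheritance class.
# Rare inherited variants outnumber de novo variants roughly thirtyfold, so
# plain classifiers ignore the minority class; RUSBoost and UnderBagging
# rebalance every base learner by random undersampling of the majority
# class.  Base learners are shallow rpart decision trees.

#' Fit a ClassDn inheritance-class classifier
#'
#' Trains an ensemble classifier that scores variants for de novo status
#' from labeled family-based data.  Two algorithms designed for imbalanced
#' data are available: `rusboost` (boosting with random undersampling of the
#' majority class before each boosting round) and `underbagging` (bagging
#' where each bag pairs a bootstrap of the minority class with an
#' equal-sized undersample of the majority class).  Every base learner is
#' trained on a class-balanced (1:1) subsample.
#'
#' The response must be binary with 1 = de novo and 0 = inherited.  The
#' allele-frequency covariate `AF`, when present, is log10-transformed with
#' a 1e-9 pseudo-count before fitting because it spans orders of magnitude.
#' Rows with missing covariates are dropped; the count is recorded in the
#' fitted object (`$n_dropped`).
#'
#' @param formula model formula, e.g. `label ~ AF + LOEUF + CCR +
#'   FDR_TADA_DD + obs_lof + exp_lof` or `label ~ .`.
#' @param data data.frame of labeled variants.
#' @param algorithm `"rusboost"` or `"underbagging"`.
#' @param n_estimators number of base learners.
#' @param max_depth maximum depth of each decision tree.
#' @param learning_rate boosting shrinkage (rusboost only).
#' @param rng_seed integer seed; fits are deterministic given the seed.
#' @return An object of class `classdn` with components `algorithm`,
#'   `learners`, `alphas`, `feature_order`, `balance` (per-learner minority
#'   and majority subsample sizes), `n_dropped`, `rng_seed`.
#' @seealso [predict.classdn()], [performance_curve()]
#' @examples
#' cfg <- cohort_config(n_genes = 40, n_variants_total = 600, rng_seed = 5)
#' fam <- simulate_family_variants(cfg)
#' fit <- classdn(label ~ . - gene_id, fam, algorithm = "underbagging",
#'                n_estimators = 10)
#' fit
#' @export
classdn <- function(formula, data,
                    algorithm = c("rusboost", "underbagging"),
                    n_estimators = 100L, max_depth = 3L,
                    learning_rate = 0.5, rng_seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_estimators >= 1, max_depth >= 1, learning_rate > 0)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  feature_order <- attr(stats::terms(mf), "term.labels")
  X <- mf[, feature_order, drop = FALSE]
  keep <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  y <- as.integer(y[keep])
  if (!all(y %in% c(0L, 1L)))
    stop("response must be binary: 1 = de novo, 0 = inherited")
  if (length(unique(y)) < 2L)
    stop("training data must contain both inheritance classes")
  X <- preprocess_covariates(X)
  fit <- with_seed(derive_seed(rng_seed, paste0("classdn_", algorithm)),
                   switch(algorithm,
                          rusboost = fit_rusboost(X, y, n_estimators,
                                                  max_depth, learning_rate),
                          underbagging = fit_underbagging(X, y, n_estimators,
                                                          max_depth)))
  structure(list(algorithm = algorithm,
                 learners = fit$learners,
                 alphas = fit$alphas,
                 balance = fit$balance,
                 feature_order = feature_order,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 n_dropped = n_dropped,
                 n_train = length(y),
                 rng_seed = as.integer(rng_seed)),
            class = "classdn")
}

preprocess_covariates <- function(X) {
  if ("AF" %in% names(X)) X$AF <- log10(X$AF + 1e-9)
  X
}

tree_control <- function(max_depth) {
  rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 10,
                       minbucket = 5, xval = 0)
}

fit_tree <- function(X, y, idx, w, max_depth) {
  d <- X[idx, , drop = FALSE]
  d$.y <- factor(y[idx], levels = c(0L, 1L))
  wts <- w[idx]
  wts <- wts / sum(wts) * length(idx)
  f <- .y ~ .
  environment(f) <- environment()  # so rpart finds `wts`
  rpart::rpart(f, data = d, weights = wts, method = "class",
               control = tree_control(max_depth))
}

tree_prob <- function(tree, newdata) {
  p <- predict(tree, newdata, type = "prob")
  if ("1" %in% colnames(p)) p[, "1"] else rep(0, nrow(newdata))
}

# Boosting with random undersampling: before each round the majority class
# is undersampled (weighted, without replacement) to the minority size, a
# weak tree is fit on the balanced subsample, and AdaBoost weight updates
# are applied on the full training set.
fit_rusboost <- function(X, y, n_estimators, max_depth, learning_rate) {
  n <- length(y)
  min_class <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == min_class)
  idx_maj <- which(y != min_class)
  w <- rep(1 / n, n)
  learners <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  balance <- matrix(NA_integer_, n_estimators, 2,
                    dimnames = list(NULL, c("minority", "majority")))
  for (t in seq_len(n_estimators)) {
    k <- min(length(idx_min), length(idx_maj))
    sub_maj <- sample(idx_maj, k, prob = w[idx_maj])
    sub <- c(idx_min, sub_maj)
    balance[t, ] <- c(length(idx_min), k)
    tree <- fit_tree(X, y, sub, w, max_depth)
    p <- tree_prob(tree, X)
    miss <- as.integer(p > 0.5) != y
    err <- sum(w[miss])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    alpha <- max(alpha, 1e-10)  # keep weight positive on degenerate rounds
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    learners[[t]] <- tree
    alphas[t] <- alpha
  }
  list(learners = learners, alphas = alphas, balance = balance)
}

# Bagging over balanced bags: bootstrap of the minority class paired with an
# equal-sized undersample (without replacement) of the majority class.
fit_underbagging <- function(X, y, n_estimators, max_depth) {
  n <- length(y)
  min_class <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == min_class)
  idx_maj <- which(y != min_class)
  w <- rep(1, n)
  learners <- vector("list", n_estimators)
  balance <- matrix(NA_integer_, n_estimators, 2,
                    dimnames = list(NULL, c("minority", "majority")))
  k <- min(length(idx_min), length(idx_maj))
  for (t in seq_len(n_estimators)) {
    sub <- c(sample(idx_min, k, replace = TRUE), sample(idx_maj, k))
    balance[t, ] <- c(k, k)
    learners[[t]] <- fit_tree(X, y, sub, w, max_depth)
  }
  list(learners = learners, alphas = rep(1, n_estimators), balance = balance)
}

#' De novo scores for new variants
#'
#' Scores each row of `newdata` with the fitted ensemble: the weighted mean
#' of the base learners' de novo class probabilities (weights are the
#' boosting coefficients for rusboost, uniform for underbagging).  Scores
#' lie in \[0, 1\] and preserve row order.
#'
#' @param object a fitted [classdn()] model.
#' @param newdata data.frame containing the model's covariate columns.
#' @param type `"score"` for de novo scores, `"class"` for thresholded
#'   0/1 labels.
#' @param threshold classification threshold used when `type = "class"`
#'   (strict: class 1 iff score > threshold).
#' @param ... unused.
#' @return Numeric vector of scores in \[0, 1\] (or integer classes).
#' @export
predict.classdn <- function(object, newdata, type = c("score", "class"),
                            threshold = 0.7, ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$feature_order, names(newdata))
  if (length(missing_cols))
    stop("newdata is missing required covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  X <- preprocess_covariates(newdata[, object$feature_order, drop = FALSE])
  if (nrow(X) == 0L)
    return(if (type == "score") numeric(0) else integer(0))
  probs <- vapply(object$learners, tree_prob, numeric(nrow(X)),
                  newdata = X)
  probs <- matrix(probs, nrow = nrow(X))
  scores <- as.numeric(probs %*% object$alphas / sum(object$alphas))
  scores <- pmin(pmax(scores, 0), 1)
  if (type == "score") scores else classify_at_threshold(scores, threshold)
}

#' @export
print.classdn <- function(x, ...) {
  cat("ClassDn inheritance-class classifier\n")
  cat("  algorithm:   ", x$algorithm, "\n", sep = "")
  cat("  base learners: ", x$n_estimators, " trees (max depth ",
      x$max_depth, ")\n", sep = "")
  cat("  covariates:  ", paste(x$feature_order, collapse = ", "), "\n",
      sep = "")
  cat("  trained on ", x$n_train, " variants (", x$n_dropped,
      " dropped for missing covariates)\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels; ties get
#' half credit.
#'
#' @param labels binary vector (1 = positive class).
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
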