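# Unit checks of the native learners on tiny constructed inputs.

test_that("CART tree recovers an axis-aligned split and honours depth", {
  x <- cbind(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 0, 0, 0))
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- phenoENM:::tree_fit(x, y, max_depth = 5)
  p <- phenoENM:::tree_predict(tr, x)
  expect_equal(p, y)
  expect_false(tr$root$leaf)
  expect_equal(tr$root$j, 1)
  expect_true(tr$root$thr > 3 && tr$root$thr < 10)

  stump_only <- phenoENM:::tree_fit(x, y, max_depth = 0)
  expect_true(stump_only$root$leaf)
  expect_equal(phenoENM:::tree_predict(stump_only, x), rep(0.5, 6))
})

test_that("weighted tree fitting responds to sample weights", {
  # upweighting the minority flips the majority-vote leaf
  x <- cbind(c(1, 1, 1, 1), c(0, 0, 0, 0))
  y <- c(1, 0, 0, 0)
  w_eq <- rep(0.25, 4)
  w_up <- c(0.91, 0.03, 0.03, 0.03)
  leaf_eq <- phenoENM:::tree_fit(x, y, w = w_eq, max_depth = 1)$root
  leaf_up <- phenoENM:::tree_fit(x, y, w = w_up, max_depth = 1)$root
  expect_equal(leaf_eq$prob, 0.25)
  expect_equal(leaf_up$prob, 0.91)
})

test_that("random forest and AdaBoost separate the separable", {
  tab <- separable_samples(60, seed = 2)
  x <- scale(as.matrix(tab[, c("mPPT", "mT_min")]))
  y <- tab$label
  withr::with_seed(5, {
    rf <- phenoENM:::forest_fit(x, y, n_trees = 50)
  })
  expect_gt(auc_roc(y, phenoENM:::forest_predict(rf, x)), 0.99)
  ab <- phenoENM:::adaboost_fit(x, y, n_iter = 20)
  expect_gt(auc_roc(y, phenoENM:::adaboost_predict(ab, x)), 0.99)
  expect_true(all(phenoENM:::forest_predict(rf, x) >= 0 &
                    phenoENM:::forest_predict(rf, x) <= 1))
})

test_that("AdaBoost on stumps beats a single stump on a stepped signal", {
  # one stump can cut once; boosting should capture the second cut
  x <- cbind(seq(-3, 3, length.out = 120), 0)
  y <- as.integer(x[, 1] > -1 & x[, 1] < 1)
  stump <- phenoENM:::tree_fit(x, y, max_depth = 1)
  ab <- phenoENM:::adaboost_fit(x, y, n_iter = 50)
  auc_stump <- auc_roc(y, phenoENM:::tree_predict(stump, x))
  auc_boost <- auc_roc(y, phenoENM:::adaboost_predict(ab, x))
  expect_gt(auc_boost, auc_stump)
  expect_gt(auc_boost, 0.9)
})

test_that("Gaussian naive Bayes matches the closed-form Bayes rule", {
  # 4 points, 2 per class: hand-evaluated posterior
  x <- cbind(c(0, 2, 10, 12), c(1, -1, 5, 7))
  y <- c(0, 0, 1, 1)
  model <- phenoENM:::nbc_fit(x, y)
  query <- cbind(c(1, 11, 6), c(0, 6, 3))
  # independent oracle: ML per-class moments and Gaussian likelihoods
  dens <- function(q, mu, v) prod(1 / sqrt(2 * pi * v) *
                                    exp(-0.5 * (q - mu)^2 / v))
  mu0 <- colMeans(x[y == 0, ]); v0 <- apply(x[y == 0, ], 2,
    function(c) mean((c - mean(c))^2))
  mu1 <- colMeans(x[y == 1, ]); v1 <- apply(x[y == 1, ], 2,
    function(c) mean((c - mean(c))^2))
  expected <- apply(query, 1, function(q) {
    l0 <- dens(q, mu0, v0) * 0.5
    l1 <- dens(q, mu1, v1) * 0.5
    l1 / (l0 + l1)
  })
  expect_equal(phenoENM:::nbc_predict(model, query), expected,
               tolerance = 1e-6)
})

test_that("QDA posterior matches a direct multivariate-normal evaluation", {
  withr::with_seed(8, {
    x0 <- cbind(rnorm(40, 0), rnorm(40, 0))
    x1 <- cbind(rnorm(40, 3), rnorm(40, 1))
  })
  x <- rbind(x0, x1); y <- rep(c(0, 1), each = 40)
  model <- phenoENM:::qda_fit(x, y)
  q <- cbind(c(0.5, 2.5), c(0.2, 1.1))
  dmvn <- function(q, mu, S) {
    d <- q - mu
    exp(-0.5 * t(d) %*% solve(S) %*% d) / (2 * pi * sqrt(det(S)))
  }
  expected <- apply(q, 1, function(qi) {
    l0 <- dmvn(qi, colMeans(x0), cov(x0)) * 0.5
    l1 <- dmvn(qi, colMeans(x1), cov(x1)) * 0.5
    as.numeric(l1 / (l0 + l1))
  })
  expect_equal(phenoENM:::qda_predict(model, q), expected,
               tolerance = 1e-5)
})

test_that("GP classifier is calibrated on trivial geometry", {
  # two well-separated blobs: probabilities ordered correctly and
  # uncertain midway between them
  withr::with_seed(10, {
    x <- rbind(cbind(rnorm(30, -2, 0.3), rnorm(30, 0, 0.3)),
               cbind(rnorm(30, 2, 0.3), rnorm(30, 0, 0.3)))
  })
  y <- rep(c(0, 1), each = 30)
  model <- phenoENM:::gpc_fit(x, y, optimize = FALSE)
  p <- phenoENM:::gpc_predict(model, cbind(c(-2, 0, 2), c(0, 0, 0)))
  expect_lt(p[1], 0.2)
  expect_gt(p[3], 0.8)
  expect_lt(abs(p[2] - 0.5), 0.15)
  # marginal-likelihood optimization should not degrade training AUC
  opt <- phenoENM:::gpc_fit(x, y, optimize = TRUE)
  expect_gte(auc_roc(y, phenoENM:::gpc_predict(opt, x)), 0.99)
})

test_that("ANN learns a separable boundary, deterministically per seed", {
  tab <- separable_samples(50, seed = 3)
  x <- scale(as.matrix(tab[, c("mPPT", "mT_min")]))
  y <- tab$label
  m1 <- phenoENM:::ann_fit(x, y, seed = 4)
  m2 <- phenoENM:::ann_fit(x, y, seed = 4)
  expect_identical(m1, m2)
  expect_gt(auc_roc(y, phenoENM:::ann_predict(m1, x)), 0.99)
  p <- phenoENM:::ann_predict(m1, x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("KNN probability is the neighbour vote fraction", {
  x <- cbind(c(0, 0.1, 0.2, 5, 5.1), 0)
  y <- c(1, 1, 0, 0, 0)
  m <- phenoENM:::knn_fit(x, y, k = 3)
  # neighbours of 0.05: the three left points -> 2/3
  expect_equal(phenoENM:::knn_predict(m, cbind(0.05, 0)), 2 / 3)
  # unanimous vote yields probability 1
  m1 <- phenoENM:::knn_fit(cbind(1:5, 0), rep(1, 5), k = 5)
  expect_equal(phenoENM:::knn_predict(m1, cbind(99, 0)), 1)
})
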