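test_that("confusion-matrix metrics reproduce the precision/recall/F1 formulas", {
  # perfect classifier
  cm <- diag(c(5, 3, 7))
  dimnames(cm) <- list(letters[1:3], letters[1:3])
  rep <- metrics_from_confusion(cm)
  expect_true(all(rep$per_class$f1 == 1))
  expect_equal(rep$macro_f1, 1)
  # binary: TP = 1, FP = 1, FN = 1, TN = 1 -> everything 0.5
  cm2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("p", "n"), c("p", "n")))
  rep2 <- metrics_from_confusion(cm2)
  expect_equal(rep2$per_class$precision, c(0.5, 0.5))
  expect_equal(rep2$per_class$recall, c(0.5, 0.5))
  expect_equal(rep2$per_class$f1, c(0.5, 0.5))
  # random matrices vs the naive oracle; macro = unweighted mean
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 4), k, k)
    rep <- metrics_from_confusion(cm)
    want <- naive_metrics(cm)
    expect_equal(rep$per_class$f1, want$f1, tolerance = 1e-12)
    expect_equal(rep$macro_f1, mean(rep$per_class$f1), tolerance = 1e-12)
    expect_true(all(rep$per_class$precision >= 0 & rep$per_class$precision <= 1))
  }
  expect_error(metrics_from_confusion(matrix(numeric(0), 0, 0)), "non-empty")
})

separable_toy <- function(n = 40) {
  set.seed(22)
  x <- rbind(matrix(rnorm(n, 0, 0.3), ncol = 2),
             matrix(rnorm(n, 5, 0.3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c("a", "b"), each = n / 2))
}

test_that("classifiers train, predict, and are seed/row-order deterministic", {
  toy <- separable_toy()
  for (alg in c("RF", "kNN")) {
    model <- train_classifier(classifier_config(alg), toy$x, toy$y, seed = 1)
    expect_equal(mean(as.character(predict(model, toy$x)) == toy$y), 1)
  }
  # permuting training rows with the same seed leaves RF predictions unchanged
  m1 <- train_classifier(classifier_config("RF"), toy$x, toy$y, seed = 9)
  perm <- sample(nrow(toy$x))
  m2 <- train_classifier(classifier_config("RF"), toy$x[perm, ], toy$y[perm],
                         seed = 9)
  set.seed(33)
  newx <- matrix(runif(40, -1, 6), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  expect_identical(predict(m1, newx), predict(m2, newx))
  expect_error(train_classifier(classifier_config("RF"), toy$x,
                                rep("a", nrow(toy$x))), "single class")
})

test_that("kNN with k = 3 agrees with hand-computed neighbours", {
  x <- matrix(c(0, 0,  1, 0,  0, 1,  5, 5,  6, 5), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c("near", "near", "near", "far", "far")
  model <- train_classifier(classifier_config("kNN"), x, y, seed = 1)
  # query (0.2, 0.2): 3 nearest are the three "near" points
  expect_identical(as.character(predict(model, matrix(c(0.2, 0.2), 1,
    dimnames = list(NULL, c("f1", "f2"))))), "near")
  # query (4.5, 4.4): nearest are the two "far" points and (0,1) -> majority far
  expect_identical(as.character(predict(model, matrix(c(4.5, 4.4), 1,
    dimnames = list(NULL, c("f1", "f2"))))), "far")
})

test_that("OOB permutation importance behaves on known structure", {
  set.seed(23)
  n <- 300
  y <- rep(c("a", "b", "c"), each = n / 3)
  informative <- as.numeric(factor(y)) + rnorm(n, 0, 0.2)
  x <- cbind(inf1 = informative, inf2 = informative + rnorm(n, 0, 0.05),
             constant = rep(1, n),
             null1 = rnorm(n), null2 = rnorm(n), null3 = rnorm(n))
  imp <- oob_importance(x, y, seed = 5)
  # permuting a constant changes nothing: importance exactly zero
  expect_identical(imp$importance[imp$feature == "constant"], 0)
  # both copies of the informative signal outrank every null feature
  rank_of <- function(f) which(imp$feature == f)
  expect_true(max(rank_of("inf1"), rank_of("inf2")) <
              min(rank_of("null1"), rank_of("null2"), rank_of("null3")))
  expect_error(oob_importance(x, y, classifier_config("kNN")), "RF")
})

test_that("a label-independent feature has importance near zero across seeds", {
  set.seed(24)
  n <- 240
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(sig = as.numeric(factor(y)) + rnorm(n, 0, 0.1),
             nullf = rnorm(n))
  scores <- vapply(1:20, function(s) {
    imp <- oob_importance(x, y, seed = s)
    imp$importance[imp$feature == "nullf"]
  }, numeric(1))
  expect_lt(abs(mean(scores)), 3 * stats::sd(scores) / sqrt(length(scores)) + 1e-8)
})

test_that("LOSO folds are subject-disjoint and pool correctly", {
  set.seed(25)
  n <- 120
  subjects <- rep(paste0("s", 1:6), each = n / 6)
  y <- rep(rep(c("a", "b"), each = 10), 6)
  x <- cbind(f1 = as.numeric(factor(y)) + rnorm(n, 0, 0.2),
             f2 = rnorm(n))
  res <- loso_cv(x, y, subjects, seed = 1)
  expect_length(res$folds, 6L)
  # two subjects -> two folds
  res2 <- loso_cv(x[subjects %in% c("s1", "s2"), ], y[subjects %in% c("s1", "s2")],
                  subjects[subjects %in% c("s1", "s2")], seed = 1)
  expect_length(res2$folds, 2L)
  # pooled confusion row sums equal the test supports
  expect_equal(unname(rowSums(res$confusion)), as.vector(table(factor(y))))
  expect_error(loso_cv(x, y, rep("s1", n)), "two subjects")
})

test_that("feature selection finds small sufficient subsets", {
  set.seed(26)
  n <- 180
  subjects <- rep(paste0("s", 1:6), each = n / 6)
  y <- factor(rep(rep(c("a", "b", "c"), each = 10), 6))
  perfect <- as.numeric(y)
  x <- cbind(perfect = perfect,
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("null", 1:6))))
  # perfectly predictive feature ranked first -> curve flat at 1 from n = 1
  curve <- select_features(colnames(x), x, as.character(y), subjects,
                           sizes = c(1, 3, 5), seed = 1)
  expect_true(all(curve$points$macro_f1 == 1))
  expect_identical(curve$best_n, 1L)
  # 5 informative + 50 null features -> best_n stays small
  set.seed(27)
  n2 <- 240
  subjects2 <- rep(paste0("s", 1:6), each = n2 / 6)
  y2 <- rep(rep(c("a", "b", "c"), each = 4, length.out = n2 / 6), 6)
  centers <- matrix(rnorm(15, sd = 2), 3, 5)
  inf <- centers[as.integer(factor(y2)), ] + matrix(rnorm(n2 * 5, 0, 0.4), n2, 5)
  colnames(inf) <- paste0("inf", 1:5)
  nulls <- matrix(rnorm(n2 * 50), n2, 50,
                  dimnames = list(NULL, paste0("null", 1:50)))
  x2 <- cbind(inf, nulls)
  ranked <- oob_importance(x2, y2, seed = 2)$feature
  curve2 <- select_features(ranked, x2, y2, subjects2,
                            sizes = c(1, 2, 3, 5, 8, 10, 20, 40, 55), seed = 2)
  expect_lte(curve2$best_n, 10L)
  # determinism under a fixed seed
  curve2b <- select_features(ranked, x2, y2, subjects2,
                             sizes = c(1, 2, 3, 5, 8, 10, 20, 40, 55), seed = 2)
  expect_identical(curve2$points, curve2b$points)
})

test_that("paired fold test degrades gracefully on identical scores", {
  ht <- paired_fold_test(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_identical(ht$t, 0)
  expect_identical(ht$p, 1)
  set.seed(28)
  a <- runif(10); b <- a + rnorm(10, 0.1, 0.05)
  ht2 <- paired_fold_test(a, b)
  want <- t.test(a, b, paired = TRUE)
  expect_equal(ht2$t, unname(want$statistic))
  expect_equal(ht2$p, want$p.value)
  # missing folds are dropped pairwise
  ht3 <- paired_fold_test(c(a, NA), c(b, 0.2))
  expect_identical(ht3$n, 10L)
})

test_that("the random forest matches or beats the other classifiers", {
  ds <- small_dataset()
  s <- part_samples(ds, "trunk")
  # rank once with the RF, evaluate all five algorithms on the same subset
  ranked <- oob_importance(s$x, s$y, seed = 3)$feature[1:25]
  x <- s$x[, ranked, drop = FALSE]
  algs <- c("RF", "NB", "SVM", "MLP", "kNN")
  f1 <- vapply(algs, function(a) {
    cfg <- if (a == "MLP") classifier_config("MLP", size = 64L) else classifier_config(a)
    suppressWarnings(
      loso_cv(x, s$y, s$subjects, config = cfg, seed = 3,
              classes = trunk_classes())$report$macro_f1
    )
  }, numeric(1))
  expect_gte(f1[["RF"]], max(f1) - 0.02)
})
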