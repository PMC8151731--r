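#' Classifier configuration
#'
#' Bundles an algorithm choice with the hyperparameters used throughout the
#' package. Defaults mirror the evaluated configurations: random forest with
#' 10 candidate variables per split and at most 200 splits per tree (tree
#' count 100); RBF-kernel SVM on standardised inputs; a one-hidden-layer
#' perceptron of width 512 trained for 40 optimisation passes; 3-nearest
#' neighbours; and naive Bayes (Gaussian per feature, since the features are
#' continuous).
#'
#' @param algorithm One of `"RF"`, `"SVM"`, `"MLP"`, `"kNN"`, `"NB"`.
#' @param ... Hyperparameter overrides: `ntree`, `mtry`, `max_splits` (RF);
#'   `size`, `maxit`, `decay` (MLP); `k` (kNN).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(algorithm = c("RF", "SVM", "MLP", "kNN", "NB"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    RF = list(ntree = 100L, mtry = 10L, max_splits = 200L),
    SVM = list(kernel = "radial", standardize = TRUE),
    MLP = list(size = 512L, maxit = 40L, decay = 1e-4),
    kNN = list(k = 3L),
    NB = list()
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  structure(c(list(algorithm = algorithm), defaults), class = "classifier_config")
}

# Deterministic canonical row order (lexicographic over features, then label)
# so that a fixed seed yields predictions invariant to input row permutation.
canonical_order <- function(x, y) {
  do.call(order, c(unname(as.data.frame(x)), list(as.character(y))))
}

#' Train a posture classifier
#'
#' @param config A [classifier_config()].
#' @param x Numeric feature matrix (rows = samples, named columns).
#' @param y Class labels (coerced to factor); at least two classes required.
#' @param seed Integer seed; training is deterministic given the seed and is
#'   invariant to the row order of `x`.
#' @return An object of class `seatpose_classifier`.
#' @export
train_classifier <- function(config, x, y, seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("training set contains a single class; need at least two", call. = FALSE)
  }
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  ord <- canonical_order(x, y)
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  set.seed(seed)
  fit <- switch(config$algorithm,
    RF = randomForest::randomForest(
      x = x, y = y,
      ntree = config$ntree,
      mtry = min(config$mtry, ncol(x)),
      maxnodes = min(config$max_splits + 1L, nrow(x))
    ),
    SVM = e1071::svm(
      x = x, y = y, kernel = config$kernel,
      scale = apply(x, 2L, stats::sd) > 0
    ),
    MLP = nnet::nnet(
      x = x, y = nnet::class.ind(y), size = config$size,
      softmax = TRUE, maxit = config$maxit, decay = config$decay,
      MaxNWts = 1e7, trace = FALSE
    ),
    kNN = list(x = x, y = y, k = config$k),
    NB = e1071::naiveBayes(x = as.data.frame(x), y = y)
  )
  structure(list(config = config, fit = fit, levels = levels(y),
                 features = colnames(x), seed = seed),
            class = "seatpose_classifier")
}

#' @export
predict.seatpose_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  out <- switch(object$config$algorithm,
    RF = as.character(predict(object$fit, newdata)),
    SVM = as.character(predict(object$fit, newdata)),
    MLP = {
      pr <- predict(object$fit, newdata)
      object$levels[max.col(pr, ties.method = "first")]
    },
    kNN = {
      set.seed(object$seed)
      as.character(class::knn(object$fit$x, newdata, object$fit$y,
                              k = object$fit$k))
    },
    NB = as.character(predict(object$fit, as.data.frame(newdata)))
  )
  factor(out, levels = object$levels)
}

#' Build a confusion matrix
#'
#' @param true,predicted Label vectors.
#' @param classes Ordered class levels; defaults to the union of labels.
#' @return Square integer matrix, rows = true, cols = predicted.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(true),
                                                 as.character(predicted))))
  as.matrix(table(factor(as.character(true), levels = classes),
                  factor(as.character(predicted), levels = classes)))
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): precision = TP / (TP + FP), recall =
#' TP / (TP + FN), F1 = 2 * precision * recall / (precision + recall), with
#' F1 = 0 when precision + recall = 0 (precision/recall of an empty
#' denominator are taken as 0). The macro F1 is the unweighted mean of the
#' per-class F1 scores.
#'
#' @param cm Square counts matrix (rows = true classes, cols = predicted).
#' @return List with `per_class` (data frame: class, support, precision,
#'   recall, f1), `macro_f1` and `accuracy`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) == 0L || nrow(cm) != ncol(cm)) {
    stop("confusion matrix must be a non-empty square matrix", call. = FALSE)
  }
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  per_class <- data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                          support = rowSums(cm),
                          precision = unname(prec), recall = unname(rec),
                          f1 = unname(f1), stringsAsFactors = FALSE)
  list(per_class = per_class,
       macro_f1 = mean(f1),
       accuracy = sum(tp) / max(sum(cm), 1))
}

#' Out-of-bag permutation feature importance
#'
#' Fits a random forest and scores every feature by the mean increase in
#' out-of-bag classification error when that feature's values are permuted,
#' averaged over trees (the permutation importance computed on each tree's
#' OOB set). Constant features score exactly 0.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param config A [classifier_config()] with `algorithm = "RF"`.
#' @param seed Integer seed.
#' @return Data frame with columns `feature` and `importance`, sorted by
#'   decreasing importance (ties broken by original feature order).
#' @export
oob_importance <- function(x, y, config = classifier_config("RF"), seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  if (config$algorithm != "RF") {
    stop("OOB permutation importance is defined for the RF configuration only",
         call. = FALSE)
  }
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  ord <- canonical_order(x, y)
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x[ord, , drop = FALSE], y = y[ord],
    ntree = config$ntree, mtry = min(config$mtry, ncol(x)),
    maxnodes = min(config$max_splits + 1L, nrow(x)), importance = TRUE
  )
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  out <- data.frame(feature = colnames(x), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the classifier is trained on all other subjects and
#' tested on the held-out subject, so no subject ever contributes to both
#' training and test data of a fold. Test predictions are pooled into a single
#' confusion matrix; per-fold reports are retained for paired comparisons.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param subjects Subject identifier per row; at least two distinct subjects.
#' @param config A [classifier_config()].
#' @param seed Integer seed (same seed used in every fold's training call).
#' @param classes Ordered class levels for the confusion matrix.
#' @return List of class `loso_result`: `confusion`, `report` (from
#'   [metrics_from_confusion()]), `folds` (per-subject reports) and
#'   `fold_f1` (classes x subjects matrix of per-class F1 per fold).
#' @export
loso_cv <- function(x, y, subjects, config = classifier_config("RF"),
                    seed = 1L, classes = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  subjects <- as.character(subjects)
  sids <- unique(subjects)
  if (length(sids) < 2L) stop("LOSO needs at least two subjects", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(y))
  pred <- rep(NA_character_, length(y))
  folds <- list()
  fold_f1 <- matrix(NA_real_, length(classes), length(sids),
                    dimnames = list(classes, sids))
  for (sid in sids) {
    test <- subjects == sid
    if (length(unique(y[test])) < 2L) {
      warning("subject ", sid, " spans a single class; fold proceeds",
              call. = FALSE)
    }
    model <- train_classifier(config, x[!test, , drop = FALSE], y[!test],
                              seed = seed)
    pred[test] <- as.character(predict(model, x[test, , drop = FALSE]))
    cm_fold <- confusion_matrix(y[test], pred[test], classes)
    rep_fold <- metrics_from_confusion(cm_fold)
    present <- rowSums(cm_fold) > 0
    fold_f1[present, sid] <- rep_fold$per_class$f1[present]
    folds[[sid]] <- rep_fold
  }
  cm <- confusion_matrix(y, pred, classes)
  structure(list(confusion = cm, report = metrics_from_confusion(cm),
                 folds = folds, fold_f1 = fold_f1,
                 predictions = pred, subjects = subjects),
            class = "loso_result")
}

#' Select the best feature subset along an importance ranking
#'
#' Evaluates macro F1 by cross-validation for growing prefixes of a ranked
#' feature list and picks `best_n` as the smallest prefix whose score is
#' within `tolerance` of the curve maximum (adding features beyond that does
#' not reliably improve recognition).
#'
#' @param ranked Character vector of feature names, most important first.
#' @param x Feature matrix containing at least those columns.
#' @param y Labels.
#' @param subjects Subject IDs for LOSO evaluation.
#' @param config A [classifier_config()].
#' @param sizes Prefix sizes to evaluate; defaults to a coarse grid.
#' @param tolerance Allowed macro-F1 shortfall from the maximum.
#' @param seed Integer seed.
#' @return List of class `selection_curve`: `ranked`, `points` (data frame of
#'   `n_features`, `macro_f1`), `best_n`, `best_features`.
#' @export
select_features <- function(ranked, x, y, subjects,
                            config = classifier_config("RF"), sizes = NULL,
                            tolerance = 0.01, seed = 1L) {
  stopifnot(length(ranked) > 0L, all(ranked %in% colnames(x)))
  if (is.null(sizes)) {
    sizes <- unique(pmin(c(1:10, seq(12L, length(ranked), by = 4L),
                           length(ranked)), length(ranked)))
  }
  sizes <- sort(unique(as.integer(sizes)))
  f1 <- vapply(sizes, function(n) {
    loso_cv(x[, ranked[seq_len(n)], drop = FALSE], y, subjects,
            config = config, seed = seed)$report$macro_f1
  }, numeric(1))
  best_n <- sizes[which(f1 >= max(f1) - tolerance)[1L]]
  structure(list(ranked = ranked,
                 points = data.frame(n_features = sizes, macro_f1 = f1),
                 best_n = best_n,
                 best_features = ranked[seq_len(best_n)]),
            class = "selection_curve")
}

#' Paired t-test that tolerates identical score vectors
#'
#' Two-sided paired t-test on per-fold scores, pairing by fold. When every
#' pairwise difference is zero (e.g. a layout that reproduces the benchmark
#' exactly) the statistic is reported as t = 0 with p = 1 instead of an error.
#' Pairs with a missing value on either side are dropped.
#'
#' @param scores_a,scores_b Numeric vectors of per-fold scores.
#' @return List with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_fold_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  ok <- stats::complete.cases(scores_a, scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  d <- a - b
  n <- length(d)
  if (n < 2L) return(list(t = NA_real_, p = NA_real_, df = n - 1L,
                          mean_diff = mean(d), n = n))
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = 1, df = n - 1L, mean_diff = mean(d), n = n))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d), n = n)
}
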