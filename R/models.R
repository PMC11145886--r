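#' Stratified train/test split
#'
#' Per-class random split at the given fraction: each class contributes
#' \code{round(n_class * (1 - fraction))} test samples, adjusted (largest
#' class first) so the total test count equals
#' \code{round(n * (1 - fraction))}. Deterministic per seed.
#'
#' @param info sample metadata with columns sample_id and group (two classes).
#' @param fraction training fraction, default 0.8.
#' @param seed integer seed.
#' @return A \code{SplitSpec} list: \code{train_ids}, \code{test_ids},
#'   \code{fraction}, \code{seed}.
#' @export
stratifiedSplit <- function(info, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  groups <- split(info$sample_id, info$group)
  if (length(groups) != 2L) stop("exactly two classes required")
  n <- nrow(info)
  n_test_target <- round(n * (1 - fraction))
  n_test <- vapply(groups, function(g) round(length(g) * (1 - fraction)), 0)
  excess <- sum(n_test) - n_test_target
  if (excess != 0) {
    ord <- order(-lengths(groups))
    n_test[ord[1]] <- n_test[ord[1]] - excess
  }
  for (k in seq_along(groups)) {
    if (n_test[k] < 1 || n_test[k] > length(groups[[k]]) - 1)
      stop("class too small to place at least one sample in each partition")
  }
  set.seed(seed)
  test_ids <- unlist(lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    g[sample.int(length(g), n_test[k])]
  }), use.names = FALSE)
  structure(list(
    train_ids = setdiff(info$sample_id, test_ids),
    test_ids = test_ids, fraction = fraction, seed = as.integer(seed)),
    class = "SplitSpec")
}

# minority class label: the positive class for all minority-focused metrics
minorityClass <- function(y) names(which.min(table(y)))

# ---- classifier family abstraction -----------------------------------------

scaledFamilies <- c("SVC", "LR", "KNN")

# documented random-search spaces; each draw is one hyperparameter setting
sampleParams <- function(family, n_iter, seed) {
  set.seed(seed)
  draw <- switch(family,
    GB = function() list(
      nrounds = sample(20:150, 1), eta = 10^runif(1, -2, -0.5),
      max_depth = sample(2:6, 1), subsample = runif(1, 0.6, 1),
      colsample_bytree = runif(1, 0.6, 1)),
    SVC = function() list(
      cost = 10^runif(1, -2, 2), gamma = 10^runif(1, -3, 1),
      kernel = sample(c("linear", "radial", "polynomial"), 1),
      degree = sample(2:3, 1)),
    RF = function() list(
      num.trees = sample(c(100L, 200L, 300L), 1),
      mtry_frac = runif(1, 0.2, 1), min.node.size = sample(1:10, 1)),
    ET = function() list(
      num.trees = sample(c(100L, 200L, 300L), 1),
      mtry_frac = runif(1, 0.2, 1), min.node.size = sample(1:10, 1),
      num.random.splits = sample(1:3, 1)),
    LR = function() list(
      lambda = 10^runif(1, -4, 1), alpha = sample(c(0, 0.5, 1), 1)),
    KNN = function() list(k = sample(seq(1L, 25L, 2L), 1)),
    stop("unknown family: ", family)
  )
  lapply(seq_len(n_iter), function(i) draw())
}

trainScaler <- function(X) {
  list(center = colMeans(X), scale = pmax(apply(X, 2, sd), 1e-12))
}

applyScaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, `-`), 2, sc$scale, `/`)
}

# fit one classifier; returns a self-contained bundle used by predictFit()
fitClassifier <- function(family, X, y, params, positive, seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  negative <- setdiff(classes, positive)
  scaler <- NULL
  if (family %in% scaledFamilies) {
    scaler <- trainScaler(X)
    X <- applyScaler(X, scaler)
  }
  set.seed(seed)
  fit <- switch(family,
    GB = xgboost::xgboost(
      x = X, y = factor(y, levels = c(negative, positive)),
      nrounds = params$nrounds, learning_rate = params$eta,
      max_depth = params$max_depth, subsample = params$subsample,
      colsample_bytree = params$colsample_bytree,
      nthreads = 1, seed = seed %% 2147483647L, verbosity = 0),
    SVC = e1071::svm(
      x = X, y = factor(y, levels = c(negative, positive)),
      cost = params$cost, gamma = params$gamma, kernel = params$kernel,
      degree = params$degree, scale = FALSE),
    RF = ranger::ranger(
      x = X, y = factor(y), num.trees = params$num.trees,
      mtry = max(1L, round(params$mtry_frac * ncol(X))),
      min.node.size = params$min.node.size, probability = TRUE,
      num.threads = 1, seed = seed),
    ET = ranger::ranger(
      x = X, y = factor(y), num.trees = params$num.trees,
      mtry = max(1L, round(params$mtry_frac * ncol(X))),
      min.node.size = params$min.node.size, probability = TRUE,
      splitrule = "extratrees", num.random.splits = params$num.random.splits,
      num.threads = 1, seed = seed),
    LR = {
      Xg <- if (ncol(X) == 1L) cbind(X, .dummy = 0) else X
      glmnet::glmnet(Xg, factor(y, levels = c(negative, positive)),
                     family = "binomial", alpha = params$alpha,
                     lambda = params$lambda)
    },
    KNN = list(X = X, y = factor(y), k = min(params$k, nrow(X) - 1L)),
    stop("unknown family: ", family))
  structure(list(family = family, fit = fit, params = params,
                 scaler = scaler, positive = positive, negative = negative,
                 seed = seed),
            class = "sentinelFit")
}

# predicted labels and positive-class scores for a fitted bundle
predictFit <- function(bundle, X) {
  if (!is.null(bundle$scaler)) X <- applyScaler(X, bundle$scaler)
  pos <- bundle$positive; neg <- bundle$negative
  switch(bundle$family,
    GB = {
      s <- predict(bundle$fit, X)  # probability of the second (positive) level
      list(labels = ifelse(s > 0.5, pos, neg), scores = s)
    },
    SVC = {
      pr <- predict(bundle$fit, X, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # decision value sign refers to the first level of the column label
      flip <- !startsWith(colnames(attr(pr, "decision.values"))[1], pos)
      list(labels = as.character(pr), scores = if (flip) -dv else dv)
    },
    RF = ,
    ET = {
      pr <- predict(bundle$fit, X, num.threads = 1)$predictions
      s <- pr[, pos]
      list(labels = ifelse(s > 0.5, pos, neg), scores = s)
    },
    LR = {
      Xg <- if (ncol(X) == 1L) cbind(X, .dummy = 0) else X
      s <- drop(predict(bundle$fit, Xg, type = "response"))
      list(labels = ifelse(s > 0.5, pos, neg), scores = s)
    },
    KNN = {
      set.seed(bundle$seed)  # knn breaks ties at random
      pr <- class::knn(bundle$fit$X, X, bundle$fit$y, k = bundle$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      s <- ifelse(as.character(pr) == pos, win, 1 - win)
      list(labels = as.character(pr), scores = s)
    })
}

# ---- metrics ----------------------------------------------------------------

#' Classification metrics on the positive (minority) class
#'
#' Confusion-matrix metrics with the zero-division convention: precision is
#' 0 (with a warning) when no positive predictions are made; F1 is 0 when
#' precision + recall is 0.
#'
#' @param truth,pred label vectors.
#' @param positive the positive-class label.
#' @param warn warn on the degenerate no-positive-prediction case.
#' @return Named numeric: accuracy, precision, recall, f1.
#' @export
classificationMetrics <- function(truth, pred, positive, warn = TRUE) {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp == 0) {
    if (warn) warning("no positive predictions; precision defined as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = mean(pred == truth), precision = precision,
    recall = recall, f1 = f1)
}

#' Precision-recall area under the curve (average precision)
#'
#' Step-wise average precision: ranks by decreasing score, groups tied
#' scores, and sums recall increments times the precision at each threshold.
#' No trapezoidal interpolation.
#'
#' @param scores positive-class scores (probabilities or decision values).
#' @param labels true labels.
#' @param positive positive-class label.
#' @return Average precision in [0, 1].
#' @examples
#' prAuc(c(0.9, 0.8, 0.3), c(1, 0, 1), positive = 1)
#' @export
prAuc <- function(scores, labels, positive) {
  labels <- as.character(labels) == as.character(positive)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  ord <- order(-scores)
  scores <- scores[ord]; labels <- labels[ord]
  # group tied scores: metrics evaluated only at distinct thresholds
  grp_end <- cumsum(rle(scores)$lengths)
  tp <- cumsum(labels)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  d_tp <- diff(c(0, tp))
  sum(d_tp * prec) / sum(labels)
}

# ---- cross-validated random search ------------------------------------------

stratifiedFolds <- function(y, k, seed, max_redraws = 20L) {
  y <- as.character(y)
  for (attempt in seq_len(max_redraws)) {
    set.seed(deriveSeed(seed, attempt - 1L))
    folds <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds == f])) == 2L, TRUE))
    if (ok) return(folds)
    warning("a fold missed a class; re-drawing fold seed")
  }
  stop("could not build stratified folds with both classes present")
}

#' Random hyperparameter search with stratified k-fold cross-validation
#'
#' Samples \code{n_iter} settings from the family's documented search space
#' and scores each by the mean F1 (positive class) over stratified
#' cross-validation folds; deterministic per seed.
#'
#' @param family one of \code{"GB"}, \code{"SVC"}, \code{"RF"}, \code{"ET"},
#'   \code{"LR"}, \code{"KNN"}.
#' @param X samples x features numeric matrix (training partition).
#' @param y labels.
#' @param n_iter number of settings to try (<= 200).
#' @param k_folds folds, default 5.
#' @param seed integer seed.
#' @param positive positive-class label; default the minority class.
#' @return \code{list(best_params, mean_cv_f1, family)}.
#' @export
randomHyperparameterSearch <- function(family, X, y, n_iter = 25L,
                                       k_folds = 5L, seed = 1L,
                                       positive = minorityClass(y)) {
  if (n_iter < 1 || n_iter > 200) stop("n_iter must lie in 1..200")
  settings <- sampleParams(family, n_iter, seed = deriveSeed(seed, 1L))
  folds <- stratifiedFolds(y, k_folds, seed = deriveSeed(seed, 2L))
  cv_f1 <- vapply(seq_along(settings), function(si) {
    fold_f1 <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      bundle <- fitClassifier(family, X[tr, , drop = FALSE], y[tr],
                              settings[[si]], positive,
                              seed = deriveSeed(seed, 100L * si + f))
      pred <- predictFit(bundle, X[!tr, , drop = FALSE])
      classificationMetrics(y[!tr], pred$labels, positive,
                            warn = FALSE)[["f1"]]
    }, numeric(1))
    mean(fold_f1)
  }, numeric(1))
  best <- which.max(cv_f1)
  list(best_params = settings[[best]], mean_cv_f1 = cv_f1[best],
       family = family)
}

# ---- linkage-distance sweep --------------------------------------------------

#' Sweep classifier families over linkage-distance thresholds
#'
#' For each threshold the training-partition correlation tree is cut, one
#' sentinel per cluster is drawn, and each classifier family undergoes a
#' random hyperparameter search with cross-validated F1. The chosen cell is
#' the argmax of mean CV F1 (ties broken toward the lower threshold, then
#' the family order supplied). Clustering, sentinel selection,
#' standardization and tuning use training samples only.
#'
#' @param m log2-scale \linkS4class{QuantMatrix} (cleaned).
#' @param info sample metadata (two groups).
#' @param split a \code{SplitSpec} from \code{\link{stratifiedSplit}}.
#' @param families character subset of GB, SVC, RF, ET, LR, KNN.
#' @param thresholds numeric linkage distances (default 0 to 5 by 0.25).
#' @param n_iter random-search iterations per cell.
#' @param k_folds CV folds.
#' @param seed integer seed.
#' @param positive positive-class label; default the minority class.
#' @param absolute use 1 - |rho| dissimilarities.
#' @return A \linkS4class{SweepResult}.
#' @export
linkageSweep <- function(m, info, split,
                         families = c("GB", "SVC", "RF", "ET", "LR", "KNN"),
                         thresholds = seq(0, 5, by = 0.25),
                         n_iter = 25L, k_folds = 5L, seed = 1L,
                         positive = NULL, absolute = FALSE) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  stopifnot(inherits(split, "SplitSpec"))
  train <- split$train_ids
  grp <- setNames(as.character(info$group), info$sample_id)
  y_train <- unname(grp[train])
  if (is.null(positive)) positive <- minorityClass(grp[info$sample_id])

  rho <- spearmanMatrix(m, train)
  d <- correlationToCondensedDistance(rho, absolute = absolute)
  merges <- wardLinkage(d)
  fid <- featureIds(m)
  Xall <- t(quantValues(m))  # samples x features

  rows <- list()
  sentinel_sets <- list()
  label_sets <- list()
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    labels <- cutAtThreshold(merges, t)
    sent <- selectSentinels(labels, fid, seed = deriveSeed(seed, 7000L + ti))
    if (length(sent) < 2L)
      warning(sprintf("threshold %.3g yields %d cluster(s)", t, length(sent)))
    sentinel_sets[[as.character(t)]] <- sent
    label_sets[[as.character(t)]] <- labels
    Xt <- Xall[train, sent, drop = FALSE]
    for (fi in seq_along(families)) {
      fam <- families[fi]
      res <- randomHyperparameterSearch(
        fam, Xt, y_train, n_iter = n_iter, k_folds = k_folds,
        seed = deriveSeed(seed, 1000L * ti + fi), positive = positive)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, threshold = t, n_clusters = length(sent),
        mean_cv_f1 = res$mean_cv_f1, stringsAsFactors = FALSE)
      rows[[length(rows)]]$best_params <- I(list(res$best_params))
    }
  }
  tab <- do.call(rbind, rows)
  fam_rank <- match(tab$family, families)
  ord <- order(-tab$mean_cv_f1, tab$threshold, fam_rank)
  chosen <- ord[1]

  t_star <- tab$threshold[chosen]
  labels_star <- label_sets[[as.character(t_star)]]
  model <- new("ClusterModel", featureIds = fid, distances = as.numeric(d),
               merges = merges, threshold = t_star,
               labels = setNames(labels_star, fid),
               sentinels = sentinel_sets[[as.character(t_star)]],
               seed = deriveSeed(seed, 7000L + match(t_star, thresholds)))
  new("SweepResult", table = tab, chosen = as.integer(chosen),
      clusterTree = model, sentinelSets = sentinel_sets)
}

#' Refit the chosen model on all training data and evaluate held-out samples
#'
#' Fits the chosen family/hyperparameters once on the full training
#' partition (standardization statistics from training samples only) and
#' reports minority-class metrics on the held-out partition.
#'
#' @param sweep a \linkS4class{SweepResult}, or NULL if \code{family} and
#'   \code{params} are given directly.
#' @param m log2-scale \linkS4class{QuantMatrix}.
#' @param info sample metadata.
#' @param split the \code{SplitSpec} used for the sweep.
#' @param positive positive-class label; default the minority class.
#' @param seed integer seed (refit determinism).
#' @return \code{list(report = TestReport, fit = fitted bundle,
#'   sentinels = feature ids used)}.
#' @export
refitAndEvaluate <- function(sweep, m, info, split, positive = NULL,
                             seed = 1L) {
  stopifnot(is(sweep, "SweepResult"))
  cell <- chosenCell(sweep)
  sent <- sentinels(sweep@clusterTree)
  grp <- setNames(as.character(info$group), info$sample_id)
  if (is.null(positive)) positive <- minorityClass(grp[info$sample_id])
  Xall <- t(quantValues(m))
  X_train <- Xall[split$train_ids, sent, drop = FALSE]
  X_test <- Xall[split$test_ids, sent, drop = FALSE]
  y_train <- unname(grp[split$train_ids])
  y_test <- unname(grp[split$test_ids])
  if (length(unique(y_test)) < 2L) stop("a class is absent from the test set")
  bundle <- fitClassifier(cell$family, X_train, y_train,
                          cell$best_params[[1]], positive,
                          seed = deriveSeed(seed, 31L))
  pred <- predictFit(bundle, X_test)
  mets <- classificationMetrics(y_test, pred$labels, positive)
  report <- new("TestReport",
                accuracy = unname(mets["accuracy"]),
                precision = unname(mets["precision"]),
                recall = unname(mets["recall"]),
                f1 = unname(mets["f1"]),
                prAuc = prAuc(pred$scores, y_test, positive),
                positiveClass = positive)
  list(report = report, fit = bundle, sentinels = unname(sent))
}
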