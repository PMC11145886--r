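make_info <- function(n_a, n_b, seed = 1) {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n_a + n_b)),
    group = rep(c("TypeB", "DTAA"), c(n_a, n_b)),
    age = 60, sex = "M", ethnicity = "E", batch = "b1",
    stringsAsFactors = FALSE)
}

test_that("stratified split hits exact per-class proportions", {
  info <- make_info(60, 40)
  sp <- stratifiedSplit(info, fraction = 0.8, seed = 1)
  grp <- setNames(info$group, info$sample_id)
  expect_identical(sum(grp[sp$test_ids] == "TypeB"), 12L)
  expect_identical(sum(grp[sp$test_ids] == "DTAA"), 8L)
  expect_identical(sort(c(sp$train_ids, sp$test_ids)), sort(info$sample_id))
  expect_identical(stratifiedSplit(info, 0.8, seed = 7),
                   stratifiedSplit(info, 0.8, seed = 7))
  info2 <- make_info(75, 62)
  sp2 <- stratifiedSplit(info2, 0.8, seed = 3)
  grp2 <- setNames(info2$group, info2$sample_id)
  expect_identical(sum(grp2[sp2$train_ids] == "TypeB") +
                     sum(grp2[sp2$test_ids] == "TypeB"), 75L)
  expect_identical(sum(grp2[sp2$train_ids] == "DTAA") +
                     sum(grp2[sp2$test_ids] == "DTAA"), 62L)
  expect_identical(length(sp2$test_ids), 27L)
  expect_error(stratifiedSplit(make_info(3, 1), 0.8, seed = 1), "too small")
})

test_that("classification metrics follow confusion-matrix arithmetic", {
  mets <- classificationMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
  expect_equal(unname(mets), c(0.75, 1, 0.5, 2 / 3))
  perfect <- classificationMetrics(c(1, 0, 1), c(1, 0, 1), positive = 1)
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  expect_warning(
    degen <- classificationMetrics(c(1, 0), c(0, 0), positive = 1),
    "precision")
  expect_equal(unname(degen[c("precision", "recall", "f1")]), c(0, 0, 0))
})

test_that("PR AUC is step-wise average precision", {
  expect_equal(prAuc(c(0.9, 0.8, 0.3), c(1, 0, 1), positive = 1),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(prAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), positive = 1), 1)
  expect_error(prAuc(c(0.5, 0.6), c(1, 1), positive = 1), "both classes")
  # tied scores are grouped at a single threshold
  expect_equal(prAuc(c(0.5, 0.5), c(1, 0), positive = 1), 0.5)
  # null scores: average precision concentrates near prevalence (with the
  # known small positive finite-sample bias of AP)
  set.seed(2)
  aps <- replicate(1000, prAuc(runif(40), rep(c(1, 0), 20), positive = 1))
  expect_lt(abs(mean(aps) - 0.5), 0.05)
})

test_that("random search is deterministic and respects n_iter", {
  set.seed(99)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("TypeB", "DTAA"), 30)
  one <- randomHyperparameterSearch("KNN", X, y, n_iter = 1, seed = 5)
  expect_length(one$best_params, 1)
  again <- randomHyperparameterSearch("KNN", X, y, n_iter = 1, seed = 5)
  expect_identical(one, again)
  expect_error(randomHyperparameterSearch("KNN", X, y, n_iter = 500),
               "n_iter")
  expect_error(randomHyperparameterSearch("nope", X, y, n_iter = 1),
               "unknown family")
})

test_that("separable data reaches perfect CV F1 for margin-based families", {
  set.seed(4)
  n <- 40
  y <- rep(c("TypeB", "DTAA"), each = n / 2)
  X <- cbind(f1 = ifelse(y == "DTAA", 5, -5) + rnorm(n, sd = 0.1),
             f2 = rnorm(n))
  for (fam in c("SVC", "LR")) {
    res <- randomHyperparameterSearch(fam, X, y, n_iter = 5, seed = 2)
    expect_equal(res$mean_cv_f1, 1.0, tolerance = 1e-12)
  }
})

test_that("all six families fit, predict and score", {
  set.seed(8)
  n <- 50
  y <- rep(c("TypeB", "DTAA"), c(30, 20))
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  X[y == "DTAA", 1] <- X[y == "DTAA", 1] + 2
  for (fam in c("GB", "SVC", "RF", "ET", "LR", "KNN")) {
    res <- randomHyperparameterSearch(fam, X, y, n_iter = 3, k_folds = 3,
                                      seed = 3)
    expect_true(res$mean_cv_f1 >= 0 && res$mean_cv_f1 <= 1)
    bundle <- ProteoSentinel:::fitClassifier(fam, X, y, res$best_params,
                                             positive = "DTAA", seed = 1)
    pred <- ProteoSentinel:::predictFit(bundle, X)
    expect_length(pred$labels, n)
    expect_length(pred$scores, n)
    expect_true(all(pred$labels %in% c("TypeB", "DTAA")))
    expect_gt(prAuc(pred$scores, y, "DTAA"), 0.5)
  }
})

test_that("the linkage sweep covers the grid and prefers informative structure", {
  sim <- generateDataset(smallSimConfig(seed = 31))
  cl <- cleanPipeline(sim$quant, sim$samples)
  sp <- stratifiedSplit(cl$samples, 0.8, seed = 2)
  sw <- linkageSweep(cl$quant, cl$samples, sp, families = c("LR", "SVC"),
                     thresholds = c(0.5, 1.5), n_iter = 4, seed = 2)
  tab <- sweepTable(sw)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$family, c("LR", "SVC"))
  expect_setequal(tab$threshold, c(0.5, 1.5))
  expect_equal(chosenCell(sw)$mean_cv_f1, max(tab$mean_cv_f1))
  # single cell: chosen is that cell
  sw1 <- linkageSweep(cl$quant, cl$samples, sp, families = "LR",
                      thresholds = 1, n_iter = 2, seed = 2)
  expect_identical(nrow(sweepTable(sw1)), 1L)
  expect_identical(sw1@chosen, 1L)
})

test_that("duplicated features collapse into the same decorrelated clusters", {
  # appending an exact duplicate of every feature scales every positive Ward
  # merge height by exactly sqrt(2) (cluster sizes double everywhere), so
  # cluster counts are preserved at sqrt(2)-scaled thresholds
  sim <- generateDataset(smallSimConfig(seed = 17))
  cl <- cleanPipeline(sim$quant, sim$samples)
  m <- cl$quant
  v <- quantValues(m)
  dup <- rbind(v, `rownames<-`(v, paste0(rownames(v), "_dup")))
  m_dup <- QuantMatrix(dup, scale = "log2")
  sp <- stratifiedSplit(cl$samples, 0.8, seed = 4)
  train <- sp$train_ids
  merges <- wardLinkage(correlationToCondensedDistance(spearmanMatrix(m, train)))
  merges_dup <- wardLinkage(
    correlationToCondensedDistance(spearmanMatrix(m_dup, train)))
  n <- nrow(v)
  # first n merges pair each feature with its duplicate at height 0
  expect_equal(unname(merges_dup[1:n, "height"]), rep(0, n))
  expect_equal(unname(merges_dup[(n + 1):(2 * n - 1), "height"]),
               sqrt(2) * unname(merges[, "height"]), tolerance = 1e-8)
  for (t in c(0.5, 1, 2)) {
    k <- length(unique(cutAtThreshold(merges, t)))
    k_dup <- length(unique(cutAtThreshold(merges_dup, t * sqrt(2))))
    expect_identical(k_dup, k)
  }
})

test_that("no training-side quantity leaks information from test samples", {
  sim <- generateDataset(smallSimConfig(seed = 23))
  cl <- cleanPipeline(sim$quant, sim$samples)
  m <- cl$quant; info <- cl$samples
  sp <- stratifiedSplit(info, 0.8, seed = 6)
  v <- quantValues(m)
  v[, sp$test_ids] <- v[, sp$test_ids] + matrix(
    rnorm(length(v[, sp$test_ids]), sd = 3), nrow(v))
  m_pert <- QuantMatrix(v, scale = "log2")
  args <- list(info = info, split = sp, families = c("LR", "KNN"),
               thresholds = c(0.75, 1.5), n_iter = 3, seed = 6)
  sw_a <- do.call(linkageSweep, c(list(m), args))
  sw_b <- do.call(linkageSweep, c(list(m_pert), args))
  expect_identical(sw_a@clusterTree@merges, sw_b@clusterTree@merges)
  expect_identical(sw_a@clusterTree@sentinels, sw_b@clusterTree@sentinels)
  expect_identical(sweepTable(sw_a)$mean_cv_f1, sweepTable(sw_b)$mean_cv_f1)
  expect_identical(chosenCell(sw_a), chosenCell(sw_b))
  ev_a <- refitAndEvaluate(sw_a, m, info, sp, seed = 6)
  ev_b <- refitAndEvaluate(sw_b, m_pert, info, sp, seed = 6)
  expect_identical(ev_a$fit$scaler, ev_b$fit$scaler)
  # and the scaler really is the train-partition statistics
  sent <- sentinels(sw_a@clusterTree)
  Xtr <- t(quantValues(m))[sp$train_ids, sent, drop = FALSE]
  expect_equal(ev_a$fit$scaler$center, colMeans(Xtr))
})

test_that("refit evaluation returns a coherent test report", {
  sim <- generateDataset(smallSimConfig(seed = 41))
  cl <- cleanPipeline(sim$quant, sim$samples)
  sp <- stratifiedSplit(cl$samples, 0.8, seed = 3)
  sw <- linkageSweep(cl$quant, cl$samples, sp, families = "SVC",
                     thresholds = 1, n_iter = 5, seed = 3)
  ev <- refitAndEvaluate(sw, cl$quant, cl$samples, sp, seed = 3)
  expect_s4_class(ev$report, "TestReport")
  mets <- reportMetrics(ev$report)
  expect_true(all(mets >= 0 & mets <= 1))
  expect_identical(ev$report@positiveClass, "DTAA")  # minority class
  expect_identical(sort(ev$sentinels),
                   sort(unname(sentinels(sw@clusterTree))))
})
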