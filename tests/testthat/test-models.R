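test_that("train/test split is disjoint, exhaustive, seeded and seed-sensitive", {
  ids <- sprintf("BC%03d", 1:100)
  sp <- splitTrainTest(ids, testSize = 0.2, seed = 42)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- splitTrainTest(ids, testSize = 0.2, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- splitTrainTest(ids, testSize = 0.2, seed = 43)
  expect_false(setequal(sp$test, sp3$test))
  expect_warning(splitTrainTest(ids, 0.2, 42,
                                labels = c("positive", rep("negative", 99))),
                 "absent from")
})

test_that("stratified folds preserve class proportions within one cell", {
  y <- rep(c("positive", "negative"), c(30, 70))
  fold <- stratifiedFolds(y, k = 5, seed = 1)
  for (f in 1:5) {
    held <- y[fold == f]
    expect_equal(sum(held == "positive"), 6, tolerance = 0)
    expect_equal(length(held), 20)
  }
  expect_identical(fold, stratifiedFolds(y, k = 5, seed = 1))
  expect_error(stratifiedFolds(rep(c("positive", "negative"), c(3, 97)), k = 5),
               "at least k members")
})

test_that("CV scoring on cleanly separable synthetic data is near-perfect", {
  td <- simTrainingData(nCells = 400, nGenes = 200, seed = 5, de_log2fc = 4)
  hp <- list(model_kind = "svm_rbf", t_de_upper = 1.5, t_de_lower = -1.5,
             p_hn = 0.05, c_svm = 10, gamma = 0.02)
  sc <- stratifiedKFoldScore(hp, td$train, k = 5, seed = 1)
  expect_identical(sc$metric, "accuracy")
  expect_equal(sc$mean, mean(sc$folds))
  expect_gte(sc$mean, 0.99)
  # same seed -> identical fold assignment and scores
  sc2 <- stratifiedKFoldScore(hp, td$train, k = 5, seed = 1)
  expect_identical(sc, sc2)
})

test_that("the GP optimizer solves a 1-D quadratic and honors its stopping rule", {
  fn <- function(x) -(x[["u"]] - 0.62)^2
  opt <- gpOptimize(fn, c(u = 0), c(u = 1), maxIter = 15, seed = 3)
  expect_lt(abs(opt$par[["u"]] - 0.62), 0.05)
  # ei_tol = Inf stops right after the 5-point design
  opt2 <- gpOptimize(fn, c(u = 0), c(u = 1), maxIter = 15, eiTol = Inf,
                     seed = 3)
  expect_equal(nrow(opt2$trace), 5)
  expect_true(all(opt2$trace$phase == "design"))
  # determinism of the full trace
  opt3 <- gpOptimize(fn, c(u = 0), c(u = 1), maxIter = 15, seed = 3)
  expect_identical(opt$trace, opt3$trace)
})

test_that("RBF SVM solves the XOR toy that defeats the linear kernel", {
  set.seed(8)
  corners <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  X <- corners[rep(1:4, each = 10), ] + matrix(rnorm(80, 0, 0.05), 40, 2)
  y <- rep(c("negative", "negative", "positive", "positive"), each = 10)
  rbf <- svmFit(X, y, kernel = "rbf", C = 10, gamma = 1)
  lin <- svmFit(X, y, kernel = "linear", C = 10)
  accOf <- function(fit) mean((svmDecision(fit, X) >= 0) == (y == "positive"))
  expect_equal(accOf(rbf), 1.0)
  expect_lte(accOf(lin), 0.75)
})

test_that("every classifier family fits, predicts and is seed-deterministic", {
  td <- simTrainingData(nCells = 300, nGenes = 200, seed = 9, de_log2fc = 2.5)
  tr <- td$train
  fs <- local({
    de <- qpGlmDe(tr$corrected, tr$y)
    corr <- spearmanScreen(tr$residuals, pHn = 0.05)
    selectFeatures(de, corr, 1.5, -1.5, 0.05)
  })
  X <- t(tr$residuals[featureGenes(fs), ])
  hp <- list(c_lr = 1, c_svm = 5, gamma = 0.05, n_layers = 1, n_nodes = 32,
             eta = 5e-3, rho = 0.2, t_de_upper = 1.5, t_de_lower = -1.5,
             p_hn = 0.05)
  for (kind in c("lr", "svm_linear", "svm_rbf", "stack", "mlp")) {
    m1 <- fitFinal(kind, c(hp, list(model_kind = kind)), tr,
                   featureSet = fs, seed = 4)
    m2 <- fitFinal(kind, c(hp, list(model_kind = kind)), tr,
                   featureSet = fs, seed = 4)
    p1 <- predictCells(m1, X)
    p2 <- predictCells(m2, X)
    expect_identical(p1, p2, label = kind)
    expect_gte(mean((p1$label == "positive") == (tr$y == "positive")), 0.9)
    # predicting on the training matrix reproduces the stored accuracy
    expect_equal(mean((p1$label == "positive") == (tr$y == "positive")),
                 m1@metadata$train_accuracy, label = kind)
  }
})

test_that("a stack whose base models agree reproduces their common prediction", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- factor(rep(c("negative", "positive"), each = 30),
              levels = c("negative", "positive"))
  fit <- CiteGate:::.stackFit(X, y, list(c_lr = 1, c_svm = 10, gamma = 0.5))
  baseLr <- CiteGate:::.lrPredict(fit$lr, X) >= 0.5
  baseSvm <- svmDecision(fit$svm, X) >= 0
  expect_identical(baseLr, baseSvm)     # trivially separable: they agree
  meta <- CiteGate:::.stackScore(fit, X)
  expect_identical(meta$label, baseLr)
})

test_that("MLP training reduces the loss and dropout is off at prediction", {
  set.seed(12)
  X <- rbind(matrix(rnorm(200, -1), 100, 2), matrix(rnorm(200, 1), 100, 2))
  y <- rep(c("negative", "positive"), each = 100)
  fit <- mlpFit(X, y, nLayers = 2, nNodes = 32, eta = 5e-3, rho = 0.3,
                seed = 1)
  expect_lt(mean(tail(fit$loss, 3)), mean(head(fit$loss, 3)))
  p1 <- mlpPredict(fit, X)
  expect_identical(p1, mlpPredict(fit, X))   # deterministic at inference
  expect_gte(mean((p1 >= 0.5) == (y == "positive")), 0.9)
})

test_that("model archives round-trip bit-identically and detect corruption", {
  td <- simTrainingData(nCells = 250, nGenes = 200, seed = 14, de_log2fc = 2.5)
  hp <- list(model_kind = "svm_rbf", t_de_upper = 1.5, t_de_lower = -1.5,
             p_hn = 0.05, c_svm = 10, gamma = 0.05)
  model <- fitFinal("svm_rbf", hp, td$train, seed = 2,
                    prep = S4Vectors::metadata(td$sce)$normalization)
  X <- t(td$train$residuals[featureGenes(featureSet(model)), ])
  dir <- file.path(withr::local_tempdir(), "model")
  saveModel(model, dir)
  back <- readModel(dir)
  expect_identical(predictCells(back, X), predictCells(model, X))
  # truncate the payload -> hash mismatch
  rds <- file.path(dir, "model.rds")
  raw <- readBin(rds, "raw", file.size(rds))
  writeBin(raw[1:(length(raw) - 10)], rds)
  expect_error(readModel(dir), "manifest hash mismatch")
  expect_error(readModel(withr::local_tempdir()), "not a model archive")
})

test_that("evaluation metrics match hand-computed confusion counts", {
  # TP=3 FP=1 FN=2 TN=4
  truth <- c(rep("positive", 5), rep("negative", 5))
  pred <- c("positive", "positive", "positive", "negative", "negative",
            "positive", "negative", "negative", "negative", "negative")
  m <- evaluatePredictions(truth, pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(unname(m$confusion), c(3, 1, 2, 4))

  # perfect predictions with a separating score
  truth2 <- rep(c("positive", "negative"), each = 10)
  sc <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  p2 <- evaluatePredictions(truth2, truth2, score = sc)
  expect_equal(p2$accuracy, 1)
  expect_equal(p2$auc, 1)
  expect_equal(p2$average_precision, 1)

  # no positive truth: precision/recall undefined, not zero
  m0 <- evaluatePredictions(rep("negative", 8),
                            rep(c("negative", "positive"), 4))
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$recall))

  # per-cluster misclassification table
  cl <- rep(c("c1", "c2"), 5)
  mc <- evaluatePredictions(truth, pred, clusters = cl)
  expect_equal(sort(mc$cluster_misclassification$cluster), c("c1", "c2"))
})

test_that("coin-flip predictions on balanced labels sit near chance", {
  set.seed(2718)
  n <- 10000
  truth <- rep(c("positive", "negative"), each = n / 2)
  sc <- runif(n)
  pred <- ifelse(sc >= 0.5, "positive", "negative")
  m <- evaluatePredictions(truth, pred, score = sc)
  expect_gt(m$accuracy, 0.48); expect_lt(m$accuracy, 0.52)
  expect_gt(m$auc, 0.48); expect_lt(m$auc, 0.52)
})

test_that("empty feature sets score zero so the optimizer avoids them", {
  td <- simTrainingData(nCells = 250, nGenes = 200, seed = 25,
                        de_log2fc = 2)
  hp <- list(model_kind = "svm_rbf", t_de_upper = 3.9, t_de_lower = -3.9,
             p_hn = 1e-6, c_svm = 1, gamma = 0.1)
  sc <- stratifiedKFoldScore(hp, td$train, k = 5, seed = 1)
  expect_equal(sc$mean, 0)
})
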