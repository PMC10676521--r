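#' Shuffle split into training and testing cells
#'
#' Plain (unstratified) shuffle split; the pipeline default mirrors the
#' training recipe: test size 0.2, seed 42. The test side takes
#' \code{ceiling(n * testSize)} cells.
#'
#' @param cellIds character vector of barcodes.
#' @param testSize fraction held out (default 0.2).
#' @param seed integer seed (default 42).
#' @param labels optional per-cell labels; a warning is raised when a class
#'   is absent from either side.
#' @return list(train = barcodes, test = barcodes), disjoint and exhaustive.
#' @export
splitTrainTest <- function(cellIds, testSize = 0.2, seed = 42, labels = NULL) {
  n <- length(cellIds)
  if (n < 2L) .cgStop("need at least 2 cells to split")
  set.seed(seed)
  nTest <- ceiling(n * testSize)
  testIdx <- sample.int(n, nTest)
  out <- list(train = cellIds[-testIdx], test = cellIds[testIdx])
  if (!is.null(labels)) {
    labels <- stats::setNames(as.character(labels), cellIds)
    for (side in names(out)) {
      missing <- setdiff(unique(labels), unique(labels[out[[side]]]))
      if (length(missing))
        warning("class ", paste(missing, collapse = ","),
                " absent from the ", side, " side")
    }
  }
  out
}

#' Stratified k-fold assignment
#'
#' Shuffles within class (seeded) and deals cells round-robin so every fold
#' preserves the class proportions within rounding.
#'
#' @param labels per-cell class labels.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @return integer fold id per cell (1..k).
#' @export
stratifiedFolds <- function(labels, k = 5, seed = 0) {
  labels <- as.character(labels)
  if (any(table(labels) < k))
    .cgStop("every class needs at least k members")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Bundle labeled training data for model fitting
#'
#' Restricts the normalized object to the given cells (dropping
#' \code{excluded} label cells) and carries the matrices the classifier
#' stack needs.
#'
#' @param sce normalized SingleCellExperiment (assays \code{residuals},
#'   \code{corrected}).
#' @param adtLabels an \linkS4class{AdtLabels}.
#' @param cells barcodes to keep (e.g. the training split); NULL = all.
#' @param anchor anchor gene for the correlation screen.
#' @return list with \code{residuals}, \code{corrected} (genes x cells),
#'   \code{y} (factor negative/positive), \code{cellIds}, \code{anchor}.
#' @export
makeTrainingData <- function(sce, adtLabels, cells = NULL,
                             anchor = "HNRNPLL") {
  lab <- stats::setNames(as.character(adtLabels@labels), adtLabels@cellIds)
  keep <- intersect(if (is.null(cells)) colnames(sce) else cells,
                    names(lab)[lab != "excluded"])
  if (length(keep) < 4L) .cgStop("too few labeled cells")
  list(residuals = as.matrix(SummarizedExperiment::assay(sce, "residuals"))[, keep, drop = FALSE],
       corrected = as.matrix(SummarizedExperiment::assay(sce, "corrected"))[, keep, drop = FALSE],
       y = factor(lab[keep], levels = c("negative", "positive")),
       cellIds = keep, anchor = anchor)
}

## selection rule of the correlation screen applied to a cached CorrResult
.corrSelect <- function(result, anchor, pHn) {
  absRho <- abs(result$rho)
  ok <- !is.na(result$rho) & result$gene != anchor
  cut <- stats::quantile(absRho[!is.na(absRho)], probs = 1 - pHn,
                         names = FALSE, type = 7)
  sel <- result$gene[ok & absRho >= cut & result$p_value < 0.05]
  sel[order(-absRho[match(sel, result$gene)], sel)]
}

## per-fold (or full-set) DE + correlation statistics; computed once because
## the tunable thresholds only slice these tables
.foldStats <- function(train, k, seed) {
  fold <- stratifiedFolds(train$y, k = k, seed = seed)
  stats <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    list(de = qpGlmDe(train$corrected[, tr, drop = FALSE], train$y[tr]),
         corr = spearmanScreen(train$residuals[, tr, drop = FALSE],
                               anchor = train$anchor, pHn = 0.5)$result)
  })
  list(fold = fold, stats = stats)
}

.featureSetFrom <- function(de, corrResult, anchor, hp) {
  selectFeatures(de, list(selected = .corrSelect(corrResult, anchor, hp$p_hn)),
                 tDeUpper = hp$t_de_upper, tDeLower = hp$t_de_lower,
                 pHn = hp$p_hn)
}

#' Stratified cross-validation score of one hyperparameter point
#'
#' For each of the k folds the feature set is re-derived from that fold's
#' training portion at the candidate thresholds (no information from the
#' held-out fold is used), the classifier is fitted and the held-out fold is
#' scored. Metric: accuracy for lr/svm/stack, binary cross-entropy for the
#' MLP. An empty feature set in any fold scores 0 (worst) so the optimizer
#' steers away.
#'
#' @param hp named list of hyperparameters including \code{model_kind} and,
#'   unless a fixed \code{featureSet} is given, \code{t_de_upper},
#'   \code{t_de_lower}, \code{p_hn}.
#' @param train from \code{\link{makeTrainingData}}.
#' @param k folds (default 5).
#' @param seed fold-assignment / fit seed.
#' @param featureSet optional fixed \linkS4class{FeatureSet} (the MLP reuses
#'   the features optimized for an SVM).
#' @param cache internal: precomputed \code{.foldStats}.
#' @return list(folds = per-fold values, mean, metric).
#' @export
stratifiedKFoldScore <- function(hp, train, k = 5, seed = 0,
                                 featureSet = NULL, cache = NULL) {
  if (is.null(cache) && is.null(featureSet)) cache <- .foldStats(train, k, seed)
  fold <- if (!is.null(cache)) cache$fold else stratifiedFolds(train$y, k, seed)
  isMlp <- identical(hp$model_kind, "mlp")
  vals <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fs <- if (!is.null(featureSet)) featureSet else tryCatch(
      .featureSetFrom(cache$stats[[f]]$de, cache$stats[[f]]$corr,
                      train$anchor, hp),
      citegate_empty_features = function(e) NULL)
    if (is.null(fs)) { vals[f] <- if (isMlp) Inf else 0; next }
    Xtr <- t(train$residuals[fs@genes, tr, drop = FALSE])
    Xte <- t(train$residuals[fs@genes, !tr, drop = FALSE])
    fit <- .coreFit(hp$model_kind, Xtr, train$y[tr], hp, seed = seed + f)
    sc <- .coreScore(hp$model_kind, fit, Xte)
    yte <- train$y[!tr] == "positive"
    if (isMlp) {
      p <- pmin(pmax(sc$prob, 1e-12), 1 - 1e-12)
      vals[f] <- -mean(yte * log(p) + (1 - yte) * log(1 - p))
    } else {
      vals[f] <- mean(sc$label == yte)
    }
  }
  list(folds = vals, mean = mean(vals),
       metric = if (isMlp) "binary_cross_entropy" else "accuracy")
}

#' Hyperparameter search boxes
#'
#' The per-classifier boxes: tDE upper in (1,4), lower in (-4,-1), Phn in
#' (1e-6, 0.1), C_SVM in (1e-6, 100), gamma in (1e-6, 2), C_LR in (1e-6, 2),
#' N_layers in 1..3, N_nodes in 16..128, eta in (1e-4, 0.01), dropout in
#' (0.1, 0.5).
#'
#' @param modelKind classifier family.
#' @return list(lower, upper, integer) of named bounds.
#' @export
defaultBounds <- function(modelKind) {
  feat <- list(lower = c(t_de_upper = 1, t_de_lower = -4, p_hn = 1e-6),
               upper = c(t_de_upper = 4, t_de_lower = -1, p_hn = 0.1))
  add <- switch(modelKind,
    lr = list(lower = c(c_lr = 1e-6), upper = c(c_lr = 2)),
    svm_linear = list(lower = c(c_svm = 1e-6), upper = c(c_svm = 100)),
    svm_rbf = list(lower = c(c_svm = 1e-6, gamma = 1e-6),
                   upper = c(c_svm = 100, gamma = 2)),
    stack = list(lower = c(c_svm = 1e-6, gamma = 1e-6, c_lr = 1e-6),
                 upper = c(c_svm = 100, gamma = 2, c_lr = 2)),
    mlp = list(lower = c(n_layers = 1, n_nodes = 16, eta = 1e-4, rho = 0.1),
               upper = c(n_layers = 3, n_nodes = 128, eta = 0.01, rho = 0.5)),
    .cgStop("unknown modelKind"))
  if (modelKind == "mlp")
    return(list(lower = add$lower, upper = add$upper,
                integer = c("n_layers", "n_nodes")))
  list(lower = c(feat$lower, add$lower), upper = c(feat$upper, add$upper),
       integer = character(0))
}

#' Joint Bayesian optimization of thresholds and hyperparameters
#'
#' Tunes the feature-selection thresholds together with the classifier
#' hyperparameters (for the MLP: network parameters only, on a fixed feature
#' set) by maximizing the stratified k-fold score with
#' \code{\link{gpOptimize}} (Matern-5/2 GP surrogate, expected improvement,
#' at most \code{maxIter} iterations past the 5-point design or until EI <
#' \code{eiTol}). Per-fold DE and correlation tables are computed once:
#' the thresholds only slice them.
#'
#' @inheritParams stratifiedKFoldScore
#' @param modelKind classifier family.
#' @param bounds optional override of \code{\link{defaultBounds}}.
#' @param maxIter,eiTol optimizer budget (defaults 30 and 1e-6).
#' @return list(hp = best hyperparameters (named list incl. model_kind),
#'   value = best CV mean, trace = evaluation trace).
#' @export
bayesOptimize <- function(modelKind, train, bounds = NULL, maxIter = 30,
                          eiTol = 1e-6, seed = 0, k = 5, featureSet = NULL) {
  if (modelKind == "mlp" && is.null(featureSet))
    .cgStop("the MLP reuses SVM-optimized features: supply featureSet")
  if (is.null(bounds)) bounds <- defaultBounds(modelKind)
  cache <- if (is.null(featureSet)) .foldStats(train, k, seed) else NULL
  sign <- if (modelKind == "mlp") -1 else 1       # maximize -BCE for the MLP
  objective <- function(x) {
    hp <- c(as.list(x), list(model_kind = modelKind))
    sc <- stratifiedKFoldScore(hp, train, k = k, seed = seed,
                               featureSet = featureSet, cache = cache)
    sign * sc$mean
  }
  opt <- gpOptimize(objective, bounds$lower, bounds$upper,
                    integerDims = bounds$integer, maxIter = maxIter,
                    eiTol = eiTol, seed = seed)
  if (all(opt$trace$value == 0))
    .cgStop("optimization degenerate: every evaluation scored 0")
  list(hp = c(as.list(opt$par), list(model_kind = modelKind)),
       value = sign * opt$value, trace = opt$trace)
}

## ---- core fits per classifier family --------------------------------------

.coreFit <- function(kind, X, y, hp, seed = 0) {
  switch(kind,
    lr = .lrFit(X, y, C = hp$c_lr),
    svm_linear = svmFit(X, y, kernel = "linear", C = hp$c_svm),
    svm_rbf = svmFit(X, y, kernel = "rbf", C = hp$c_svm, gamma = hp$gamma),
    stack = .stackFit(X, y, hp),
    mlp = mlpFit(X, y, nLayers = hp$n_layers, nNodes = hp$n_nodes,
                 eta = hp$eta, rho = hp$rho, seed = seed),
    .cgStop("unknown modelKind"))
}

## score = decision value (SVM) or probability (others); label = logical
.coreScore <- function(kind, fit, X) {
  switch(kind,
    lr = {
      p <- .lrPredict(fit, X)
      list(prob = p, score = p, label = p >= 0.5)
    },
    svm_linear = ,
    svm_rbf = {
      d <- svmDecision(fit, X)
      list(prob = NULL, score = d, label = d >= 0)
    },
    stack = .stackScore(fit, X),
    mlp = {
      p <- mlpPredict(fit, X)
      list(prob = p, score = p, label = p >= 0.5)
    })
}

## sklearn-style L2 logistic regression: lambda = 1/(C n), no standardization
.lrFit <- function(X, y, C = 1) {
  if (length(unique(y)) < 2L) .cgStop("training labels are single-class")
  n <- nrow(X)
  fit <- glmnet::glmnet(X, factor(y, levels = c("negative", "positive")),
                        family = "binomial", alpha = 0,
                        lambda = 1 / (max(C, 1e-12) * n),
                        standardize = FALSE, thresh = 1e-10)
  list(a0 = as.numeric(fit$a0), beta = as.numeric(fit$beta))
}

.lrPredict <- function(fit, X) {
  as.numeric(stats::plogis(fit$a0 + as.matrix(X) %*% fit$beta))
}

## meta logistic regression on the hard 0/1 predictions of LR + RBF SVM;
## the meta model is unpenalized and not tuned
.stackFit <- function(X, y, hp) {
  lr <- .lrFit(X, y, C = hp$c_lr)
  svm <- svmFit(X, y, kernel = "rbf", C = hp$c_svm, gamma = hp$gamma)
  z <- cbind(1, as.numeric(.lrPredict(lr, X) >= 0.5),
             as.numeric(svmDecision(svm, X) >= 0))
  yb <- as.numeric(y == "positive")
  meta <- suppressWarnings(stats::glm.fit(z, yb,
                                          family = stats::binomial()))
  cf <- meta$coefficients
  cf[!is.finite(cf)] <- 0
  list(lr = lr, svm = svm, meta = cf)
}

.stackScore <- function(fit, X) {
  z <- cbind(1, as.numeric(.lrPredict(fit$lr, X) >= 0.5),
             as.numeric(svmDecision(fit$svm, X) >= 0))
  p <- as.numeric(stats::plogis(z %*% fit$meta))
  list(prob = p, score = p, label = p >= 0.5)
}

#' Fit the final classifier on the full training set
#'
#' Re-derives the feature set from the entire training data at the optimized
#' thresholds (the MLP reuses a given feature set), fits the classifier with
#' the optimized hyperparameters, and packages everything needed at
#' inference time into a \linkS4class{TrainedModel}.
#'
#' @param modelKind classifier family.
#' @param hp named hyperparameter list (from \code{\link{bayesOptimize}}).
#' @param train from \code{\link{makeTrainingData}}.
#' @param prep preprocessing parameters saved from normalization
#'   (\code{metadata(sce)$normalization}) so queries can be put on the
#'   training scale.
#' @param seed fit seed.
#' @param featureSet fixed features for the MLP.
#' @param metadata extra metadata (optimizer trace, CV score) to carry.
#' @return a \linkS4class{TrainedModel}.
#' @export
fitFinal <- function(modelKind, hp, train, prep = list(), seed = 0,
                     featureSet = NULL, metadata = list()) {
  if (length(unique(train$y)) < 2L)
    .cgStop("training labels are single-class")
  .auditRecord("fit", train$cellIds)
  fs <- if (!is.null(featureSet)) featureSet else {
    de <- qpGlmDe(train$corrected, train$y)
    corr <- spearmanScreen(train$residuals, anchor = train$anchor,
                           pHn = hp$p_hn)
    selectFeatures(de, corr, tDeUpper = hp$t_de_upper,
                   tDeLower = hp$t_de_lower, pHn = hp$p_hn)
  }
  X <- t(train$residuals[fs@genes, , drop = FALSE])
  fit <- .coreFit(modelKind, X, train$y, hp, seed = seed)
  sc <- .coreScore(modelKind, fit, X)
  trainAcc <- mean(sc$label == (train$y == "positive"))
  thr <- if (modelKind %in% c("svm_linear", "svm_rbf")) 0 else 0.5
  new("TrainedModel", modelKind = modelKind, fit = list(core = fit, hp = hp),
      featureSet = fs, prep = prep, threshold = thr,
      metadata = c(metadata, list(seed = seed, train_accuracy = trainAcc,
                                  n_train = nrow(X))))
}

#' Predict scores and labels on a feature matrix
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param X cells x features matrix aligned to
#'   \code{featureGenes(featureSet(model))}.
#' @return data.frame(barcode, label, score); label is positive iff score is
#'   at or above the model's decision threshold.
#' @export
predictCells <- function(model, X) {
  sc <- .coreScore(model@modelKind, model@fit$core, X)
  data.frame(barcode = if (!is.null(rownames(X))) rownames(X)
                       else as.character(seq_len(nrow(X))),
             label = ifelse(sc$label, "positive", "negative"),
             score = sc$score, stringsAsFactors = FALSE)
}

#' Classification metrics
#'
#' Accuracy, precision and recall (positive class = marker-positive), the
#' ROC curve with AUC, the precision-recall curve with average precision,
#' and optionally a per-cluster misclassification table. With no positive
#' truth cells, precision and recall are reported as \code{NA} (undefined),
#' not 0.
#'
#' @param truth true labels (positive/negative; excluded cells must be
#'   dropped beforehand).
#' @param predicted predicted labels.
#' @param score optional continuous score for the curves.
#' @param clusters optional per-cell cluster assignment.
#' @return list of metrics.
#' @export
evaluatePredictions <- function(truth, predicted, score = NULL,
                                clusters = NULL) {
  t1 <- .asPm1(truth) > 0
  p1 <- .asPm1(predicted) > 0
  tp <- sum(t1 & p1); fp <- sum(!t1 & p1)
  fn <- sum(t1 & !p1); tn <- sum(!t1 & !p1)
  out <- list(
    accuracy = (tp + tn) / length(t1),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (!any(t1)) NA_real_ else tp / (tp + fn),
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn))
  if (!any(t1)) out$precision <- NA_real_   # undefined without positives
  if (!is.null(score) && any(t1) && any(!t1)) {
    out$roc <- .rocCurve(t1, score)
    out$auc <- .rankAuc(t1, score)
    pr <- .prCurve(t1, score)
    out$pr <- pr$curve
    out$average_precision <- pr$ap
  }
  if (!is.null(clusters)) {
    mis <- tapply(p1 != t1, clusters, mean)
    out$cluster_misclassification <- data.frame(
      cluster = names(mis), misclassification = as.numeric(mis))
  }
  out
}

.rankAuc <- function(truth, score) {
  r <- rank(score)
  nPos <- sum(truth); nNeg <- sum(!truth)
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.rocCurve <- function(truth, score) {
  ord <- order(-score)
  tpr <- cumsum(truth[ord]) / sum(truth)
  fpr <- cumsum(!truth[ord]) / sum(!truth)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

.prCurve <- function(truth, score) {
  ord <- order(-score)
  tp <- cumsum(truth[ord])
  prec <- tp / seq_along(tp)
  rec <- tp / sum(truth)
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(recall = rec, precision = prec), ap = ap)
}
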