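#' Default pipeline configuration
#'
#' Every tunable of the end-to-end training pipeline with its default:
#' exclusion margin 0.5 on the normalized-log ADT scale, 256 Otsu bins,
#' test size 0.2 with split seed 42, 5-fold stratified cross-validation,
#' at most 30 optimizer iterations past the design with EI tolerance 1e-6,
#' MLP epochs 15 / batch 32 (fixed inside \code{\link{mlpFit}}), anchor gene
#' HNRNPLL, covariates mito_frac + cc_diff regressed during normalization.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    model_kind = "svm_rbf",
    margin = 0.5, n_bins = 256,
    test_size = 0.2, split_seed = 42,
    k = 5, max_iter = 30, ei_tol = 1e-6,
    seed = 0,
    anchor = "HNRNPLL",
    gate = TRUE, qc = TRUE,
    min_ribo_frac = 0.05, min_cells_per_gene = 2,
    min_counts = NULL, max_mito_frac = NULL,
    regress = c("mito_frac", "cc_diff"),
    threads = 1)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' End-to-end training pipeline
#'
#' QC gates and filters, covariate computation, variance-stabilizing
#' normalization, Otsu labeling with margin exclusion, train/test split,
#' then — on the training split only — per-fold feature selection jointly
#' optimized with the classifier hyperparameters, a final refit on the whole
#' training split, and evaluation on both splits. An internal assertion
#' verifies that no test barcode reached differential expression,
#' correlation screening or model fitting (enable \code{\link{auditCells}}
#' for an inspectable trail).
#'
#' For \code{model_kind = "mlp"} the feature set is first optimized for an
#' RBF SVM (the pipeline's feature donor) and then held fixed while the
#' network hyperparameters are tuned.
#'
#' @param sce SingleCellExperiment with raw \code{counts}.
#' @param adt named ADT vector; when NULL, taken from \code{colData(sce)$adt}.
#' @param config from \code{\link{defaultConfig}}.
#' @return list: \code{model} (\linkS4class{TrainedModel}), \code{labels},
#'   \code{split}, \code{opt} (optimizer output), \code{eval_train},
#'   \code{eval_test}, \code{qc_reports}.
#' @export
trainPipeline <- function(sce, adt = NULL, config = defaultConfig()) {
  config <- utils::modifyList(defaultConfig(), config)
  qcReports <- list()
  if (is.null(adt)) {
    if (is.null(SummarizedExperiment::colData(sce)$adt))
      .cgStop("no ADT vector supplied or found in colData")
    adt <- stats::setNames(SummarizedExperiment::colData(sce)$adt,
                           colnames(sce))
  }
  if (isTRUE(config$gate)) {
    g <- gateTCells(sce)
    sce <- g$sce; qcReports$gate <- g$report
  }
  if (isTRUE(config$qc)) {
    f <- filterCellsGenes(sce, minRiboFrac = config$min_ribo_frac,
                          minCellsPerGene = config$min_cells_per_gene,
                          minCounts = config$min_counts,
                          maxMitoFrac = config$max_mito_frac)
    sce <- f$sce; qcReports$filters <- f$report
  }
  cov <- cellCycleScore(sce, seed = config$seed)
  sce <- normalizeRegress(sce, cov, regress = config$regress)

  adt <- adt[colnames(sce)]
  labels <- otsuLabels(adt, margin = config$margin, nBins = config$n_bins)

  lab <- as.character(labels@labels)
  labeledCells <- labels@cellIds[lab != "excluded"]
  split <- splitTrainTest(labeledCells, testSize = config$test_size,
                          seed = config$split_seed,
                          labels = lab[match(labeledCells, labels@cellIds)])

  train <- makeTrainingData(sce, labels, cells = split$train,
                            anchor = config$anchor)
  prep <- S4Vectors::metadata(sce)$normalization

  if (config$model_kind == "mlp") {
    donor <- bayesOptimize("svm_rbf", train, maxIter = config$max_iter,
                           eiTol = config$ei_tol, seed = config$seed,
                           k = config$k)
    de <- qpGlmDe(train$corrected, train$y)
    corr <- spearmanScreen(train$residuals, anchor = train$anchor,
                           pHn = donor$hp$p_hn)
    fs <- selectFeatures(de, corr, donor$hp$t_de_upper, donor$hp$t_de_lower,
                         donor$hp$p_hn)
    opt <- bayesOptimize("mlp", train, maxIter = config$max_iter,
                         eiTol = config$ei_tol, seed = config$seed,
                         k = config$k, featureSet = fs)
    model <- fitFinal("mlp", opt$hp, train, prep = prep, seed = config$seed,
                      featureSet = fs,
                      metadata = list(cv_mean = opt$value, trace = opt$trace,
                                      donor_hp = donor$hp))
  } else {
    opt <- bayesOptimize(config$model_kind, train, maxIter = config$max_iter,
                         eiTol = config$ei_tol, seed = config$seed,
                         k = config$k)
    model <- fitFinal(config$model_kind, opt$hp, train, prep = prep,
                      seed = config$seed,
                      metadata = list(cv_mean = opt$value, trace = opt$trace))
  }

  .assertNoLeakage(split$test)

  evalOn <- function(cells) {
    X <- t(alignFeatures(
      as.matrix(SummarizedExperiment::assay(sce, "residuals"))[, cells,
                                                               drop = FALSE],
      model@featureSet))
    pred <- predictCells(model, X)
    truth <- lab[match(cells, labels@cellIds)]
    evaluatePredictions(truth, pred$label, score = pred$score)
  }
  list(model = model, labels = labels, split = split, opt = opt,
       eval_train = evalOn(split$train), eval_test = evalOn(split$test),
       qc_reports = qcReports, sce = sce)
}

## hard assertion: when the audit trail is on, no test barcode may have
## reached DE, correlation screening or fitting
.assertNoLeakage <- function(testCells) {
  trail <- auditTrail()
  if (!length(trail)) return(invisible(TRUE))
  for (stage in names(trail)) {
    leak <- intersect(trail[[stage]], testCells)
    if (length(leak))
      stop("leakage: ", length(leak), " test barcodes reached stage ", stage)
  }
  invisible(TRUE)
}
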