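#' Restrict and order a matrix to a model's feature space
#'
#' Rows are reordered to the feature genes; genes absent from the input are
#' filled with zeros and counted — a warning is raised above 20% missing and
#' an error above 50%.
#'
#' @param mat genes x cells matrix (counts or residuals).
#' @param fs a \linkS4class{FeatureSet}.
#' @return features x cells matrix in \code{featureGenes(fs)} order, with an
#'   attribute \code{n_missing}.
#' @export
alignFeatures <- function(mat, fs) {
  genes <- fs@genes
  present <- intersect(genes, rownames(mat))
  missing <- setdiff(genes, rownames(mat))
  fracMissing <- length(missing) / length(genes)
  if (fracMissing > 0.5)
    .cgStop(sprintf("feature space mismatch: %.0f%% of model features absent",
                    100 * fracMissing))
  if (fracMissing > 0.2)
    warning(sprintf("%.0f%% of model features absent from input; filled with 0",
                    100 * fracMissing))
  out <- matrix(0, length(genes), ncol(mat),
                dimnames = list(genes, colnames(mat)))
  out[present, ] <- as.matrix(mat[present, , drop = FALSE])
  attr(out, "n_missing") <- length(missing)
  out
}

#' Predict marker status on a query count matrix
#'
#' Applies the stored preprocessing contract: library-size offsets are refit
#' on the query, while per-gene rates and dispersions come from training
#' (queries may lack the covariates, so covariate regression is skipped
#' unless covariates are supplied), then features are aligned and every cell
#' is scored. Deterministic.
#'
#' @param model a \linkS4class{TrainedModel} with stored \code{prep}.
#' @param sce SingleCellExperiment with raw \code{counts} (or an object that
#'   already carries a \code{residuals} assay when \code{normalize = FALSE}).
#' @param normalize apply the stored normalization (default TRUE).
#' @param covariates optional DataFrame to regress out, as in training.
#' @return data.frame(barcode, label, score), one row per input cell.
#' @export
inferCells <- function(model, sce, normalize = TRUE, covariates = NULL) {
  if (normalize) {
    counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
    prep <- model@prep
    if (is.null(prep$rate)) .cgStop("model carries no preprocessing parameters")
    lib <- colSums(counts)
    lib[lib == 0] <- 1
    common <- intersect(rownames(counts), names(prep$rate))
    res <- .nbResiduals(counts[common, , drop = FALSE], lib,
                        prep$rate[common], prep$phi[common], prep$clip)
    if (!is.null(covariates)) {
      X <- cbind(1, as.matrix(as.data.frame(
        covariates[colnames(counts), prep$regressed, drop = FALSE])))
      res <- res - (res %*% X %*% solve(crossprod(X))) %*% t(X)
    }
  } else {
    res <- SummarizedExperiment::assay(sce, "residuals")
  }
  Xq <- t(alignFeatures(res, model@featureSet))
  predictCells(model, Xq)
}

#' Save a trained model as a versioned archive
#'
#' Writes a directory with \code{model.rds} (the serialized model), the
#' feature set as JSON, and \code{manifest.json} recording the package
#' version, seed and the MD5 hash of the payload. \code{\link{readModel}}
#' refuses archives whose hash does not match.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path archive directory (created).
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rds <- file.path(path, "model.rds")
  saveRDS(model, rds, version = 3)
  featureSetJson(model@featureSet, file.path(path, "featureset.json"))
  manifest <- list(
    format = "citegate-model/1",
    package_version = as.character(utils::packageVersion("CiteGate")),
    model_kind = model@modelKind,
    seed = model@metadata$seed,
    md5 = unname(tools::md5sum(rds)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' Load and verify a model archive
#'
#' @param path archive directory from \code{\link{saveModel}}.
#' @return the \linkS4class{TrainedModel}.
#' @export
readModel <- function(path) {
  man <- file.path(path, "manifest.json")
  rds <- file.path(path, "model.rds")
  if (!file.exists(man) || !file.exists(rds))
    .cgStop("not a model archive (manifest.json/model.rds missing)")
  manifest <- jsonlite::fromJSON(man)
  if (!identical(manifest$format, "citegate-model/1"))
    .cgStop("unsupported model archive version")
  if (!identical(unname(tools::md5sum(rds)), manifest$md5))
    .cgStop("manifest hash mismatch: model archive is corrupt or truncated")
  readRDS(rds)
}

#' Write predictions as CSV
#' @param pred data.frame from \code{\link{inferCells}}
#' @param path output CSV
#' @export
writePredictions <- function(pred, path) {
  pred$score <- formatC(pred$score, digits = 10, format = "g")
  utils::write.csv(pred, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
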