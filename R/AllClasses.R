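#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Ternary ADT-derived marker labels
#'
#' Per-cell marker calls derived from an antibody-derived-tag (ADT) level by
#' Otsu thresholding with a symmetric exclusion margin: cells with
#' \eqn{adt \ge t^* + margin} are \code{positive}, cells with
#' \eqn{adt \le t^* - margin} are \code{negative}, and cells in the open
#' interval in between are \code{excluded} and never used for training.
#'
#' @slot labels factor with levels \code{negative}, \code{excluded},
#'   \code{positive}, one entry per cell.
#' @slot tStar numeric(1), the Otsu threshold on the ADT scale.
#' @slot margin numeric(1), non-negative exclusion half-width.
#' @slot nBins integer(1), histogram bin count used for thresholding.
#' @slot cellIds character, barcodes aligned with \code{labels}.
#' @exportClass AdtLabels
setClass("AdtLabels",
  representation(
    labels  = "factor",
    tStar   = "numeric",
    margin  = "numeric",
    nBins   = "integer",
    cellIds = "character"
  )
)

setValidity("AdtLabels", function(object) {
  msg <- NULL
  if (!all(levels(object@labels) %in% c("negative", "excluded", "positive")))
    msg <- c(msg, "labels must use levels negative/excluded/positive")
  if (length(object@labels) != length(object@cellIds))
    msg <- c(msg, "labels and cellIds lengths differ")
  if (length(object@margin) != 1L || object@margin < 0)
    msg <- c(msg, "margin must be a single non-negative number")
  if (length(object@tStar) != 1L || !is.finite(object@tStar))
    msg <- c(msg, "tStar must be a single finite number")
  if (is.null(msg)) TRUE else msg
})

#' Selected classifier features with provenance
#'
#' Ordered gene list assembled from two sources: differential expression
#' (provenance \code{"de"}) and Spearman correlation with the anchor gene
#' (provenance \code{"corr"}; genes found by both sources are \code{"both"}).
#' The thresholds that produced the set are carried along so that the same
#' selection can be re-derived on other data.
#'
#' @slot genes character, unique, deterministic order (DE genes by decreasing
#'   |log2FC|, then correlation-only genes by decreasing |rho|, ties broken
#'   lexicographically).
#' @slot provenance character aligned with \code{genes}, values in
#'   \code{de}, \code{corr}, \code{both}.
#' @slot tDeUpper,tDeLower numeric(1), log2 fold-change cutoffs (upper > 0 >
#'   lower).
#' @slot pHn numeric(1), top fraction of |rho| retained by the correlation
#'   screen.
#' @exportClass FeatureSet
setClass("FeatureSet",
  representation(
    genes      = "character",
    provenance = "character",
    tDeUpper   = "numeric",
    tDeLower   = "numeric",
    pHn        = "numeric"
  )
)

setValidity("FeatureSet", function(object) {
  msg <- NULL
  if (anyDuplicated(object@genes)) msg <- c(msg, "genes must be unique")
  if (length(object@genes) != length(object@provenance))
    msg <- c(msg, "genes and provenance lengths differ")
  if (!all(object@provenance %in% c("de", "corr", "both")))
    msg <- c(msg, "provenance values must be de/corr/both")
  if (length(object@tDeUpper) == 1L && length(object@tDeLower) == 1L &&
      !(object@tDeUpper > 0 && object@tDeLower < 0))
    msg <- c(msg, "need tDeUpper > 0 > tDeLower")
  if (is.null(msg)) TRUE else msg
})

#' A fitted marker classifier plus everything needed at inference time
#'
#' @slot modelKind one of \code{lr}, \code{svm_linear}, \code{svm_rbf},
#'   \code{stack}, \code{mlp}.
#' @slot fit opaque list of fitted parameters (kernel coefficients, network
#'   weights, ...), serializable.
#' @slot featureSet the \linkS4class{FeatureSet} the model consumes.
#' @slot prep list of preprocessing parameters saved from training
#'   (per-gene NB rates and dispersions, residual clip bound, median library
#'   size) so that query data can be put on the training scale.
#' @slot threshold numeric(1) decision threshold: 0.5 on probabilities for
#'   lr/stack/mlp, 0 on the decision value for SVMs.
#' @slot metadata list: seed, cross-validation scores, optimizer trace,
#'   training accuracy.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(
    modelKind  = "character",
    fit        = "list",
    featureSet = "FeatureSet",
    prep       = "list",
    threshold  = "numeric",
    metadata   = "list"
  )
)

setValidity("TrainedModel", function(object) {
  if (!object@modelKind %in% c("lr", "svm_linear", "svm_rbf", "stack", "mlp"))
    return("unknown modelKind")
  TRUE
})

#' Quality-control report
#'
#' Bookkeeping for every filtering stage: cells/genes in and out plus a
#' per-stage removal table, exportable as JSON.
#'
#' @slot nCellsIn,nCellsOut,nGenesIn,nGenesOut integer(1).
#' @slot steps data.frame with columns stage, axis (cell/gene), removed,
#'   parameters.
#' @exportClass QcReport
setClass("QcReport",
  representation(
    nCellsIn  = "integer",
    nCellsOut = "integer",
    nGenesIn  = "integer",
    nGenesOut = "integer",
    steps     = "data.frame"
  )
)

setValidity("QcReport", function(object) {
  cellrm <- sum(object@steps$removed[object@steps$axis == "cell"])
  generm <- sum(object@steps$removed[object@steps$axis == "gene"])
  if (object@nCellsIn - cellrm != object@nCellsOut)
    return("cell removal counts do not sum to in/out totals")
  if (object@nGenesIn - generm != object@nGenesOut)
    return("gene removal counts do not sum to in/out totals")
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn AdtLabels per-cell label factor
#' @param x an object
#' @export
markerLabels <- function(x) x@labels

#' @describeIn AdtLabels the Otsu threshold t*
#' @export
adtThreshold <- function(x) x@tStar

#' @describeIn AdtLabels the exclusion margin
#' @export
adtMargin <- function(x) x@margin

#' @describeIn FeatureSet ordered gene list
#' @export
featureGenes <- function(x) x@genes

#' @describeIn FeatureSet per-gene provenance
#' @export
featureProvenance <- function(x) x@provenance

#' @describeIn TrainedModel classifier family identifier
#' @export
modelKind <- function(x) x@modelKind

#' @describeIn TrainedModel the model's FeatureSet
#' @export
featureSet <- function(x) x@featureSet

## ---- show methods ----------------------------------------------------------

setMethod("show", "AdtLabels", function(object) {
  tab <- table(object@labels)
  cat("AdtLabels: t* =", format(object@tStar, digits = 4),
      " margin =", object@margin, "\n")
  cat("  ", paste(names(tab), as.integer(tab), sep = "=", collapse = "  "), "\n")
})

setMethod("show", "FeatureSet", function(object) {
  tab <- table(factor(object@provenance, c("de", "corr", "both")))
  cat("FeatureSet:", length(object@genes), "genes",
      sprintf("(de=%d corr=%d both=%d)", tab[["de"]], tab[["corr"]], tab[["both"]]), "\n")
  cat("  thresholds: tDE in [", format(object@tDeLower, digits = 4), ",",
      format(object@tDeUpper, digits = 4), "], Phn =",
      format(object@pHn, digits = 4), "\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel <", object@modelKind, "> on ",
      length(object@featureSet@genes), " features, decision threshold ",
      object@threshold, "\n", sep = "")
  if (!is.null(object@metadata$cv_mean))
    cat("  CV mean score:", format(object@metadata$cv_mean, digits = 4), "\n")
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport: cells ", object@nCellsIn, " -> ", object@nCellsOut,
      "; genes ", object@nGenesIn, " -> ", object@nGenesOut, "\n", sep = "")
  for (i in seq_len(nrow(object@steps)))
    cat(sprintf("  %-28s %-5s removed %d\n", object@steps$stage[i],
                object@steps$axis[i], object@steps$removed[i]))
})

#' Export a QcReport as JSON
#'
#' @param report a \linkS4class{QcReport}
#' @param path optional file; when NULL the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
qcReportJson <- function(report, path = NULL) {
  obj <- list(
    n_cells_in = report@nCellsIn, n_cells_out = report@nCellsOut,
    n_genes_in = report@nGenesIn, n_genes_out = report@nGenesOut,
    steps = report@steps
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

## internal constructor for QcReport
.qcReport <- function(nCellsIn, nCellsOut, nGenesIn, nGenesOut, steps) {
  new("QcReport",
      nCellsIn = as.integer(nCellsIn), nCellsOut = as.integer(nCellsOut),
      nGenesIn = as.integer(nGenesIn), nGenesOut = as.integer(nGenesOut),
      steps = steps)
}

## validation-error condition used by the CLI to pick exit code 2
.cgStop <- function(msg, class = "citegate_validation_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
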