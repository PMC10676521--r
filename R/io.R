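#' Read a cell x gene UMI count matrix
#'
#' Reads raw counts from a 10x-style MTX triplet (\code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv}, optionally gzipped) or from a
#' dense CSV/TSV with a header row, and returns a
#' \link[SingleCellExperiment]{SingleCellExperiment} with a \code{counts}
#' assay laid out genes x cells (the Bioconductor convention; on-disk
#' orientation is detected and normalized).
#'
#' Orientation of dense files is resolved from the identifiers: barcodes are
#' recognized as ACGT strings with an optional \code{-1} suffix. When neither
#' axis looks like barcodes, genes-as-rows is assumed (the field convention).
#'
#' @param path for \code{mtx10x}, the directory holding the triplet; for
#'   csv/tsv, the file.
#' @param format one of \code{"mtx10x"}, \code{"csv"}, \code{"tsv"}.
#' @return a \code{SingleCellExperiment} with integer-valued sparse
#'   \code{counts}, rownames = gene symbols, colnames = barcodes.
#' @export
readCounts <- function(path, format = c("mtx10x", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx10x") {
    mtx <- .firstExisting(path, c("matrix.mtx", "matrix.mtx.gz"))
    fea <- .firstExisting(path, c("features.tsv", "features.tsv.gz",
                                  "genes.tsv", "genes.tsv.gz"))
    bar <- .firstExisting(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    m <- Matrix::readMM(mtx)                      # genes x cells on disk
    feat <- utils::read.delim(fea, header = FALSE, stringsAsFactors = FALSE)
    genes <- feat[[min(2L, ncol(feat))]]          # 10x: column 2 = symbol
    cells <- readLines(bar)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      .cgStop("MTX dimensions do not match features/barcodes files")
    counts <- methods::as(m, "CsparseMatrix")
  } else {
    if (!file.exists(path)) .cgStop(paste("file not found:", path))
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      .cgStop(paste0("duplicate gene identifier: ", ids[duplicated(ids)][1]))
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- ids
    storage.mode(mat) <- "double"
    if (.looksLikeBarcodes(rownames(mat)) && !.looksLikeBarcodes(colnames(mat))) {
      mat <- t(mat)                               # cells were rows
    }
    genes <- rownames(mat)
    cells <- colnames(mat)
    counts <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  }
  .validateCounts(counts, genes, cells)
  dimnames(counts) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

#' Write a count matrix in a format readCounts() accepts
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param path directory (mtx10x) or file (csv/tsv).
#' @param format output format.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(sce, path, format = c("mtx10x", "csv", "tsv")) {
  format <- match.arg(format)
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (format == "mtx10x") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(id = rownames(counts), symbol = rownames(counts),
                 type = "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    m <- as.matrix(counts)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell ADT level vector
#'
#' Single-column CSV keyed by barcode (columns \code{barcode,adt}; a header
#' row is required). Values are expected on the provider's normalized,
#' log-transformed scale.
#'
#' @param path CSV file.
#' @return named numeric vector (names = barcodes).
#' @export
readAdt <- function(path) {
  if (!file.exists(path)) .cgStop(paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .cgStop("ADT CSV needs columns barcode,adt")
  v <- as.numeric(df[[2]])
  if (any(!is.finite(v))) .cgStop("ADT values must be finite")
  names(v) <- as.character(df[[1]])
  v
}

#' Attach an ADT vector to a SingleCellExperiment
#'
#' Aligns by barcode and stores the vector in \code{colData(sce)$adt}.
#'
#' @param sce SingleCellExperiment.
#' @param adt named numeric vector from \code{\link{readAdt}} (or unnamed, in
#'   matrix cell order).
#' @return the annotated SingleCellExperiment.
#' @export
attachAdt <- function(sce, adt) {
  if (!is.null(names(adt))) {
    miss <- setdiff(colnames(sce), names(adt))
    if (length(miss))
      .cgStop(paste0("ADT values missing for ", length(miss),
                     " barcodes (first: ", miss[1], ")"))
    adt <- adt[colnames(sce)]
  } else if (length(adt) != ncol(sce)) {
    .cgStop("unnamed ADT vector length differs from cell count")
  }
  SummarizedExperiment::colData(sce)$adt <- unname(adt)
  sce
}

.firstExisting <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  .cgStop(paste0("none of ", paste(names, collapse = "/"),
                 " found under ", dir))
}

.looksLikeBarcodes <- function(ids) {
  if (is.null(ids)) return(FALSE)
  mean(grepl("^[ACGTN]+(-[0-9]+)?$", ids)) > 0.9
}

.validateCounts <- function(counts, genes, cells) {
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    .cgStop(paste0("duplicate gene identifier: ", dup))
  }
  if (anyDuplicated(cells)) {
    dup <- cells[duplicated(cells)][1]
    .cgStop(paste0("duplicate cell barcode: ", dup))
  }
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  bad <- which(x < 0 | x != floor(x))
  if (length(bad)) {
    .cgStop(paste0("counts must be non-negative integers; first offending ",
                   "stored value is ", format(x[bad[1]])))
  }
  invisible(TRUE)
}
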