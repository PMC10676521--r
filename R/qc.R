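#' T-cell gating by lineage markers
#'
#' Keeps cells that express at least one CD3 complex gene (raw count > 0) and
#' do not express the B-cell exclusion gene (raw count == 0). \code{CD3Z} is
#' accepted as an alias for \code{CD247}. Marker genes absent from the matrix
#' are reported with a warning, not an error.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param cd3Genes CD3 complex gene symbols; default CD3D/CD3E/CD3G/CD247.
#' @param exclusionGene gene whose expression disqualifies a cell
#'   (default CD19).
#' @return list(sce = filtered object, report = \linkS4class{QcReport}).
#' @export
gateTCells <- function(sce,
                       cd3Genes = c("CD3D", "CD3E", "CD3G", "CD247"),
                       exclusionGene = "CD19") {
  counts <- SummarizedExperiment::assay(sce, "counts")
  genes <- rownames(counts)
  resolve <- function(g) {
    if (g == "CD3Z" && !("CD3Z" %in% genes) && "CD247" %in% genes) "CD247"
    else if (g == "CD247" && !("CD247" %in% genes) && "CD3Z" %in% genes) "CD3Z"
    else g
  }
  cd3Genes <- vapply(cd3Genes, resolve, character(1))
  hit <- cd3Genes %in% genes
  if (!all(hit))
    warning("CD3 genes not found in matrix: ",
            paste(cd3Genes[!hit], collapse = ", "))
  cd3Genes <- cd3Genes[hit]
  if (!length(cd3Genes)) .cgStop("none of the CD3 gating genes are present")

  hasCd3 <- Matrix::colSums(counts[cd3Genes, , drop = FALSE] > 0) > 0
  hasExcl <- if (exclusionGene %in% genes) {
    counts[exclusionGene, ] > 0
  } else {
    warning("exclusion gene not found in matrix: ", exclusionGene)
    rep(FALSE, ncol(counts))
  }
  keep <- hasCd3 & !hasExcl
  if (!any(keep))
    .cgStop("T-cell gate removed every cell; review gating genes/thresholds")
  steps <- data.frame(
    stage = "gate_t_cells", axis = "cell", removed = sum(!keep),
    parameters = paste0("cd3=", paste(cd3Genes, collapse = "|"),
                        ";exclude=", exclusionGene),
    stringsAsFactors = FALSE)
  report <- .qcReport(ncol(counts), sum(keep), nrow(counts), nrow(counts), steps)
  list(sce = sce[, keep], report = report)
}

#' Cell- and gene-level quality filters
#'
#' Cells with a ribosomal-count fraction below \code{minRiboFrac} (default 5%)
#' are dropped; zero-library cells are dropped with reason "zero library size"
#' since the fraction is undefined. Afterwards, genes with nonzero counts in
#' fewer than \code{minCellsPerGene} cells (default 2) are excluded — a gene
#' seen in exactly 2 cells passes. Optional low-UMI and mitochondrial-fraction
#' filters default OFF (upstream providers typically pre-apply them).
#'
#' @param sce SingleCellExperiment with \code{counts}.
#' @param minRiboFrac minimum ribosomal fraction per cell.
#' @param minCellsPerGene minimum number of cells a gene must appear in.
#' @param riboRegex regex on gene symbols identifying ribosomal protein genes.
#' @param minCounts optional minimum UMI count per cell (NULL = off;
#'   providers used 1000).
#' @param maxMitoFrac optional maximum mitochondrial fraction (NULL = off;
#'   providers used 0.20).
#' @param mitoRegex regex identifying mitochondrial genes.
#' @return list(sce, report).
#' @export
filterCellsGenes <- function(sce, minRiboFrac = 0.05, minCellsPerGene = 2,
                             riboRegex = "^(RPS|RPL)", minCounts = NULL,
                             maxMitoFrac = NULL, mitoRegex = "^MT-") {
  counts <- SummarizedExperiment::assay(sce, "counts")
  nCellsIn <- ncol(counts); nGenesIn <- nrow(counts)
  steps <- list()

  total <- Matrix::colSums(counts)
  zero <- total == 0
  steps[[length(steps) + 1L]] <- data.frame(
    stage = "zero_library", axis = "cell", removed = sum(zero),
    parameters = "reason=zero library size", stringsAsFactors = FALSE)
  counts <- counts[, !zero, drop = FALSE]
  total <- total[!zero]

  riboGenes <- grepl(riboRegex, rownames(counts), ignore.case = TRUE)
  riboFrac <- Matrix::colSums(counts[riboGenes, , drop = FALSE]) / total
  keep <- riboFrac >= minRiboFrac
  steps[[length(steps) + 1L]] <- data.frame(
    stage = "ribosomal_fraction", axis = "cell", removed = sum(!keep),
    parameters = paste0("min_ribo_frac=", minRiboFrac, ";regex=", riboRegex),
    stringsAsFactors = FALSE)
  counts <- counts[, keep, drop = FALSE]
  total <- total[keep]

  if (!is.null(minCounts)) {
    keep <- total >= minCounts
    steps[[length(steps) + 1L]] <- data.frame(
      stage = "min_umi", axis = "cell", removed = sum(!keep),
      parameters = paste0("min_counts=", minCounts), stringsAsFactors = FALSE)
    counts <- counts[, keep, drop = FALSE]
    total <- total[keep]
  }
  if (!is.null(maxMitoFrac)) {
    mito <- grepl(mitoRegex, rownames(counts), ignore.case = TRUE)
    frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / total
    keep <- frac <= maxMitoFrac
    steps[[length(steps) + 1L]] <- data.frame(
      stage = "mito_fraction", axis = "cell", removed = sum(!keep),
      parameters = paste0("max_mito_frac=", maxMitoFrac),
      stringsAsFactors = FALSE)
    counts <- counts[, keep, drop = FALSE]
  }
  if (ncol(counts) == 0L)
    .cgStop("cell filters removed every cell; review thresholds")

  # gene filter comes after the cell filters by contract
  nCellsExpr <- Matrix::rowSums(counts > 0)
  keepG <- nCellsExpr >= minCellsPerGene
  steps[[length(steps) + 1L]] <- data.frame(
    stage = "gene_min_cells", axis = "gene", removed = sum(!keepG),
    parameters = paste0("min_cells_per_gene=", minCellsPerGene),
    stringsAsFactors = FALSE)
  counts <- counts[keepG, , drop = FALSE]

  report <- .qcReport(nCellsIn, ncol(counts), nGenesIn, nrow(counts),
                      do.call(rbind, steps))
  list(sce = sce[rownames(counts), colnames(counts)], report = report)
}

#' External doublet-removal hook
#'
#' Doublet detection (e.g. Scrublet) is deliberately not reimplemented here;
#' supply a logical keep-vector or a predicate computed by an external tool.
#'
#' @param sce SingleCellExperiment.
#' @param keep logical per cell (TRUE = singlet) or a function(sce) returning
#'   one.
#' @return list(sce, report).
#' @export
dropDoublets <- function(sce, keep) {
  if (is.function(keep)) keep <- keep(sce)
  stopifnot(is.logical(keep), length(keep) == ncol(sce))
  steps <- data.frame(stage = "doublet_hook", axis = "cell",
                      removed = sum(!keep), parameters = "external",
                      stringsAsFactors = FALSE)
  report <- .qcReport(ncol(sce), sum(keep), nrow(sce), nrow(sce), steps)
  list(sce = sce[, keep], report = report)
}
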