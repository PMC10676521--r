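#' Configuration for the CITE-seq simulator
#'
#' Defaults describe a small but realistic CITE-seq T-cell experiment:
#' a clearly bimodal normalized-log ADT (components N(1, 0.5^2) and
#' N(4, 0.5^2), 45% marker-positive), negative-binomial counts with
#' dispersion 0.5, log-normal library sizes around 2500 UMIs, 30 planted DE
#' genes at |log2FC| = 2 (half up in each class), and a 50-gene block
#' rank-correlated (target Spearman rho 0.6) with the splicing-factor anchor
#' gene. Marker genes needed by QC (CD3D/E/G/CD247, CD19, ribosomal and
#' mitochondrial genes) are included so the full pipeline runs end to end.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param adt_means,adt_sds,frac_positive ADT mixture (negative, positive).
#' @param n_de_genes,de_log2fc planted differential expression.
#' @param n_corr_genes,corr_strength planted anchor-correlated block.
#' @param nb_dispersion NB dispersion phi (Var = mu + phi mu^2).
#' @param lib_meanlog,lib_sdlog library-size log-normal parameters.
#' @param n_high_disp,high_disp_factor optional genes with inflated
#'   dispersion (for variance-ranking checks; off by default).
#' @param anchor anchor gene symbol.
#' @param seed integer seed for cells, ADT and counts.
#' @param gene_seed seed for the gene catalog (abundances, planted roles).
#'   Fixed by default so simulations with different \code{seed}s emulate
#'   different experiments on the same biology — same genes, same expression
#'   levels — rather than different organisms.
#' @return list of validated settings.
#' @export
simConfig <- function(n_cells = 3000, n_genes = 1000,
                      adt_means = c(1, 4), adt_sds = c(0.5, 0.5),
                      frac_positive = 0.45,
                      n_de_genes = 30, de_log2fc = 2,
                      n_corr_genes = 50, corr_strength = 0.6,
                      nb_dispersion = 0.5,
                      lib_meanlog = log(2500), lib_sdlog = 0.3,
                      n_high_disp = 0, high_disp_factor = 10,
                      anchor = "HNRNPLL", seed = 1, gene_seed = 1000) {
  if (!(frac_positive > 0 && frac_positive < 1))
    .cgStop("frac_positive must be in (0,1)")
  if (abs(corr_strength) > 0.98)
    .cgStop("infeasible corr_strength (|rho| > 0.98)")
  if (n_de_genes > 0 && de_log2fc == 0)
    .cgStop("de_log2fc must be nonzero when DE genes are planted")
  as.list(environment())
}

#' Simulate a CITE-seq experiment with known ground truth
#'
#' ADT levels are drawn from the two-component Gaussian mixture directly on
#' the provider-normalized log scale; component membership is the true
#' marker status. Gene counts are negative binomial with a log library-size
#' offset. Planted DE genes have a class-mean ratio of
#' \eqn{2^{de\_log2fc}} (half up in the marker-negative class, half up in the
#' positive class). The correlated block is generated through a Gaussian
#' copula against the anchor gene's latent expression, with the latent
#' correlation set to \eqn{2\sin(\pi\rho_S/6)} so the target Spearman rho is
#' achieved (up to count ties).
#'
#' @param cfg from \code{\link{simConfig}}.
#' @return list: \code{sce} (counts + \code{colData}$adt), \code{adt} (named
#'   vector), \code{truth} (class per cell, DE gene table, correlated gene
#'   table, config).
#' @export
simulateCiteSeq <- function(cfg = simConfig()) {
  set.seed(cfg$gene_seed)
  genes <- .simGeneTable(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_cells
  cells <- sprintf("%s-1", .randomBarcodes(n))

  positive <- stats::runif(n) < cfg$frac_positive
  comp <- ifelse(positive, 2, 1)
  adt <- stats::rnorm(n, cfg$adt_means[comp], cfg$adt_sds[comp])

  lib <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)
  relLib <- lib / mean(lib)

  counts <- matrix(0L, nrow(genes), n,
                   dimnames = list(genes$gene, cells))
  sizeOf <- function(phi) 1 / phi
  latentAnchor <- stats::rnorm(n)
  rLatent <- 2 * sin(pi * cfg$corr_strength / 6)

  for (g in seq_len(nrow(genes))) {
    base <- genes$abundance[g]
    fc <- rep(1, n)
    if (genes$role[g] == "de") {
      r <- 2^cfg$de_log2fc
      if (genes$direction[g] == "up_in_negative") fc[!positive] <- r
      else fc[positive] <- r
    }
    mu <- base * relLib * fc
    phi <- cfg$nb_dispersion * genes$disp_factor[g]
    if (genes$role[g] %in% c("anchor", "corr")) {
      # depth-free block: with mu constant across cells the Gaussian copula
      # transfers its rank correlation to the counts up to discreteness only
      z <- if (genes$role[g] == "anchor") latentAnchor
           else rLatent * latentAnchor +
                sqrt(1 - rLatent^2) * stats::rnorm(n)
      u <- stats::pnorm(z)
      counts[g, ] <- stats::qnbinom(u, size = sizeOf(phi), mu = base * fc)
    } else {
      counts[g, ] <- stats::rnbinom(n, size = sizeOf(phi), mu = mu)
    }
  }

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")))
  SummarizedExperiment::colData(sce)$adt <- adt
  SummarizedExperiment::colData(sce)$true_class <-
    ifelse(positive, "positive", "negative")

  deTab <- genes[genes$role == "de", c("gene", "direction")]
  deTab$log2fc <- if (nrow(deTab)) ifelse(deTab$direction == "up_in_negative",
                                          cfg$de_log2fc, -cfg$de_log2fc)
                  else numeric(0)
  corrTab <- genes[genes$role == "corr", "gene", drop = FALSE]
  corrTab$target_rho <- rep(cfg$corr_strength, nrow(corrTab))
  list(sce = sce, adt = stats::setNames(adt, cells),
       truth = list(class = stats::setNames(ifelse(positive, "positive",
                                                   "negative"), cells),
                    de_genes = deTab, corr_genes = corrTab, config = cfg))
}

## gene catalog: housekeeping background + QC marker genes + planted blocks
.simGeneTable <- function(cfg) {
  cc <- c(utils::head(defaultCellCycleGenes("s"), 10),
          utils::head(defaultCellCycleGenes("g2m"), 10))
  nSpecial <- 40 + 5 + 5 + 1 + length(cc)   # ribo+mito+lineage+anchor+cycle
  nPlanted <- cfg$n_de_genes + cfg$n_corr_genes + cfg$n_high_disp
  nBg <- cfg$n_genes - nSpecial - nPlanted
  if (nBg < 0) .cgStop("n_genes too small for the planted blocks")

  ribo <- data.frame(
    gene = c(sprintf("RPS%d", 1:20), sprintf("RPL%d", 1:20)),
    abundance = stats::rlnorm(40, log(8), 0.4), role = "background")
  mito <- data.frame(gene = sprintf("MT-SIM%d", 1:5),
                     abundance = stats::rlnorm(5, log(2), 0.3),
                     role = "background")
  lineage <- data.frame(
    gene = c("CD3D", "CD3E", "CD3G", "CD247", "CD19"),
    abundance = c(3, 3, 2, 2, 0.002), role = "background")
  cycle <- data.frame(gene = cc,
                      abundance = stats::rlnorm(length(cc), log(2), 0.3),
                      role = "background")
  # anchor/correlated genes are well expressed so count ties do not wash out
  # the planted rank correlation
  anchor <- data.frame(gene = cfg$anchor, abundance = 15, role = "anchor")
  de <- if (cfg$n_de_genes > 0) data.frame(
    gene = sprintf("DEG%03d", seq_len(cfg$n_de_genes)),
    abundance = stats::rlnorm(cfg$n_de_genes, log(2), 0.3), role = "de")
    else NULL
  corr <- if (cfg$n_corr_genes > 0) data.frame(
    gene = sprintf("COR%03d", seq_len(cfg$n_corr_genes)),
    abundance = stats::rlnorm(cfg$n_corr_genes, log(12), 0.3), role = "corr")
    else NULL
  hv <- if (cfg$n_high_disp > 0) data.frame(
    gene = sprintf("HVG%03d", seq_len(cfg$n_high_disp)),
    abundance = stats::rlnorm(cfg$n_high_disp, log(2), 0.3), role = "hv")
    else NULL
  bg <- data.frame(gene = sprintf("G%04d", seq_len(nBg)),
                   abundance = stats::rlnorm(nBg, log(0.8), 1), role = "background")
  tab <- rbind(ribo, mito, lineage, cycle, anchor, de, corr, hv, bg)
  tab$direction <- "none"
  if (cfg$n_de_genes > 0) {
    i <- which(tab$role == "de")
    half <- ceiling(length(i) / 2)
    tab$direction[i[seq_len(half)]] <- "up_in_negative"
    tab$direction[i[-seq_len(half)]] <- "up_in_positive"
  }
  tab$disp_factor <- 1
  tab$disp_factor[tab$role == "hv"] <- cfg$high_disp_factor
  tab
}

.randomBarcodes <- function(n) {
  bc <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = ""),
    character(1))
  while (anyDuplicated(bc)) {
    d <- which(duplicated(bc))
    bc[d] <- vapply(d, function(i)
      paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = ""),
      character(1))
  }
  bc
}

#' Write a simulation in the on-disk formats the readers accept
#'
#' 10x MTX triplet + ADT CSV + truth JSON.
#'
#' @param sim from \code{\link{simulateCiteSeq}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(sim$sce, file.path(dir, "counts"), format = "mtx10x")
  utils::write.csv(data.frame(barcode = names(sim$adt), adt = sim$adt),
                   file.path(dir, "adt.csv"), row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  writeLines(jsonlite::toJSON(list(
    class = as.list(truth$class),
    de_genes = truth$de_genes, corr_genes = truth$corr_genes,
    config = truth$config[setdiff(names(truth$config), "")]),
    auto_unbox = TRUE, digits = NA), file.path(dir, "truth.json"))
  invisible(dir)
}

#' The packaged hand-checkable toy fixture
#'
#' A 40-cell x 20-gene dataset with a cleanly bimodal ADT, two obviously
#' differential genes and small integer counts, sized so the brute-force
#' oracles (exhaustive Otsu search, quasi-likelihood grid search, hand
#' Benjamini-Hochberg) run in milliseconds. Shipped as CSV under
#' \code{inst/extdata/worked_toy}.
#'
#' @return list(sce, adt) as in \code{\link{simulateCiteSeq}}.
#' @export
workedToy <- function() {
  dir <- system.file("extdata", "worked_toy", package = "CiteGate")
  sce <- readCounts(file.path(dir, "counts.csv"), format = "csv")
  adt <- readAdt(file.path(dir, "adt.csv"))
  sce <- attachAdt(sce, adt)
  list(sce = sce, adt = adt)
}
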