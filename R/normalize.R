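#' Cell-cycle scores and per-cell covariates
#'
#' Computes the classic bin-control module score for the S and G2M phase gene
#' sets on log-normalized expression: for each set, score =
#' mean(expression of set genes) - mean(expression of control genes), where
#' control genes are drawn (seeded, without replacement within bin where
#' possible) from the same average-expression bins as the set genes. The
#' regression covariate used downstream is cc_diff = s_score - g2m_score.
#' The per-cell mitochondrial fraction is computed alongside.
#'
#' @param sce SingleCellExperiment with \code{counts}.
#' @param sGenes,g2mGenes character vectors of phase genes; \code{NULL} loads
#'   the packaged 43 S-phase / 54 G2M-phase human symbols.
#' @param nBins number of average-expression bins (default 25).
#' @param nCtrl control genes drawn per set gene (default 50).
#' @param seed integer seed for the control draws.
#' @param mitoRegex regex identifying mitochondrial genes.
#' @return \link[S4Vectors]{DataFrame} with columns \code{mito_frac},
#'   \code{s_score}, \code{g2m_score}, \code{cc_diff}, rownames = barcodes.
#' @export
cellCycleScore <- function(sce, sGenes = NULL, g2mGenes = NULL, nBins = 25,
                           nCtrl = 50, seed = 0, mitoRegex = "^MT-") {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (is.null(sGenes)) sGenes <- defaultCellCycleGenes("s")
  if (is.null(g2mGenes)) g2mGenes <- defaultCellCycleGenes("g2m")

  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  # log-normalized expression, dense (genes x cells)
  expr <- log1p(t(t(as.matrix(counts)) / lib) * 1e4)
  avg <- rowMeans(expr)

  scoreSet <- function(set, seed) {
    set <- intersect(set, rownames(expr))
    if (length(set) < 5L) {
      warning("fewer than 5 set genes found in matrix; score set to 0")
      return(rep(0, ncol(expr)))
    }
    # bins of average expression (quantile cut so bins are populated)
    brk <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = nBins + 1)))
    bin <- cut(avg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    names(bin) <- rownames(expr)
    set.seed(seed)
    ctrl <- character(0)
    for (g in set) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], set)
      if (!length(pool)) pool <- setdiff(names(bin), set)
      ctrl <- c(ctrl, sample(pool, min(nCtrl, length(pool)), replace = FALSE))
    }
    ctrl <- unique(ctrl)
    colMeans(expr[set, , drop = FALSE]) - colMeans(expr[ctrl, , drop = FALSE])
  }

  s <- scoreSet(sGenes, seed)
  g2m <- scoreSet(g2mGenes, seed + 1L)
  mito <- grepl(mitoRegex, rownames(counts), ignore.case = TRUE)
  mitoFrac <- as.numeric(Matrix::colSums(counts[mito, , drop = FALSE]) /
                           Matrix::colSums(counts))
  mitoFrac[!is.finite(mitoFrac)] <- 0
  S4Vectors::DataFrame(mito_frac = mitoFrac, s_score = s, g2m_score = g2m,
                       cc_diff = s - g2m, row.names = colnames(counts))
}

#' Packaged S / G2M phase gene sets
#'
#' @param phase "s" or "g2m"
#' @return character vector of human gene symbols
#' @export
defaultCellCycleGenes <- function(phase = c("s", "g2m")) {
  phase <- match.arg(phase)
  f <- system.file("extdata", "cellcycle",
                   paste0(phase, "_genes.txt"), package = "CiteGate")
  readLines(f)
}

#' Variance-stabilizing normalization with covariate regression
#'
#' Produces (1) per-gene Pearson residuals under a negative-binomial
#' mean-variance model \eqn{Var = \mu + \phi \mu^2} with a library-size
#' offset, clipped at \eqn{\pm\sqrt{n_{cells}}}; (2) the same residuals with
#' the named per-cell covariates regressed out by OLS; and (3)
#' "corrected counts": expected counts under the fitted model at the median
#' library size plus the (clipped) residual noise mapped back to the count
#' scale, rounded half-to-even and floored at zero, for use as GLM input.
#'
#' The per-gene rate is estimated as the unweighted mean of per-cell rates
#' \eqn{\lambda_g = mean_i(y_{ig}/\ell_i)}, which is exactly invariant to
#' rescaling all counts of a single cell (the library-size offset absorbs
#' it); \eqn{\phi_g} is method-of-moments on the fitted residuals.
#'
#' @param sce SingleCellExperiment with \code{counts} (post-QC).
#' @param covariates DataFrame from \code{\link{cellCycleScore}} (or NULL to
#'   skip regression).
#' @param regress covariate names to regress out; default
#'   \code{c("mito_frac","cc_diff")}; an empty vector leaves residuals
#'   untouched.
#' @return the input object with dense assays \code{residuals} and
#'   \code{corrected} added, covariates in \code{colData}, and the fitted
#'   per-gene parameters in \code{metadata(sce)$normalization}.
#' @export
normalizeRegress <- function(sce, covariates = NULL,
                             regress = c("mito_frac", "cc_diff")) {
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  n <- ncol(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) .cgStop("zero-library cells present; run QC first")

  prm <- .nbParams(counts, lib)
  res <- .nbResiduals(counts, lib, prm$rate, prm$phi, prm$clip)

  if (length(regress) && !is.null(covariates)) {
    bad <- setdiff(regress, colnames(covariates))
    if (length(bad)) .cgStop(paste("unknown covariate(s):",
                                   paste(bad, collapse = ", ")))
    X <- as.matrix(as.data.frame(covariates[colnames(counts), regress,
                                            drop = FALSE]))
    const <- apply(X, 2, function(v) stats::sd(v) == 0 || !all(is.finite(v)))
    if (any(const)) {
      warning("constant covariate(s) skipped: ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
    if (ncol(X)) {
      Xd <- cbind(`(Intercept)` = 1, X)
      # residuals of each gene's row on Xd:  R - R P,  P = Xd (Xd'Xd)^-1 Xd'
      coefs <- res %*% Xd %*% solve(crossprod(Xd))
      res <- res - coefs %*% t(Xd)
    }
  }

  corrected <- .correctedCounts(res, prm$rate, prm$phi, stats::median(lib))

  SummarizedExperiment::assay(sce, "residuals") <- res
  SummarizedExperiment::assay(sce, "corrected") <- corrected
  if (!is.null(covariates))
    SummarizedExperiment::colData(sce) <- cbind(
      SummarizedExperiment::colData(sce),
      covariates[colnames(counts), , drop = FALSE])
  S4Vectors::metadata(sce)$normalization <- list(
    rate = prm$rate, phi = prm$phi, clip = prm$clip,
    median_lib = stats::median(lib), regressed = regress)
  sce
}

## per-gene NB rate and regularized dispersion: raw method-of-moments
## estimates are smoothed against log abundance (the sctransform idea), so
## genes whose dispersion exceeds the trend keep residual variance > 1 and
## remain discoverable as highly variable
.nbParams <- function(counts, lib) {
  n <- ncol(counts)
  rate <- rowMeans(sweep(counts, 2, lib, "/"))           # lambda_g
  mu <- rate %o% lib                                     # genes x cells
  num <- rowSums((counts - mu)^2 - mu)
  den <- rowSums(mu^2)
  phiHat <- pmax(num / pmax(den, .Machine$double.eps) * n / max(n - 1, 1), 0)
  phi <- .regularizeDispersion(phiHat, rate)
  phi[rate == 0] <- 1e-8
  list(rate = rate, phi = phi, phi_raw = phiHat, clip = sqrt(n))
}

.regularizeDispersion <- function(phiHat, rate) {
  ok <- rate > 0
  if (sum(ok) < 20L) return(pmax(rep(stats::median(phiHat[ok]),
                                     length(phiHat)), 1e-8))
  x <- log10(rate[ok])
  fit <- suppressWarnings(stats::loess(phiHat[ok] ~ x, span = 0.5,
                                       degree = 1, family = "symmetric"))
  phi <- rep(stats::median(phiHat[ok]), length(phiHat))
  phi[ok] <- stats::predict(fit, x)
  bad <- !is.finite(phi)
  phi[bad] <- stats::median(phiHat[ok])
  phi <- pmax(phi, 1e-8)
  names(phi) <- names(phiHat)
  phi
}

.nbResiduals <- function(counts, lib, rate, phi, clip) {
  mu <- rate %o% lib
  sdv <- sqrt(mu + phi * mu^2)
  res <- (counts - mu) / sdv
  res[!is.finite(res)] <- 0                              # all-zero genes
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  res
}

.correctedCounts <- function(res, rate, phi, medianLib) {
  muMed <- rate * medianLib
  sdMed <- sqrt(muMed + phi * muMed^2)
  y <- muMed + res * sdMed                               # recycled by row
  y <- round(y)                                          # half-to-even
  y[y < 0] <- 0
  y
}

#' Top highly variable genes by residual variance
#'
#' @param sce SingleCellExperiment with a \code{residuals} assay.
#' @param nTop how many genes (default 3000).
#' @return character vector, variance-descending, ties broken
#'   lexicographically by gene id.
#' @export
highlyVariableGenes <- function(sce, nTop = 3000) {
  res <- SummarizedExperiment::assay(sce, "residuals")
  if (nTop > nrow(res)) .cgStop("nTop exceeds the number of genes")
  v <- apply(res, 1, stats::var)
  ord <- order(-v, rownames(res))
  rownames(res)[ord][seq_len(nTop)]
}
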