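# Small in-code fixtures shared across the suite.

# tiny SingleCellExperiment from a dense genes x cells matrix
makeSce <- function(m, genes = rownames(m), cells = colnames(m)) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("C%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")))
}

# brute-force Otsu oracle: naive per-candidate between-class variance from
# the same histogram, with tie averaging
otsuOracle <- function(adt, nBins) {
  h <- CiteGate:::.adtHist(adt, nBins)
  sb <- rep(-Inf, nBins - 1L)
  for (k in seq_len(nBins - 1L)) {
    lo <- 1:k; hi <- (k + 1L):nBins
    w0 <- sum(h$counts[lo]); w1 <- sum(h$counts[hi])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h$counts[lo] * h$centers[lo]) / w0
    m1 <- sum(h$counts[hi] * h$centers[hi]) / w1
    sb[k] <- (w0 / (w0 + w1)) * (w1 / (w0 + w1)) * (m0 - m1)^2
  }
  mx <- max(sb)
  mean(h$centers[seq_len(nBins - 1L)][sb >= mx - abs(mx) * 1e-9])
}

# brute-force quasi-likelihood grid oracle for the two-group LRT statistic:
# group means maximized by grid refinement at the method-of-moments phi
# (the full-model quasi-likelihood separates over the two groups)
glmGridOracle <- function(y, pos) {
  qllVec <- function(yy, mu, phi) {
    sum(ifelse(yy > 0, yy * log(mu), 0) - (yy + 1 / phi) * log1p(phi * mu))
  }
  gridMax1 <- function(f, lo, hi) {
    for (rep in 1:50) {
      xs <- seq(lo, hi, length.out = 41)
      v <- vapply(xs, f, numeric(1))
      i <- which.max(v)
      lo <- xs[max(1, i - 1)]; hi <- xs[min(41, i + 1)]
    }
    f((lo + hi) / 2)
  }
  muP <- mean(y[pos]); muN <- mean(y[!pos])
  muHat <- ifelse(pos, muP, muN)
  n <- length(y)
  phi <- max(sum((y - muHat)^2 - muHat) / sum(muHat^2) * n / (n - 2), 1e-8)
  lo <- 1e-4; hi <- max(y) + 2
  full <- gridMax1(function(m) qllVec(y[pos], m, phi), lo, hi) +
          gridMax1(function(m) qllVec(y[!pos], m, phi), lo, hi)
  null <- gridMax1(function(m) qllVec(y, m, phi), lo, hi)
  2 * (full - null)
}

# exhaustive Spearman with average-rank tie correction (textbook formula via
# Pearson on ranks)
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# quick labeled training bundle from a simulation (skips gating for speed)
simTrainingData <- function(nCells = 400, nGenes = 200, seed = 5, ...) {
  sim <- simulateCiteSeq(simConfig(n_cells = nCells, n_genes = nGenes,
                                   seed = seed, ...))
  f <- filterCellsGenes(sim$sce)$sce
  nm <- normalizeRegress(f, cellCycleScore(f, seed = seed))
  adt <- stats::setNames(SummarizedExperiment::colData(nm)$adt, colnames(nm))
  lab <- otsuLabels(adt)
  list(sim = sim, sce = nm, labels = lab,
       train = makeTrainingData(nm, lab))
}
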