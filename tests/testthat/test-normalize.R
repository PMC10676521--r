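test_that("cell-cycle scores are zero for uniform expression and respond to planted signal", {
  sGenes <- defaultCellCycleGenes("s")
  g2m <- defaultCellCycleGenes("g2m")
  genes <- c(sGenes[1:10], g2m[1:10], sprintf("BG%02d", 1:40))
  n <- 60

  # identical expression everywhere: set mean == control mean for each cell
  m <- matrix(4L, length(genes), n, dimnames = list(genes, NULL))
  sce <- makeSce(m)
  cov0 <- cellCycleScore(sce, seed = 1)
  expect_equal(unname(cov0$s_score), rep(0, n))
  expect_equal(unname(cov0$g2m_score), rep(0, n))

  # double counts on S genes in half of the cells -> those cells score higher
  set.seed(42)
  m2 <- matrix(rpois(length(genes) * n, 4), length(genes), n,
               dimnames = list(genes, NULL))
  boosted <- 1:30
  m2[sGenes[1:10], boosted] <- m2[sGenes[1:10], boosted] * 2L
  cov2 <- cellCycleScore(makeSce(m2), seed = 1)
  expect_gt(mean(cov2$s_score[boosted]), mean(cov2$s_score[-boosted]))

  # independent recomputation of the bin-control formula for one seed
  counts <- as.matrix(SummarizedExperiment::assay(makeSce(m2), "counts"))
  lib <- colSums(counts)
  expr <- log1p(t(t(counts) / lib) * 1e4)
  avg <- rowMeans(expr)
  brk <- unique(quantile(avg, probs = seq(0, 1, length.out = 26)))
  bin <- cut(avg, brk, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(expr)
  set.seed(1)
  setg <- intersect(sGenes, rownames(expr))
  ctrl <- character(0)
  for (g in setg) {
    pool <- setdiff(names(bin)[bin == bin[[g]]], setg)
    if (!length(pool)) pool <- setdiff(names(bin), setg)
    ctrl <- c(ctrl, sample(pool, min(50, length(pool))))
  }
  ctrl <- unique(ctrl)
  oracle <- colMeans(expr[setg, ]) - colMeans(expr[ctrl, ])
  expect_equal(unname(cov2$s_score), unname(oracle))

  # determinism
  cov3 <- cellCycleScore(makeSce(m2), seed = 1)
  expect_identical(cov2$s_score, cov3$s_score)
  expect_identical(cov2$g2m_score, cov3$g2m_score)
})

test_that("residuals: zero-variance genes, covariate orthogonality, Pearson variance contract", {
  set.seed(7)
  n <- 2000
  genes <- c("FLAT", sprintf("P%03d", 1:80))
  m <- matrix(rpois(81 * n, 5), 81, n, dimnames = list(genes, NULL))
  m["FLAT", ] <- 7L                       # identical counts, equal libraries?
  sce <- makeSce(m)
  cov <- S4Vectors::DataFrame(mito_frac = runif(n, 0, 0.1),
                              cc_diff = rnorm(n),
                              row.names = colnames(sce))
  nm <- normalizeRegress(sce, cov)
  res <- SummarizedExperiment::assay(nm, "residuals")

  # orthogonality after OLS regression
  expect_lt(max(abs(cor(t(res), cov$mito_frac))), 1e-8)
  expect_lt(max(abs(cor(t(res), cov$cc_diff))), 1e-8)

  # Poisson data, no covariates: per-gene residual variance ~ 1 within 20%
  nm0 <- normalizeRegress(sce, covariates = NULL, regress = character(0))
  res0 <- SummarizedExperiment::assay(nm0, "residuals")
  v <- apply(res0[sprintf("P%03d", 1:80), ], 1, var)
  expect_true(all(v > 0.8 & v < 1.2))

  # equal library sizes -> a constant gene has an all-zero residual vector
  eq <- matrix(5L, 3, 50, dimnames = list(c("A", "B", "C"), NULL))
  eq["B", ] <- 9L
  nmEq <- normalizeRegress(makeSce(eq), covariates = NULL,
                           regress = character(0))
  expect_equal(unname(SummarizedExperiment::assay(nmEq, "residuals")["B", ]),
               rep(0, 50))
})

test_that("empty regress list is the identity on residuals", {
  set.seed(3)
  m <- matrix(rpois(200, 3), 10, 20)
  sce <- makeSce(m)
  cov <- S4Vectors::DataFrame(mito_frac = runif(20), cc_diff = rnorm(20),
                              row.names = colnames(sce))
  a <- SummarizedExperiment::assay(
    normalizeRegress(sce, cov, regress = character(0)), "residuals")
  b <- SummarizedExperiment::assay(
    normalizeRegress(sce, covariates = NULL, regress = character(0)),
    "residuals")
  expect_identical(a, b)
})

test_that("scaling one cell's counts is absorbed by its offset, leaving other cells near-unchanged", {
  set.seed(11)
  m <- matrix(rpois(1500, 4) + 1L, 15, 100)
  sce <- makeSce(m)
  nm1 <- normalizeRegress(sce, NULL, regress = character(0))
  r1 <- SummarizedExperiment::assay(nm1, "residuals")
  m2 <- m
  m2[, 5] <- m2[, 5] * 3L
  nm2 <- normalizeRegress(makeSce(m2), NULL, regress = character(0))
  r2 <- SummarizedExperiment::assay(nm2, "residuals")
  # the per-gene rate (hence every other cell's fitted mean) is exactly
  # invariant: the library-size offset absorbs the scaling
  expect_equal(S4Vectors::metadata(nm1)$normalization$rate,
               S4Vectors::metadata(nm2)$normalization$rate)
  # residuals of other cells move only through the re-estimated dispersion
  # trend, an O(1/n) perturbation
  expect_lt(max(abs(r2[, -5] - r1[, -5])), 0.05)
})

test_that("highly variable genes rank by residual variance with lexicographic ties", {
  set.seed(5)
  m <- matrix(rpois(30 * 40, 3), 30, 40,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  sce <- normalizeRegress(makeSce(m), NULL, regress = character(0))
  all <- highlyVariableGenes(sce, nTop = 30)
  expect_setequal(all, rownames(sce))           # degenerate top-k
  v <- apply(SummarizedExperiment::assay(sce, "residuals"), 1, var)
  expect_identical(all, rownames(sce)[order(-v, rownames(sce))])
  expect_error(highlyVariableGenes(sce, nTop = 31), "exceeds")

  # exact tie -> lexicographic: duplicate one gene's counts under two names
  m2 <- rbind(m, zzz_dup = m["g01", ])
  m2 <- m2[c(nrow(m2), 1:(nrow(m2) - 1)), ]     # put duplicate first on disk
  sce2 <- normalizeRegress(makeSce(m2), NULL, regress = character(0))
  top <- highlyVariableGenes(sce2, nTop = nrow(m2))
  expect_lt(which(top == "g01"), which(top == "zzz_dup"))
})

test_that("planted high-dispersion genes dominate the variable-gene ranking", {
  sim <- simulateCiteSeq(simConfig(n_cells = 500, n_genes = 300,
                                   n_de_genes = 0, n_corr_genes = 0,
                                   n_high_disp = 50, seed = 13))
  nm <- normalizeRegress(sim$sce, NULL, regress = character(0))
  top <- highlyVariableGenes(nm, nTop = 50)
  expect_gte(sum(grepl("^HVG", top)), 45)
})

test_that("corrected counts stay on the count scale and preserve group contrasts", {
  td <- simTrainingData(nCells = 300, nGenes = 200, seed = 21)
  corrected <- td$train$corrected
  expect_true(all(corrected >= 0))
  expect_true(all(corrected == floor(corrected)))
  # planted DE contrast survives correction: ratio near 2^2 on up genes
  up <- td$sim$truth$de_genes
  g <- up$gene[up$direction == "up_in_negative"][1]
  neg <- td$train$y == "negative"
  ratio <- mean(corrected[g, neg]) / mean(corrected[g, !neg])
  expect_gt(ratio, 2.5)
})
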