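test_that("null genes give near-zero fold change and p near 1", {
  y <- rep(c(8L, 8L), each = 20)                 # identical group means
  cond <- rep(c("positive", "negative"), each = 20)
  f <- fitQpGlm(y, cond)
  expect_lt(abs(f$log2fc), 1e-6)
  expect_gt(f$p_value, 0.99)
  expect_equal(f$D, 0, tolerance = 1e-10)
})

test_that("the LRT statistic matches the quasi-likelihood grid oracle", {
  set.seed(17)
  cond <- rep(c("positive", "negative"), each = 20)
  pos <- cond == "positive"
  # 40-cell toy, group means 8 and 2
  y <- c(rpois(20, 8), rpois(20, 2))
  f <- fitQpGlm(y, cond)
  expect_equal(f$D, glmGridOracle(y, pos), tolerance = 1e-3)
  # a few random draws including null and overdispersed cases
  for (i in 1:6) {
    y <- c(rnbinom(20, mu = sample(2:8, 1), size = 2),
           rnbinom(20, mu = sample(2:8, 1), size = 2))
    if (sum(y) == 0) next
    f <- fitQpGlm(y, cond)
    expect_equal(f$D, glmGridOracle(y, pos), tolerance = 1e-3)
    expect_gte(f$D, 0)
    expect_gt(f$phi, 0)
  }
})

test_that("the GLM is invariant to cell order and handles degenerate genes", {
  set.seed(23)
  cond <- rep(c("positive", "negative"), each = 15)
  y <- rnbinom(30, mu = 4, size = 1)
  f1 <- fitQpGlm(y, cond)
  perm <- sample(30)
  f2 <- fitQpGlm(y[perm], cond[perm])
  expect_equal(f1, f2)
  # all-zero gene
  f0 <- fitQpGlm(rep(0L, 30), cond)
  expect_equal(f0$D, 0)
  expect_equal(f0$p_value, 1)
  expect_identical(f0$beta_pos, -Inf)
  expect_error(fitQpGlm(1:5, c("positive", rep("negative", 4))),
               "at least 2 cells")
})

test_that("vectorized DE equals the single-gene path and D >= 0 on null sweeps", {
  set.seed(29)
  n <- 60
  cond <- rep(c("positive", "negative"), each = n / 2)
  y <- matrix(rnbinom(200 * n, mu = 3, size = 2), 200, n,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("c%03d", 1:n)))
  de <- qpGlmDe(y, cond)
  expect_true(all(de$D >= 0))
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  for (g in c(1, 57, 200)) {
    f <- fitQpGlm(y[g, ], cond)
    expect_equal(unname(de$D[g]), f$D, tolerance = 1e-10)
    expect_equal(unname(de$phi[g]), f$phi, tolerance = 1e-10)
    expect_equal(unname(de$log2fc[g]), f$log2fc, tolerance = 1e-10)
  }
})

test_that("log2 fold change follows the base-2, up-in-negative convention", {
  # exact ratio 4 between group means -> +2 when higher in negatives
  y <- rep(c(1L, 4L), each = 10)
  cond <- rep(c("positive", "negative"), each = 10)
  f <- fitQpGlm(y, cond)
  expect_equal(f$log2fc, 2.0)
  expect_equal(log2FoldChange(log(4), log(1)), 2.0)
  expect_equal(log2FoldChange(log(3), log(3)), 0)
  # random NB data: coefficient difference agrees with the direct mean ratio
  set.seed(31)
  for (i in 1:10) {
    y <- c(rnbinom(50, mu = runif(1, 1, 10), size = 2),
           rnbinom(50, mu = runif(1, 1, 10), size = 2))
    cond <- rep(c("negative", "positive"), each = 50)
    mNeg <- mean(y[1:50]); mPos <- mean(y[51:100])
    if (mNeg < 1 || mPos < 1) next
    f <- fitQpGlm(y, cond)
    expect_equal(f$log2fc, log2(mNeg / mPos), tolerance = 0.05)
  }
})

test_that("BH q-values match the hand-computed step-up and p.adjust", {
  expect_equal(bhQvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhQvalues(rep(1, 5)), rep(1, 5))
  # hand-computed: sorted p * m / rank with cumulative minima from the top
  p <- c(0.004, 0.03, 0.7, 0.01, 0.2)
  # sorted: .004,.01,.03,.2,.7 -> raw .02,.025,.05,.25,.7 -> monotone same
  expect_equal(bhQvalues(p), c(0.02, 0.05, 0.7, 0.025, 0.25))
  set.seed(37)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))
    q <- bhQvalues(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bhQvalues(c(0.5, 1.2)), "lie in")
})

test_that("Spearman screen: exact rho for monotone transforms and brute-force parity", {
  set.seed(41)
  n <- 24
  anchor <- rnorm(n)
  mat <- rbind(HNRNPLL = anchor,
               SAME = anchor + 100,            # strictly increasing transform
               FLIP = exp(-anchor),            # strictly decreasing transform
               NOISE1 = rnorm(n),
               NOISE2 = rnorm(n),
               TIED = rep(c(1, 2), n / 2))
  out <- spearmanScreen(mat, anchor = "HNRNPLL", pHn = 0.4)
  expect_equal(unname(out$result["HNRNPLL", "rho"]), 1)
  expect_equal(unname(out$result["SAME", "rho"]), 1)
  expect_equal(unname(out$result["FLIP", "rho"]), -1)
  # brute-force rank-formula oracle with tie correction
  for (g in rownames(mat))
    expect_equal(unname(out$result[g, "rho"]), spearmanOracle(mat[g, ], anchor),
                 tolerance = 1e-12)
  # p-value of a perfect correlation is 0, selection excludes the anchor
  expect_false("HNRNPLL" %in% out$selected)
  expect_true(all(c("SAME", "FLIP") %in% out$selected))
})

test_that("Spearman screen errors on a missing anchor with near misses", {
  mat <- matrix(rnorm(40), 4, 10,
                dimnames = list(c("HNRNPA2B1", "HNRNPC", "AQP3", "CD28"),
                                NULL))
  expect_error(spearmanScreen(mat, anchor = "HNRNPLL", pHn = 0.2),
               "near misses.*HNRNP")
})

test_that("feature selection honors thresholds, q-cutoff, provenance and ordering", {
  de <- S4Vectors::DataFrame(
    gene = c("UP1", "UP2", "DOWN1", "WEAK", "NOTSIG"),
    log2fc = c(3, 2.2, -2.5, 0.5, 4),
    q_value = c(1e-4, 1e-3, 1e-4, 1e-4, 0.2),
    converged = TRUE)
  corr <- list(selected = c("CORR1", "UP2"))
  fs <- selectFeatures(de, corr, tDeUpper = 2, tDeLower = -2, pHn = 0.05)
  expect_identical(featureGenes(fs), c("UP1", "DOWN1", "UP2", "CORR1"))
  expect_identical(featureProvenance(fs), c("de", "de", "both", "corr"))
  expect_error(selectFeatures(de, list(selected = character(0)),
                              tDeUpper = 10, tDeLower = -10, pHn = 0.01),
               "no features")
  expect_error(selectFeatures(de, corr, tDeUpper = -1, tDeLower = -2,
                              pHn = 0.05), "tDeUpper")
})

test_that("planted DE genes are recovered and tightening thresholds is monotone", {
  td <- simTrainingData(nCells = 500, nGenes = 250, seed = 19,
                        de_log2fc = 3)
  de <- qpGlmDe(td$train$corrected, td$train$y)
  corr <- spearmanScreen(td$train$residuals, pHn = 0.02)
  fs <- selectFeatures(de, corr, tDeUpper = 2, tDeLower = -2, pHn = 0.02)
  planted <- td$sim$truth$de_genes$gene
  expect_true(all(planted %in% featureGenes(fs)))
  prov <- featureProvenance(fs)[match(planted, featureGenes(fs))]
  expect_true(all(prov %in% c("de", "both")))

  sizes <- vapply(c(1, 1.5, 2, 2.5, 3.2), function(t) {
    f <- tryCatch(selectFeatures(de, corr, t, -t, pHn = 0.02),
                  citegate_empty_features = function(e) NULL)
    if (is.null(f)) 0L else length(featureGenes(f))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  # and tightening pHn shrinks the correlation source too
  n1 <- length(CiteGate:::.corrSelect(corr$result, "HNRNPLL", 0.05))
  n2 <- length(CiteGate:::.corrSelect(corr$result, "HNRNPLL", 0.01))
  expect_lte(n2, n1)
})
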