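#' Quasi-Poisson GLM likelihood-ratio test for one gene
#'
#' Two-condition model with log link, \eqn{\log(\mu_{ij}) = X_{ij}\beta_j}
#' (plus an optional offset), and variance \eqn{Var(y) = \mu + \phi\mu^2}.
#' Condition coefficients are the GLM maximum-likelihood solutions (for a
#' saturated two-group design the score equations have the closed form
#' \eqn{e^{\beta_j} = \sum_{i \in j} y_i / \sum_{i \in j} e^{o_i}}, which is
#' also the quasi-likelihood root when offsets are constant within groups).
#' \eqn{\phi} is estimated by method of moments on the full-model residuals,
#' \eqn{\hat\phi = \sum[(y-\hat\mu)^2 - \hat\mu] / \sum \hat\mu^2 \cdot
#' n/(n-2)}, floored at 1e-8. The statistic \eqn{D = 2(\ell_{full} -
#' \ell_{null})} uses the quasi-likelihood
#' \eqn{Q(\mu;y) = y\log\mu - (y + 1/\phi)\log(1 + \phi\mu)} with the
#' full-model \eqn{\phi} plugged into both models, and is referred to
#' \eqn{\chi^2_1}.
#'
#' @param counts non-negative counts (corrected counts) for one gene across
#'   the labeled cells.
#' @param condition factor/character/logical with the positive class first:
#'   accepts a factor with levels \code{c("positive","negative")}, a logical
#'   (TRUE = positive), or the strings themselves.
#' @param offset optional per-cell log offset (default 0: corrected counts
#'   are already depth-normalized).
#' @return list with \code{beta_pos}, \code{beta_neg} (natural-log scale),
#'   \code{phi}, \code{D}, \code{p_value}, \code{log2fc}
#'   (= (beta_neg - beta_pos)/ln 2, positive when higher in the
#'   marker-negative class) and \code{converged}.
#' @export
fitQpGlm <- function(counts, condition, offset = NULL) {
  pos <- .asPositive(condition)
  if (sum(pos) < 2L || sum(!pos) < 2L)
    .cgStop("each condition needs at least 2 cells")
  if (any(counts < 0)) .cgStop("counts must be non-negative")
  y <- as.numeric(counts)
  n <- length(y)
  eo <- if (is.null(offset)) rep(1, n) else exp(offset)

  muHatPos <- sum(y[pos]) / sum(eo[pos])
  muHatNeg <- sum(y[!pos]) / sum(eo[!pos])
  muHat0 <- sum(y) / sum(eo)
  muFull <- ifelse(pos, muHatPos, muHatNeg) * eo
  muNull <- muHat0 * eo

  if (sum(y) == 0) {
    return(list(beta_pos = -Inf, beta_neg = -Inf, phi = 1e-8, D = 0,
                p_value = 1, log2fc = 0, converged = TRUE))
  }
  phi <- max(sum((y - muFull)^2 - muFull) / max(sum(muFull^2),
             .Machine$double.eps) * n / max(n - 2, 1), 1e-8)
  D <- max(0, 2 * (.quasiLL(y, muFull, phi) - .quasiLL(y, muNull, phi)))
  list(beta_pos = log(muHatPos), beta_neg = log(muHatNeg), phi = phi,
       D = D, p_value = stats::pchisq(D, df = 1, lower.tail = FALSE),
       log2fc = log2FoldChange(log(muHatNeg), log(muHatPos)),
       converged = TRUE)
}

## quasi-likelihood kernel for Var = mu + phi mu^2 (NB-type),
## Q = sum y log(mu) - (y + 1/phi) log(1 + phi mu);  0*log(0) := 0
.quasiLL <- function(y, mu, phi) {
  t1 <- ifelse(y > 0, y * log(pmax(mu, .Machine$double.xmin)), 0)
  sum(t1 - (y + 1 / phi) * log1p(phi * mu))
}

.asPositive <- function(condition) {
  if (is.logical(condition)) return(condition)
  cc <- as.character(condition)
  if (!all(cc %in% c("positive", "negative")))
    .cgStop("condition must code positive/negative")
  cc == "positive"
}

#' log2 fold change from natural-log GLM coefficients
#'
#' The GLM link is the natural logarithm, so the raw coefficient difference
#' \eqn{\beta_{C2} - \beta_{C1}} is on the ln scale; it is divided by
#' \eqn{\ln 2} here so that the returned value agrees with the base-2
#' definition \eqn{\log_2(\bar y_{C2} / \bar y_{C1})}. Positive values mean
#' higher expression in the marker-negative class (C2).
#'
#' @param betaNeg,betaPos condition coefficients, natural-log scale.
#' @return numeric log2 fold change.
#' @export
log2FoldChange <- function(betaNeg, betaPos) (betaNeg - betaPos) / log(2)

#' Differential expression across all genes
#'
#' Vectorized quasi-Poisson LRT (see \code{\link{fitQpGlm}}) of every gene
#' between marker-positive and marker-negative cells, with
#' Benjamini-Hochberg q-values.
#'
#' @param corrected corrected-count matrix, genes x cells (labeled cells
#'   only).
#' @param condition per-cell condition (see \code{\link{fitQpGlm}}).
#' @return \link[S4Vectors]{DataFrame} with columns \code{gene},
#'   \code{beta_pos}, \code{beta_neg}, \code{phi}, \code{D}, \code{p_value},
#'   \code{q_value}, \code{log2fc}, \code{converged}.
#' @export
qpGlmDe <- function(corrected, condition) {
  pos <- .asPositive(condition)
  if (sum(pos) < 2L || sum(!pos) < 2L)
    .cgStop("each condition needs at least 2 cells")
  .auditRecord("de", colnames(corrected))
  y <- as.matrix(corrected)
  n <- ncol(y); np <- sum(pos); nn <- n - np

  sP <- rowSums(y[, pos, drop = FALSE])
  sN <- rowSums(y[, !pos, drop = FALSE])
  muP <- sP / np; muN <- sN / nn; mu0 <- (sP + sN) / n

  # method-of-moments phi on full-model residuals, vectorized:
  # sum over cells of (y - mu)^2 with group-constant mu
  ssqP <- rowSums(y[, pos, drop = FALSE]^2)
  ssqN <- rowSums(y[, !pos, drop = FALSE]^2)
  ssFull <- (ssqP - 2 * muP * sP + np * muP^2) +
            (ssqN - 2 * muN * sN + nn * muN^2)
  num <- ssFull - (np * muP + nn * muN)
  den <- np * muP^2 + nn * muN^2
  phi <- pmax(num / pmax(den, .Machine$double.eps) * n / (n - 2), 1e-8)

  # Q with group-constant mu: y log mu sums to s * log(mu);
  # (y + 1/phi) log(1+phi mu) sums to (s + n_g/phi) log(1+phi mu)
  term <- function(s, ng, mu) {
    ifelse(s > 0, s * log(pmax(mu, .Machine$double.xmin)), 0) -
      (s + ng / phi) * log1p(phi * mu)
  }
  llFull <- term(sP, np, muP) + term(sN, nn, muN)
  llNull <- term(sP, np, mu0) + term(sN, nn, mu0)
  D <- pmax(0, 2 * (llFull - llNull))
  allZero <- sP + sN == 0
  D[allZero] <- 0
  p <- stats::pchisq(D, df = 1, lower.tail = FALSE)
  p[allZero] <- 1
  S4Vectors::DataFrame(
    gene = rownames(y),
    beta_pos = log(muP), beta_neg = log(muN), phi = phi, D = D,
    p_value = p, q_value = bhQvalues(p),
    log2fc = ifelse(allZero, 0, log2FoldChange(log(muN), log(muP))),
    converged = TRUE, row.names = rownames(y))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} with
#' monotonicity enforcement, values capped at 1, input order preserved.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order.
#' @export
bhQvalues <- function(pValues) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    .cgStop("p-values must lie in [0, 1]")
  m <- length(pValues)
  ord <- order(pValues)
  q <- pValues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Spearman-correlation screen against an anchor gene
#'
#' Rank-based correlation (average ranks on ties) of every gene's normalized
#' expression with the anchor gene (default HNRNPLL, the splicing factor
#' controlling CD45RA exon exclusion), with two-sided p-values from the
#' t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}. Selected genes are
#' those (anchor excluded) whose |rho| lies in the top \code{pHn} fraction of
#' all tested genes and whose p-value is below 0.05.
#'
#' @param sce SingleCellExperiment with a \code{residuals} assay, or a plain
#'   genes x cells matrix of normalized values.
#' @param anchor anchor gene symbol (default \code{"HNRNPLL"}).
#' @param pHn top fraction of |rho| to keep, in (0, 1).
#' @param cells optional barcodes to restrict to (training cells).
#' @return list with \code{result} (DataFrame: gene, rho, p_value,
#'   abs_rank_quantile) and \code{selected} (character vector).
#' @export
spearmanScreen <- function(sce, anchor = "HNRNPLL", pHn = 0.05, cells = NULL) {
  mat <- if (methods::is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "residuals") else as.matrix(sce)
  if (!is.null(cells)) mat <- mat[, cells, drop = FALSE]
  if (!(pHn > 0 && pHn < 1)) .cgStop("pHn must be in (0, 1)")
  if (!anchor %in% rownames(mat)) {
    near <- utils::head(grep(substr(anchor, 1, 4), rownames(mat),
                             value = TRUE, ignore.case = TRUE), 5)
    .cgStop(paste0("anchor gene ", anchor, " not in matrix",
                   if (length(near)) paste0("; near misses: ",
                                            paste(near, collapse = ", "))
                   else ""))
  }
  .auditRecord("corr", colnames(mat))
  n <- ncol(mat)
  rho <- suppressWarnings(
    as.numeric(stats::cor(t(mat), mat[anchor, ], method = "spearman")))
  names(rho) <- rownames(mat)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  absRho <- abs(rho)
  qtl <- rank(absRho, ties.method = "average", na.last = "keep") / sum(!is.na(absRho))
  result <- S4Vectors::DataFrame(gene = rownames(mat), rho = rho, p_value = p,
                                 abs_rank_quantile = qtl,
                                 row.names = rownames(mat))
  ok <- !is.na(rho) & rownames(mat) != anchor
  cut <- stats::quantile(absRho[!is.na(absRho)], probs = 1 - pHn,
                         names = FALSE, type = 7)
  selected <- rownames(mat)[ok & absRho >= cut & p < 0.05]
  selected <- selected[order(-absRho[selected], selected)]
  list(result = result, selected = selected)
}

#' Assemble the classifier feature set
#'
#' Union of (a) DE genes with q < 0.05 and log2FC at or beyond the
#' thresholds (\code{log2fc >= tDeUpper} or \code{log2fc <= tDeLower}) and
#' (b) the anchor-correlation screen at \code{pHn}. DE genes come first,
#' ordered by decreasing |log2FC|; correlation-only genes follow by
#' decreasing |rho|; ties break lexicographically. Genes found by both
#' sources get provenance \code{"both"}.
#'
#' @param de DataFrame from \code{\link{qpGlmDe}}.
#' @param corr list from \code{\link{spearmanScreen}} run at the same
#'   \code{pHn} (its \code{selected} component is honored).
#' @param tDeUpper,tDeLower log2FC cutoffs, \code{tDeUpper > 0 > tDeLower}.
#' @param pHn the correlation fraction, recorded in the result.
#' @param qCut DE q-value eligibility cutoff (default 0.05).
#' @return a \linkS4class{FeatureSet}.
#' @export
selectFeatures <- function(de, corr, tDeUpper, tDeLower, pHn, qCut = 0.05) {
  if (!(tDeUpper > 0 && tDeLower < 0))
    .cgStop("need tDeUpper > 0 > tDeLower")
  deOk <- de$converged & de$q_value < qCut &
    (de$log2fc >= tDeUpper | de$log2fc <= tDeLower)
  deGenes <- de$gene[deOk]
  deGenes <- deGenes[order(-abs(de$log2fc[deOk]), deGenes)]
  corrGenes <- corr$selected
  both <- intersect(deGenes, corrGenes)
  genes <- c(deGenes, setdiff(corrGenes, deGenes))
  if (!length(genes))
    .cgStop("no features at these thresholds", class = "citegate_empty_features")
  prov <- ifelse(genes %in% both, "both",
                 ifelse(genes %in% deGenes, "de", "corr"))
  new("FeatureSet", genes = genes, provenance = prov,
      tDeUpper = tDeUpper, tDeLower = tDeLower, pHn = pHn)
}

#' Export DE results as TSV
#' @param de DataFrame from \code{\link{qpGlmDe}}
#' @param path output file
#' @export
writeDeTable <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a FeatureSet as JSON
#' @param fs a \linkS4class{FeatureSet}
#' @param path optional output file
#' @export
featureSetJson <- function(fs, path = NULL) {
  js <- jsonlite::toJSON(list(genes = fs@genes, provenance = fs@provenance,
                              t_de_upper = fs@tDeUpper,
                              t_de_lower = fs@tDeLower, p_hn = fs@pHn),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

## ---- leakage audit ---------------------------------------------------------
.cgAudit <- new.env(parent = emptyenv())

#' Enable/inspect the leakage audit trail
#'
#' When enabled, differential expression, correlation screening and model
#' fitting record the barcodes of every cell they see, so a pipeline run can
#' prove that no held-out cell reached feature selection or training.
#'
#' @param on logical; TRUE resets and starts recording.
#' @return (auditTrail) named list of barcode vectors per stage.
#' @export
auditCells <- function(on = TRUE) {
  .cgAudit$enabled <- isTRUE(on)
  .cgAudit$trail <- list()
  invisible(on)
}

#' @rdname auditCells
#' @export
auditTrail <- function() .cgAudit$trail

.auditRecord <- function(stage, cellIds) {
  if (isTRUE(.cgAudit$enabled) && !is.null(cellIds)) {
    .cgAudit$trail[[stage]] <- unique(c(.cgAudit$trail[[stage]], cellIds))
  }
  invisible(NULL)
}
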