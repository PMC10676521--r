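#' Otsu threshold of an ADT level vector
#'
#' Histogram-based Otsu thresholding: values are binned into \code{nBins}
#' equal-width bins over [min, max]; for every split point the between-class
#' variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} is computed and the
#' split maximizing it is returned as the center of the last bin assigned to
#' the low class. When the maximum is attained by several splits (typical for
#' well-separated modes: every split inside the empty gap scores the same)
#' the maximizing bin centers are averaged, per Otsu's original
#' recommendation, so the threshold sits mid-gap. Deterministic for fixed
#' input.
#'
#' @param adt numeric vector of per-cell ADT levels (normalized/log scale).
#' @param nBins histogram bin count (default 256).
#' @return numeric(1) threshold t*, inside the observed ADT range.
#' @export
otsuThreshold <- function(adt, nBins = 256) {
  adt <- as.numeric(adt)
  if (any(!is.finite(adt))) .cgStop("ADT values must be finite")
  if (length(unique(adt)) < 2L) .cgStop("degenerate ADT distribution")
  h <- .adtHist(adt, nBins)
  w <- h$counts / sum(h$counts)
  c0 <- cumsum(w)                     # omega0 after bin k
  m <- cumsum(w * h$centers)
  mt <- m[length(m)]
  k <- seq_len(nBins - 1L)
  w0 <- c0[k]
  w1 <- 1 - w0
  # sigma_b^2 = w0 w1 (mu0 - mu1)^2 = (mt*w0 - m)^2 / (w0 w1)
  num <- (mt * w0 - m[k])^2
  den <- w0 * w1
  sb <- ifelse(den > 0, num / den, -Inf)
  mx <- max(sb)
  ties <- sb >= mx - abs(mx) * 1e-9          # plateau across empty-gap splits
  mean(h$centers[k][ties])
}

.adtHist <- function(adt, nBins) {
  rng <- range(adt)
  width <- diff(rng) / nBins
  # right-closed bins except the first, matching hist(); top value in last bin
  edges <- rng[1] + width * (0:nBins)
  idx <- pmin(pmax(ceiling((adt - rng[1]) / width), 1L), nBins)
  counts <- tabulate(idx, nbins = nBins)
  centers <- rng[1] + width * (seq_len(nBins) - 0.5)
  list(counts = counts, centers = centers, edges = edges)
}

#' Ternary marker labels from an ADT vector
#'
#' Cells with \code{adt >= tStar + margin} are labeled \code{positive}, cells
#' with \code{adt <= tStar - margin} are \code{negative} (both boundaries
#' inclusive), and cells strictly inside the margin band are \code{excluded}
#' so that training never sees ambiguous cells. With \code{margin = 0} every
#' cell is assigned; a value exactly at t* is then \code{negative} (the
#' threshold bounds the low class from above).
#'
#' @param adt numeric vector, optionally named by barcode.
#' @param tStar threshold from \code{\link{otsuThreshold}}.
#' @param margin exclusion half-width on the ADT scale (default 0.5).
#' @param nBins bin count recorded for provenance.
#' @return an \linkS4class{AdtLabels} object.
#' @export
assignLabels <- function(adt, tStar, margin = 0.5, nBins = 256) {
  if (margin < 0) .cgStop("margin must be non-negative")
  adt <- if (is.null(names(adt))) stats::setNames(adt, seq_along(adt)) else adt
  lab <- rep("excluded", length(adt))
  lab[adt >= tStar + margin] <- "positive"
  lab[adt <= tStar - margin] <- "negative"
  if (margin == 0) lab[adt == tStar] <- "negative"
  if (!any(lab != "excluded"))
    .cgStop("all cells fall inside the exclusion margin; use a smaller margin")
  new("AdtLabels",
      labels = factor(lab, levels = c("negative", "excluded", "positive")),
      tStar = tStar, margin = margin, nBins = as.integer(nBins),
      cellIds = names(adt))
}

#' Otsu gating in one call
#'
#' @inheritParams assignLabels
#' @inheritParams otsuThreshold
#' @return an \linkS4class{AdtLabels}
#' @export
otsuLabels <- function(adt, margin = 0.5, nBins = 256) {
  assignLabels(adt, otsuThreshold(adt, nBins), margin = margin, nBins = nBins)
}

#' Write labels as a barcode,label CSV
#' @param labels an \linkS4class{AdtLabels}
#' @param path output CSV
#' @export
writeLabels <- function(labels, path) {
  utils::write.csv(
    data.frame(barcode = labels@cellIds,
               label = as.character(labels@labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
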