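#' Soft-margin support vector machine (hinge loss, SMO solver)
#'
#' C-SVC trained by sequential minimal optimization on a precomputed kernel
#' matrix (linear or radial-basis-function kernel). No probability
#' calibration: the decision value \eqn{f(x) = \sum_i \alpha_i y_i k(x_i, x)
#' + b} is thresholded at 0.
#'
#' @param X numeric matrix, cells x features.
#' @param y labels: factor/character positive/negative, or 0/1, or logical.
#' @param kernel "linear" or "rbf".
#' @param C soft-margin cost.
#' @param gamma RBF coefficient (ignored for linear).
#' @param tol SMO KKT violation tolerance.
#' @param maxIter cap on pair updates.
#' @return list with class \code{"cgSvm"}: support vectors, dual
#'   coefficients, intercept, kernel parameters.
#' @export
svmFit <- function(X, y, kernel = c("linear", "rbf"), C = 1, gamma = 0.1,
                   tol = 1e-3, maxIter = 500000L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  ypm <- .asPm1(y)
  if (length(unique(ypm)) < 2L) .cgStop("training labels are single-class")
  K <- .kernelMatrix(X, X, kernel, gamma)
  sol <- .smoSolve(K, ypm, C, tol, as.integer(maxIter))
  sv <- which(sol$alpha > 1e-12)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 sv = X[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * ypm[sv],
                 b = sol$b, iter = sol$iter, converged = sol$converged),
            class = "cgSvm")
}

#' SVM decision values
#' @param fit a \code{cgSvm} object
#' @param X cells x features matrix on the training feature space
#' @return numeric decision values (positive = marker-positive side)
#' @export
svmDecision <- function(fit, X) {
  K <- .kernelMatrix(as.matrix(X), fit$sv, fit$kernel, fit$gamma)
  as.numeric(K %*% fit$coef + fit$b)
}

.kernelMatrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

.asPm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.numeric(y)) return(ifelse(y > 0, 1, -1))
  cc <- as.character(y)
  if (!all(cc %in% c("positive", "negative")))
    .cgStop("labels must code positive/negative")
  ifelse(cc == "positive", 1, -1)
}
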