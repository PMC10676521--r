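#' Gaussian-process Bayesian optimization (expected improvement)
#'
#' Maximizes a black-box objective over a box with a Gaussian-process
#' surrogate (Matern nu = 5/2 kernel, isotropic length scale, observation
#' nugget; hyperparameters refit by marginal likelihood each iteration;
#' inputs min-max scaled to the unit box, objective values standardized).
#' Acquisition is expected improvement, maximized over a seeded random
#' candidate set. The initial design is a 5-point Latin hypercube; no priors
#' are placed on the optimum. Stops after \code{maxIter} evaluations beyond
#' the design, or as soon as the best achievable expected improvement drops
#' below \code{eiTol}.
#'
#' @param fn objective, called with a named numeric vector; larger is better.
#' @param lower,upper named numeric vectors bounding the box.
#' @param integerDims names of dimensions rounded to integers before
#'   evaluation.
#' @param maxIter maximum post-design evaluations (default 30).
#' @param eiTol expected-improvement stopping threshold (default 1e-6).
#' @param seed integer seed (design, candidates).
#' @param nInit design size (default 5).
#' @param nCandidates acquisition candidate count.
#' @return list: \code{par} (arg-best observed), \code{value},
#'   \code{trace} data.frame (iteration, parameters, objective value).
#' @export
gpOptimize <- function(fn, lower, upper, integerDims = character(0),
                       maxIter = 30, eiTol = 1e-6, seed = 0, nInit = 5,
                       nCandidates = 1000) {
  stopifnot(length(lower) == length(upper), !is.null(names(lower)))
  d <- length(lower)
  nm <- names(lower)
  set.seed(seed)

  toUnit <- function(x) (x - lower) / (upper - lower)
  fromUnit <- function(u) {
    x <- lower + u * (upper - lower)
    x[integerDims] <- round(x[integerDims])
    x
  }
  evalAt <- function(u) {
    x <- stats::setNames(fromUnit(u), nm)
    as.numeric(fn(x))
  }

  # Latin hypercube design
  U <- vapply(seq_len(d),
              function(j) (sample.int(nInit) - stats::runif(nInit)) / nInit,
              numeric(nInit))
  U <- matrix(U, nrow = nInit)
  Y <- apply(U, 1, evalAt)

  des <- do.call(rbind, lapply(seq_len(nInit), function(i) fromUnit(U[i, ])))
  trace <- data.frame(iteration = seq_len(nInit),
                      phase = "design", des, value = Y)
  names(trace)[3:(2 + d)] <- nm

  for (it in seq_len(maxIter)) {
    gp <- .gpFit(U, Y)
    cand <- matrix(stats::runif(nCandidates * d), ncol = d)
    # local refinement around the incumbent
    best <- U[which.max(Y), , drop = FALSE]
    loc <- pmin(pmax(best[rep(1, 50), , drop = FALSE] +
                       matrix(stats::rnorm(50 * d, 0, 0.05), ncol = d), 0), 1)
    cand <- rbind(cand, loc)
    ei <- .gpEi(gp, cand, max(Y))
    if (max(ei) < eiTol) break
    u <- cand[which.max(ei), ]
    y <- evalAt(u)
    U <- rbind(U, u)
    Y <- c(Y, y)
    row <- data.frame(iteration = nInit + it, phase = "bo",
                      matrix(fromUnit(u), nrow = 1), value = y)
    names(row)[3:(2 + d)] <- nm
    trace <- rbind(trace, row)
  }
  ibest <- which.max(Y)
  list(par = stats::setNames(fromUnit(U[ibest, ]), nm), value = Y[ibest],
       trace = trace)
}

## Matern 5/2 kernel on scaled inputs
.matern52 <- function(D, ell) {
  a <- sqrt(5) * D / ell
  (1 + a + a^2 / 3) * exp(-a)
}

.pdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

## fit GP hyperparameters (log ell, log nugget) by marginal likelihood;
## y standardized, unit signal variance
.gpFit <- function(U, Y) {
  mu <- mean(Y); sdv <- stats::sd(Y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (Y - mu) / sdv
  D <- .pdist(U, U)
  nll <- function(par) {
    ell <- exp(par[1]); nug <- exp(par[2])
    K <- .matern52(D, ell) + diag(nug, nrow(U))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(ch)))
  }
  opt <- stats::optim(c(log(0.5), log(1e-4)), nll, method = "L-BFGS-B",
                      lower = c(log(0.01), log(1e-8)),
                      upper = c(log(10), log(1)))
  ell <- exp(opt$par[1]); nug <- exp(opt$par[2])
  K <- .matern52(D, ell) + diag(nug, nrow(U))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), (Y - mu) / sdv))
  list(U = U, mu = mu, sd = sdv, ell = ell, nug = nug, chol = ch,
       alpha = alpha)
}

.gpPredict <- function(gp, X) {
  Ks <- .matern52(.pdist(X, gp$U), gp$ell)
  m <- as.numeric(Ks %*% gp$alpha) * gp$sd + gp$mu
  v <- backsolve(gp$chol, forwardsolve(t(gp$chol), t(Ks)))
  s2 <- pmax(1 - colSums(v * t(Ks) / 1), 1e-12) * gp$sd^2
  list(mean = m, sd = sqrt(s2))
}

.gpEi <- function(gp, X, yBest) {
  pr <- .gpPredict(gp, X)
  z <- (pr$mean - yBest) / pr$sd
  (pr$mean - yBest) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
}
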