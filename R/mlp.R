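#' Multilayer perceptron for binary classification
#'
#' Dense feed-forward network: \code{nLayers} hidden layers of \code{nNodes}
#' ReLU units each with inverted dropout at rate \code{rho}, a sigmoid output
#' unit, binary cross-entropy loss, Adam optimization. He-uniform weight
#' initialization, fixed 15 epochs and batch size 32 (the training recipe of
#' the pipeline); all randomness is governed by \code{seed}.
#'
#' @param X cells x features matrix.
#' @param y labels (positive/negative, logical or 0/1).
#' @param nLayers hidden layers (1-3).
#' @param nNodes units per hidden layer (16-128).
#' @param eta Adam learning rate.
#' @param rho dropout fraction in (0, 1).
#' @param epochs,batch training schedule.
#' @param seed integer seed.
#' @return list with class \code{"cgMlp"}: weights, biases, architecture,
#'   per-epoch training loss.
#' @export
mlpFit <- function(X, y, nLayers = 2, nNodes = 64, eta = 1e-3, rho = 0.2,
                   epochs = 15, batch = 32, seed = 0) {
  X <- as.matrix(X)
  yb <- as.numeric(.asPm1(y) > 0)
  n <- nrow(X); p <- ncol(X)
  nLayers <- as.integer(round(nLayers)); nNodes <- as.integer(round(nNodes))
  set.seed(seed)
  sizes <- c(p, rep(nNodes, nLayers), 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    lim <- sqrt(6 / sizes[l])                       # He-uniform
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(x) x * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  L <- length(W)
  lossTrace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epLoss <- 0
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      A <- list(X[idx, , drop = FALSE])
      masks <- list()
      for (l in seq_len(L - 1L)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        H <- pmax(Z, 0)
        M <- matrix(stats::runif(length(H)) >= rho, nrow(H), ncol(H)) / (1 - rho)
        masks[[l]] <- M * (Z > 0)                   # combined relu'+dropout
        A[[l + 1L]] <- H * M
      }
      zOut <- sweep(A[[L]] %*% W[[L]], 2, b[[L]], "+")
      prob <- 1 / (1 + exp(-zOut))
      yi <- yb[idx]
      epLoss <- epLoss - sum(yi * log(pmax(prob, 1e-12)) +
                             (1 - yi) * log(pmax(1 - prob, 1e-12)))
      delta <- (prob - yi) / length(idx)            # dBCE/dz at output
      gW <- list(); gB <- list()
      for (l in rev(seq_len(L))) {
        gW[[l]] <- t(A[[l]]) %*% delta
        gB[[l]] <- colSums(delta)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * masks[[l - 1L]]
      }
      tstep <- tstep + 1
      corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - eta * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
        vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
        b[[l]] <- b[[l]] - eta * (mB[[l]] / corr1) /
          (sqrt(vB[[l]] / corr2) + eps)
      }
    }
    lossTrace[ep] <- epLoss / n
  }
  structure(list(W = W, b = b, nLayers = nLayers, nNodes = nNodes,
                 eta = eta, rho = rho, loss = lossTrace),
            class = "cgMlp")
}

#' MLP predicted probabilities (dropout off)
#' @param fit a \code{cgMlp}
#' @param X cells x features matrix
#' @return numeric vector of P(positive)
#' @export
mlpPredict <- function(fit, X) {
  A <- as.matrix(X)
  L <- length(fit$W)
  for (l in seq_len(L - 1L))
    A <- pmax(sweep(A %*% fit$W[[l]], 2, fit$b[[l]], "+"), 0)
  z <- sweep(A %*% fit$W[[L]], 2, fit$b[[L]], "+")
  as.numeric(1 / (1 + exp(-z)))
}
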