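# Compact exact t-SNE (O(n^2), adequate for the few hundred samples
# embedded here): Gaussian input affinities with per-point perplexity
# calibration by bisection, Student-t low-dimensional kernel, gradient
# descent with momentum and early exaggeration.

tsnePerplexityP <- function(X, perplexity) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1e-12, length(di)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-12)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Two-dimensional t-SNE embedding
#'
#' @param X numeric matrix (samples in rows).
#' @param perplexity effective neighbour count (reduced automatically when
#'   the sample is small).
#' @param maxIter gradient-descent iterations.
#' @param seed optional seed for the initial layout.
#' @return n x 2 coordinate matrix.
#' @export
tsneEmbed <- function(X, perplexity = 10, maxIter = 300L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("t-SNE needs at least 4 samples")
  perplexity <- min(perplexity, (n - 1) / 3)
  if (!is.null(seed)) set.seed(seed)
  P <- tsnePerplexityP(X, perplexity)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (iter in seq_len(maxIter)) {
    ex <- if (iter <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - 200 * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 100) momentum <- 0.8
  }
  Y
}
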