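# Exact (O(n^2)) t-SNE, sufficient for the few-hundred-point embeddings used
# here. Standard recipe: binary-search per-point bandwidths to match the
# target perplexity, symmetrise, early exaggeration, momentum gradient
# descent on the Kullback-Leibler divergence to a Student-t low-dimensional
# affinity.

tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  D2 <- pairwise_sqdist(as.matrix(x))
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 10; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2-D t-SNE embedding (exact, small-n)
#'
#' @param x Numeric matrix (rows = points).
#' @param perplexity Target perplexity (default 30; clipped to `(n-1)/3`).
#' @param n_iter Gradient-descent iterations (default 400).
#' @param seed Integer seed for the random initialisation.
#' @return n x 2 matrix of coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, n_iter = 400, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) abort("tsne_embed: need at least 4 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  P <- tsne_affinities(x, perplexity)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    d2 <- pairwise_sqdist(Y)
    W <- 1 / (1 + d2)
    diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    L <- (ex * P - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    mom <- if (it <= 250) 0.5 else 0.8
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
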