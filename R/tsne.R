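# Exact t-SNE on a precomputed dissimilarity matrix.
#
# Standard formulation: input affinities p_{j|i} from a Gaussian kernel on
# squared dissimilarities with per-point bandwidth calibrated by binary
# search so the perplexity of each conditional distribution matches the
# target; symmetrized joint P; Student-t (1 df) low-dimensional affinities;
# gradient descent with early exaggeration, momentum switching and
# delta-bar-delta per-parameter gains.  Exact O(n^2) per iteration, which is
# the right trade-off at the few-hundred-entity scale this package targets.

tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    for (try in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      err <- H - target
      if (abs(err) < tol) break
      if (err > 0) {  # entropy too high -> sharpen
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- P + t(P)
  P <- P / sum(P)
  pmax(P, .Machine$double.xmin)
}

tsne_precomputed <- function(D, dims = 2L, perplexity = 30, seed = NULL,
                             max_iter = 1000L, eta = NULL,
                             exaggeration = 12, mom_switch = 250L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 5L) stop("t-SNE needs at least 5 points")
  if (perplexity < 3 || perplexity >= n)
    stop("perplexity must lie in [3, n_entities)")
  if (anyNA(D)) stop("dissimilarity matrix must be complete (no NA)")
  if (is.null(eta)) eta <- max(50, n / 12)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  P <- tsne_affinities(D^2, perplexity)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= mom_switch) exaggeration else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (ex * P - Q) * num
    grad <- 4 * ((diag(rowSums(L), n) - L) %*% Y)
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * (gains * grad)
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == mom_switch) momentum <- 0.8
  }
  if (!all(is.finite(Y))) stop("t-SNE diverged to non-finite coordinates")
  Y
}
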