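# t-distributed stochastic neighbour embedding, exact (O(n^2)) variant.
# Implemented in the package because the embedding is applied to small
# cohorts (tens of samples); the standard algorithm is used: per-point
# bandwidths found by bisection to match a target perplexity, symmetrized
# input affinities, Student-t output kernel, gradient descent with momentum,
# adaptive gains and early exaggeration.

# Conditional Gaussian affinities with entropy matched to log(perplexity).
tsne_input_affinities <- function(d2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- d2[i, -i]
    for (tries in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
        pj <- w
      } else {
        h <- log(sw) + beta * sum(di * w) / sw
        pj <- w / sw
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    p[i, -i] <- pj
  }
  p
}

#' t-SNE embedding of samples
#'
#' Embeds the rows of a numeric matrix (samples x features, e.g. samples by
#' `log2(RPM + 1)` piRNA expression) into a low-dimensional map. Exact
#' t-SNE; deterministic for a fixed seed.
#'
#' @param x Numeric matrix, one row per sample.
#' @param dims Output dimensionality (default 3).
#' @param perplexity Target perplexity (default 10); requires
#'   `nrow(x) > 3 * perplexity`.
#' @param max_iter Gradient-descent iterations (default 1000).
#' @param seed RNG seed for the initial layout (default 1).
#' @param eta Learning rate (default 200).
#' @return An object of class `tsne_embedding`: `coords` (samples x `dims`,
#'   row order preserved) and `params`.
#' @export
tsne_embed <- function(x, dims = 3L, perplexity = 10, max_iter = 1000L,
                       seed = 1L, eta = 200) {
  x <- as.matrix(x)
  n <- nrow(x)
  abort_if(n <= 3 * perplexity,
           "perplexity %g too large: need n_samples > 3 * perplexity (i.e. n > %g, got %d)",
           perplexity, 3 * perplexity, n)
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_input_affinities(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, .Machine$double.eps)

  exaggeration <- 4
  stop_exaggeration <- 100L
  momentum <- 0.5
  final_momentum <- 0.8
  momentum_switch <- 250L

  y <- with_seed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)

  pe <- p * exaggeration
  for (iter in seq_len(max_iter)) {
    pm <- if (iter <= stop_exaggeration) pe else p
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), .Machine$double.eps)
    mult <- (pm - q) * num
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- (if (iter < momentum_switch) momentum else final_momentum) * inc -
      eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
  }
  rownames(y) <- rownames(x)
  colnames(y) <- paste0("dim", seq_len(dims))
  structure(
    list(coords = y,
         params = list(dims = dims, perplexity = perplexity,
                       max_iter = max_iter, seed = seed, eta = eta)),
    class = "tsne_embedding"
  )
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("tsne_embedding: %d samples in %d dimensions (perplexity %g, seed %d)\n",
              nrow(x$coords), x$params$dims, x$params$perplexity,
              x$params$seed))
  invisible(x)
}
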