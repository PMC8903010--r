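# 2-D neighborhood-graph embedding of neuron medoids, used as a
# pre-processing step for density clustering. The construction follows the
# UMAP recipe: a fuzzy k-nearest-neighbor graph with locally adaptive kernel
# widths, a low-dimensional layout optimized under the standard
# attraction/repulsion curve 1 / (1 + a * d^(2b)) with (a, b) fitted from
# `min_dist`, and negative sampling for repulsion. Updates are applied in
# deterministic per-epoch batches (all edges each epoch, weighted by edge
# membership strength) rather than stochastic per-edge scheduling, which keeps
# the layout reproducible from the seed alone.

# Fit the (a, b) curve parameters so that 1/(1 + a d^(2b)) approximates
# exp(-(d - min_dist)) beyond min_dist and 1 below it.
fit_ab <- function(min_dist, spread = 1) {
  ds <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(ds < min_dist, 1, exp(-(ds - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * ds^(2 * b)) - target)^2)
  }
  p <- stats::optim(c(log(1.6), log(0.9)), obj, method = "Nelder-Mead")$par
  c(a = exp(p[1]), b = exp(p[2]))
}

# Fuzzy kNN graph: rho_i = distance to the nearest neighbor, sigma_i solved by
# bisection so the smoothed neighbor weights sum to log2(k). Returns an edge
# list symmetrized by probabilistic union (w1 + w2 - w1 * w2).
fuzzy_knn_graph <- function(D, k) {
  n <- nrow(D)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    nbr <- order(d)[seq_len(k)]
    dn <- d[nbr]
    rho <- min(dn)
    target <- log2(k)
    lo <- 1e-10; hi <- max(dn - rho) + 1
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-pmax(dn - rho, 0) / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    sigma <- (lo + hi) / 2
    cols <- seq_len(n)[-i][nbr]
    W[i, cols] <- exp(-pmax(dn - rho, 0) / sigma)
  }
  S <- W + t(W) - W * t(W)
  idx <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = S[idx])
}

#' Embed neuron medoids in two dimensions
#'
#' Builds a fuzzy k-nearest-neighbor graph over the medoid vectors (Euclidean
#' metric) and optimizes a 2-D layout with attractive forces along graph edges
#' and repulsive forces against negative samples. Deterministic for a fixed
#' seed. Intended as pre-processing for [cluster_neurons()].
#'
#' @param medoids matrix of medoid vectors from [neuron_medoids()] (one row
#'   per occupied neuron).
#' @param n_neighbors local neighborhood size (default 6).
#' @param min_dist minimum effective distance between embedded points
#'   (default 0.3).
#' @param n_epochs layout optimization epochs (default 100).
#' @param seed integer seed.
#' @param neg_samples negative samples per edge endpoint per epoch.
#' @param learning_rate initial layout learning rate (decays linearly to 0).
#' @return n x 2 matrix of embedded coordinates (rownames preserved), with
#'   attribute `neuron` carried over from `medoids` when present.
#' @export
embed_neurons <- function(medoids, n_neighbors = 6, min_dist = 0.3,
                          n_epochs = 100, seed = 1, neg_samples = 5,
                          learning_rate = 1) {
  X <- as.matrix(medoids)
  n <- nrow(X)
  if (n < n_neighbors + 1)
    stopf("need at least n_neighbors + 1 = %d points, got %d",
          n_neighbors + 1, n)
  D <- as.matrix(stats::dist(X))
  edges <- fuzzy_knn_graph(D, n_neighbors)
  ab <- fit_ab(min_dist)
  a <- ab["a"]; b <- ab["b"]
  clamp <- function(v) pmax(pmin(v, 4), -4)
  Y <- with_seed(seed, {
    # PCA initialization, rescaled; deterministic and structure-preserving
    pc <- stats::prcomp(X, rank. = 2)$x
    if (ncol(pc) < 2) pc <- cbind(pc, 0)
    span <- max(abs(pc), 1e-9)
    Y <- pc / span * 10
    Y <- Y + matrix(stats::rnorm(2 * n, sd = 1e-4), n, 2)  # break exact ties
    ei <- edges$i; ej <- edges$j; ew <- edges$w
    ne <- length(ei)
    for (epoch in seq_len(n_epochs)) {
      alpha <- learning_rate * (1 - (epoch - 1) / n_epochs)
      diff <- Y[ei, , drop = FALSE] - Y[ej, , drop = FALSE]
      d2 <- rowSums(diff^2)
      att <- (-2 * a * b * d2^pmax(b - 1, 0)) / (1 + a * d2^b)
      f <- cbind(clamp(att * diff[, 1]), clamp(att * diff[, 2])) * ew
      upd <- rowsum(rbind(f, -f), group = c(ei, ej))
      rows <- as.integer(rownames(upd))
      Y[rows, ] <- Y[rows, ] + alpha * upd
      # repulsion by negative sampling from both edge endpoints
      src <- rep(c(ei, ej), each = neg_samples)
      tgt <- sample.int(n, length(src), replace = TRUE)
      keep <- src != tgt
      src <- src[keep]; tgt <- tgt[keep]
      diff <- Y[src, , drop = FALSE] - Y[tgt, , drop = FALSE]
      d2 <- rowSums(diff^2)
      rep_c <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
      f <- cbind(clamp(rep_c * diff[, 1]), clamp(rep_c * diff[, 2]))
      upd <- rowsum(f, group = src)
      rows <- as.integer(rownames(upd))
      Y[rows, ] <- Y[rows, ] + alpha * upd / neg_samples
    }
    Y
  })
  rownames(Y) <- rownames(medoids)
  colnames(Y) <- c("dim1", "dim2")
  attr(Y, "neuron") <- attr(medoids, "neuron")
  Y
}
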