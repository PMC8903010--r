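#' Parameters of a self-organizing feature map
#'
#' The map is a square Kohonen grid of `grid_side^2` neurons, each holding a
#' weight vector of the input dimension. During training, the best-matching
#' unit (BMU) of a sample is the neuron minimizing Euclidean distance; every
#' neuron within Chebyshev grid distance `learning_radius` of the BMU is moved
#' toward the sample by `step * exp(-d^2 / (2 * std^2))`, with `d` the
#' Euclidean grid distance. Step and radius are held constant across epochs.
#'
#' @param grid_side side of the neuron grid (default 30, i.e. 900 neurons).
#' @param learning_radius neighborhood cutoff in grid units (default 5).
#' @param std Gaussian neighborhood standard deviation (default 0.5).
#' @param step learning rate (default 0.01).
#' @param epochs training epochs (default 30).
#' @param seed integer seed for weight init and per-epoch sample shuffles.
#' @param radius_metric grid metric for the neighborhood cutoff; the Gaussian
#'   itself always uses Euclidean grid distance.
#' @return An object of class `sofm_params`.
#' @export
sofm_params <- function(grid_side = 30, learning_radius = 5, std = 0.5,
                        step = 0.01, epochs = 30, seed = 1,
                        radius_metric = c("chebyshev", "euclidean")) {
  radius_metric <- match.arg(radius_metric)
  if (grid_side <= 0 || learning_radius <= 0 || std <= 0 || step <= 0 ||
      epochs <= 0)
    stopf("all SOFM parameters must be positive")
  structure(list(grid_side = as.integer(grid_side),
                 learning_radius = learning_radius, std = std, step = step,
                 epochs = as.integer(epochs), seed = seed,
                 radius_metric = radius_metric),
            class = "sofm_params")
}

# Precompute, for each neuron, the indices of its neighborhood (cutoff on the
# chosen grid metric) and their Gaussian factors. The grid never changes, so
# this is done once per training run.
sofm_neighborhoods <- function(params) {
  g <- params$grid_side
  row <- (seq_len(g * g) - 1L) %/% g
  col <- (seq_len(g * g) - 1L) %% g
  lapply(seq_len(g * g), function(k) {
    dr <- row - row[k]
    dc <- col - col[k]
    cut <- if (params$radius_metric == "chebyshev") pmax(abs(dr), abs(dc))
           else sqrt(dr^2 + dc^2)
    idx <- which(cut <= params$learning_radius)
    d2 <- dr[idx]^2 + dc[idx]^2
    list(idx = idx, gauss = exp(-d2 / (2 * params$std^2)))
  })
}

# Batch best-matching units: brute-force nearest neuron for each row of X,
# ties broken by the lowest neuron index.
bmu_assign <- function(W, X) {
  d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
  max.col(-d2, ties.method = "first")
}

#' Train a self-organizing feature map
#'
#' Weights are initialized uniformly at random in (0, 1) from the seed.
#' Each epoch visits the samples in a seeded shuffle and applies the
#' neighborhood update described in [sofm_params()]. Final assignments map
#' every sample to its BMU.
#'
#' @param X transformed `submatrix_set` or numeric matrix (samples x cells)
#'   with values in (0, 1).
#' @param params an [sofm_params()].
#' @return An object of class `sofm_model`: `params`, `weights`
#'   (`grid_side^2` x d), `grid` (0-based `row`,`col` per neuron),
#'   `assignments` (neuron index per sample), `n_samples`.
#' @export
train_sofm <- function(X, params = sofm_params()) {
  if (inherits(X, "submatrix_set")) {
    if (!isTRUE(X$transformed)) stopf("submatrices must be transformed first")
    X <- X$X
  }
  X <- as.matrix(X)
  if (nrow(X) == 0) stopf("no samples to train on")
  g <- params$grid_side
  nn <- g * g
  d <- ncol(X)
  nb <- sofm_neighborhoods(params)
  W <- with_seed(params$seed, {
    W <- matrix(stats::runif(nn * d), nn, d)
    rs <- rowSums(W^2)
    for (e in seq_len(params$epochs)) {
      ord <- sample.int(nrow(X))
      for (s in ord) {
        x <- X[s, ]
        dist2 <- rs - 2 * drop(W %*% x)  # + const(x), irrelevant for argmin
        b <- which.min(dist2)
        hood <- nb[[b]]
        idx <- hood$idx
        upd <- params$step * hood$gauss
        delta <- (matrix(x, length(idx), d, byrow = TRUE) -
                    W[idx, , drop = FALSE]) * upd
        W[idx, ] <- W[idx, , drop = FALSE] + delta
        rs[idx] <- rowSums(W[idx, , drop = FALSE]^2)
      }
    }
    W
  })
  structure(list(
    params = params, weights = W,
    grid = data.frame(row = (seq_len(nn) - 1L) %/% g,
                      col = (seq_len(nn) - 1L) %% g),
    assignments = bmu_assign(W, X),
    n_samples = nrow(X), d = d
  ), class = "sofm_model")
}

#' @export
print.sofm_model <- function(x, ...) {
  occ <- length(unique(x$assignments))
  cat(sprintf("<sofm_model> %dx%d grid (%d neurons, %d occupied), %d samples\n",
              x$params$grid_side, x$params$grid_side, nrow(x$weights), occ,
              x$n_samples))
  invisible(x)
}

#' Map samples to their best-matching neurons
#'
#' @param model a trained [train_sofm()] model.
#' @param X numeric matrix or transformed `submatrix_set`.
#' @return integer vector of neuron indices (1-based).
#' @export
map_to_neurons <- function(model, X) {
  if (inherits(X, "submatrix_set")) X <- X$X
  bmu_assign(model$weights, as.matrix(X))
}

#' Per-neuron medoid submatrices
#'
#' The medoid of a neuron is the member submatrix minimizing the summed
#' Euclidean distance to all members of that neuron (a singleton is its own
#' medoid); it is always an actual member, never an average. Empty neurons are
#' absent from the result.
#'
#' @param model a trained SOFM model.
#' @param X the training matrix / `submatrix_set` (row order must match the
#'   model's assignments).
#' @return matrix of medoid vectors (one row per occupied neuron), with
#'   attributes `neuron` (neuron indices) and `sample` (row index of each
#'   medoid in `X`).
#' @export
neuron_medoids <- function(model, X) {
  if (inherits(X, "submatrix_set")) X <- X$X
  X <- as.matrix(X)
  occ <- sort(unique(model$assignments))
  med_sample <- vapply(occ, function(k) {
    members <- which(model$assignments == k)
    if (length(members) == 1) return(members)
    D <- as.matrix(stats::dist(X[members, , drop = FALSE]))
    members[which.min(colSums(D))]
  }, integer(1))
  out <- X[med_sample, , drop = FALSE]
  rownames(out) <- as.character(occ)
  attr(out, "neuron") <- occ
  attr(out, "sample") <- med_sample
  out
}

#' Per-neuron mean submatrices
#'
#' The average of all member submatrices of each occupied neuron. Unlike the
#' medoid (an actual member), the mean suppresses per-sample noise, which
#' makes it the better distance substrate for clustering neurons; the medoid
#' remains the representation of choice for display.
#'
#' @inheritParams neuron_medoids
#' @return matrix of mean vectors (one row per occupied neuron) with
#'   attribute `neuron`.
#' @export
neuron_means <- function(model, X) {
  if (inherits(X, "submatrix_set")) X <- X$X
  X <- as.matrix(X)
  occ <- sort(unique(model$assignments))
  out <- t(vapply(occ, function(k)
    colMeans(X[model$assignments == k, , drop = FALSE]), numeric(ncol(X))))
  rownames(out) <- as.character(occ)
  attr(out, "neuron") <- occ
  out
}

#' Map pair anchors to compartment eigenvector values
#'
#' Each pair's two anchor positions (at the fine, e.g. 5 kb, scale) are mapped
#' to bins of the coarse compartment track and the eigenvector values there
#' are returned (NA outside the track or at masked bins).
#'
#' @param pairs pair table (needs `up_center`, `down_center`).
#' @param track a `compartment_track`.
#' @return n x 2 numeric matrix of eigenvector values per anchor.
#' @export
pair_eigen_values <- function(pairs, track) {
  f <- function(pos) {
    b <- pos_to_bin(pos, track$resolution) + 1L
    ok <- b >= 1 & b <= length(track$eigenvector)
    out <- rep(NA_real_, length(pos))
    out[ok] <- track$eigenvector[b[ok]]
    out
  }
  cbind(up = f(pairs$up_center), down = f(pairs$down_center))
}

#' SOFM model-selection metrics
#'
#' Three quality measures used to choose SOFM parameters:
#' `pct_classified`, the percentage of samples landing in neurons holding at
#' least two samples (singleton neurons count as unclassified);
#' `inter_neuron_variability`, the mean pairwise Euclidean distance between
#' weight vectors of occupied neurons; and `segregation_score`, the mean over
#' occupied neurons of the absolute mean compartment-eigenvector value across
#' all anchor bins of the neuron's submatrices (both anchors contribute).
#'
#' @param model a trained SOFM model.
#' @param anchor_eigen n x 2 matrix from [pair_eigen_values()] aligned with
#'   the model's samples, or `NULL` to skip the segregation score.
#' @param weighted if `TRUE`, the segregation score weights neurons by
#'   occupancy instead of the default unweighted mean.
#' @return list of class `selection_metrics` with the three values.
#' @export
selection_metrics <- function(model, anchor_eigen = NULL, weighted = FALSE) {
  counts <- table(model$assignments)
  n <- model$n_samples
  pct <- 100 * sum(counts[counts >= 2]) / n
  occ <- as.integer(names(counts))
  W_occ <- model$weights[occ, , drop = FALSE]
  variability <- if (length(occ) < 2) 0 else mean(stats::dist(W_occ))
  segregation <- NA_real_
  if (!is.null(anchor_eigen)) {
    scores <- vapply(occ, function(k) {
      vals <- anchor_eigen[model$assignments == k, , drop = FALSE]
      vals <- vals[is.finite(vals)]
      if (length(vals) == 0) NA_real_ else abs(mean(vals))
    }, numeric(1))
    wts <- if (weighted) as.numeric(counts) else rep(1, length(occ))
    ok <- is.finite(scores)
    segregation <- sum(scores[ok] * wts[ok]) / sum(wts[ok])
  }
  structure(list(pct_classified = pct,
                 inter_neuron_variability = variability,
                 segregation_score = segregation),
            class = "selection_metrics")
}

#' @export
print.selection_metrics <- function(x, ...) {
  cat(sprintf(paste0("<selection_metrics> classified: %.1f%%, ",
                     "inter-neuron variability: %.4f, segregation: %.4f\n"),
              x$pct_classified, x$inter_neuron_variability,
              x$segregation_score))
  invisible(x)
}

#' Grid search over SOFM parameters
#'
#' Trains one model per parameter combination and tabulates the selection
#' metrics. The recommended pick (attribute `"best"`) is Pareto-optimal on the
#' three metrics with `pct_classified` prioritized for tie-breaking.
#'
#' @param X sample matrix or transformed `submatrix_set`.
#' @param param_grid named list of parameter vectors (any subset of
#'   `grid_side`, `learning_radius`, `std`, `step`, `epochs`); crossed with
#'   `expand.grid`.
#' @param anchor_eigen optional n x 2 eigenvector matrix for the segregation
#'   score.
#' @param seed seed used for every trained model.
#' @return data.frame with one row per combination and the three metric
#'   columns; attribute `"best"` is the recommended row index.
#' @export
sofm_grid_search <- function(X, param_grid, anchor_eigen = NULL, seed = 1) {
  combos <- expand.grid(param_grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(combos) == 0) stopf("empty parameter grid")
  res <- lapply(seq_len(nrow(combos)), function(r) {
    args <- as.list(combos[r, , drop = FALSE])
    args$seed <- seed
    p <- do.call(sofm_params, args)
    m <- selection_metrics(train_sofm(X, p), anchor_eigen)
    data.frame(combos[r, , drop = FALSE],
               pct_classified = m$pct_classified,
               inter_neuron_variability = m$inter_neuron_variability,
               segregation_score = m$segregation_score)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  metrics <- as.matrix(tab[, c("pct_classified", "inter_neuron_variability",
                               "segregation_score")])
  metrics[!is.finite(metrics)] <- -Inf
  dominated <- vapply(seq_len(nrow(metrics)), function(i) {
    any(vapply(seq_len(nrow(metrics)), function(j) {
      j != i && all(metrics[j, ] >= metrics[i, ]) &&
        any(metrics[j, ] > metrics[i, ])
    }, logical(1)))
  }, logical(1))
  front <- which(!dominated)
  best <- front[order(-metrics[front, 1], -metrics[front, 2],
                      -metrics[front, 3])][1]
  attr(tab, "best") <- best
  tab
}
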