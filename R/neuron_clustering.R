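#' Summarize neuron clusters into topology classes
#'
#' Pools, for each cluster of neurons, its member submatrices; records the
#' pooled medoid (the member submatrix minimizing summed Euclidean distance
#' to all pooled members) and the neuron/submatrix counts. Clusters are then
#' ordered by descending central-pixel intensity of their medoid, so cluster 1
#' is the most loop-like and the last cluster the flattest. Noise neurons
#' (label -1) are excluded from every summary.
#'
#' @param labels cluster labels from [cluster_neurons()] (attribute `neuron`
#'   mapping each label to its neuron index, as produced by the
#'   [neuron_medoids()] -> [embed_neurons()] -> [cluster_neurons()] chain).
#' @param model the trained SOFM model.
#' @param X the sample matrix / transformed `submatrix_set` behind the model.
#' @param medoid_cap at most this many pooled members are used when computing
#'   a cluster medoid (the first `medoid_cap` by sample index), bounding the
#'   quadratic distance computation.
#' @return An object of class `cluster_summary`: `summary` (data.frame with
#'   `cluster`, `n_neurons`, `n_submatrices`, `central_intensity`), `medoids`
#'   (k x d matrix), `neuron_map` (list cluster -> neuron indices),
#'   `sample_cluster` (per-sample cluster id; -1 for samples in noise or
#'   unlabelled neurons).
#' @export
summarize_clusters <- function(labels, model, X, medoid_cap = 2000) {
  if (inherits(X, "submatrix_set")) X <- X$X
  X <- as.matrix(X)
  neurons <- attr(labels, "neuron")
  if (is.null(neurons)) stopf("labels must carry a 'neuron' attribute")
  ids <- sort(unique(labels[labels > 0]))
  d <- ncol(X)
  center_cell <- (d + 1) %/% 2  # cell (5,5) of a row-major 9x9, i.e. 41
  rows <- list(); meds <- list(); nmap <- list()
  for (cl in ids) {
    neu <- neurons[labels == cl]
    members <- which(model$assignments %in% neu)
    pool <- members[seq_len(min(length(members), medoid_cap))]
    if (length(pool) == 1) {
      med <- X[pool, ]
    } else {
      Dm <- as.matrix(stats::dist(X[pool, , drop = FALSE]))
      med <- X[pool[which.min(colSums(Dm))], ]
    }
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cl, n_neurons = length(neu), n_submatrices = length(members),
      central_intensity = med[center_cell])
    meds[[length(meds) + 1]] <- med
    nmap[[length(nmap) + 1]] <- neu
  }
  if (length(rows) == 0) {
    return(structure(list(
      summary = data.frame(cluster = integer(), n_neurons = integer(),
                           n_submatrices = integer(),
                           central_intensity = numeric()),
      medoids = matrix(numeric(0), 0, d), neuron_map = list(),
      sample_cluster = rep(-1L, model$n_samples)), class = "cluster_summary"))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$central_intensity, tab$cluster)
  tab <- tab[ord, ]
  meds <- do.call(rbind, meds)[ord, , drop = FALSE]
  nmap <- nmap[ord]
  tab$cluster <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  rownames(meds) <- as.character(tab$cluster)
  names(nmap) <- as.character(tab$cluster)
  sample_cluster <- rep(-1L, model$n_samples)
  for (z in seq_len(nrow(tab))) {
    sample_cluster[model$assignments %in% nmap[[z]]] <- z
  }
  structure(list(summary = tab, medoids = meds, neuron_map = nmap,
                 sample_cluster = sample_cluster),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %d clusters\n", nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Partition clusters into loop and no-loop sides
#'
#' Clusters (already ordered most-loop-like first) are split at the largest
#' gap in medoid central-pixel intensity: clusters above the gap form the
#' `loop` side, clusters below it the `no_loop` side. The split is
#' deterministic and parameter-free; inspect `summary$central_intensity` when
#' overriding it by hand.
#'
#' @param cs a [summarize_clusters()] result with >= 2 clusters.
#' @return list with integer vectors `loop` and `no_loop` of cluster ids.
#' @export
partition_clusters <- function(cs) {
  tab <- cs$summary
  if (nrow(tab) < 2) stopf("need >= 2 clusters to partition")
  ci <- tab$central_intensity  # already sorted decreasing
  gap <- which.max(ci[-length(ci)] - ci[-1])
  list(loop = tab$cluster[seq_len(gap)],
       no_loop = tab$cluster[(gap + 1):nrow(tab)])
}
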