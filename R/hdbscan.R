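# Hierarchical density-based clustering of the embedded neurons, following
# the HDBSCAN construction: core distances from `min_samples` nearest
# neighbors, mutual-reachability distances, single-linkage hierarchy, tree
# condensation at `min_cluster_size`, and excess-of-mass cluster selection.
# A single all-encompassing cluster is allowed (a dataset that is one dense
# blob yields one cluster, not noise). Points in no selected cluster are
# labelled -1.

# Leaf points (1..n) of a subtree of an hclust merge matrix.
hc_leaves <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (k < 0) out <- c(out, -k)
    else stack <- c(stack, merge[k, 1], merge[k, 2])
  }
  out
}

#' Density-based clustering of embedded neurons
#'
#' @param embedding n x 2 coordinate matrix from [embed_neurons()] (any
#'   numeric matrix of points works).
#' @param min_cluster_size smallest allowed cluster (default 6; must be >= 2).
#' @param min_samples neighborhood size for core distances (default 6); the
#'   core distance of a point is the distance to its `min_samples`-th nearest
#'   neighbor, the point itself included.
#' @return integer vector of cluster labels (1..k, noise = -1), with
#'   attribute `neuron` carried over from the embedding when present.
#' @export
cluster_neurons <- function(embedding, min_cluster_size = 6, min_samples = 6) {
  X <- as.matrix(embedding)
  n <- nrow(X)
  mcs <- as.integer(min_cluster_size)
  if (mcs < 2) stopf("min_cluster_size must be >= 2")
  labels <- rep(-1L, n)
  if (n < mcs) {
    attr(labels, "neuron") <- attr(embedding, "neuron")
    return(labels)
  }
  D <- as.matrix(stats::dist(X))
  k <- min(min_samples, n)
  core <- apply(D, 1, function(r) sort(r)[k])
  M <- pmax(D, outer(core, core, pmax))
  diag(M) <- 0
  hc <- stats::hclust(stats::as.dist(M), method = "single")
  merge <- hc$merge
  hgt <- hc$height
  nsize <- integer(n - 1)
  for (r in seq_len(n - 1)) {
    s1 <- if (merge[r, 1] < 0) 1L else nsize[merge[r, 1]]
    s2 <- if (merge[r, 2] < 0) 1L else nsize[merge[r, 2]]
    nsize[r] <- s1 + s2
  }
  lam <- function(r) 1 / max(hgt[r], 1e-12)

  # --- condense the hierarchy -------------------------------------------
  parent <- integer(0); birth <- numeric(0); stability <- numeric(0)
  children <- list()
  attach <- integer(n)  # condensed-tree cluster each point falls out of
  new_cluster <- function(p, b) {
    parent[length(parent) + 1] <<- p
    birth[length(birth) + 1] <<- b
    stability[length(stability) + 1] <<- 0
    children[[length(children) + 1]] <<- integer(0)
    if (p > 0) children[[p]] <<- c(children[[p]], length(parent))
    length(parent)
  }
  root <- new_cluster(0L, 0)
  stack <- list(list(node = n - 1L, cluster = root))
  while (length(stack)) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- it$node; cl <- it$cluster
    l <- lam(node)
    ch <- merge[node, ]
    sz <- ifelse(ch < 0, 1L, nsize[pmax(ch, 1)])
    big <- sz >= mcs
    if (all(big)) {
      stability[cl] <- stability[cl] + sum(sz) * (l - birth[cl])
      for (side in 1:2) {
        sub <- new_cluster(cl, l)
        stack[[length(stack) + 1]] <- list(node = ch[side], cluster = sub)
      }
    } else if (any(big)) {
      small <- which(!big); keep <- which(big)
      pts <- hc_leaves(merge, ch[small])
      attach[pts] <- cl
      stability[cl] <- stability[cl] + length(pts) * (l - birth[cl])
      stack[[length(stack) + 1]] <- list(node = ch[keep], cluster = cl)
    } else {
      pts <- c(hc_leaves(merge, ch[1]), hc_leaves(merge, ch[2]))
      attach[pts] <- cl
      stability[cl] <- stability[cl] + length(pts) * (l - birth[cl])
    }
  }

  # --- excess-of-mass selection -----------------------------------------
  nc <- length(parent)
  selected <- logical(nc)
  hat <- numeric(nc)
  descendants <- function(c0) {
    out <- integer(0); st <- children[[c0]]
    while (length(st)) {
      x <- st[length(st)]; st <- st[-length(st)]
      out <- c(out, x); st <- c(st, children[[x]])
    }
    out
  }
  for (cl in nc:1) {
    kids <- children[[cl]]
    if (length(kids) == 0) {
      selected[cl] <- TRUE
      hat[cl] <- stability[cl]
    } else if (cl == root) {
      # the root is born at lambda 0, which inflates its mass; it only
      # stands as a cluster when the tree never produced a true split
      hat[cl] <- sum(hat[kids])
    } else {
      csum <- sum(hat[kids])
      if (stability[cl] >= csum) {
        selected[cl] <- TRUE
        selected[descendants(cl)] <- FALSE
        hat[cl] <- stability[cl]
      } else {
        hat[cl] <- csum
      }
    }
  }

  # --- hard labels -------------------------------------------------------
  lab_of <- integer(nc)  # selected ancestor-or-self, 0 if none
  for (cl in seq_len(nc)) {
    cur <- cl
    while (cur > 0 && !selected[cur]) cur <- parent[cur]
    lab_of[cl] <- cur
  }
  raw <- lab_of[attach]
  used <- unique(raw[raw > 0])
  if (length(used)) {
    # stable numbering by first member point
    firsts <- vapply(used, function(u) min(which(raw == u)), integer(1))
    used <- used[order(firsts)]
    for (z in seq_along(used)) labels[raw == used[z]] <- z
  }
  attr(labels, "neuron") <- attr(embedding, "neuron")
  labels
}
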