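# Reproducibility and biological-relevance metrics for loop-call sets.

loop_keys <- function(x) paste(x$chrom, x$bin_i, x$bin_j)

#' Exact-anchor Jaccard index between two loop-call sets
#'
#' Two loops are identical iff they share both anchoring bins (and the
#' chromosome) exactly.
#'
#' @param A,B `loop_calls` data.frames at the same resolution.
#' @return |A intersect B| / |A union B|.
#' @export
loop_jaccard <- function(A, B) {
  if (nrow(A) == 0 && nrow(B) == 0)
    stopf("Jaccard undefined for two empty loop sets")
  ka <- unique(loop_keys(A)); kb <- unique(loop_keys(B))
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Loose-anchor Jaccard index
#'
#' Greedy one-to-one matching in ascending anchor order: loops match iff both
#' anchors differ by at most `tol_bins`. With `tol_bins = 0` this reduces to
#' [loop_jaccard()]. The index is `matched / (|A| + |B| - matched)`.
#'
#' @param A,B `loop_calls` data.frames.
#' @param tol_bins per-anchor tolerance in bins (default 1).
#' @return loose Jaccard fraction.
#' @export
loop_jaccard_loose <- function(A, B, tol_bins = 1) {
  if (nrow(A) == 0 && nrow(B) == 0)
    stopf("Jaccard undefined for two empty loop sets")
  matched <- 0L
  for (ch in union(A$chrom, B$chrom)) {
    a <- A[A$chrom == ch, , drop = FALSE]
    b <- B[B$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    a <- a[order(a$bin_i, a$bin_j), ]
    b <- b[order(b$bin_i, b$bin_j), ]
    taken <- rep(FALSE, nrow(b))
    for (r in seq_len(nrow(a))) {
      cand <- which(!taken &
                      abs(b$bin_i - a$bin_i[r]) <= tol_bins &
                      abs(b$bin_j - a$bin_j[r]) <= tol_bins)
      if (length(cand)) {
        taken[cand[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  matched / (nrow(A) + nrow(B) - matched)
}

#' Chromatin-state proportions at loop anchors
#'
#' Fraction of loops whose anchor-bin pair satisfies each functional category
#' (categories are non-exclusive, so fractions need not sum to 1).
#'
#' @param loops a `loop_calls` data.frame.
#' @param annotations an [annotate_bins()] table at the loops' resolution.
#' @param categories categories to report (default: promoter-enhancer,
#'   heterochromatin-heterochromatin, not-expected).
#' @return named numeric vector of fractions.
#' @export
anchor_state_proportions <- function(loops, annotations,
                                     categories = c(
                                       "promoter-enhancer",
                                       "heterochromatin-heterochromatin",
                                       "not-expected")) {
  if (nrow(loops) == 0) return(stats::setNames(rep(0, length(categories)),
                                               categories))
  cats <- pair_categories(annotations, loops$bin_i, loops$bin_j, loops$chrom)
  colMeans(cats[, categories, drop = FALSE])
}

#' CTCF convergence fraction of called loops
#'
#' A loop is convergent iff its upstream anchor bin contains at least one
#' forward-strand CTCF motif peak and its downstream anchor bin at least one
#' reverse-strand peak.
#'
#' @param loops a `loop_calls` data.frame.
#' @param peaks stranded peak data.frame.
#' @param resolution bin size (default: the loops' attribute).
#' @return fraction of convergent loops.
#' @export
convergence_fraction <- function(loops, peaks,
                                 resolution = attr(loops, "resolution")) {
  if (nrow(loops) == 0) return(0)
  pb <- pos_to_bin(peak_centers(peaks), resolution)
  plus <- paste(peaks$chrom, pb)[peaks$strand == "+"]
  minus <- paste(peaks$chrom, pb)[peaks$strand == "-"]
  mean(paste(loops$chrom, loops$bin_i) %in% plus &
         paste(loops$chrom, loops$bin_j) %in% minus)
}

#' Replicate-consensus loops
#'
#' Loops present (exact anchor match) in at least `k` of the supplied call
#' sets; coordinates are taken from the first set containing each loop.
#'
#' @param sets list of `loop_calls` data.frames.
#' @param k minimum number of supporting replicates (default 2).
#' @return consensus `loop_calls` data.frame.
#' @export
consensus_loops <- function(sets, k = 2) {
  keys <- lapply(sets, function(s) unique(loop_keys(s)))
  counts <- table(unlist(keys))
  keep <- names(counts)[counts >= k]
  pooled <- do.call(rbind, lapply(sets, function(s)
    s[, c("chrom", "bin_i", "bin_j", "prob")]))
  pooled <- pooled[loop_keys(pooled) %in% keep, , drop = FALSE]
  out <- pooled[!duplicated(loop_keys(pooled)), , drop = FALSE]
  out <- out[order(out$chrom, out$bin_i, out$bin_j), ]
  rownames(out) <- NULL
  attr(out, "resolution") <- attr(sets[[1]], "resolution")
  class(out) <- c("loop_calls", "data.frame")
  out
}
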