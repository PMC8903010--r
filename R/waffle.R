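# 9x9 CTCF-CTCF submatrix extraction and the train/serve value transform.
# Submatrices are stored row-major: row axis = upstream anchor (bin_i - 4 ..
# bin_i + 4), column axis = downstream anchor; cell (r, c) of the 9x9 window
# sits at flat position (r - 1) * 9 + c.

new_submatrix_set <- function(X, meta, chrom, resolution, transformed,
                              skipped = NULL) {
  structure(list(X = X, meta = meta, chrom = chrom, resolution = resolution,
                 transformed = transformed, skipped = skipped),
            class = "submatrix_set")
}

#' @export
print.submatrix_set <- function(x, ...) {
  cat(sprintf("<submatrix_set> %d submatrices (%d cells each), %s\n",
              nrow(x$X), ncol(x$X),
              if (x$transformed) "transformed" else "raw"))
  invisible(x)
}

#' Extract 9x9 submatrices centered on CTCF-CTCF pairs
#'
#' For each pair, the window spans the upstream anchor bin +/- `flank` bins on
#' the row axis and the downstream anchor bin +/- `flank` bins on the column
#' axis (45 kb squared at 5 kb resolution with the default flank of 4). Pairs
#' whose window crosses a matrix edge are skipped and reported.
#'
#' @param m a [contact_matrix()].
#' @param pairs pair table from [enumerate_pairs()] (needs `up_center`,
#'   `down_center`), or a data.frame with 0-based `bin_i`, `bin_j` columns.
#' @param flank half-window in bins (default 4, i.e. 9x9).
#' @return A `submatrix_set`: `X` (n x 81 matrix, row-major windows), `meta`
#'   (the pair rows plus `bin_i`, `bin_j`), `skipped` (edge-crossing rows).
#' @export
extract_submatrices <- function(m, pairs, flank = 4L) {
  stopifnot(inherits(m, "contact_matrix"))
  pairs <- as.data.frame(pairs)
  if (!all(c("bin_i", "bin_j") %in% names(pairs))) {
    pairs$bin_i <- pos_to_bin(pairs$up_center, m$resolution)
    pairs$bin_j <- pos_to_bin(pairs$down_center, m$resolution)
  }
  n <- m$n_bins
  ok <- pairs$bin_i >= flank & pairs$bin_i <= n - 1L - flank &
    pairs$bin_j >= flank & pairs$bin_j <= n - 1L - flank
  if (any(!ok))
    message(sprintf("extract_submatrices: skipped %d/%d pairs at matrix edges",
                    sum(!ok), length(ok)))
  meta <- pairs[ok, , drop = FALSE]
  rownames(meta) <- NULL
  w <- 2L * flank + 1L
  dr <- rep(-flank:flank, each = w)   # row-major: row offset varies slowest
  dc <- rep(-flank:flank, times = w)
  offset <- dc * n + dr
  base <- meta$bin_j * n + meta$bin_i + 1L  # column-major linear index
  X <- matrix(m$values[outer(base, offset, "+")], nrow = nrow(meta))
  new_submatrix_set(X, meta, m$chrom, m$resolution, transformed = FALSE,
                    skipped = pairs[!ok, , drop = FALSE])
}

# Per-row z-score followed by the logistic map; rows with zero spread become
# all 0.5. Shared by training-time transformation and scan-time windows.
transform_rows <- function(X) {
  mu <- rowMeans(X)
  ctr <- X - mu
  sdv <- sqrt(rowSums(ctr^2) / (ncol(X) - 1))
  z <- ctr / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  logistic(z)
}

#' Combine submatrix sets
#'
#' Row-binds several `submatrix_set` objects (e.g. one per chromosome) into
#' one; all sets must share the transform state and window size.
#'
#' @param ... `submatrix_set` objects.
#' @return the pooled `submatrix_set`.
#' @export
c.submatrix_set <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "submatrix_set")))
  tr <- unique(vapply(sets, function(s) isTRUE(s$transformed), TRUE))
  if (length(tr) != 1) stopf("cannot combine transformed with raw sets")
  dims <- unique(vapply(sets, function(s) ncol(s$X), 1L))
  if (length(dims) != 1) stopf("window sizes differ")
  common <- Reduce(intersect, lapply(sets, function(s) names(s$meta)))
  chroms <- unique(unlist(lapply(sets, function(s) s$chrom)))
  new_submatrix_set(
    do.call(rbind, lapply(sets, function(s) s$X)),
    do.call(rbind, lapply(sets, function(s) s$meta[, common, drop = FALSE])),
    chrom = if (length(chroms) == 1) chroms else chroms,
    resolution = sets[[1]]$resolution, transformed = tr)
}

#' Sigmoid transform of submatrices
#'
#' Each submatrix is z-scored over its own 81 cells (mean 0, sd 1; a constant
#' submatrix maps to all zeros) and then passed through the logistic function
#' `1 / (1 + exp(-z))`, scaling values strictly into (0, 1). Scaling per
#' submatrix makes the classification reflect interaction shape rather than
#' sequencing depth; the transform is rank-preserving within a submatrix.
#'
#' @param s a raw `submatrix_set`, or a plain numeric matrix of row-vectors.
#' @return The transformed `submatrix_set` (or matrix).
#' @export
sigmoid_transform <- function(s) {
  if (is.matrix(s)) return(transform_rows(s))
  stopifnot(inherits(s, "submatrix_set"))
  if (isTRUE(s$transformed)) stopf("submatrix set is already transformed")
  s$X <- transform_rows(s$X)
  s$transformed <- TRUE
  s
}

#' Write / read a submatrix set as a flat TSV table
#'
#' One row per submatrix: the meta columns followed by the 81 cell values
#' (`v1..v81`, row-major).
#'
#' @param s a `submatrix_set`.
#' @param path file path.
#' @export
write_submatrices <- function(s, path) {
  vals <- as.data.frame(s$X)
  names(vals) <- paste0("v", seq_len(ncol(vals)))
  df <- cbind(s$meta, vals)
  df$.transformed <- s$transformed
  df$.chrom <- s$chrom
  df$.resolution <- s$resolution
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_submatrices
#' @export
read_submatrices <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  X <- as.matrix(df[, vcols])
  dimnames(X) <- NULL
  meta <- df[, setdiff(names(df), c(names(df)[vcols],
                                    ".transformed", ".chrom", ".resolution")),
             drop = FALSE]
  new_submatrix_set(X, meta, chrom = df$.chrom[1],
                    resolution = df$.resolution[1],
                    transformed = isTRUE(df$.transformed[1]))
}
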