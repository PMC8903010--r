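#' Binned intra-chromosomal contact matrix
#'
#' A single chromosome's symmetric, nonnegative, binned interaction map at a
#' fixed resolution. Bin indices are 0-based throughout the package
#' (`bin = floor(position / resolution)`).
#'
#' @param values symmetric numeric matrix of nonnegative contacts.
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param normalized logical flag; matrices are assumed pre-normalized
#'   (balancing is out of scope).
#' @param tol relative tolerance for the symmetry check.
#' @return An object of class `contact_matrix` with fields `chrom`,
#'   `resolution`, `n_bins`, `values`, `normalized`.
#' @export
contact_matrix <- function(values, resolution, chrom = "chr1",
                           normalized = TRUE, tol = 1e-6) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("contact matrix must be square")
  if (any(values < 0)) stopf("contact matrix has negative entries")
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1e-12)
  if (asym > tol * scale)
    stopf("matrix is asymmetric beyond tolerance (max |v - t(v)| = %g)", asym)
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  structure(list(chrom = chrom, resolution = resolution,
                 n_bins = nrow(values), values = values,
                 normalized = normalized),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp (%snormalized)\n",
              x$chrom, x$n_bins, x$resolution,
              if (x$normalized) "" else "not "))
  invisible(x)
}

#' Read a contact matrix from text
#'
#' Two plain-text layouts are supported: `dense` (whitespace-separated square
#' matrix) and `sparse` bin-pair triples `bin_i bin_j value` with 0-based bins
#' (the layout of a `cooler dump` of one chromosome). Sparse input is mirrored
#' across the diagonal. Asymmetric dense input (beyond tolerance) and negative
#' values are rejected.
#'
#' @param path file path.
#' @param format `"dense"`, `"sparse"`, or `"auto"` (3-column files that are
#'   not 3x3 square are treated as sparse).
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param n_bins number of bins for sparse input (default: largest bin + 1).
#' @param normalized flag stored on the result.
#' @return A [contact_matrix()].
#' @export
read_contacts <- function(path, format = c("auto", "dense", "sparse"),
                          resolution, chrom = "chr1", n_bins = NULL,
                          normalized = TRUE) {
  format <- match.arg(format)
  tab <- utils::read.table(path, header = FALSE)
  if (format == "auto") {
    format <- if (ncol(tab) == 3 && nrow(tab) != 3) "sparse" else "dense"
  }
  if (format == "dense") {
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    return(contact_matrix(m, resolution, chrom, normalized))
  }
  if (ncol(tab) != 3) stopf("sparse input must have 3 columns")
  i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]]); v <- as.numeric(tab[[3]])
  if (any(v < 0)) stopf("contact matrix has negative entries")
  if (is.null(n_bins)) n_bins <- max(i, j) + 1L
  m <- matrix(0, n_bins, n_bins)
  m[cbind(i + 1L, j + 1L)] <- v
  m[cbind(j + 1L, i + 1L)] <- v
  contact_matrix(m, resolution, chrom, normalized)
}

#' Write a contact matrix as text
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @param format `"dense"` or `"sparse"` (upper-triangle nonzero triples).
#' @export
write_contacts <- function(m, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(format(m$values, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       path, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  } else {
    up <- which(upper.tri(m$values, diag = TRUE) & m$values != 0,
                arr.ind = TRUE)
    df <- data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
                     value = m$values[up])
    df <- df[order(df$bin_i, df$bin_j), ]
    utils::write.table(format(df, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       path, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Observed/expected transform over the valid (nonzero-marginal) bins.
# Expected at distance d = mean of observed over valid bin pairs at d.
# Returns list(oe = full-size matrix with NA at invalid bins, valid = mask).
oe_transform <- function(m) {
  v <- m$values
  valid <- rowSums(v) > 0
  if (!any(valid)) stopf("all-zero contact matrix")
  idx <- which(valid)
  sub <- v[idx, idx, drop = FALSE]
  d <- abs(outer(idx, idx, "-"))
  expd <- tapply(sub, d, mean)
  oe_sub <- sub / as.numeric(expd[as.character(d)])
  dim(oe_sub) <- dim(sub)
  oe <- matrix(NA_real_, m$n_bins, m$n_bins)
  oe[idx, idx] <- oe_sub
  list(oe = oe, valid = valid)
}

#' A/B compartment eigenvector of a contact matrix
#'
#' Computes the classic compartment signal: observed/expected transform (the
#' expected value of a bin pair is the mean contact at its diagonal distance,
#' over bins with nonzero marginals), Pearson correlation matrix of O/E, and
#' the eigenvector of the largest-magnitude eigenvalue. Positive sign denotes
#' the A compartment once oriented. Orientation requires an external
#' `reference` per-bin signal (e.g. active-chromatin density): the eigenvector
#' is flipped so its correlation with the reference is positive. Without a
#' reference the sign is left as computed and flagged un-oriented.
#'
#' @param m a [contact_matrix()] (coarse resolution intended, e.g. 100 kb).
#' @param reference optional numeric per-bin reference signal of length
#'   `m$n_bins`.
#' @param low_conf_frac leading-eigenvalue fraction of total variance below
#'   which the track is flagged low-confidence.
#' @return An object of class `compartment_track`: `chrom`, `resolution`,
#'   `eigenvector` (NA at masked bins), `valid_mask`, `oriented`,
#'   `var_explained`, `low_confidence`.
#' @export
compartment_eigenvector <- function(m, reference = NULL,
                                    low_conf_frac = 0.1) {
  tr <- oe_transform(m)
  idx <- which(tr$valid)
  oe_sub <- tr$oe[idx, idx, drop = FALSE]
  cc <- suppressWarnings(stats::cor(oe_sub))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  e <- eigen(cc, symmetric = TRUE)
  k <- which.max(abs(e$values))
  ev <- e$vectors[, k]
  var_explained <- abs(e$values[k]) / sum(abs(e$values))
  oriented <- FALSE
  if (!is.null(reference)) {
    if (length(reference) != m$n_bins)
      stopf("reference must have one value per bin")
    r <- reference[idx]
    s <- sum(ev * (r - mean(r)))
    if (s < 0) ev <- -ev
    oriented <- TRUE
  }
  full <- rep(NA_real_, m$n_bins)
  full[idx] <- ev
  structure(list(chrom = m$chrom, resolution = m$resolution,
                 eigenvector = full, valid_mask = tr$valid,
                 oriented = oriented, var_explained = var_explained,
                 low_confidence = var_explained < low_conf_frac),
            class = "compartment_track")
}

#' @export
print.compartment_track <- function(x, ...) {
  cat(sprintf(
    "<compartment_track> %s @ %g bp: %d/%d valid bins, var explained %.3f%s%s\n",
    x$chrom, x$resolution, sum(x$valid_mask), length(x$eigenvector),
    x$var_explained, if (x$oriented) ", oriented" else ", un-oriented",
    if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Write a compartment track as bedGraph
#'
#' @param track a `compartment_track`.
#' @param path output file.
#' @export
write_compartments <- function(track, path) {
  ok <- which(track$valid_mask)
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = (ok - 1L) * track$resolution + 1,
                     width = track$resolution),
    score = track$eigenvector[ok])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
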