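#' Read a BED6 or ENCODE narrowPeak file
#'
#' Peaks are represented in-memory as data.frames in BED convention (0-based,
#' half-open) with columns `chrom,start,end,name,score,strand` and, for
#' narrowPeak, `summit` (absolute bp of the point source when the offset is
#' >= 0).
#'
#' @param path file path.
#' @param format `"auto"` (by extension / column count), `"bed"`, or
#'   `"narrowPeak"`.
#' @return data.frame of peaks.
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak"
    else if (ncol(utils::read.table(path, nrows = 1)) >= 10) "narrowPeak"
    else "bed"
  }
  if (format == "narrowPeak") {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    df <- gr_to_bed(gr, keep = c("name", "score", "peak"))
    df$summit <- ifelse(df$peak >= 0, df$start + df$peak, NA_integer_)
    df$peak <- NULL
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    df <- gr_to_bed(gr, keep = c("name", "score"))
  }
  if (is.null(df$name)) df$name <- paste0("peak_", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  df
}

#' Write peaks as BED6
#' @param peaks peak data.frame.
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  gr <- bed_to_gr(transform(peaks, strand = ifelse(strand == ".", "*", strand)),
                  keep = c("name", "score"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Peak centers
#'
#' The center of a peak is the narrowPeak summit when present, else the
#' midpoint of `(start, end)`.
#'
#' @param peaks peak data.frame.
#' @return numeric vector of bp positions.
#' @export
peak_centers <- function(peaks) {
  ctr <- (peaks$start + peaks$end) / 2
  if (!is.null(peaks$summit)) {
    has <- !is.na(peaks$summit)
    ctr[has] <- peaks$summit[has]
  }
  ctr
}

#' Replicate-common peaks
#'
#' Keeps the peaks of the first replicate that overlap (by at least
#' `min_overlap_bp`) a peak in every other replicate.
#'
#' @param replicates list of >= 2 peak data.frames.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return data.frame of surviving peaks from `replicates[[1]]`.
#' @export
common_peaks <- function(replicates, min_overlap_bp = 1L) {
  if (length(replicates) < 2) stopf("need >= 2 replicate peak sets")
  if (any(vapply(replicates, nrow, 1L) == 0)) {
    warnf("empty replicate set: no common peaks")
    return(replicates[[1]][0, ])
  }
  first <- replicates[[1]]
  keep <- rep(TRUE, nrow(first))
  gr1 <- bed_to_gr(first)
  for (other in replicates[-1]) {
    hit <- IRanges::overlapsAny(gr1, bed_to_gr(other),
                                minoverlap = min_overlap_bp)
    keep <- keep & hit
  }
  first[keep, , drop = FALSE]
}

#' Read a FIMO-style motif table
#'
#' Accepts either a FIMO TSV (columns including `sequence_name`, `start`,
#' `stop`, `strand`, `p-value`; 1-based inclusive coordinates, converted) or a
#' plain table with columns `chrom,start,end,strand,p` in BED convention.
#'
#' @param path file path.
#' @return data.frame with columns `chrom,start,end,strand,p`.
#' @export
read_motifs <- function(path) {
  head1 <- readLines(path, n = 1)
  if (grepl("sequence_name", head1)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE)
    data.frame(chrom = tab$sequence_name, start = tab$start - 1L,
               end = tab$stop, strand = tab$strand, p = tab[["p-value"]],
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE)
    stopifnot(all(c("chrom", "start", "end", "strand", "p") %in% names(tab)))
    tab[, c("chrom", "start", "end", "strand", "p")]
  }
}

#' Annotate peaks with motif strand
#'
#' A peak is kept iff it contains a motif with `p < p_cutoff` (strict) lying
#' entirely within the peak interval; it takes that motif's strand. When
#' several significant motifs fall in one peak, the lowest-p motif wins.
#'
#' @param peaks peak data.frame.
#' @param motifs motif data.frame (`chrom,start,end,strand,p`), see
#'   [read_motifs()].
#' @param p_cutoff significance cutoff (default 0.05, strict `<`).
#' @return data.frame of surviving peaks with strand set from the motif.
#' @export
annotate_strand <- function(peaks, motifs, p_cutoff = 0.05) {
  motifs <- motifs[motifs$p < p_cutoff, , drop = FALSE]
  if (nrow(peaks) == 0 || nrow(motifs) == 0) return(peaks[0, , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(bed_to_gr(motifs), bed_to_gr(peaks),
                                      type = "within")
  if (length(hits) == 0) return(peaks[0, , drop = FALSE])
  hdf <- data.frame(motif = S4Vectors::queryHits(hits),
                    peak = S4Vectors::subjectHits(hits))
  hdf$p <- motifs$p[hdf$motif]
  hdf <- hdf[order(hdf$peak, hdf$p, hdf$motif), ]
  best <- hdf[!duplicated(hdf$peak), ]
  out <- peaks[best$peak, , drop = FALSE]
  out$strand <- as.character(motifs$strand[best$motif])
  rownames(out) <- NULL
  out
}

#' Isolation filter
#'
#' Keeps a peak iff no other peak's center lies strictly within
#' `window_bp` of its center (same chromosome). Centers exactly `window_bp`
#' apart are both kept.
#'
#' @param peaks peak data.frame.
#' @param window_bp isolation window in bp (default 50 kb).
#' @return data.frame of isolated peaks.
#' @export
isolated_peaks <- function(peaks, window_bp = 50000) {
  if (nrow(peaks) <= 1) return(peaks)
  ctr <- peak_centers(peaks)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- peaks$chrom == peaks$chrom[i]
    same[i] <- FALSE
    !any(abs(ctr[same] - ctr[i]) < window_bp)
  }, logical(1))
  peaks[keep, , drop = FALSE]
}

#' Enumerate CTCF-CTCF peak pairs
#'
#' All ordered same-chromosome pairs with center-to-center separation between
#' `min_sep` and `max_sep` (inclusive). Orientation is `convergent` when the
#' upstream motif is "+" and the downstream "-", `divergent` for the reverse,
#' and `parallel` otherwise.
#'
#' @param peaks stranded peak data.frame (typically isolated, motif-annotated).
#' @param min_sep,max_sep separation bounds in bp (defaults 45 kb and 1.5 Mb).
#' @return data.frame of pairs: `chrom, up_center, down_center, up_strand,
#'   down_strand, separation, orientation, up_idx, down_idx`.
#' @export
enumerate_pairs <- function(peaks, min_sep = 45000, max_sep = 1500000) {
  if (min_sep > max_sep) stopf("min_sep must be <= max_sep")
  ctr <- peak_centers(peaks)
  out <- list()
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    idx <- idx[order(ctr[idx])]
    n <- length(idx)
    if (n < 2) next
    ii <- rep(seq_len(n - 1), times = (n - 1):1)
    jj <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
    sep <- ctr[idx[jj]] - ctr[idx[ii]]
    ok <- sep >= min_sep & sep <= max_sep
    if (!any(ok)) next
    up <- idx[ii[ok]]; down <- idx[jj[ok]]
    out[[ch]] <- data.frame(
      chrom = ch,
      up_center = ctr[up], down_center = ctr[down],
      up_strand = peaks$strand[up], down_strand = peaks$strand[down],
      separation = sep[ok],
      up_idx = up, down_idx = down,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), up_center = numeric(),
                      down_center = numeric(), up_strand = character(),
                      down_strand = character(), separation = numeric(),
                      orientation = character(), up_idx = integer(),
                      down_idx = integer(), stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  pairs$orientation <- ifelse(
    pairs$up_strand == "+" & pairs$down_strand == "-", "convergent",
    ifelse(pairs$up_strand == "-" & pairs$down_strand == "+", "divergent",
           "parallel"))
  pairs[, c("chrom", "up_center", "down_center", "up_strand", "down_strand",
            "separation", "orientation", "up_idx", "down_idx")]
}

#' Fraction of anchors overlapping another peak set
#'
#' @param anchors nonempty peak data.frame.
#' @param other peak data.frame (e.g. cohesin subunit peaks).
#' @return fraction in `[0, 1]` of anchors overlapping >= 1 peak in `other`.
#' @export
overlap_fraction <- function(anchors, other) {
  if (nrow(anchors) == 0) stopf("overlap_fraction undefined for empty anchors")
  if (nrow(other) == 0) return(0)
  mean(IRanges::overlapsAny(bed_to_gr(anchors), bed_to_gr(other)))
}
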