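# Chromatin-state integration: 15-state segmentation -> 4 major classes,
# 5 kb bin annotation, CTCF-pair functional categories, and per-cluster
# enrichment statistics.

# Roadmap-style core 15-state vocabulary: mnemonic and descriptive name.
STATE15 <- data.frame(
  mnemonic = c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
               "ZNF/Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC",
               "ReprPCWk", "Quies"),
  name = c("Active TSS", "Flanking Active TSS", "Transcr. at gene 5' and 3'",
           "Strong transcription", "Weak transcription", "Genic enhancers",
           "Enhancers", "ZNF genes & repeats", "Heterochromatin",
           "Bivalent/Poised TSS", "Flanking Bivalent TSS/Enh",
           "Bivalent Enhancer", "Repressed PolyComb",
           "Weak Repressed PolyComb", "Quiescent/Low"),
  stringsAsFactors = FALSE
)

# 15 -> 4 merge; transcription-associated states and ZNF/repeats are dropped.
MERGE4 <- c(
  TssA = "promoter", TssAFlnk = "promoter", TssBiv = "promoter",
  BivFlnk = "promoter",
  Enh = "enhancer", EnhG = "enhancer", EnhBiv = "enhancer",
  ReprPC = "polycomb", ReprPCWk = "polycomb",
  Het = "heterochromatin", Quies = "heterochromatin"
)

STATE_CLASSES <- c("promoter", "enhancer", "polycomb", "heterochromatin")

# Normalize a vector of state labels (mnemonic or descriptive, case
# insensitive) to mnemonics; errors on anything outside the vocabulary.
canonical_state <- function(x) {
  lx <- tolower(x)
  hit <- match(lx, tolower(STATE15$mnemonic))
  hit2 <- match(lx, tolower(STATE15$name))
  hit[is.na(hit)] <- hit2[is.na(hit)]
  if (anyNA(hit))
    stopf("unknown chromatin state label(s): %s",
          paste(unique(x[is.na(hit)]), collapse = ", "))
  STATE15$mnemonic[hit]
}

#' Merge a 15-state segmentation into four major classes
#'
#' Promoter (Active TSS, Flanking Active TSS, Bivalent/Poised TSS, Flanking
#' Bivalent TSS/Enh), enhancer (Enhancers, Genic enhancers, Bivalent
#' Enhancer), polycomb (Repressed PolyComb, Weak Repressed PolyComb) and
#' heterochromatin (Heterochromatin, Quiescent/Low). Transcription-associated
#' states and ZNF/repeats belong to no class and their intervals are dropped.
#' Unknown mnemonics are rejected.
#'
#' @param track data.frame of intervals `chrom,start,end,state` (states as
#'   mnemonics or full names of the 15-state vocabulary); see
#'   [read_state_track()].
#' @return the track with `state` replaced by the 4-class label.
#' @export
merge_states <- function(track) {
  mn <- canonical_state(track$state)
  cls <- MERGE4[mn]
  out <- track[!is.na(cls), , drop = FALSE]
  out$state <- unname(cls[!is.na(cls)])
  rownames(out) <- NULL
  out
}

#' Read / write a 4-column BED chromatin-state segmentation
#' @param path file path.
#' @return data.frame `chrom,start,end,state`.
#' @export
read_state_track <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- gr_to_bed(gr, keep = "name")
  names(df)[names(df) == "name"] <- "state"
  df[, c("chrom", "start", "end", "state")]
}

#' @rdname read_state_track
#' @param track state data.frame.
#' @export
write_state_track <- function(track, path) {
  out <- data.frame(chrom = track$chrom, start = as.integer(track$start),
                    end = as.integer(track$end), state = track$state)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Annotate genomic bins with chromatin-state classes
#'
#' The chromosome is segmented into `resolution`-sized bins; a bin carries a
#' class iff the summed overlap of that class's intervals with the bin
#' exceeds `min_overlap_bp` (strictly). A bin may carry zero, one, or several
#' classes.
#'
#' @param track4 merged 4-class track from [merge_states()].
#' @param resolution bin size in bp (default 5000).
#' @param chrom_length optional chromosome length (default: last interval
#'   end).
#' @param min_overlap_bp strict overlap threshold in bp (default 50).
#' @return data.frame with `chrom`, `bin` (0-based) and one logical column
#'   per class (`promoter`, `enhancer`, `polycomb`, `heterochromatin`).
#' @export
annotate_bins <- function(track4, resolution = 5000, chrom_length = NULL,
                          min_overlap_bp = 50) {
  out <- list()
  for (ch in unique(track4$chrom)) {
    tr <- track4[track4$chrom == ch, , drop = FALSE]
    len <- if (is.null(chrom_length)) max(tr$end) else chrom_length
    nb <- as.integer(ceiling(len / resolution))
    bins <- IRanges::IRanges(start = (0:(nb - 1)) * resolution + 1,
                             width = resolution)
    ann <- data.frame(chrom = ch, bin = 0:(nb - 1))
    for (cls in STATE_CLASSES) {
      iv <- tr[tr$state == cls, , drop = FALSE]
      flag <- rep(FALSE, nb)
      if (nrow(iv) > 0) {
        ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1,
                                               end = iv$end))
        hits <- IRanges::findOverlaps(bins, ir)
        if (length(hits) > 0) {
          ov <- IRanges::width(IRanges::pintersect(
            bins[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
          tot <- tapply(ov, S4Vectors::queryHits(hits), sum)
          flag[as.integer(names(tot))] <- tot > min_overlap_bp
        }
      }
      ann[[cls]] <- flag
    }
    out[[ch]] <- ann
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Functional category of an interacting bin pair
#'
#' Categories are symmetric in anchor order and non-exclusive: a pair may
#' belong to several. `not-expected` marks a promoter- or enhancer-class bin
#' interacting with a heterochromatin bin.
#'
#' @param a1,a2 logical class indicators for the two anchor bins (named
#'   vectors or 1-row slices of an [annotate_bins()] table).
#' @return character vector of categories (possibly empty).
#' @export
categorize_pair <- function(a1, a2) {
  g <- function(a, cls) isTRUE(as.logical(a[[cls]]))
  out <- character(0)
  if ((g(a1, "promoter") && g(a2, "enhancer")) ||
      (g(a1, "enhancer") && g(a2, "promoter")))
    out <- c(out, "promoter-enhancer")
  if (g(a1, "enhancer") && g(a2, "enhancer"))
    out <- c(out, "enhancer-enhancer")
  if (g(a1, "polycomb") && g(a2, "polycomb"))
    out <- c(out, "polycomb-polycomb")
  if ((g(a1, "promoter") && g(a2, "polycomb")) ||
      (g(a1, "polycomb") && g(a2, "promoter")))
    out <- c(out, "promoter-polycomb")
  if (g(a1, "heterochromatin") && g(a2, "heterochromatin"))
    out <- c(out, "heterochromatin-heterochromatin")
  if (((g(a1, "promoter") || g(a1, "enhancer")) && g(a2, "heterochromatin")) ||
      ((g(a2, "promoter") || g(a2, "enhancer")) && g(a1, "heterochromatin")))
    out <- c(out, "not-expected")
  out
}

PAIR_CATEGORIES <- c("promoter-enhancer", "enhancer-enhancer",
                     "polycomb-polycomb", "promoter-polycomb",
                     "heterochromatin-heterochromatin", "not-expected")

#' Categorize many bin pairs at once
#'
#' @param annotations an [annotate_bins()] table.
#' @param bin1,bin2 0-based anchor bins (vectors of equal length).
#' @param chrom chromosome name(s), recycled.
#' @return logical matrix, one row per pair and one column per category; rows
#'   whose anchors are not annotated are all-FALSE.
#' @export
pair_categories <- function(annotations, bin1, bin2, chrom = NULL) {
  n <- length(bin1)
  if (is.null(chrom)) chrom <- annotations$chrom[1]
  chrom <- rep_len(chrom, n)
  key <- paste(annotations$chrom, annotations$bin)
  i1 <- match(paste(chrom, bin1), key)
  i2 <- match(paste(chrom, bin2), key)
  out <- matrix(FALSE, n, length(PAIR_CATEGORIES),
                dimnames = list(NULL, PAIR_CATEGORIES))
  ok <- which(!is.na(i1) & !is.na(i2))
  for (r in ok) {
    cats <- categorize_pair(annotations[i1[r], ], annotations[i2[r], ])
    out[r, cats] <- TRUE
  }
  out
}

#' Per-cluster feature enrichment with Wilcoxon tests
#'
#' For every cluster and every feature column, compares the cluster's per-pair
#' values against all other clusters pooled using a two-sided Wilcoxon
#' rank-sum test, and reports the cluster value (proportion for logical
#' features, mean otherwise), the global mean, the direction of the deviation,
#' and significance tiers at p < 0.05 (`*`), < 0.001 (`**`), < 0.0001
#' (`***`).
#'
#' @param features data.frame of per-pair features (logical or numeric
#'   columns, e.g. orientation indicators, compartment sign, separation,
#'   functional categories).
#' @param cluster integer/character cluster label per pair; pairs labelled
#'   `-1` or `NA` are excluded.
#' @return tidy data.frame: `cluster`, `feature`, `n`, `value`, `global_mean`,
#'   `direction`, `p`, `signif`.
#' @export
cluster_enrichment <- function(features, cluster) {
  keep <- !is.na(cluster) & cluster != -1
  features <- features[keep, , drop = FALSE]
  cluster <- cluster[keep]
  out <- list()
  for (cl in sort(unique(cluster))) {
    inc <- cluster == cl
    for (f in names(features)) {
      x <- as.numeric(features[[f]][inc])
      y <- as.numeric(features[[f]][!inc])
      p <- if (length(x) < 2 || length(y) < 1) NA_real_ else
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
      val <- mean(x)
      out[[length(out) + 1]] <- data.frame(
        cluster = cl, feature = f, n = sum(inc), value = val,
        global_mean = mean(as.numeric(features[[f]])),
        direction = if (length(y) && val >= mean(y)) "enriched" else "depleted",
        p = p,
        signif = if (is.na(p)) "" else if (p < 1e-4) "***"
                 else if (p < 1e-3) "**" else if (p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
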