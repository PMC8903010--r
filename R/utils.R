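# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Logistic (sigmoid) function
#' @param z numeric vector.
#' @return 1 / (1 + exp(-z)), elementwise.
#' @keywords internal
logistic <- function(z) 1 / (1 + exp(-z))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. Used by every randomized operation so that
# results depend only on the explicit seed argument.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# Derive a stream-specific child seed from a master seed, kept < 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + 97 * k) %% 2147483647
}

# 0-based genomic bin of a position at a given resolution (BED arithmetic).
pos_to_bin <- function(pos, resolution) floor(pos / resolution)

# data.frame of BED intervals (0-based half-open) -> GRanges (1-based).
bed_to_gr <- function(df, keep = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

gr_to_bed <- function(gr, keep = character()) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- ifelse(s == "*", ".", s)
  mc <- S4Vectors::mcols(gr)
  for (k in intersect(keep, colnames(mc))) df[[k]] <- mc[[k]]
  df
}
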