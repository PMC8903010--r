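#' Specification of a synthetic Hi-C chromosome
#'
#' Describes a toy chromosome from which contact matrices, peak lists and
#' chromatin-state tracks can be simulated. The contact model is a power-law
#' distance decay plus optional planted loops (2-D Gaussian bumps at chosen
#' anchor-bin pairs), an optional A/B checkerboard compartment structure, and
#' multiplicative log-normal noise. Log-normal noise keeps the matrix
#' nonnegative and right-skewed, like normalized Hi-C counts.
#'
#' @param chrom_length chromosome length in bp.
#' @param resolution bin size in bp.
#' @param decay_exponent power-law exponent of the distance decay
#'   (expected contact at bin distance d is `scale * d^-decay_exponent`).
#' @param scale contact level at bin distance 1.
#' @param loop_anchors `NULL` or a data.frame with columns `bin1`, `bin2`
#'   (0-based bins, `bin1 < bin2`) and `amplitude` (>= 0, contact units).
#' @param loop_sd standard deviation (in bins) of the planted Gaussian bumps;
#'   a per-loop `sd` column in `loop_anchors` overrides it.
#' @param noise_sd sdlog of the multiplicative log-normal noise; 0 disables
#'   noise. The noise has unit mean (`meanlog = -noise_sd^2/2`).
#' @param compartment_block `NULL`, or the A/B block size in bins: contacts
#'   between bins whose block indices have equal parity are scaled up by
#'   `compartment_factor`, producing a checkerboard.
#' @param compartment_factor same-type block scaling (default 1.5).
#' @param chrom chromosome name.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_length, resolution = 5000, decay_exponent = 1,
                           scale = 100, loop_anchors = NULL, loop_sd = 1,
                           noise_sd = 0, compartment_block = NULL,
                           compartment_factor = 1.5, chrom = "chrS", seed = 1) {
  if (resolution <= 0) stopf("resolution must be > 0")
  if (chrom_length <= 0) stopf("chrom_length must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  if (!is.null(loop_anchors)) {
    loop_anchors <- as.data.frame(loop_anchors)
    stopifnot(all(c("bin1", "bin2", "amplitude") %in% names(loop_anchors)))
    if (any(loop_anchors$bin1 < 0) || any(loop_anchors$bin2 >= n_bins))
      stopf("loop anchor outside matrix (bins must be in [0, %d])", n_bins - 1)
    if (any(loop_anchors$bin1 >= loop_anchors$bin2))
      stopf("loop anchors must satisfy bin1 < bin2")
    if (any(loop_anchors$amplitude < 0)) stopf("loop amplitude must be >= 0")
  }
  if (!is.null(compartment_block) && compartment_block <= 0)
    stopf("compartment_block must be > 0")
  structure(list(
    chrom = chrom, chrom_length = chrom_length, resolution = resolution,
    n_bins = n_bins, decay_exponent = decay_exponent, scale = scale,
    loop_anchors = loop_anchors, loop_sd = loop_sd, noise_sd = noise_sd,
    compartment_block = compartment_block,
    compartment_factor = compartment_factor, seed = seed
  ), class = "synthetic_spec")
}

#' Expected contact level at a given bin distance
#'
#' The noise-free decay value `scale * max(d, 1)^-decay_exponent`; useful to
#' express planted-loop amplitudes as multiples of the local background.
#'
#' @param spec a [synthetic_spec()].
#' @param d bin distance(s).
#' @return numeric vector of expected contacts.
#' @export
decay_value <- function(spec, d) spec$scale * pmax(d, 1)^(-spec$decay_exponent)

#' Simulate a contact matrix from a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return A [contact_matrix()] of `spec$n_bins` bins.
#' @export
simulate_contacts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_bins
  idx <- 0:(n - 1)
  d <- abs(outer(idx, idx, "-"))
  v <- decay_value(spec, d)
  if (!is.null(spec$compartment_block)) {
    blk <- idx %/% spec$compartment_block
    same <- outer(blk %% 2, blk %% 2, "==")
    v[same] <- v[same] * spec$compartment_factor
  }
  if (!is.null(spec$loop_anchors) && nrow(spec$loop_anchors) > 0) {
    for (k in seq_len(nrow(spec$loop_anchors))) {
      i <- spec$loop_anchors$bin1[k]
      j <- spec$loop_anchors$bin2[k]
      a <- spec$loop_anchors$amplitude[k]
      sdk <- if (!is.null(spec$loop_anchors$sd)) spec$loop_anchors$sd[k]
             else spec$loop_sd
      bump <- a * exp(-(outer((idx - i)^2, (idx - j)^2, "+")) / (2 * sdk^2))
      v <- v + bump + t(bump)
    }
  }
  if (spec$noise_sd > 0) {
    v <- with_seed(spec$seed, {
      fac <- matrix(1, n, n)
      up <- upper.tri(fac, diag = TRUE)
      fac[up] <- stats::rlnorm(sum(up), meanlog = -spec$noise_sd^2 / 2,
                               sdlog = spec$noise_sd)
      fac[lower.tri(fac)] <- t(fac)[lower.tri(fac)]
      v * fac
    })
  }
  contact_matrix(v, resolution = spec$resolution, chrom = spec$chrom,
                 normalized = TRUE)
}

#' Simulate a stranded CTCF-like peak list
#'
#' One point-source peak per anchor, centered on the midpoint of the anchor's
#' bin, with the given motif strand. Optional decoy peaks (strand ".") can be
#' placed at explicit positions.
#'
#' @param spec a [synthetic_spec()].
#' @param anchors data.frame with columns `bin` (0-based) and `strand`
#'   ("+"/"-"), one row per peak; order is preserved.
#' @param peak_width width in bp of each emitted peak (centered on the bin
#'   midpoint).
#' @param decoys optional numeric vector of bp positions for unstranded decoys.
#' @return data.frame of BED6-style peaks (`chrom,start,end,name,score,strand`,
#'   0-based half-open).
#' @export
simulate_peaks <- function(spec, anchors, peak_width = 200, decoys = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("bin", "strand") %in% names(anchors)))
  if (any(anchors$bin < 0 | anchors$bin >= spec$n_bins))
    stopf("anchor bin outside chromosome")
  mid <- anchors$bin * spec$resolution + spec$resolution / 2
  pk <- data.frame(
    chrom = spec$chrom,
    start = as.integer(round(mid - peak_width / 2)),
    end = as.integer(round(mid + peak_width / 2)),
    name = paste0("peak_", seq_len(nrow(anchors))),
    score = 1000,
    strand = as.character(anchors$strand),
    stringsAsFactors = FALSE
  )
  if (!is.null(decoys) && length(decoys) > 0) {
    dk <- data.frame(
      chrom = spec$chrom,
      start = as.integer(round(decoys - peak_width / 2)),
      end = as.integer(round(decoys + peak_width / 2)),
      name = paste0("decoy_", seq_along(decoys)),
      score = 500, strand = ".", stringsAsFactors = FALSE
    )
    pk <- rbind(pk, dk)
  }
  pk
}

#' Simulate a chromatin-state segmentation track
#'
#' Emits one interval per run of identical per-bin labels, each covering whole
#' bins, so the majority state of every bin equals the requested label.
#'
#' @param spec a [synthetic_spec()].
#' @param labels_per_bin character vector (one 15-state mnemonic or full state
#'   name per bin); recycled to `spec$n_bins` if length 1.
#' @return data.frame of 4-column BED intervals (`chrom,start,end,state`).
#' @export
simulate_states <- function(spec, labels_per_bin) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(labels_per_bin) == 1)
    labels_per_bin <- rep(labels_per_bin, spec$n_bins)
  if (length(labels_per_bin) != spec$n_bins)
    stopf("labels_per_bin must have one label per bin (%d)", spec$n_bins)
  labels_per_bin <- canonical_state(labels_per_bin)  # errors on unknown labels
  r <- rle(labels_per_bin)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(
    chrom = spec$chrom,
    start = as.integer(starts * spec$resolution),
    end = as.integer(pmin(ends * spec$resolution, spec$chrom_length)),
    state = r$values,
    stringsAsFactors = FALSE
  )
}

#' Simulate a CTCF-bound toy chromosome with planted loops
#'
#' Lays out stranded CTCF-like peaks along a toy chromosome (inter-peak gaps
#' drawn uniformly, keeping every peak isolated at the 50 kb scale), selects
#' convergent peak pairs within the scanning band and plants Gaussian loop
#' bumps on a subset of them, with amplitudes expressed as multiples of the
#' local distance-decay background. The result bundles everything the
#' classification pipeline consumes: the contact matrix, the stranded peak
#' list, and the ground-truth loop anchors.
#'
#' @param n_bins chromosome size in bins.
#' @param resolution bin size in bp (default 5000).
#' @param loop_frac fraction of eligible convergent pairs that loop (used
#'   when `n_loops` is `NULL`).
#' @param n_loops exact number of planted loops (overrides `loop_frac`).
#' @param noise_sd multiplicative log-normal noise sdlog.
#' @param amp_range loop amplitude range, in multiples of the local decay.
#' @param loop_sd Gaussian bump width in bins; a length-2 vector draws each
#'   loop's width uniformly from that range (loop widths vary in real data).
#' @param gap_range inter-peak gap range in bins (min must keep peaks
#'   isolated: `gap_range[1] * resolution >= 50000` at the default window).
#' @param sep_range eligible pair separations in bins (default the 9-300
#'   scanning band).
#' @param compartment_block optional A/B block size in bins.
#' @param seed integer seed driving layout, loop choice, amplitudes and noise.
#' @return list with `spec`, `matrix` (a [contact_matrix()]), `peaks`
#'   (stranded data.frame), `loop_anchors` (data.frame `bin1,bin2,amplitude`)
#'   and `layout` (all peak bins and strands).
#' @export
simulate_ctcf_world <- function(n_bins, resolution = 5000, loop_frac = 0.65,
                                n_loops = NULL, noise_sd = 0.25,
                                amp_range = c(4, 10), loop_sd = c(0.8, 1.8),
                                gap_range = c(11, 18), sep_range = c(9, 300),
                                compartment_block = NULL, seed = 1) {
  flank <- 6
  world <- with_seed(seed, {
    bins <- integer(0)
    b <- flank
    while (b <= n_bins - flank - 1) {
      bins <- c(bins, b)
      b <- b + sample(gap_range[1]:gap_range[2], 1)
    }
    layout <- data.frame(bin = bins,
                         strand = sample(c("+", "-"), length(bins),
                                         replace = TRUE))
    cand <- list()
    for (i in seq_len(nrow(layout) - 1)) {
      for (j in (i + 1):nrow(layout)) {
        d <- layout$bin[j] - layout$bin[i]
        if (d >= sep_range[1] && d <= sep_range[2] &&
            layout$strand[i] == "+" && layout$strand[j] == "-")
          cand[[length(cand) + 1]] <- c(layout$bin[i], layout$bin[j])
      }
    }
    cand <- do.call(rbind, cand)
    k <- if (is.null(n_loops)) round(loop_frac * nrow(cand))
         else min(n_loops, nrow(cand))
    sel <- sort(sample(nrow(cand), k))
    anchors <- data.frame(bin1 = cand[sel, 1], bin2 = cand[sel, 2])
    amp_mult <- stats::runif(nrow(anchors), amp_range[1], amp_range[2])
    anchors$sd <- if (length(loop_sd) == 2)
      stats::runif(nrow(anchors), loop_sd[1], loop_sd[2])
    else rep(loop_sd, nrow(anchors))
    list(layout = layout, anchors = anchors, amp_mult = amp_mult)
  })
  base <- synthetic_spec(n_bins * resolution, resolution = resolution,
                         noise_sd = noise_sd, seed = seed)
  world$anchors$amplitude <- world$amp_mult *
    decay_value(base, world$anchors$bin2 - world$anchors$bin1)
  spec <- synthetic_spec(n_bins * resolution, resolution = resolution,
                         loop_anchors = world$anchors,
                         noise_sd = noise_sd,
                         compartment_block = compartment_block,
                         seed = seed)
  list(spec = spec, matrix = simulate_contacts(spec),
       peaks = simulate_peaks(spec, world$layout),
       loop_anchors = world$anchors, layout = world$layout)
}

#' Simulate labelled 9x9 pattern submatrices
#'
#' Generates raw (untransformed) 9x9 submatrices of two planted topologies:
#' `cross` (enriched central row/column with a focal center peak, the canonical
#' loop signature) and `flat` (uniform background). Multiplicative log-normal
#' noise is applied per cell. Used to exercise the classifier modules with a
#' known ground truth.
#'
#' @param n_cross,n_flat number of submatrices of each pattern.
#' @param noise_sd sdlog of the multiplicative log-normal noise.
#' @param seed integer seed.
#' @param cross_gain stripe elevation of the cross pattern; the center cell
#'   gets twice this gain on top.
#' @return A `submatrix_set` (see [extract_submatrices()]) with
#'   `meta$pattern` in `c("cross", "flat")`.
#' @export
simulate_pattern_submatrices <- function(n_cross, n_flat, noise_sd = 0.2,
                                         seed = 1, cross_gain = 1) {
  base_flat <- matrix(1, 9, 9)
  base_cross <- base_flat
  base_cross[5, ] <- base_cross[5, ] + cross_gain
  base_cross[, 5] <- base_cross[, 5] + cross_gain
  base_cross[5, 5] <- base_cross[5, 5] + 2 * cross_gain
  n <- n_cross + n_flat
  pattern <- c(rep("cross", n_cross), rep("flat", n_flat))
  X <- with_seed(seed, {
    out <- matrix(0, n, 81)
    for (k in seq_len(n)) {
      b <- if (pattern[k] == "cross") base_cross else base_flat
      noise <- if (noise_sd > 0)
        matrix(stats::rlnorm(81, -noise_sd^2 / 2, noise_sd), 9, 9)
      else matrix(1, 9, 9)
      out[k, ] <- as.vector(t(b * noise))  # row-major flattening
    }
    out
  })
  new_submatrix_set(X,
                    meta = data.frame(pattern = pattern,
                                      stringsAsFactors = FALSE),
                    chrom = "synthetic", resolution = NA_real_,
                    transformed = FALSE)
}
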