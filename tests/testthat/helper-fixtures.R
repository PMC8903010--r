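# Shared fixture builders. Everything is generated in code at test time.

# A tiny decay matrix with optional planted loops, no noise unless asked.
toy_matrix <- function(n_bins = 60, resolution = 5000, loops = NULL,
                       noise_sd = 0, seed = 1, block = NULL) {
  spec <- synthetic_spec(n_bins * resolution, resolution = resolution,
                         loop_anchors = loops, noise_sd = noise_sd,
                         compartment_block = block, seed = seed)
  simulate_contacts(spec)
}

# Peak data.frame straight from centers/strands (BED convention, width 200).
peaks_at <- function(centers, strands = "+", chrom = "chr1", width = 200) {
  data.frame(chrom = chrom,
             start = as.integer(centers - width / 2),
             end = as.integer(centers + width / 2),
             name = paste0("p", seq_along(centers)),
             score = 0,
             strand = rep_len(strands, length(centers)),
             stringsAsFactors = FALSE)
}

loops_df <- function(bin_i, bin_j, prob = 1, chrom = "chr1",
                     resolution = 5000) {
  out <- data.frame(chrom = chrom, bin_i = bin_i, bin_j = bin_j,
                    prob = rep_len(prob, length(bin_i)),
                    stringsAsFactors = FALSE)
  attr(out, "resolution") <- resolution
  class(out) <- c("loop_calls", "data.frame")
  out
}

# The full classification -> caller chain on pooled toy chromosomes; returns
# everything needed to judge planted-loop recovery. Mirrors the documented
# toy-scale protocol (two 600-bin training chromosomes, 12x12 map, sd 1).
run_toy_pipeline <- function(seed, n_bins = 600, n_train_chroms = 2,
                             grid_side = 12) {
  s <- function(k) (seed * 1000003 + 97 * k) %% 2147483647
  subs_list <- list()
  for (cc in seq_len(n_train_chroms)) {
    tw <- simulate_ctcf_world(n_bins, seed = s(10 + cc))
    tw$matrix$chrom <- tw$peaks$chrom <- paste0("chrS", cc)
    pr <- enumerate_pairs(tw$peaks)
    subs_list[[cc]] <- sigmoid_transform(extract_submatrices(tw$matrix, pr))
  }
  subs <- do.call(c, subs_list)
  model <- train_sofm(subs, sofm_params(grid_side = grid_side, std = 1,
                                        seed = s(2)))
  mu <- neuron_means(model, subs)
  emb <- embed_neurons(mu, seed = s(3))
  labels <- cluster_neurons(emb)
  cs <- summarize_clusters(labels, model, subs)
  part <- partition_clusters(cs)
  ts <- suppressWarnings(assemble_training(cs, subs, part$loop, part$no_loop,
                                           seed = s(4)))
  net <- train_cnn(build_cnn(cnn_spec(), seed = s(5)), ts, seed = s(6))
  list(subs = subs, model = model, clustering = cs, partition = part,
       training = ts, net = net, seed_fn = s)
}

# Memoized standard toy run (600-bin chromosomes, the documented protocol);
# several tests inspect different aspects of the same trained chain.
.toy_cache <- new.env(parent = emptyenv())
get_toy_pipeline <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- run_toy_pipeline(seed)
  .toy_cache[[key]]
}

# Recovery of planted loops by a call set, within +/- tol bins per anchor.
recovery_stats <- function(calls, anchors, tol = 1) {
  near <- rep(FALSE, nrow(calls))
  rec <- 0L
  for (r in seq_len(nrow(anchors))) {
    m1 <- abs(calls$bin_i - anchors$bin1[r]) <= tol &
      abs(calls$bin_j - anchors$bin2[r]) <= tol
    near <- near | m1
    rec <- rec + as.integer(any(m1))
  }
  list(recovered = rec, false_calls = sum(!near))
}
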