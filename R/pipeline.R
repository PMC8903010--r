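# End-to-end orchestration: peaks -> pairs -> submatrices -> SOFM ->
# neuron clustering -> training -> scanning -> benchmark, with plain-file
# stage outputs so every stage doubles as a library entry point and a run can
# resume from prior outputs.

#' Build and validate a pipeline configuration
#'
#' All tunables default to the method's standard values: pair separation
#' 45 kb-1.5 Mb, isolation window 50 kb, motif p < 0.05, SOFM 30x30 grid /
#' radius 5 / sd 0.5 / step 0.01 / 30 epochs, embedding 6 neighbors /
#' min-dist 0.3 / 100 epochs, density clustering 6/6, 6000 + 6000 training
#' submatrices with a 20% leave-out, dropout 0.2, scan window 9 with step 1,
#' call threshold 0.9.
#'
#' @param matrix_fine,matrix_coarse paths to the fine (5 kb intended) and
#'   coarse (100 kb intended) contact matrices (text; see [read_contacts()]).
#'   `matrix_coarse` is optional.
#' @param peaks character vector of replicate peak files (BED6/narrowPeak).
#' @param motifs motif table path (see [read_motifs()]).
#' @param states optional 4-column BED chromatin-state segmentation.
#' @param chrom chromosome name of the matrices.
#' @param resolution_fine,resolution_coarse bin sizes in bp.
#' @param min_sep,max_sep,isolation_bp,motif_p peak-module parameters.
#' @param sofm list overriding [sofm_params()] fields.
#' @param embed list overriding [embed_neurons()] arguments.
#' @param hdbscan list overriding [cluster_neurons()] arguments.
#' @param n_per_class,holdout,cnn_epochs,cnn_batch training parameters.
#' @param min_sep_bins,max_sep_bins,threshold scan/call parameters.
#' @param seed master seed; every stage derives its own stream from it.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_fine, peaks, motifs,
                            matrix_coarse = NULL, states = NULL,
                            chrom = "chr1",
                            resolution_fine = 5000,
                            resolution_coarse = 100000,
                            min_sep = 45000, max_sep = 1500000,
                            isolation_bp = 50000, motif_p = 0.05,
                            sofm = list(), embed = list(), hdbscan = list(),
                            n_per_class = 6000, holdout = 0.2,
                            cnn_epochs = 20, cnn_batch = 64,
                            min_sep_bins = 9, max_sep_bins = 300,
                            threshold = 0.9, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$min_sep > cfg$max_sep) stopf("min_sep > max_sep")
  if (cfg$min_sep_bins > cfg$max_sep_bins) stopf("min_sep_bins > max_sep_bins")
  if (cfg$resolution_fine <= 0 || cfg$resolution_coarse <= 0)
    stopf("resolutions must be positive")
  if (cfg$threshold < 0 || cfg$threshold > 1) stopf("threshold must be in [0,1]")
  if (cfg$holdout <= 0 || cfg$holdout >= 1) stopf("holdout must be in (0,1)")
  cfg$sofm <- do.call(sofm_params, cfg$sofm)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file; keys as in [pipeline_config()].
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_log <- function(dir, stage, outputs) {
  line <- jsonlite::toJSON(list(stage = stage,
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                outputs = outputs), auto_unbox = TRUE)
  cat(paste0(line, "\n"), file = file.path(dir, "pipeline.log"), append = TRUE)
  message(sprintf("[%s] done: %s", stage, paste(outputs, collapse = ", ")))
}

#' Run the full loop-calling pipeline
#'
#' Stages: peak filtering (replicate intersection, motif-strand annotation,
#' isolation), pair enumeration, submatrix extraction + transform, optional
#' compartment eigenvector, SOFM training + selection metrics, neuron
#' clustering and loop/no-loop partition, network training, chromosome scan
#' and loop calling, and (when a state track is given) anchor-state and
#' convergence benchmarks. Each stage writes plain files under `out_dir`; with
#' `resume = TRUE` a stage whose outputs exist is skipped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param resume reuse existing stage outputs (default FALSE).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_rec <- config
  cfg_rec$sofm <- unclass(cfg_rec$sofm)
  jsonlite::write_json(
    list(config = unclass(cfg_rec), seed = config$seed,
         package_version = as.character(utils::packageVersion("hicloops"))),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  path <- function(f) file.path(out_dir, f)

  # -- peaks -------------------------------------------------------------
  f_peaks <- path("peaks_filtered.tsv")
  if (!(resume && file.exists(f_peaks))) {
    reps <- lapply(config$peaks, read_peaks)
    pk <- if (length(reps) > 1) common_peaks(reps) else reps[[1]]
    pk <- annotate_strand(pk, read_motifs(config$motifs),
                          p_cutoff = config$motif_p)
    pk <- isolated_peaks(pk, window_bp = config$isolation_bp)
    utils::write.table(pk, f_peaks, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_log(out_dir, "peaks", basename(f_peaks))
  }
  pk <- utils::read.table(f_peaks, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)

  # -- pairs -------------------------------------------------------------
  f_pairs <- path("pairs.tsv")
  if (!(resume && file.exists(f_pairs))) {
    pairs <- enumerate_pairs(pk, min_sep = config$min_sep,
                             max_sep = config$max_sep)
    utils::write.table(pairs, f_pairs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_log(out_dir, "pairs", basename(f_pairs))
  }
  pairs <- utils::read.table(f_pairs, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) stopf("stage 'pairs': no CTCF-CTCF pairs enumerated")

  # -- submatrices -------------------------------------------------------
  mfine <- read_contacts(config$matrix_fine, resolution = config$resolution_fine,
                         chrom = config$chrom)
  f_subs <- path("submatrices.tsv")
  if (!(resume && file.exists(f_subs))) {
    subs <- sigmoid_transform(extract_submatrices(mfine, pairs))
    write_submatrices(subs, f_subs)
    stage_log(out_dir, "waffle", basename(f_subs))
  }
  subs <- read_submatrices(f_subs)
  if (nrow(subs$X) == 0) stopf("stage 'waffle': no submatrices extracted")

  # -- compartments ------------------------------------------------------
  eig <- NULL
  if (!is.null(config$matrix_coarse)) {
    mc <- read_contacts(config$matrix_coarse,
                        resolution = config$resolution_coarse,
                        chrom = config$chrom)
    reference <- NULL
    if (!is.null(config$states)) {
      ann <- annotate_bins(merge_states(read_state_track(config$states)),
                           resolution = config$resolution_coarse)
      reference <- rep(0, mc$n_bins)
      active <- ann$bin[ann$promoter | ann$enhancer] + 1L
      reference[active[active <= mc$n_bins]] <- 1
    }
    eig <- compartment_eigenvector(mc, reference = reference)
    write_compartments(eig, path("compartments.bedGraph"))
    stage_log(out_dir, "compartments", "compartments.bedGraph")
  }

  # -- SOFM --------------------------------------------------------------
  sp <- config$sofm
  sp$seed <- child_seed(config$seed, 1)
  model <- train_sofm(subs, sp)
  anchor_eigen <- if (!is.null(eig)) pair_eigen_values(subs$meta, eig) else NULL
  metrics <- selection_metrics(model, anchor_eigen)
  utils::write.table(cbind(model$grid, t(matrix(model$weights,
                                                ncol = nrow(model$weights)))),
                     path("sofm_weights.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(sample = seq_along(model$assignments),
                                neuron = model$assignments),
                     path("sofm_assignments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(metrics), path("sofm_metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_log(out_dir, "sofm",
            c("sofm_weights.tsv", "sofm_assignments.tsv", "sofm_metrics.json"))

  # -- neuron clustering -------------------------------------------------
  med <- neuron_medoids(model, subs)
  emb <- embed_neurons(med, n_neighbors = config$embed$n_neighbors %||% 6,
                       min_dist = config$embed$min_dist %||% 0.3,
                       n_epochs = config$embed$n_epochs %||% 100,
                       seed = child_seed(config$seed, 2))
  labels <- cluster_neurons(emb,
                            min_cluster_size = config$hdbscan$min_cluster_size %||% 6,
                            min_samples = config$hdbscan$min_samples %||% 6)
  cs <- summarize_clusters(labels, model, subs)
  utils::write.table(data.frame(neuron = attr(labels, "neuron"),
                                dim1 = emb[, 1], dim2 = emb[, 2],
                                label = as.integer(labels)),
                     path("neuron_clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cs$summary, path("cluster_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_log(out_dir, "cluster", c("neuron_clusters.tsv", "cluster_summary.tsv"))

  # -- network training --------------------------------------------------
  part <- partition_clusters(cs)
  ts <- assemble_training(cs, subs, part$loop, part$no_loop,
                          n_per_class = config$n_per_class,
                          holdout = config$holdout,
                          seed = child_seed(config$seed, 3))
  net <- build_cnn(cnn_spec(), seed = child_seed(config$seed, 4))
  net <- train_cnn(net, ts, epochs = config$cnn_epochs,
                   batch = config$cnn_batch,
                   seed = child_seed(config$seed, 5))
  jsonlite::write_json(list(loop_clusters = part$loop,
                            noloop_clusters = part$no_loop,
                            test_accuracy = as.list(net$test_accuracy),
                            n_params = n_params(net)),
                       path("training.json"), auto_unbox = TRUE, digits = NA)
  stage_log(out_dir, "train", "training.json")

  # -- scan + call -------------------------------------------------------
  pmap <- scan_contacts(net, mfine, min_sep_bins = config$min_sep_bins,
                        max_sep_bins = config$max_sep_bins)
  calls <- call_loops(pmap, threshold = config$threshold)
  write_bedpe(calls, path("loops.bedpe"))
  stage_log(out_dir, "call", "loops.bedpe")

  # -- benchmark ---------------------------------------------------------
  bench <- list(n_calls = nrow(calls),
                n_centers = attr(pmap, "n_centers"))
  if (!is.null(config$states)) {
    annf <- annotate_bins(merge_states(read_state_track(config$states)),
                          resolution = config$resolution_fine)
    bench$anchor_state_proportions <-
      as.list(anchor_state_proportions(calls, annf))
  }
  bench$convergence_fraction <- convergence_fraction(
    calls, pk, resolution = config$resolution_fine)
  jsonlite::write_json(bench, path("benchmark.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_log(out_dir, "bench", "benchmark.json")

  invisible(list(peaks = pk, pairs = pairs, submatrices = subs, model = model,
                 metrics = metrics, clustering = cs, partition = part,
                 network = net, prob_map = pmap, calls = calls,
                 benchmark = bench))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
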