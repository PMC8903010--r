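# Loop-caller network: 9x9 window -> flatten -> dense 1024 (ReLU) ->
# dropout 0.2 -> dense 4 (softmax, no bias on the final layer). Only output
# units 1 (loop) and 2 (no-loop) are ever targets; the 4-unit softmax and the
# bias-free final layer are kept exactly as designed, giving
# 81*1024 + 1024 + 1024*4 = 88,064 trainable parameters. Training is
# mini-batch Adam on the cross-entropy of the one-hot targets.

#' Loop-caller network architecture
#'
#' @param input_shape shape of an input window (default `c(9, 9)`).
#' @param hidden_units width of the hidden ReLU layer (default 1024).
#' @param dropout dropout rate after the hidden layer (default 0.2).
#' @param output_units softmax width (default 4; classes occupy units 1-2).
#' @return An object of class `cnn_spec` with the derived `n_params`
#'   (`n_in * hidden + hidden + hidden * out`; the final layer has no bias).
#' @export
cnn_spec <- function(input_shape = c(9, 9), hidden_units = 1024,
                     dropout = 0.2, output_units = 4) {
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (output_units < 2) stopf("need >= 2 output units")
  n_in <- prod(input_shape)
  structure(list(input_shape = input_shape, n_in = n_in,
                 hidden_units = as.integer(hidden_units), dropout = dropout,
                 output_units = as.integer(output_units),
                 n_params = n_in * hidden_units + hidden_units +
                   hidden_units * output_units),
            class = "cnn_spec")
}

#' Build an untrained loop-caller model
#'
#' Weights use seeded Glorot-uniform initialization; the hidden bias starts
#' at zero.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  with_seed(seed, {
    l1 <- sqrt(6 / (spec$n_in + spec$hidden_units))
    l2 <- sqrt(6 / (spec$hidden_units + spec$output_units))
    structure(list(
      spec = spec,
      W1 = matrix(stats::runif(spec$n_in * spec$hidden_units, -l1, l1),
                  spec$n_in, spec$hidden_units),
      b1 = numeric(spec$hidden_units),
      W2 = matrix(stats::runif(spec$hidden_units * spec$output_units,
                               -l2, l2),
                  spec$hidden_units, spec$output_units),
      trained = FALSE, seed = seed
    ), class = "cnn_model")
  })
}

#' Trainable parameter count
#' @param x a `cnn_spec` or `cnn_model`.
#' @return integer parameter count.
#' @export
n_params <- function(x) {
  if (inherits(x, "cnn_model")) x <- x$spec
  stopifnot(inherits(x, "cnn_spec"))
  x$n_params
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d-%d-%d, %d parameters, %s\n",
              x$spec$n_in, x$spec$hidden_units, x$spec$output_units,
              x$spec$n_params, if (x$trained) "trained" else "untrained"))
  if (!is.null(x$test_accuracy))
    cat(sprintf("  held-out accuracy: loop %.3f, no-loop %.3f\n",
                x$test_accuracy[["loop"]], x$test_accuracy[["no_loop"]]))
  invisible(x)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Class probabilities for 9x9 windows
#'
#' @param model a `cnn_model`.
#' @param X matrix of flattened (and transformed) windows, one per row.
#' @return n x `output_units` matrix of softmax probabilities (column 1 is
#'   the loop class).
#' @export
predict_cnn <- function(model, X) {
  X <- as.matrix(X)
  H <- pmax(sweep(X %*% model$W1, 2, model$b1, "+"), 0)
  softmax_rows(H %*% model$W2)
}

#' Assemble a balanced loop / no-loop training set from clusters
#'
#' Samples, without replacement and from the seed, up to `n_per_class`
#' submatrices whose SOFM neuron falls in the loop-side clusters and likewise
#' for the no-loop side; mid clusters and noise neurons are excluded simply by
#' not being listed. A seeded stratified split holds out a fraction of each
#' class for testing.
#'
#' @param cs a [summarize_clusters()] result.
#' @param subs the transformed `submatrix_set` (or matrix) behind the model.
#' @param loop_clusters,noloop_clusters integer vectors of cluster ids.
#' @param n_per_class submatrices to draw per class (default 6000); capped
#'   with a warning when a side holds fewer.
#' @param holdout held-out fraction (default 0.2).
#' @param balance if `TRUE` (default) both classes are capped at the size of
#'   the smaller side, keeping the set balanced when a side is short.
#' @param seed integer seed.
#' @return An object of class `training_set` with `train_x`, `train_y`,
#'   `test_x`, `test_y` (labels 1 = loop, 2 = no-loop) and the drawn sample
#'   indices.
#' @export
assemble_training <- function(cs, subs, loop_clusters, noloop_clusters,
                              n_per_class = 6000, holdout = 0.2,
                              balance = TRUE, seed = 1) {
  X <- if (inherits(subs, "submatrix_set")) subs$X else as.matrix(subs)
  sc <- cs$sample_cluster
  pools <- list(loop = which(sc %in% loop_clusters),
                no_loop = which(sc %in% noloop_clusters))
  if (any(vapply(pools, length, 1L) == 0))
    stopf("empty class side: loop %d, no-loop %d samples available",
          length(pools$loop), length(pools$no_loop))
  cap <- if (balance) min(n_per_class, vapply(pools, length, 1L))
         else n_per_class
  with_seed(seed, {
    take <- lapply(pools, function(p) {
      k <- min(cap, length(p))
      if (k < n_per_class)
        warnf("only %d submatrices taken for a class (requested %d)",
              k, n_per_class)
      sort(sample(p, k))
    })
    split1 <- function(idx) {
      nt <- floor(length(idx) * holdout)
      test <- sort(sample(seq_along(idx), nt))
      list(train = idx[-test], test = idx[test])
    }
    s_loop <- split1(take$loop)
    s_no <- split1(take$no_loop)
    structure(list(
      train_x = X[c(s_loop$train, s_no$train), , drop = FALSE],
      train_y = rep(1:2, c(length(s_loop$train), length(s_no$train))),
      test_x = X[c(s_loop$test, s_no$test), , drop = FALSE],
      test_y = rep(1:2, c(length(s_loop$test), length(s_no$test))),
      idx = list(loop = take$loop, no_loop = take$no_loop),
      seed = seed
    ), class = "training_set")
  })
}

#' Train the loop-caller network
#'
#' Mini-batch Adam on the softmax cross-entropy; targets are one-hot vectors
#' occupying output units 1 (loop) and 2 (no-loop). Dropout uses inverted
#' scaling. Reports per-class accuracy on the held-out split.
#'
#' @param model an untrained (or previously trained) `cnn_model`.
#' @param ts a [assemble_training()] result, or a list with `train_x`,
#'   `train_y`, `test_x`, `test_y`.
#' @param epochs,batch training schedule (defaults 20 and 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed for shuffles and dropout masks.
#' @return the trained model, with `history` (per-epoch training loss) and
#'   `test_accuracy` (named: `loop`, `no_loop`).
#' @export
train_cnn <- function(model, ts, epochs = 20, batch = 64, lr = 1e-3,
                      seed = 1) {
  X <- as.matrix(ts$train_x); y <- as.integer(ts$train_y)
  n <- nrow(X)
  ou <- model$spec$output_units
  drop_p <- model$spec$dropout
  Tfull <- matrix(0, n, ou)
  Tfull[cbind(seq_len(n), y)] <- 1
  W1 <- model$W1; b1 <- model$b1; W2 <- model$W2
  mW1 <- W1 * 0; vW1 <- W1 * 0; mb1 <- b1 * 0; vb1 <- b1 * 0
  mW2 <- W2 * 0; vW2 <- W2 * 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  history <- numeric(epochs)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = batch)) {
        rows <- ord[b0:min(b0 + batch - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        Tb <- Tfull[rows, , drop = FALSE]
        nb <- nrow(Xb)
        Z1 <- sweep(Xb %*% W1, 2, b1, "+")
        H <- pmax(Z1, 0)
        if (drop_p > 0) {
          mask <- matrix(stats::rbinom(length(H), 1, 1 - drop_p),
                         nrow(H), ncol(H)) / (1 - drop_p)
          Hd <- H * mask
        } else {
          mask <- NULL
          Hd <- H
        }
        P <- softmax_rows(Hd %*% W2)
        loss <- -mean(log(pmax(rowSums(P * Tb), 1e-12)))
        if (!is.finite(loss)) stopf("non-finite training loss")
        losses <- c(losses, loss)
        dS <- (P - Tb) / nb
        dW2 <- t(Hd) %*% dS
        dHd <- dS %*% t(W2)
        dH <- if (is.null(mask)) dHd else dHd * mask
        dZ1 <- dH * (Z1 > 0)
        dW1 <- t(Xb) %*% dZ1
        db1 <- colSums(dZ1)
        t <- t + 1
        adam <- function(w, g, m, v) {
          m <- beta1 * m + (1 - beta1) * g
          v <- beta2 * v + (1 - beta2) * g^2
          w <- w - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
          list(w, m, v)
        }
        u <- adam(W1, dW1, mW1, vW1); W1 <- u[[1]]; mW1 <- u[[2]]; vW1 <- u[[3]]
        u <- adam(b1, db1, mb1, vb1); b1 <- u[[1]]; mb1 <- u[[2]]; vb1 <- u[[3]]
        u <- adam(W2, dW2, mW2, vW2); W2 <- u[[1]]; mW2 <- u[[2]]; vW2 <- u[[3]]
      }
      history[e] <- mean(losses)
    }
  })
  model$W1 <- W1; model$b1 <- b1; model$W2 <- W2
  model$trained <- TRUE
  model$history <- history
  if (!is.null(ts$test_x) && nrow(ts$test_x) > 0) {
    P <- predict_cnn(model, ts$test_x)
    pred <- max.col(P, ties.method = "first")
    yt <- as.integer(ts$test_y)
    model$test_accuracy <- c(loop = mean(pred[yt == 1] == 1),
                             no_loop = mean(pred[yt == 2] == 2))
  }
  model
}

#' Scan a contact matrix with the loop caller
#'
#' Slides a 9x9 window chromosome-wise with the given step over every center
#' `(i, j)` with `min_sep_bins <= j - i <= max_sep_bins` and both window
#' halves inside the matrix; each window is transformed exactly as at training
#' time (per-window z-score + logistic) and the loop-class probability
#' recorded.
#'
#' @param model a trained `cnn_model`.
#' @param m a [contact_matrix()] at the caller's resolution.
#' @param min_sep_bins,max_sep_bins diagonal band scanned, in bins (defaults
#'   9 and 300, i.e. 45 kb to 1.5 Mb at 5 kb).
#' @param step scan step in bins (default 1).
#' @param chunk windows evaluated per batch (memory bound).
#' @return An object of class `loop_prob_map`: data.frame `bin_i`, `bin_j`
#'   (0-based), `prob`, with attributes `chrom`, `resolution`, `n_centers`.
#' @export
scan_contacts <- function(model, m, min_sep_bins = 9, max_sep_bins = 300,
                          step = 1, chunk = 8192) {
  stopifnot(inherits(m, "contact_matrix"))
  flank <- (model$spec$input_shape[1] - 1) %/% 2
  n <- m$n_bins
  if (n < 2 * flank + 1) stopf("matrix smaller than the scanning window")
  ci <- seq(flank, n - 1 - flank, by = step)  # 0-based centers
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (i in ci) {
    j <- ci[ci >= i + min_sep_bins & ci <= i + max_sep_bins]
    pairs_i <- c(pairs_i, rep.int(i, length(j)))
    pairs_j <- c(pairs_j, j)
  }
  w <- 2L * flank + 1L
  dr <- rep(-flank:flank, each = w)
  dc <- rep(-flank:flank, times = w)
  offset <- dc * n + dr
  prob <- numeric(length(pairs_i))
  for (b0 in seq(1, length(pairs_i), by = chunk)) {
    rows <- b0:min(b0 + chunk - 1, length(pairs_i))
    base <- pairs_j[rows] * n + pairs_i[rows] + 1L
    Xw <- matrix(m$values[outer(base, offset, "+")], nrow = length(rows))
    prob[rows] <- predict_cnn(model, transform_rows(Xw))[, 1]
  }
  structure(data.frame(bin_i = pairs_i, bin_j = pairs_j, prob = prob),
            class = c("loop_prob_map", "data.frame"),
            chrom = m$chrom, resolution = m$resolution,
            n_centers = length(pairs_i))
}

#' Call loops from a probability map
#'
#' Cells at or above the threshold are grouped into 8-connected components
#' (the caller produces probability clouds rather than single cells); each
#' component yields one call at its maximum-probability cell, ties resolved
#' to the lexicographically smallest `(bin_i, bin_j)`.
#'
#' @param pmap a [scan_contacts()] result.
#' @param threshold probability cutoff (default 0.9).
#' @return An object of class `loop_calls`: data.frame `chrom`, `bin_i`,
#'   `bin_j`, `prob` with attribute `resolution`.
#' @export
call_loops <- function(pmap, threshold = 0.9) {
  sel <- pmap[pmap$prob >= threshold, , drop = FALSE]
  res <- attr(pmap, "resolution")
  ch <- attr(pmap, "chrom")
  if (nrow(sel) == 0) {
    out <- data.frame(chrom = character(), bin_i = integer(),
                      bin_j = integer(), prob = numeric())
    attr(out, "resolution") <- res
    class(out) <- c("loop_calls", "data.frame")
    return(out)
  }
  span <- max(sel$bin_j) + 2L
  key <- sel$bin_i * span + sel$bin_j
  lookup <- seq_along(key)
  names(lookup) <- as.character(key)
  # union-find over 8-connected above-threshold cells
  parent <- seq_along(key)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (ddi in -1:1) for (ddj in -1:1) {
    if (ddi == 0 && ddj == 0) next
    nb <- lookup[as.character((sel$bin_i + ddi) * span + sel$bin_j + ddj)]
    has <- which(!is.na(nb))
    for (a in has) {
      ra <- find(a); rb <- find(nb[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  comp <- vapply(seq_along(key), find, integer(1))
  ord <- order(comp, -sel$prob, sel$bin_i, sel$bin_j)
  first <- ord[!duplicated(comp[ord])]
  out <- data.frame(chrom = ch, bin_i = sel$bin_i[first],
                    bin_j = sel$bin_j[first], prob = sel$prob[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$bin_i, out$bin_j), ]
  rownames(out) <- NULL
  attr(out, "resolution") <- res
  class(out) <- c("loop_calls", "data.frame")
  out
}

#' Write / read loop calls as BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score, where each
#' anchor interval is its bin and score is the call probability.
#'
#' @param calls a `loop_calls` data.frame.
#' @param path file path.
#' @param resolution bin size (taken from the calls' attribute if absent).
#' @export
write_bedpe <- function(calls, path, resolution = attr(calls, "resolution")) {
  df <- data.frame(
    chrom1 = calls$chrom, start1 = as.integer(calls$bin_i * resolution),
    end1 = as.integer((calls$bin_i + 1) * resolution),
    chrom2 = calls$chrom, start2 = as.integer(calls$bin_j * resolution),
    end2 = as.integer((calls$bin_j + 1) * resolution),
    name = paste0("loop_", seq_len(nrow(calls))),
    score = calls$prob)
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path, resolution) {
  empty <- data.frame(chrom = character(), bin_i = integer(),
                      bin_j = integer(), prob = numeric())
  tab <- tryCatch(utils::read.table(path, header = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) {
    attr(empty, "resolution") <- resolution
    class(empty) <- c("loop_calls", "data.frame")
    return(empty)
  }
  out <- data.frame(chrom = as.character(tab[[1]]),
                    bin_i = as.integer(tab[[2]] / resolution),
                    bin_j = as.integer(tab[[5]] / resolution),
                    prob = if (ncol(tab) >= 8) as.numeric(tab[[8]]) else NA,
                    stringsAsFactors = FALSE)
  attr(out, "resolution") <- resolution
  class(out) <- c("loop_calls", "data.frame")
  out
}
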