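test_that("the architecture's parameter count follows the closed form", {
  expect_equal(n_params(cnn_spec()), 88064)
  expect_equal(n_params(cnn_spec(hidden_units = 1)), 81 + 1 + 4)
  expect_equal(n_params(build_cnn(cnn_spec(), seed = 2)), 88064)
  net <- build_cnn(cnn_spec(), seed = 2)
  expect_equal(length(net$W1) + length(net$b1) + length(net$W2), 88064)
})

test_that("forward passes are softmax-normalized and seeded builds identical", {
  net <- build_cnn(cnn_spec(), seed = 5)
  p <- predict_cnn(net, matrix(runif(81), 1, 81))
  expect_equal(rowSums(p), 1)
  expect_equal(ncol(p), 4)
  expect_true(all(p > 0))
  expect_identical(net$W1, build_cnn(cnn_spec(), seed = 5)$W1)
})

test_that("training set assembly samples the named clusters only, balanced", {
  subs <- simulate_pattern_submatrices(60, 120, noise_sd = 0.2, seed = 3)
  tsubs <- sigmoid_transform(subs)
  model <- train_sofm(tsubs, sofm_params(grid_side = 4, std = 1, seed = 9))
  mu <- neuron_means(model, tsubs)
  emb <- embed_neurons(mu, n_neighbors = 3, seed = 2)
  labels <- cluster_neurons(emb, min_cluster_size = 2, min_samples = 2)
  cs <- summarize_clusters(labels, model, tsubs)
  expect_gte(nrow(cs$summary), 2)  # both pattern clusters form
  part <- partition_clusters(cs)
  ts <- suppressWarnings(
    assemble_training(cs, tsubs, part$loop, part$no_loop, n_per_class = 50,
                      seed = 4))
  expect_equal(sum(ts$train_y == 1), sum(ts$train_y == 2))
  expect_equal(length(ts$test_y), round(0.2 * 2 * 50))
  # excluded clusters contribute nothing
  excluded <- which(!(cs$sample_cluster %in% c(part$loop, part$no_loop)))
  expect_length(intersect(unlist(ts$idx), excluded), 0)
  ts2 <- suppressWarnings(
    assemble_training(cs, tsubs, part$loop, part$no_loop, n_per_class = 50,
                      seed = 4))
  expect_identical(ts$idx, ts2$idx)
})

test_that("the network separates planted patterns and trains reproducibly", {
  subs <- simulate_pattern_submatrices(1000, 1000, noise_sd = 0.2, seed = 13)
  X <- sigmoid_transform(subs)$X
  y <- ifelse(subs$meta$pattern == "cross", 1L, 2L)
  set.seed(17)
  test_idx <- sample(2000, 400)
  ts <- list(train_x = X[-test_idx, ], train_y = y[-test_idx],
             test_x = X[test_idx, ], test_y = y[test_idx])
  net <- train_cnn(build_cnn(cnn_spec(), seed = 1), ts, epochs = 5, seed = 2)
  expect_gte(net$test_accuracy[["loop"]], 0.95)
  expect_gte(net$test_accuracy[["no_loop"]], 0.95)

  net2 <- train_cnn(build_cnn(cnn_spec(), seed = 1), ts, epochs = 5, seed = 2)
  expect_identical(net$W2, net2$W2)
  expect_identical(net$test_accuracy, net2$test_accuracy)
})

test_that("scanning covers exactly the in-bounds diagonal band", {
  m <- toy_matrix(20, noise_sd = 0.1, seed = 3)
  net <- build_cnn(cnn_spec(), seed = 1)
  pmap <- scan_contacts(net, m, min_sep_bins = 9, max_sep_bins = 300)
  # centers 4..15 on both axes with j - i >= 9 (0-based)
  expected <- sum(vapply(4:15, function(i) max(0L, 15L - (i + 9L) + 1L), 1L))
  expect_equal(nrow(pmap), expected)
  expect_true(all(pmap$bin_j - pmap$bin_i >= 9))
  expect_true(all(pmap$bin_i >= 4 & pmap$bin_j <= 15))
  expect_error(scan_contacts(net, toy_matrix(5)), "smaller")
})

test_that("a trained scanner peaks at a planted loop", {
  s <- get_toy_pipeline(seed = 1)
  ew <- simulate_ctcf_world(300, n_loops = 3, noise_sd = 0.2,
                            amp_range = c(6, 8), loop_sd = 1, seed = 99)
  pmap <- scan_contacts(s$net, ew$matrix)
  for (r in seq_len(nrow(ew$loop_anchors))) {
    b1 <- ew$loop_anchors$bin1[r]; b2 <- ew$loop_anchors$bin2[r]
    hood <- pmap[abs(pmap$bin_i - b1) <= 1 & pmap$bin_j - b2 >= -1 &
                   pmap$bin_j - b2 <= 1, ]
    center <- pmap$prob[pmap$bin_i == b1 & pmap$bin_j == b2]
    expect_gte(center, max(hood$prob) - 1e-9)  # local maximum of its 3x3
  }
})

test_that("loop calls are one per connected probability cloud", {
  fake_map <- function(df, n_centers = 1000) {
    structure(df, class = c("loop_prob_map", "data.frame"),
              chrom = "chr1", resolution = 5000, n_centers = n_centers)
  }
  empty <- call_loops(fake_map(data.frame(bin_i = 10, bin_j = 30,
                                          prob = 0.5)))
  expect_equal(nrow(empty), 0)

  single <- call_loops(fake_map(data.frame(bin_i = 10, bin_j = 30,
                                           prob = 0.95)))
  expect_equal(single$bin_i, 10)
  expect_equal(single$prob, 0.95)

  cloud <- expand.grid(bin_i = 9:11, bin_j = 29:31)
  cloud$prob <- 0.91
  cloud$prob[cloud$bin_i == 10 & cloud$bin_j == 30] <- 0.99
  cloud <- rbind(cloud, data.frame(bin_i = 50, bin_j = 80, prob = 0.93))
  calls <- call_loops(fake_map(cloud))
  expect_equal(nrow(calls), 2)
  expect_equal(calls$bin_i, c(10, 50))
  expect_equal(calls$prob, c(0.99, 0.93))
})

test_that("loop calls round-trip through BEDPE", {
  calls <- loops_df(c(10, 40), c(30, 90), prob = c(0.95, 0.91))
  f <- withr::local_tempfile()
  write_bedpe(calls, f)
  back <- read_bedpe(f, resolution = 5000)
  expect_equal(back$bin_i, calls$bin_i)
  expect_equal(back$bin_j, calls$bin_j)
  expect_equal(back$prob, calls$prob)
})
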