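silhouette_mean <- function(emb, grp) {
  D <- as.matrix(dist(emb))
  s <- vapply(seq_len(nrow(emb)), function(i) {
    a <- mean(D[i, grp == grp[i] & seq_len(nrow(emb)) != i])
    b <- min(vapply(setdiff(unique(grp), grp[i]),
                    function(g) mean(D[i, grp == g]), 1))
    (b - a) / max(a, b)
  }, 1)
  mean(s)
}

test_that("well-separated medoid groups stay separated in the embedding", {
  set.seed(3)
  g1 <- matrix(runif(15 * 81, 0.0, 0.3), 15, 81)
  g2 <- matrix(runif(15 * 81, 0.7, 1.0), 15, 81)
  med <- rbind(g1, g2)
  emb <- embed_neurons(med, seed = 4)
  expect_gt(silhouette_mean(emb, rep(1:2, each = 15)), 0.5)
  expect_identical(emb, embed_neurons(med, seed = 4))  # determinism
})

test_that("duplicated medoids embed next to their own group", {
  set.seed(5)
  base <- matrix(runif(10 * 81), 10, 81)
  med <- rbind(base, base[1:3, ] + 1e-6,
               matrix(runif(10 * 81, 3, 4), 10, 81))
  emb <- embed_neurons(med, seed = 6)
  D <- as.matrix(dist(emb)); diag(D) <- Inf
  near_group <- c(rep(1, 13), rep(2, 10))
  for (i in 11:13) {  # the duplicates
    expect_equal(near_group[which.min(D[i, ])], 1)
  }
})

test_that("embedding rejects too few points", {
  expect_error(embed_neurons(matrix(runif(5 * 81), 5, 81), n_neighbors = 6),
               "n_neighbors")
})

test_that("density clustering recovers planted groups with noise semantics", {
  set.seed(11)
  two <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
               matrix(rnorm(40, 10, 0.5), 20, 2))
  lab <- cluster_neurons(two)
  expect_equal(sort(unique(lab)), c(1, 2))
  expect_equal(unname(table(lab)), as.array(c(20, 20)),
               ignore_attr = TRUE)

  few <- matrix(rnorm(10, sd = 20), 5, 2)
  expect_true(all(cluster_neurons(few) == -1))

  blob <- matrix(rnorm(60), 30, 2)
  expect_equal(unique(cluster_neurons(blob)), 1)

  # label conservation: cluster sizes plus noise count all points
  mix <- rbind(two, matrix(runif(20, -50, 50), 10, 2))
  lm <- cluster_neurons(mix)
  expect_equal(sum(table(lm)), nrow(mix))
})

test_that("cluster summaries pool counts, order by loop likeness, and expose medoids", {
  s <- get_toy_pipeline(seed = 1)
  cs <- s$clustering
  expect_equal(sum(cs$summary$n_submatrices),
               sum(s$model$assignments %in% unlist(cs$neuron_map)))
  expect_equal(cs$summary$cluster, seq_len(nrow(cs$summary)))
  expect_true(all(diff(cs$summary$central_intensity) <= 0))
  # the most loop-like cluster has its medoid maximum at the center cell
  expect_equal(which.max(cs$medoids[1, ]), 41)
  # sample labels conserve totals
  expect_equal(sum(cs$sample_cluster > 0), sum(cs$summary$n_submatrices))

  part <- partition_clusters(cs)
  expect_gt(length(part$loop), 0)
  expect_gt(length(part$no_loop), 0)
  expect_equal(sort(c(part$loop, part$no_loop)), cs$summary$cluster)
})

test_that("empty label sets summarize to empty tables", {
  fake_model <- structure(list(
    params = sofm_params(grid_side = 2, seed = 1),
    weights = matrix(0.5, 4, 81),
    grid = data.frame(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1)),
    assignments = c(1L, 2L), n_samples = 2, d = 81), class = "sofm_model")
  labels <- structure(c(-1L, -1L), neuron = c(1L, 2L))
  cs <- summarize_clusters(labels, fake_model, matrix(runif(2 * 81), 2, 81))
  expect_equal(nrow(cs$summary), 0)
  expect_true(all(cs$sample_cluster == -1))
  expect_error(partition_clusters(cs), ">= 2 clusters")
})
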