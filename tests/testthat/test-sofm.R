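test_that("training is deterministic and assignments are true BMUs", {
  subs <- simulate_pattern_submatrices(30, 30, noise_sd = 0.3, seed = 1)
  X <- sigmoid_transform(subs)$X
  p <- sofm_params(grid_side = 5, epochs = 5, seed = 3)
  m1 <- train_sofm(X, p)
  m2 <- train_sofm(X, p)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$assignments, m2$assignments)

  # brute-force nearest-neighbor oracle over all neurons
  for (s in seq_len(nrow(X))) {
    d2 <- colSums((t(m1$weights) - X[s, ])^2)
    expect_equal(m1$assignments[s], which.min(d2))
  }
})

test_that("a single sample's BMU weight contracts toward it over epochs", {
  x <- matrix(runif(81, 0.2, 0.8), 1, 81)
  dists <- sapply(c(1, 3, 6, 10), function(e) {
    m <- train_sofm(x, sofm_params(grid_side = 3, epochs = e, step = 0.2,
                                   seed = 5))
    sqrt(sum((m$weights[m$assignments[1], ] - x)^2))
  })
  expect_true(all(diff(dists) < 0))
})

test_that("neighborhood updates keep weights inside (0,1) for (0,1) inputs", {
  subs <- simulate_pattern_submatrices(40, 40, noise_sd = 0.5, seed = 2)
  X <- sigmoid_transform(subs)$X
  m <- train_sofm(X, sofm_params(grid_side = 6, std = 2, learning_radius = 4,
                                 step = 0.9, epochs = 10, seed = 7))
  expect_true(all(m$weights > 0 & m$weights < 1))
})

test_that("two planted patterns separate with high neuron purity", {
  subs <- simulate_pattern_submatrices(100, 100, noise_sd = 0.2, seed = 7)
  X <- sigmoid_transform(subs)$X
  m <- train_sofm(X, sofm_params(grid_side = 4, seed = 11))
  lab <- subs$meta$pattern
  purity <- sum(vapply(split(seq_along(lab), m$assignments),
                       function(ix) max(table(lab[ix])), 1)) / length(lab)
  expect_gte(purity, 0.95)

  # grid topology: same-pattern BMUs are closer on the grid than cross-pattern
  g <- m$grid[m$assignments, ]
  cross <- outer(lab, lab, "!=")
  gd <- as.matrix(stats::dist(g))
  expect_lt(mean(gd[!cross & upper.tri(gd)]), mean(gd[cross & upper.tri(gd)]))
})

test_that("selection metrics handle the documented edge cases", {
  fake <- structure(list(
    params = sofm_params(grid_side = 2, seed = 1),
    weights = matrix(0.5, 4, 3),
    grid = data.frame(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1)),
    assignments = c(1L, 2L, 3L), n_samples = 3, d = 3), class = "sofm_model")
  # every sample a singleton -> nothing classified; identical weights -> 0
  m0 <- selection_metrics(fake)
  expect_equal(m0$pct_classified, 0)
  expect_equal(m0$inter_neuron_variability, 0)

  # one neuron with pooled anchor eigen values {+1, +1, -1} -> |mean| = 1/3
  fake$assignments <- c(1L, 1L, 1L)
  eig <- cbind(c(1, 1, -1), NA_real_)
  expect_equal(selection_metrics(fake, eig)$segregation_score, 1 / 3)
})

test_that("medoids are members minimizing total distance", {
  X <- rbind(rep(0, 4), rep(1, 4), rep(4, 4))
  fake <- structure(list(
    params = sofm_params(grid_side = 2, seed = 1),
    weights = matrix(0.5, 4, 4),
    grid = data.frame(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1)),
    assignments = c(2L, 2L, 2L), n_samples = 3, d = 4), class = "sofm_model")
  med <- neuron_medoids(fake, X)
  expect_equal(unname(med[1, ]), rep(1, 4))      # middle of collinear points
  expect_equal(attr(med, "sample"), 2L)

  fake$assignments <- c(1L, 3L, 3L)
  med2 <- neuron_medoids(fake, X)
  expect_equal(nrow(med2), 2)                    # singleton is its own medoid
  expect_true(all(attr(med2, "sample") %in% 1:3))
  # medoid rows are actual members, never averages
  expect_true(all(apply(med2, 1, function(r)
    any(apply(X, 1, function(x) all(x == r))))))
})

test_that("grid search tabulates every combination and recommends one", {
  subs <- simulate_pattern_submatrices(20, 20, noise_sd = 0.3, seed = 5)
  X <- sigmoid_transform(subs)$X
  g1 <- sofm_grid_search(X, list(grid_side = 3, epochs = 2), seed = 2)
  expect_equal(nrow(g1), 1)
  g4 <- sofm_grid_search(X, list(grid_side = c(3, 4), epochs = c(2, 4)),
                         seed = 2)
  expect_equal(nrow(g4), 4)
  expect_true(attr(g4, "best") %in% 1:4)
  g4b <- sofm_grid_search(X, list(grid_side = c(3, 4), epochs = c(2, 4)),
                          seed = 2)
  expect_identical(g4, g4b)
})

test_that("pair anchors map onto coarse compartment bins", {
  m <- toy_matrix(60, block = 10, noise_sd = 0.05, seed = 3)
  track <- compartment_eigenvector(m)
  pairs <- data.frame(up_center = c(2500, 100e3 + 1), down_center = c(1e9, 200e3))
  ev <- pair_eigen_values(pairs, track)
  expect_equal(unname(ev[1, "up"]), track$eigenvector[1])
  expect_true(is.na(ev[1, "down"]))  # outside the track
  expect_equal(unname(ev[2, "up"]), track$eigenvector[21])
})
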