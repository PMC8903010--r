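test_that("exact Jaccard follows set arithmetic on anchor tuples", {
  A <- loops_df(c(10, 20, 30), c(50, 60, 70))
  expect_equal(loop_jaccard(A, A), 1.0)
  B <- loops_df(c(100, 200), c(150, 260))
  expect_equal(loop_jaccard(A, B), 0.0)
  C <- loops_df(c(10, 20, 33), c(50, 60, 77))
  expect_equal(loop_jaccard(A, C), 0.5)  # 2 shared of 4 distinct
  expect_error(loop_jaccard(A[0, ], B[0, ]), "empty")
})

test_that("loose Jaccard reduces to exact at tol 0 and matches one-to-one", {
  A <- loops_df(c(10, 20, 30), c(50, 60, 70))
  C <- loops_df(c(10, 21, 33), c(50, 61, 77))
  expect_equal(loop_jaccard_loose(A, C, tol_bins = 0), loop_jaccard(A, C))
  # a single pair offset by one bin matches fully at tol 1
  expect_equal(loop_jaccard_loose(loops_df(10, 50), loops_df(11, 51),
                                  tol_bins = 1), 1.0)
  # two A-loops within tol of one B-loop: only one can match
  A2 <- loops_df(c(10, 11), c(50, 51))
  B2 <- loops_df(10, 50)
  expect_equal(loop_jaccard_loose(A2, B2, tol_bins = 1), 1 / 2)
})

test_that("loose Jaccard is monotone in the tolerance", {
  set.seed(51)
  A <- loops_df(sample(10:200, 25), sample(250:400, 25))
  B <- loops_df(A$bin_i + sample(-3:3, 25, TRUE),
                A$bin_j + sample(-3:3, 25, TRUE))
  jac <- vapply(0:4, function(tol) loop_jaccard_loose(A, B, tol), 1)
  expect_true(all(diff(jac) >= 0))
  expect_equal(jac[1], loop_jaccard(A, B))
  expect_true(all(jac >= 0 & jac <= 1))
})

test_that("anchor-state proportions count category-satisfying loops", {
  ann <- data.frame(chrom = "chr1", bin = 0:9,
                    promoter = rep(c(TRUE, FALSE), 5),
                    enhancer = rep(c(FALSE, TRUE), 5),
                    polycomb = FALSE,
                    heterochromatin = c(rep(FALSE, 8), TRUE, TRUE))
  loops_pe <- loops_df(c(0, 2), c(1, 3))   # promoter x enhancer
  pr <- anchor_state_proportions(loops_pe, ann)
  expect_equal(unname(pr["promoter-enhancer"]), 1.0)
  # unannotated anchors contribute nothing
  none <- anchor_state_proportions(loops_df(100, 200), ann)
  expect_true(all(none == 0))
  # 1 of 4 loops heterochromatin on both anchors
  mix <- loops_df(c(8, 0, 2, 4), c(9, 1, 3, 5))
  expect_equal(unname(anchor_state_proportions(mix, ann)[
    "heterochromatin-heterochromatin"]), 0.25)
})

test_that("convergence fraction reads motif strands in anchor bins", {
  pk <- peaks_at(c(52500, 252500), strands = c("+", "-"))
  conv <- loops_df(10, 50)
  expect_equal(convergence_fraction(conv, pk), 1.0)
  pk_swapped <- peaks_at(c(52500, 252500), strands = c("-", "+"))
  expect_equal(convergence_fraction(conv, pk_swapped), 0.0)
  # an upstream bin holding both strands still counts as convergent
  pk_both <- peaks_at(c(52400, 52600, 252500), strands = c("+", "-", "-"))
  expect_equal(convergence_fraction(conv, pk_both), 1.0)
  expect_equal(convergence_fraction(conv[0, ], pk), 0)
})

test_that("replicate consensus keeps loops seen in at least k sets", {
  r1 <- loops_df(c(10, 20, 30), c(50, 60, 70))
  r2 <- loops_df(c(10, 20), c(50, 60))
  r3 <- loops_df(c(10, 99), c(50, 120))
  cons <- consensus_loops(list(r1, r2, r3), k = 2)
  expect_equal(cons$bin_i, c(10, 20))
  cons3 <- consensus_loops(list(r1, r2, r3), k = 3)
  expect_equal(cons3$bin_i, 10)
})
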