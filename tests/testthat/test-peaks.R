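test_that("replicate intersection keeps only peaks present everywhere", {
  a <- peaks_at(c(1000, 5000, 9000))
  expect_equal(common_peaks(list(a, a, a)), a)          # idempotence
  b <- peaks_at(c(20000, 30000))
  expect_equal(nrow(common_peaks(list(a, b))), 0)       # disjoint
  # peak at 1000 overlaps in only 2 of 3 replicates -> excluded
  r2 <- peaks_at(c(1000, 5000))
  r3 <- peaks_at(c(5000, 9000))
  kept <- common_peaks(list(a, r2, r3))
  expect_equal(kept$start, peaks_at(5000)$start)
  expect_warning(common_peaks(list(a, a[0, ])), "empty")
})

test_that("motif-strand annotation applies the strict p cutoff and tie-break", {
  pk <- peaks_at(c(1000, 5000, 9000))
  motifs <- data.frame(
    chrom = "chr1",
    start = c(990, 4990, 8970, 9010),
    end = c(1010, 5010, 8990, 9030),
    strand = c("+", "-", "+", "-"),
    p = c(0.01, 0.05, 0.001, 0.02))
  out <- annotate_strand(pk, motifs)
  # p = 0.05 is dropped (strict <); multi-motif peak takes the lowest p
  expect_equal(nrow(out), 2)
  expect_equal(out$strand, c("+", "+"))
})

test_that("isolation keeps peaks with no neighbor strictly within the window", {
  pk <- peaks_at(c(100000, 140000, 300000))
  iso <- isolated_peaks(pk)
  expect_equal((iso$start + iso$end) / 2, 300000)
  expect_equal(nrow(isolated_peaks(peaks_at(5000))), 1)
  # centers exactly 50 kb apart are both kept
  pair <- peaks_at(c(100000, 150000))
  expect_equal(nrow(isolated_peaks(pair)), 2)
})

test_that("pair enumeration respects the separation band and orientations", {
  pk <- peaks_at(c(100000, 700000), strands = c("+", "-"))
  pr <- enumerate_pairs(pk)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$separation, 600000)
  expect_equal(pr$orientation, "convergent")

  expect_equal(nrow(enumerate_pairs(peaks_at(c(100000, 130000)))), 0)

  pk4 <- peaks_at(c(0.1e6, 0.6e6, 1.2e6, 2.5e6))
  pr4 <- enumerate_pairs(pk4)
  got <- paste(pr4$up_center / 1e6, pr4$down_center / 1e6)
  expect_setequal(got, c("0.1 0.6", "0.1 1.2", "0.6 1.2", "1.2 2.5"))
})

test_that("pair enumeration matches a brute-force oracle on random peaks", {
  set.seed(77)
  for (rep in 1:3) {
    centers <- sort(sample(seq(0, 5e6, by = 1000), 80))
    centers <- centers[c(TRUE, diff(centers) > 0)]
    pk <- peaks_at(centers, strands = sample(c("+", "-"), length(centers),
                                             replace = TRUE))
    pr <- enumerate_pairs(pk)
    # O(n^2) oracle
    brute <- 0L
    conv <- div <- par <- 0L
    for (i in seq_along(centers)) for (j in seq_along(centers)) {
      if (j <= i) next
      d <- centers[j] - centers[i]
      if (d >= 45000 && d <= 1500000) {
        brute <- brute + 1L
        s <- paste0(pk$strand[i], pk$strand[j])
        if (s == "+-") conv <- conv + 1L
        else if (s == "-+") div <- div + 1L
        else par <- par + 1L
      }
    }
    expect_equal(nrow(pr), brute)
    tab <- table(factor(pr$orientation,
                        c("convergent", "divergent", "parallel")))
    expect_equal(unname(as.integer(tab)), c(conv, div, par))
    expect_equal(sum(tab), nrow(pr))  # orientations partition all pairs
  }
})

test_that("overlap fraction counts anchors overlapping the other set", {
  a <- peaks_at(c(1000, 5000, 9000, 13000))
  expect_equal(overlap_fraction(a, a), 1.0)
  expect_equal(overlap_fraction(a, peaks_at(1e6)), 0.0)
  expect_equal(overlap_fraction(a, peaks_at(1050)), 0.25)
  expect_error(overlap_fraction(a[0, ], a), "empty")
})
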