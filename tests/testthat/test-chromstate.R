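test_that("the 15-state merge follows the four-class table", {
  tr <- data.frame(chrom = "chr1",
                   start = c(0, 100, 200, 300),
                   end = c(100, 200, 300, 400),
                   state = c("Active TSS", "Quiescent/Low", "ZNF/Rpts",
                             "Enhancers"))
  m <- merge_states(tr)
  expect_equal(m$state, c("promoter", "heterochromatin", "enhancer"))
  expect_equal(m$start, c(0, 100, 300))  # ZNF/repeats dropped
  expect_error(merge_states(data.frame(chrom = "c", start = 0, end = 1,
                                       state = "Nonsense")), "unknown")
  # mnemonics work too
  expect_equal(merge_states(data.frame(chrom = "c", start = 0, end = 1,
                                       state = "TssBiv"))$state, "promoter")
})

test_that("bin annotation uses the strict >50 bp overlap rule", {
  mk <- function(start, end, state = "Active TSS")
    merge_states(data.frame(chrom = "chr1", start = start, end = end,
                            state = state))
  # 51 bp inside bin 1 -> assigned
  a51 <- annotate_bins(mk(5000, 5051), chrom_length = 15000)
  expect_true(a51$promoter[a51$bin == 1])
  # exactly 50 bp -> not assigned
  a50 <- annotate_bins(mk(5000, 5050), chrom_length = 15000)
  expect_false(a50$promoter[a50$bin == 1])
  # two classes exceeding the threshold in one bin -> both set
  tr <- merge_states(data.frame(
    chrom = "chr1", start = c(5000, 5300), end = c(5200, 5500),
    state = c("Active TSS", "Enhancers")))
  ab <- annotate_bins(tr, chrom_length = 15000)
  expect_true(ab$promoter[ab$bin == 1] && ab$enhancer[ab$bin == 1])
})

test_that("bin annotation equals a base-pair tally oracle on random tracks", {
  set.seed(21)
  classes <- c("Active TSS", "Enhancers", "Repressed PolyComb",
               "Quiescent/Low")
  starts <- sort(sample(0:19500, 30))
  widths <- sample(20:4000, 30, replace = TRUE)
  tr <- data.frame(chrom = "chr1", start = starts,
                   end = pmin(starts + widths, 20000),
                   state = sample(classes, 30, replace = TRUE))
  m4 <- merge_states(tr)
  ann <- annotate_bins(m4, resolution = 5000, chrom_length = 20000)
  # oracle: per-bp class occupancy via explicit vectors
  for (cls in c("promoter", "enhancer", "polycomb", "heterochromatin")) {
    cov <- logical(20000)
    for (r in which(m4$state == cls)) {
      cov[(m4$start[r] + 1):m4$end[r]] <- TRUE
    }
    for (b in 0:3) {
      expect_identical(ann[[cls]][ann$bin == b],
                       sum(cov[(b * 5000 + 1):((b + 1) * 5000)]) > 50)
    }
  }
})

test_that("pair categories apply all rules symmetrically and non-exclusively", {
  a <- function(p = FALSE, e = FALSE, pc = FALSE, h = FALSE)
    list(promoter = p, enhancer = e, polycomb = pc, heterochromatin = h)
  expect_equal(categorize_pair(a(p = TRUE), a(e = TRUE)), "promoter-enhancer")
  expect_equal(categorize_pair(a(h = TRUE), a(h = TRUE)),
               "heterochromatin-heterochromatin")
  expect_setequal(categorize_pair(a(p = TRUE, h = TRUE), a(e = TRUE)),
                  c("promoter-enhancer", "not-expected"))
  expect_equal(categorize_pair(a(pc = TRUE), a(pc = TRUE)),
               "polycomb-polycomb")
  expect_setequal(categorize_pair(a(p = TRUE), a(pc = TRUE)),
                  "promoter-polycomb")
  expect_length(categorize_pair(a(), a(e = TRUE)), 0)
  # symmetry on random annotations
  set.seed(31)
  for (k in 1:20) {
    x <- a(runif(1) < 0.5, runif(1) < 0.5, runif(1) < 0.5, runif(1) < 0.5)
    y <- a(runif(1) < 0.5, runif(1) < 0.5, runif(1) < 0.5, runif(1) < 0.5)
    expect_setequal(categorize_pair(x, y), categorize_pair(y, x))
  }
})

test_that("enrichment flags composition shifts and stays quiet on null data", {
  set.seed(41)
  n <- 400
  cluster <- rep(1:4, each = 100)
  conv <- c(rep(TRUE, 100), sample(c(TRUE, FALSE), 300, replace = TRUE))
  div <- c(rep(FALSE, 100), !conv[101:400])
  sepn <- ifelse(cluster == 2, 600000, sample(seq(50e3, 1.5e6, 5e3), n, TRUE))
  tab <- cluster_enrichment(
    data.frame(convergent = conv, divergent = div, separation = sepn),
    cluster)
  c1conv <- tab[tab$cluster == 1 & tab$feature == "convergent", ]
  expect_equal(c1conv$value, 1)
  expect_lt(c1conv$p, 0.05)
  expect_equal(c1conv$direction, "enriched")
  c1div <- tab[tab$cluster == 1 & tab$feature == "divergent", ]
  expect_equal(c1div$direction, "depleted")
  expect_lt(c1div$p, 0.05)
  expect_equal(tab[tab$cluster == 2 & tab$feature == "separation", "value"],
               600000)

  # clusters drawn from the global distribution show only chance-level
  # significance across many contrasts
  nn <- 800
  ncl <- sample(rep(1:8, each = 100))
  null_feat <- data.frame(flag = sample(c(TRUE, FALSE), nn, replace = TRUE),
                          separation = sample(seq(5e4, 1.5e6, 5e3), nn, TRUE))
  null_tab <- cluster_enrichment(null_feat, ncl)
  expect_lte(mean(null_tab$p < 0.05),
             0.05 + 2 * sqrt(0.05 * 0.95 / nrow(null_tab)))
  expect_gt(min(null_tab$p), 1e-4)

  tiny <- cluster_enrichment(data.frame(flag = c(TRUE, FALSE, TRUE)),
                             c(1, 2, 2))
  expect_true(is.na(tiny$p[tiny$cluster == 1]))
})
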