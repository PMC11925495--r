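named_dgc <- function(m, cells, genes) {
  m <- Matrix::Matrix(m, sparse = TRUE)
  dimnames(m) <- list(cells, genes)
  m
}

test_that("transcript metrics match hand arithmetic on a small fixture", {
  pred <- named_dgc(rbind(c(3, 1), c(0, 2)), c("a", "b"), c("g1", "g2"))
  truth <- named_dgc(rbind(c(2, 2), c(1, 2)), c("a", "b"), c("g1", "g2"))
  # per-pair min: (2, 1, 0, 2) -> tp 5; pred total 6 -> fp 1;
  # truth total 7 -> fn 2
  m <- transcriptAssignmentMetrics(pred, truth)
  expect_equal(m$tp, 5)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 2)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 5 / 7)
  expect_equal(m$f1, 2 * (5 / 6) * (5 / 7) / (5 / 6 + 5 / 7))
})

test_that("fractional predictions score by mass overlap", {
  pred <- named_dgc(rbind(c(1.5, 0.5)), "a", c("g1", "g2"))
  truth <- named_dgc(rbind(c(1, 1)), "a", c("g1", "g2"))
  m <- transcriptAssignmentMetrics(pred, truth)
  expect_equal(m$tp, 1.5)   # min(1.5,1) + min(0.5,1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
})

test_that("cell and gene universes are outer-aligned with zeros", {
  pred <- named_dgc(rbind(c(2)), "a", "g1")
  truth <- named_dgc(rbind(c(2, 1), c(3, 0)), c("a", "b"), c("g1", "g2"))
  m <- transcriptAssignmentMetrics(pred, truth)
  expect_equal(m$tp, 2)
  expect_equal(m$fn, 4)    # b's 3 on g1 plus a's 1 on g2
  expect_equal(m$fp, 0)
  expect_error(
    transcriptAssignmentMetrics(named_dgc(rbind(2), "zzz", "g1"), truth),
    "share no cell IDs"
  )
})

test_that("per-cell pooling averages over cells with any mass", {
  pred <- named_dgc(rbind(c(4, 0), c(0, 0)), c("a", "b"), c("g1", "g2"))
  truth <- named_dgc(rbind(c(2, 0), c(0, 2)), c("a", "b"), c("g1", "g2"))
  m <- transcriptAssignmentMetrics(pred, truth, pooling = "per_cell")
  # cell a: prec 0.5, rec 1; cell b: prec 0 (no pred), rec 0
  expect_equal(m$precision, 0.25)
  expect_equal(m$recall, 0.5)
  g <- transcriptAssignmentMetrics(pred, truth, pooling = "global")
  expect_equal(g$precision, 0.5)
  expect_equal(g$recall, 0.5)
})

test_that("empty overlap cases define 0/0 ratios as zero", {
  prf <- BinToCell:::.prf
  z <- prf(0, 0, 0)
  expect_equal(unlist(z), c(precision = 0, recall = 0, f1 = 0))
})

test_that("annotation metrics reproduce a hand 2x2 contingency table", {
  truth <- c(c1 = "a", c2 = "a", c3 = "b", c4 = "b")
  pred <- c(c1 = "a", c2 = "b", c3 = "b", c4 = "b")
  m <- annotationMetrics(pred, truth)
  expect_equal(m$accuracy, 3 / 4)
  expect_equal(unname(m$confusion), rbind(c(1, 1), c(0, 2)))
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == "a"], 1)
  expect_equal(pc$recall[pc$class == "a"], 0.5)
  expect_equal(pc$f1[pc$class == "a"], 2 / 3)
  expect_equal(pc$precision[pc$class == "b"], 2 / 3)
  expect_equal(pc$recall[pc$class == "b"], 1)
  expect_equal(pc$f1[pc$class == "b"], 0.8)
  expect_equal(m$weighted$precision, (1 + 2 / 3) / 2)
  expect_equal(m$weighted$recall, 0.75)
  expect_equal(m$weighted$f1, (2 / 3 + 0.8) / 2)
  # names are aligned before comparison
  m2 <- annotationMetrics(pred[c(3, 1, 4, 2)], truth)
  expect_equal(m2$accuracy, m$accuracy)
})

test_that("overlap statistics count unique, shared and orphan bins", {
  fx <- hand_fixture()
  st <- overlapStatistics(fx$overlaps, fx$grid)
  expect_equal(st$n_bins_total, 4L)
  expect_equal(st$n_bins_overlapping, 4L)
  expect_equal(st$n_bins_shared, 2L)
  expect_equal(st$shared_fraction, 0.5)
  expect_equal(st$bins_per_cell[c("A", "B")], c(A = 3L, B = 3L))
  empty <- OverlapTable(
    data.frame(bin_id = character(), cell_id = character(),
               area = numeric()), binArea = 4
  )
  expect_equal(overlapStatistics(empty, fx$grid)$shared_fraction, 0)
})
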