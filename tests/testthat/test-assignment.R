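# Expected values below are hand arithmetic on the fixture in
# helper-oracles.R:
#   counts: b00 = (g1 5), b01 = (g1 4, g2 2), b10 = (g2 2), b11 = (g2 2)
#   overlaps: b00 -> A (4); b01 -> A (3), B (1); b10 -> B (4);
#             b11 -> A (2), B (2)
# so unique bins are b00 (A) and b10 (B); b01 and b11 are shared.

as_named <- function(m) {
  out <- as.matrix(cellCounts(m))
  out[order(rownames(out)), , drop = FALSE]
}

test_that("naive assignment keeps unique bins only", {
  fx <- hand_fixture()
  m <- assignNaive(fx$grid, fx$overlaps, fx$cells)
  expect_equal(as_named(m),
               rbind(A = c(g1 = 5, g2 = 0), B = c(g1 = 0, g2 = 2)))
  expect_equal(sum(cellCounts(m)), 7)      # the unique-bin total, exactly
  expect_equal(unname(nBinsPerCell(m)), c(1L, 1L))
  expect_equal(assignmentStrategy(m), "naive")
})

test_that("area weighting splits shared bins by intersection area", {
  fx <- hand_fixture()
  m <- assignWeightByArea(fx$grid, fx$overlaps, fx$cells)
  # b01: A 3/4, B 1/4; b11: A 1/2, B 1/2
  expect_equal(as_named(m),
               rbind(A = c(g1 = 8, g2 = 2.5), B = c(g1 = 1, g2 = 3.5)))
  expect_equal(sum(cellCounts(m)), 15)     # all overlapping-bin counts
  expect_equal(unname(nBinsPerCell(m)), c(3L, 3L))
})

test_that("gene weighting follows unique-bin profiles, with area fallback", {
  fx <- hand_fixture()
  # pseudocount 0: profiles A = (5, 0), B = (0, 2) decide every gene
  m0 <- assignWeightByGene(fx$grid, fx$overlaps, fx$cells, pseudocount = 0)
  expect_equal(as_named(m0),
               rbind(A = c(g1 = 9, g2 = 0), B = c(g1 = 0, g2 = 6)))
  # pseudocount 1: weights g1 = (6, 1), g2 = (1, 3)
  m1 <- assignWeightByGene(fx$grid, fx$overlaps, fx$cells, pseudocount = 1)
  expect_equal(as_named(m1),
               rbind(A = c(g1 = 5 + 24 / 7, g2 = 1),
                     B = c(g1 = 4 / 7, g2 = 5)))
  expect_equal(sum(cellCounts(m1)), 15)
})

test_that("all-zero profiles for a gene fall back to area weights", {
  fx <- hand_fixture()
  # remove B's unique bin so both profiles are zero on g2
  rec <- overlapRecords(fx$overlaps)
  rec <- rec[rec$bin_id != "b10", ]
  ot <- OverlapTable(rec, binArea = 4)
  grid <- fx$grid[binIDs(fx$grid) != "b10"]
  m <- assignWeightByGene(grid, ot, fx$cells, pseudocount = 0)
  # g2 ties at profile 0 for both cells -> area split:
  # b01 g2: A 1.5, B 0.5; b11 g2: A 1, B 1
  expect_equal(as_named(m),
               rbind(A = c(g1 = 9, g2 = 2.5), B = c(g1 = 0, g2 = 1.5)))
})

test_that("cluster weighting with one cluster reduces to area weighting", {
  fx <- hand_fixture()
  # a single cluster gives both cells the same reference profile, so every
  # gene ties and the split falls back to area weights
  m <- assignWeightByCluster(fx$grid, fx$overlaps, fx$cells, nClusters = 1L)
  a <- assignWeightByArea(fx$grid, fx$overlaps, fx$cells)
  expect_equal(as_named(m), as_named(a))
  expect_error(
    assignWeightByCluster(fx$grid, fx$overlaps, fx$cells, nClusters = 3L),
    "n_clusters"
  )
})

test_that("integer apportionment conserves each bin's counts exactly", {
  fx <- hand_fixture()
  m <- assignWeightByArea(fx$grid, fx$overlaps, fx$cells,
                          keepFractional = FALSE)
  vals <- as_named(m)
  expect_true(all(vals == round(vals)))
  expect_equal(sum(vals), 15)
  # largest remainder on b01 g2 (shares 1.5/0.5) gives the extra unit to A
  expect_equal(vals,
               rbind(A = c(g1 = 8, g2 = 3), B = c(g1 = 1, g2 = 3)))
})

test_that("largest-remainder apportionment is exact and deterministic", {
  lr <- BinToCell:::.largest_remainder
  expect_equal(lr(10, c(0.5, 0.3, 0.2)), c(5, 3, 2))
  expect_equal(sum(lr(7, c(1, 1, 1) / 3)), 7)
  expect_equal(lr(1, c(0.5, 0.5)), c(1, 0))   # tie broken by order
  expect_equal(lr(0, c(0.7, 0.3)), c(0, 0))
})

test_that("strategies are seed-stable and leave the RNG state alone", {
  fx <- hand_fixture()
  set.seed(123)
  before <- .Random.seed
  m1 <- assignWeightByCluster(fx$grid, fx$overlaps, fx$cells, nClusters = 1L,
                              seed = 5L)
  expect_identical(.Random.seed, before)
  m2 <- assignWeightByCluster(fx$grid, fx$overlaps, fx$cells, nClusters = 1L,
                              seed = 5L)
  expect_identical(as_named(m1), as_named(m2))
})

test_that("assignment validates its inputs", {
  fx <- hand_fixture()
  bad <- OverlapTable(
    data.frame(bin_id = "nope", cell_id = "A", area = 1), binArea = 4
  )
  expect_error(assignBins(fx$grid, bad, fx$cells), "absent from the grid")
  expect_error(
    assignBins(fx$grid, fx$overlaps, fx$cells, strategy = "weight_by_gene",
               pseudocount = -1),
    "pseudocount"
  )
})

test_that("cells without overlapping bins are kept as zero rows", {
  fx <- hand_fixture()
  cells3 <- CellOutlines(
    c(polygons(fx$cells), list(cbind(c(50, 52, 52, 50), c(50, 50, 52, 52)))),
    cellIDs = c("A", "B", "C")
  )
  m <- assignWeightByArea(fx$grid, fx$overlaps, cells3)
  expect_equal(unname(as.matrix(cellCounts(m))["C", ]), c(0, 0))
  expect_equal(unname(nBinsPerCell(m)[3L]), 0L)
})
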