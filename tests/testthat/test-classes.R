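make_grid <- function() {
  BinGrid(
    counts = Matrix::sparseMatrix(i = 1:3, j = c(1L, 2L, 2L), x = c(2, 1, 4),
                                  dims = c(3L, 2L)),
    binRow = c(0L, 0L, 1L), binCol = c(0L, 1L, 0L),
    binSize = 2, nRows = 2L, nCols = 2L, geneNames = c("g1", "g2")
  )
}

test_that("BinGrid accessors and subsetting behave", {
  g <- make_grid()
  expect_equal(nBins(g), 3L)
  expect_equal(binSize(g), 2)
  expect_equal(gridOrigin(g), c(0, 0))
  expect_equal(totalCounts(g), 7)
  expect_equal(geneNames(g), c("g1", "g2"))
  sub <- g[1:2]
  expect_equal(nBins(sub), 2L)
  expect_equal(binIDs(sub), binIDs(g)[1:2])
  b <- binBounds(g)
  expect_equal(b$xmax - b$xmin, rep(2, 3))
  polys <- buildBinPolygons(g)
  expect_equal(BinToCell:::.poly_area(polys[[1]]), 4)
  expect_output(show(g), "BinGrid")
})

test_that("BinGrid validity rejects malformed input", {
  expect_error(BinGrid(
    counts = Matrix::sparseMatrix(i = 1:2, j = c(1L, 1L), x = c(1, -1),
                                  dims = c(2L, 1L)),
    binRow = c(0L, 0L), binCol = c(0L, 1L),
    nRows = 1L, nCols = 2L, geneNames = "g"
  ), "non-negative")
  expect_error(BinGrid(
    counts = Matrix::sparseMatrix(i = 1:2, j = c(1L, 1L), x = c(1, 1),
                                  dims = c(2L, 1L)),
    binRow = c(0L, 0L), binCol = c(0L, 0L),   # duplicate position
    nRows = 1L, nCols = 2L, geneNames = "g"
  ), "duplicate")
})

test_that("CellOutlines computes centroids/areas and validates rings", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  co <- CellOutlines(list(sq, sq + 5), cellIDs = c("a", "b"))
  expect_equal(length(co), 2L)
  expect_equal(areas(co), c(4, 4))
  expect_equal(unname(centroids(co)[1, ]), c(1, 1))
  expect_equal(cellIDs(co[2]), "b")
  expect_output(show(co), "CellOutlines")
  expect_error(CellOutlines(list(sq, sq), cellIDs = c("a", "a")), "duplicate")
  # degenerate (zero-area) polygon is rejected
  expect_error(CellOutlines(list(cbind(c(0, 1, 2), c(0, 0, 0)))))
  # closing vertex repeats are tolerated (cleaned away)
  co2 <- CellOutlines(list(rbind(sq, sq[1, ])), cellIDs = "a")
  expect_equal(nrow(polygons(co2)[[1]]), 4L)
})

test_that("OverlapTable validity enforces record-level bounds", {
  expect_error(OverlapTable(
    data.frame(bin_id = "b", cell_id = "c", area = 5), binArea = 4
  ), "exceeds")
  expect_error(OverlapTable(
    data.frame(bin_id = c("b", "b"), cell_id = c("c", "c"), area = c(1, 1)),
    binArea = 4
  ), "duplicate")
  ot <- OverlapTable(
    data.frame(bin_id = c("b", "b"), cell_id = c("c", "d"), area = c(1, 2)),
    binArea = 4
  )
  expect_equal(length(ot), 2L)
  expect_equal(cellsPerBin(ot)[["b"]], c("c", "d"))
  expect_equal(binsPerCell(ot)[["c"]], "b")
  expect_output(show(ot), "OverlapTable")
})

test_that("CellByGeneMatrix accessors, cellTypes<- and coercion", {
  m <- CellByGeneMatrix(
    values = Matrix::sparseMatrix(i = 1L, j = 1L, x = 2.5, dims = c(2L, 2L)),
    cellIDs = c("a", "b"), geneNames = c("g1", "g2"),
    centroids = rbind(c(0, 0), c(1, 1)), strategy = "weight_by_area",
    nBinsPerCell = c(3L, 0L)
  )
  expect_equal(assignmentStrategy(m), "weight_by_area")
  expect_equal(unname(nBinsPerCell(m)), c(3L, 0L))
  cc <- cellCounts(m)
  expect_equal(rownames(cc), c("a", "b"))
  expect_equal(colnames(cc), c("g1", "g2"))
  expect_true(all(is.na(cellTypes(m))))
  cellTypes(m) <- c("x", "y")
  expect_equal(unname(cellTypes(m)), c("x", "y"))
  expect_output(show(m), "CellByGeneMatrix")
  if (requireNamespace("SingleCellExperiment", quietly = TRUE)) {
    sce <- asSingleCellExperiment(m)
    expect_equal(dim(sce), c(2L, 2L))   # genes x cells
    expect_equal(colnames(sce), c("a", "b"))
  }
})

test_that("CellAnnotation validity and accessors", {
  a <- CellAnnotation(
    cellIDs = c("a", "b"), labels = c("t1", "Unknown"),
    scores = matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("t1", "t2"))),
    confidence = c(1, 0)
  )
  expect_equal(unname(cellLabels(a)), c("t1", "Unknown"))
  expect_equal(unname(confidence(a)), c(1, 0))
  expect_equal(colnames(typeScores(a)), c("t1", "t2"))
  expect_output(show(a), "CellAnnotation")
})
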