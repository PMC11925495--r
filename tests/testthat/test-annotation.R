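make_typed_matrix <- function() {
  # 6 cells, 4 genes; cells 1-3 express g1/g2 (type t1 markers),
  # cells 4-6 express g3/g4 (type t2 markers)
  vals <- rbind(
    c(10, 8, 0, 1), c(12, 9, 1, 0), c(9, 11, 0, 0),
    c(0, 1, 10, 9), c(1, 0, 12, 11), c(0, 0, 9, 12)
  )
  CellByGeneMatrix(
    Matrix::Matrix(vals, sparse = TRUE),
    cellIDs = paste0("c", 1:6), geneNames = paste0("g", 1:4),
    centroids = cbind(1:6, 1:6), strategy = "naive",
    nBinsPerCell = rep(1L, 6)
  )
}

test_that("marker scoring labels clearly separated types correctly", {
  m <- make_typed_matrix()
  markers <- list(t1 = c("g1", "g2"), t2 = c("g3", "g4"))
  ann <- scoreCellTypes(m, markers)
  expect_equal(unname(cellLabels(ann)), rep(c("t1", "t2"), each = 3))
  expect_true(all(confidence(ann) > 0))
  expect_equal(colnames(typeScores(ann)), c("t1", "t2"))
})

test_that("low-count cells and exact ties are labelled Unknown", {
  m <- make_typed_matrix()
  low <- m
  low@values[1, ] <- c(1, 1, 0, 0)   # total 2 < minCounts
  ann <- scoreCellTypes(low, list(t1 = c("g1", "g2"), t2 = c("g3", "g4")),
                        minCounts = 5)
  expect_equal(unname(cellLabels(ann)[1]), "Unknown")
  # identical marker lists force an exact tie for every cell
  tie <- scoreCellTypes(m, list(t1 = c("g1", "g3"), t2 = c("g1", "g3")))
  expect_true(all(cellLabels(tie) == "Unknown"))
  expect_true(all(confidence(tie) == 0))
})

test_that("absent markers are dropped with warnings; all absent is an error", {
  m <- make_typed_matrix()
  expect_warning(
    ann <- scoreCellTypes(m, list(t1 = c("g1", "nope"), t2 = c("g3", "g4"))),
    "absent"
  )
  expect_equal(unname(cellLabels(ann)), rep(c("t1", "t2"), each = 3))
  w <- capture_warnings(
    ann2 <- scoreCellTypes(m, list(t1 = "nope", t2 = c("g3", "g4")))
  )
  expect_true(any(grepl("dropped", w)))
  expect_error(
    suppressWarnings(scoreCellTypes(m, list(t1 = "nope", t2 = "missing"))),
    "no marker"
  )
})

test_that("coarse mapping relabels, defaults, and preserves Unknown", {
  a <- CellAnnotation(
    cellIDs = c("c1", "c2", "c3", "c4"),
    labels = c("t1", "t2", "t9", "Unknown"),
    scores = matrix(0, 4, 2, dimnames = list(NULL, c("t1", "t2"))),
    confidence = rep(0.5, 4)
  )
  out <- mapToCoarseLabels(a, c(t1 = "Epithelial", t2 = "Immune",
                                Unknown = "ShouldNotApply"),
                           default = "Other")
  expect_equal(unname(cellLabels(out)),
               c("Epithelial", "Immune", "Other", "Unknown"))
  expect_equal(confidence(out), confidence(a))
})
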