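test_that("polygon primitives match analytic values", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(BinToCell:::.poly_area(sq), 100)
  expect_equal(BinToCell:::.poly_centroid(sq), c(5, 5))

  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(BinToCell:::.poly_area(tri), 6)
  expect_equal(BinToCell:::.poly_centroid(tri), c(4 / 3, 1))

  # orientation does not affect unsigned area
  expect_equal(BinToCell:::.poly_area(sq[4:1, ]), 100)
})

test_that("rectangle clipping matches analytic intersection areas", {
  sq <- cbind(c(1, 3, 3, 1), c(1, 1, 3, 3))   # [1,3]^2
  # unit overlap with [0,2]^2
  expect_equal(BinToCell:::.rect_clip_area(sq, 0, 0, 2, 2), 1)
  # full containment
  expect_equal(BinToCell:::.rect_clip_area(sq, 0, 0, 5, 5), 4)
  # edge contact only: zero area
  expect_equal(BinToCell:::.rect_clip_area(sq, -2, 1, 1, 3), 0)
  # disjoint
  expect_equal(BinToCell:::.rect_clip_area(sq, 10, 10, 12, 12), 0)
})

test_that("point-in-polygon handles interior, exterior and concavity", {
  # concave L-shape
  L <- cbind(c(0, 4, 4, 2, 2, 0), c(0, 0, 2, 2, 4, 4))
  got <- BinToCell:::.points_in_polygon(
    c(1, 3, 3, 1, 5), c(1, 1, 3, 3, 5), L
  )
  expect_equal(got, c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("mitre offset of a square grows it by the offset on each side", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  grown <- BinToCell:::.mitre_offset(BinToCell:::.ensure_ccw(sq), 1)
  expect_equal(BinToCell:::.poly_area(grown), 16)   # (2 + 2*1)^2
})

test_that("spatial join equals the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:20) {
    inst <- random_join_instance()
    got <- sort_records(overlapRecords(spatialJoin(inst$grid, inst$cells)))
    want <- sort_records(brute_force_join(inst$grid, inst$cells))
    expect_identical(got$bin_id, want$bin_id)
    expect_identical(got$cell_id, want$cell_id)
    expect_equal(got$area, want$area, tolerance = 1e-9)
  }
})

test_that("bin footprints are half-open: edge contact is not an overlap", {
  grid <- BinGrid(
    counts = Matrix::sparseMatrix(i = 1:2, j = c(1L, 1L), x = c(1, 1),
                                  dims = c(2L, 1L)),
    binRow = c(0L, 0L), binCol = c(0L, 1L),
    binSize = 2, nRows = 1L, nCols = 2L, geneNames = "g"
  )
  # polygon exactly covering bin (0,0): [0,2]^2; touches bin (0,1) along x=2
  cells <- CellOutlines(list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))),
                        cellIDs = "A")
  rec <- overlapRecords(spatialJoin(grid, cells))
  expect_identical(rec$bin_id, binIDs(grid)[1L])
  expect_equal(rec$area, 4)
})

test_that("intersection areas never exceed the bin footprint", {
  set.seed(7)
  inst <- random_join_instance()
  rec <- overlapRecords(spatialJoin(inst$grid, inst$cells))
  expect_true(all(rec$area <= binSize(inst$grid)^2 + 1e-12))
  expect_true(all(rec$area > 0))
})

test_that("expandOutlines dilates outward and distance 0 is the identity", {
  sq <- CellOutlines(list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))), cellIDs = "A")
  same <- expandOutlines(sq, 0)
  expect_equal(polygons(same), polygons(sq))
  grown <- expandOutlines(sq, 1.5)
  expect_equal(unname(areas(grown)), (2 + 2 * 1.5)^2)
  expect_equal(centroids(grown)[1, ], unname(centroids(sq)[1, ]),
               ignore_attr = TRUE)
  expect_error(expandOutlines(sq, -1))
})

test_that("filterOrphanBins drops exactly the non-overlapping bins", {
  withr::local_options(BinToCell.log = "warn")
  set.seed(3)
  inst <- random_join_instance()
  ot <- spatialJoin(inst$grid, inst$cells)
  g2 <- filterOrphanBins(inst$grid, ot)
  keep <- unique(overlapRecords(ot)$bin_id)
  expect_setequal(binIDs(g2), keep)
  expect_equal(totalCounts(g2),
               sum(binCounts(inst$grid)[binIDs(inst$grid) %in% keep, ]))
})
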