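small_cfg <- function(seed = 2L, ...) {
  tissueSimConfig(fieldSize = c(60, 60), nCells = 12, seed = seed, ...)
}

test_that("simulation configs validate their parameters", {
  expect_error(tissueSimConfig(nCells = 0), "nCells")
  expect_error(tissueSimConfig(noiseFraction = 1.2), "noiseFraction")
  expect_error(tissueSimConfig(nGenes = 5, nCellTypes = 3, markersPerType = 5),
               "markersPerType|marker programs")
  expect_error(tissueSimConfig("no_such_preset"))
  # explicit arguments override preset values
  cfg <- tissueSimConfig("dense", nCells = 10, seed = 1L)
  expect_equal(cfg$nCells, 10)
  expect_equal(cfg$fieldSize, c(170, 170))
})

test_that("simulated tissue is internally consistent", {
  gt <- simulateTissue(small_cfg())
  expect_s4_class(gt, "GroundTruthTissue")
  expect_equal(length(gt@cells), 12L)
  p <- gt@points
  intra <- p[!is.na(p$cell_id), ]
  # every intracellular transcript lies inside its own cell polygon
  for (id in unique(intra$cell_id)) {
    pts <- intra[intra$cell_id == id, c("x", "y")]
    poly <- polygons(gt@cells)[[match(id, cellIDs(gt@cells))]]
    expect_true(all(BinToCell:::.points_in_polygon(pts$x, pts$y, poly)))
  }
  # nuclei sit inside their cells and scale by nucleusFraction^2 in area
  expect_equal(areas(gt@nuclei), areas(gt@cells) * 0.6^2)
  # cell types cover all cells and use the declared universe
  expect_setequal(names(gt@cellTypes), cellIDs(gt@cells))
  expect_true(all(gt@cellTypes %in% paste0("type", 1:4)))
  # noise fraction of all points is as configured (binomially noisy)
  expect_lt(abs(mean(is.na(p$cell_id)) - 0.05), 0.02)
})

test_that("simulation is seed-deterministic and seed hygiene holds", {
  set.seed(777)
  before <- .Random.seed
  gt1 <- simulateTissue(small_cfg(seed = 9L))
  expect_identical(.Random.seed, before)
  gt2 <- simulateTissue(small_cfg(seed = 9L))
  expect_identical(gt1@points, gt2@points)
  gt3 <- simulateTissue(small_cfg(seed = 10L))
  expect_false(identical(gt1@points, gt3@points))
})

test_that("binning conserves every in-field transcript", {
  gt <- simulateTissue(small_cfg(seed = 3L))
  grid <- binifyTranscripts(gt, binSize = 2)
  p <- gt@points
  infield <- p$x >= 0 & p$x < 60 & p$y >= 0 & p$y < 60
  expect_equal(totalCounts(grid), sum(infield))
  # a transcript at (x, y) falls in bin (floor(y/s), floor(x/s)): check a
  # specific point against the half-open rule
  q <- p[infield, ][1, ]
  b <- grid[grid@binRow == floor(q$y / 2) & grid@binCol == floor(q$x / 2)]
  expect_equal(nBins(b), 1L)
  # gene marginals are preserved too
  gm <- Matrix::colSums(binCounts(grid))
  tab <- table(factor(p$gene[infield], levels = geneNames(grid)))
  expect_equal(unname(gm), as.numeric(tab))
})

test_that("true cell matrices tally transcripts by origin", {
  gt <- simulateTissue(small_cfg(seed = 5L))
  tm <- trueCellMatrix(gt)
  p <- gt@points
  intra <- p[!is.na(p$cell_id), ]
  expect_equal(sum(cellCounts(tm)), nrow(intra))
  one <- cellIDs(tm)[1L]
  expect_equal(sum(cellCounts(tm)[one, ]), sum(intra$cell_id == one))
  # nucleus mode only counts transcripts inside the nucleus outline
  tn <- trueCellMatrix(gt, mode = "nucleus")
  expect_true(sum(cellCounts(tn)) < sum(cellCounts(tm)))
  expect_equal(assignmentStrategy(tm), "truth")
})

test_that("trueMarkerSet reproduces the generator's disjoint programs", {
  cfg <- small_cfg()
  mk <- trueMarkerSet(cfg)
  expect_equal(names(mk), paste0("type", 1:4))
  expect_equal(lengths(mk), setNames(rep(5L, 4), paste0("type", 1:4)))
  expect_equal(anyDuplicated(unlist(mk)), 0L)
  expect_equal(mk$type1, sprintf("gene%03d", 1:5))
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- makeDataset(small_cfg(seed = 6L))
  expect_s4_class(ds, "SyntheticDataset")
  d <- withr::local_tempdir()
  writeSyntheticDataset(ds, d)
  grid <- readVisiumHDCounts(file.path(d, "bins"))
  expect_equal(totalCounts(grid), totalCounts(ds@grid))
  cells <- readCellPolygons(file.path(d, "cells.geojson"))
  expect_equal(polygons(cells), polygons(ds@truth@cells))
  tr <- read.csv(file.path(d, "transcripts.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(ds@truth@points))
  expect_equal(tr$x, ds@truth@points$x)   # %.17g survives the round trip
  types <- read.csv(file.path(d, "cell_types.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(types), length(ds@truth@cells))
})

test_that("infeasible packing is reported, not looped forever", {
  expect_error(
    simulateTissue(tissueSimConfig(fieldSize = c(20, 20), nCells = 50,
                                   minSpacing = 10, seed = 1L)),
    "place|packing|spacing"
  )
})
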