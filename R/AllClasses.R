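#' BinGrid: a regular lattice of square capture bins with sparse counts
#'
#' Represents Visium HD-style data: a regular lattice of `binSize` x
#' `binSize` micrometre capture squares ("bins"), of which a subset is
#' present (in tissue), each carrying a gene-count vector. Bin `(r, c)`
#' occupies the half-open square
#' `[origin_x + c*s, origin_x + (c+1)*s) x [origin_y + r*s, origin_y + (r+1)*s)`
#' in a y-downward micrometre frame, so footprints tile the plane without
#' overlap. Bins are stored in canonical row-major order.
#'
#' @slot origin numeric(2), (x, y) of the lattice corner in micrometres.
#' @slot binSize side length of a bin in micrometres (default 2).
#' @slot nRows,nCols lattice extents (number of rows / columns).
#' @slot binRow,binCol 0-based lattice indices of each present bin.
#' @slot counts sparse non-negative matrix, bins x genes.
#' @slot binIDs unique bin identifiers, parallel to rows of `counts`.
#' @slot geneNames gene symbols, parallel to columns of `counts`.
#' @export
setClass("BinGrid", slots = c(
  origin = "numeric",
  binSize = "numeric",
  nRows = "integer",
  nCols = "integer",
  binRow = "integer",
  binCol = "integer",
  counts = "dgCMatrix",
  binIDs = "character",
  geneNames = "character"
))

setValidity("BinGrid", function(object) {
  msg <- character()
  if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
  if (length(object@binSize) != 1L || object@binSize <= 0) {
    msg <- c(msg, "binSize must be a single positive number")
  }
  nb <- nrow(object@counts)
  if (length(object@binRow) != nb || length(object@binCol) != nb) {
    msg <- c(msg, "binRow/binCol length must equal nrow(counts)")
  }
  if (length(object@binIDs) != nb) msg <- c(msg, "binIDs length must equal nrow(counts)")
  if (anyDuplicated(object@binIDs)) msg <- c(msg, "binIDs must be unique")
  if (length(object@geneNames) != ncol(object@counts)) {
    msg <- c(msg, "geneNames length must equal ncol(counts)")
  }
  if (nb > 0L) {
    if (anyDuplicated(object@binRow * as.double(object@nCols) + object@binCol)) {
      msg <- c(msg, "duplicate (row, col) lattice positions")
    }
    if (min(object@binRow) < 0L || max(object@binRow) >= object@nRows ||
        min(object@binCol) < 0L || max(object@binCol) >= object@nCols) {
      msg <- c(msg, "binRow/binCol outside lattice extents")
    }
  }
  if (length(object@counts@x) && min(object@counts@x) < 0) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' CellOutlines: segmented cells as simple polygons
#'
#' One polygon per segmented cell, with identifier, geometric centroid and
#' area. Vertices are stored counter-clockwise (image frame, y downward)
#' without a repeated closing vertex.
#'
#' @slot cellIDs unique cell identifiers.
#' @slot polygons list of n x 2 vertex matrices (micrometres).
#' @slot centroids n_cells x 2 matrix of polygon centroids.
#' @slot areas polygon areas in square micrometres.
#' @export
setClass("CellOutlines", slots = c(
  cellIDs = "character",
  polygons = "list",
  centroids = "matrix",
  areas = "numeric"
))

setValidity("CellOutlines", function(object) {
  msg <- character()
  n <- length(object@cellIDs)
  if (length(object@polygons) != n) msg <- c(msg, "polygons length != cellIDs length")
  if (length(object@areas) != n) msg <- c(msg, "areas length != cellIDs length")
  if (n > 0L && (nrow(object@centroids) != n || ncol(object@centroids) != 2L)) {
    msg <- c(msg, "centroids must be an n x 2 matrix")
  }
  if (anyDuplicated(object@cellIDs)) {
    dup <- unique(object@cellIDs[duplicated(object@cellIDs)])
    msg <- c(msg, sprintf("duplicate cell IDs: %s", paste(dup, collapse = ", ")))
  }
  if (n > 0L && any(object@areas <= 0)) msg <- c(msg, "all polygon areas must be > 0")
  if (length(msg)) msg else TRUE
})

#' OverlapTable: bin-cell intersection records from the spatial join
#'
#' One record per (bin, cell) pair whose footprints intersect with positive
#' area; edge or point contacts are excluded. `binArea` records the bin
#' footprint area so record-level bounds can be validated.
#'
#' @slot records data.frame with columns `bin_id`, `cell_id`, `area`.
#' @slot binArea area of one bin footprint (binSize^2).
#' @export
setClass("OverlapTable", slots = c(
  records = "data.frame",
  binArea = "numeric"
))

setValidity("OverlapTable", function(object) {
  msg <- character()
  req <- c("bin_id", "cell_id", "area")
  if (!all(req %in% names(object@records))) {
    msg <- c(msg, "records must have columns bin_id, cell_id, area")
  } else {
    a <- object@records$area
    if (length(a) && min(a) <= 0) msg <- c(msg, "all intersection areas must be > 0")
    if (length(a) && max(a) > object@binArea * (1 + 1e-9)) {
      msg <- c(msg, "intersection area exceeds bin footprint area")
    }
    if (anyDuplicated(paste(object@records$bin_id, object@records$cell_id))) {
      msg <- c(msg, "duplicate (bin, cell) records")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CellByGeneMatrix: per-cell transcript estimates
#'
#' The product of bin-to-cell assignment: a cells x genes matrix of
#' transcript estimates (integer-valued under the naive strategy, fractional
#' under the weighted ones), with per-cell centroids, the strategy that
#' produced it, and the number of bins that contributed to each cell. Cells
#' with zero contributing bins are retained as all-zero rows.
#'
#' @slot values sparse non-negative matrix, cells x genes.
#' @slot cellIDs,geneNames dimension identifiers.
#' @slot centroids n_cells x 2 matrix of cell centroids (micrometres).
#' @slot strategy one of `naive`, `weight_by_area`, `weight_by_gene`,
#'   `weight_by_cluster`, or `truth` for ground-truth tallies.
#' @slot nBinsPerCell number of distinct bins contributing to each cell.
#' @slot cellTypes per-cell labels (`NA` when unannotated).
#' @export
setClass("CellByGeneMatrix", slots = c(
  values = "dgCMatrix",
  cellIDs = "character",
  geneNames = "character",
  centroids = "matrix",
  strategy = "character",
  nBinsPerCell = "integer",
  cellTypes = "character"
))

setValidity("CellByGeneMatrix", function(object) {
  msg <- character()
  nc <- nrow(object@values)
  if (length(object@cellIDs) != nc) msg <- c(msg, "cellIDs length != nrow(values)")
  if (anyDuplicated(object@cellIDs)) msg <- c(msg, "cellIDs must be unique")
  if (length(object@geneNames) != ncol(object@values)) {
    msg <- c(msg, "geneNames length != ncol(values)")
  }
  if (nc > 0L && (nrow(object@centroids) != nc || ncol(object@centroids) != 2L)) {
    msg <- c(msg, "centroids must be n_cells x 2")
  }
  if (length(object@nBinsPerCell) != nc) msg <- c(msg, "nBinsPerCell length != n cells")
  if (length(object@cellTypes) != nc) msg <- c(msg, "cellTypes length != n cells")
  if (length(object@values@x) && min(object@values@x) < 0) {
    msg <- c(msg, "values must be non-negative")
  }
  if (length(object@strategy) != 1L) msg <- c(msg, "strategy must be a single string")
  if (length(msg)) msg else TRUE
})

#' CellAnnotation: marker-score cell-type calls
#'
#' @slot cellIDs cell identifiers.
#' @slot labels per-cell type label (`"Unknown"` for low-count or tied cells).
#' @slot scores cells x types matrix of marker scores.
#' @slot confidence top score minus runner-up, per cell.
#' @export
setClass("CellAnnotation", slots = c(
  cellIDs = "character",
  labels = "character",
  scores = "matrix",
  confidence = "numeric"
))

setValidity("CellAnnotation", function(object) {
  msg <- character()
  n <- length(object@cellIDs)
  if (length(object@labels) != n) msg <- c(msg, "labels length != cellIDs length")
  if (n > 0L && nrow(object@scores) != n) msg <- c(msg, "scores rows != n cells")
  if (length(object@confidence) != n) msg <- c(msg, "confidence length != n cells")
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  valid_labels <- c(colnames(object@scores), "Unknown")
  if (n > 0L && !all(object@labels %in% valid_labels)) {
    # after coarse mapping labels live in a different universe; allow any
    # non-NA label but never NA
    if (anyNA(object@labels)) msg <- c(msg, "labels must not be NA")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruthTissue: simulated transcripts with known cell of origin
#'
#' The evaluation reference produced by [simulateTissue()]: transcript
#' points with their true cell of origin (`NA` for extracellular noise),
#' whole-cell and nucleus outlines, and true cell types.
#'
#' @slot points data.frame with columns `x`, `y`, `gene`, `cell_id`.
#' @slot cells,nuclei [CellOutlines] for whole cells and nuclei.
#' @slot cellTypes named character, true type per cell ID.
#' @slot geneNames the full gene universe.
#' @slot fieldSize numeric(2), tissue field extent (micrometres).
#' @export
setClass("GroundTruthTissue", slots = c(
  points = "data.frame",
  cells = "CellOutlines",
  nuclei = "CellOutlines",
  cellTypes = "character",
  geneNames = "character",
  fieldSize = "numeric"
))

setValidity("GroundTruthTissue", function(object) {
  msg <- character()
  req <- c("x", "y", "gene", "cell_id")
  if (!all(req %in% names(object@points))) {
    msg <- c(msg, "points must have columns x, y, gene, cell_id")
  }
  if (length(object@cells) != length(object@nuclei)) {
    msg <- c(msg, "cells and nuclei must have matching lengths")
  }
  if (!all(names(object@cellTypes) %in% object@cells@cellIDs)) {
    msg <- c(msg, "cellTypes names must be cell IDs")
  }
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0)) {
    msg <- c(msg, "fieldSize must be two positive extents")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: a degraded observation paired with its ground truth
#'
#' @slot grid the [BinGrid] observation after binning transcripts.
#' @slot truth the [GroundTruthTissue-class] that generated it.
#' @slot config echo of the [tissueSimConfig()] used.
#' @export
setClass("SyntheticDataset", slots = c(
  grid = "BinGrid",
  truth = "GroundTruthTissue",
  config = "list"
))

setValidity("SyntheticDataset", function(object) {
  fs <- object@truth@fieldSize
  p <- object@truth@points
  in_field <- sum(p$x >= 0 & p$x < fs[1L] & p$y >= 0 & p$y < fs[2L])
  if (abs(sum(object@grid@counts) - in_field) > 1e-9) {
    return("grid total counts must equal the number of in-field transcript points")
  }
  TRUE
})
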