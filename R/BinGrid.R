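#' Construct a BinGrid
#'
#' @param counts bins x genes matrix (coerced to sparse). Rows must be
#'   parallel to `binRow`/`binCol`.
#' @param binRow,binCol 0-based lattice indices of each bin.
#' @param binSize bin side length in micrometres.
#' @param origin (x, y) of the lattice corner in micrometres.
#' @param binIDs bin identifiers; defaults to `"r<row>_c<col>"`.
#' @param geneNames gene symbols; defaults to `colnames(counts)`.
#' @param nRows,nCols lattice extents; default to the maximal index + 1.
#'
#' @details Bins are reordered into canonical row-major order (by row, then
#'   column) regardless of input order.
#' @return A [BinGrid-class] object.
#' @export
BinGrid <- function(counts, binRow, binCol, binSize = 2, origin = c(0, 0),
                    binIDs = NULL, geneNames = NULL,
                    nRows = NULL, nCols = NULL) {
  counts <- .as_dgc(counts)
  binRow <- as.integer(binRow)
  binCol <- as.integer(binCol)
  if (is.null(geneNames)) {
    geneNames <- colnames(counts)
    if (is.null(geneNames)) geneNames <- paste0("gene", seq_len(ncol(counts)))
  }
  if (is.null(binIDs)) binIDs <- sprintf("r%d_c%d", binRow, binCol)
  if (is.null(nRows)) nRows <- if (length(binRow)) max(binRow) + 1L else 0L
  if (is.null(nCols)) nCols <- if (length(binCol)) max(binCol) + 1L else 0L
  ord <- order(binRow, binCol)
  counts <- counts[ord, , drop = FALSE]
  dimnames(counts) <- NULL
  methods::new("BinGrid",
    origin = as.numeric(origin), binSize = as.numeric(binSize),
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    binRow = binRow[ord], binCol = binCol[ord],
    counts = counts, binIDs = as.character(binIDs)[ord],
    geneNames = as.character(geneNames)
  )
}

#' @rdname BinGrid-class
#' @aliases binSize gridOrigin binCounts binIDs geneNames nBins totalCounts
#' @export
setMethod("binSize", "BinGrid", function(x) x@binSize)

#' @rdname BinGrid-class
#' @export
setMethod("gridOrigin", "BinGrid", function(x) x@origin)

#' @rdname BinGrid-class
#' @export
setMethod("binCounts", "BinGrid", function(x) {
  m <- x@counts
  dimnames(m) <- list(x@binIDs, x@geneNames)
  m
})

#' @rdname BinGrid-class
#' @export
setMethod("binIDs", "BinGrid", function(x) x@binIDs)

#' @rdname BinGrid-class
#' @export
setMethod("geneNames", "BinGrid", function(x) x@geneNames)

#' @rdname BinGrid-class
#' @export
setMethod("nBins", "BinGrid", function(x) nrow(x@counts))

#' @rdname BinGrid-class
#' @export
setMethod("totalCounts", "BinGrid", function(x) sum(x@counts))

#' Subset a BinGrid by bin index
#'
#' @param x a [BinGrid-class].
#' @param i integer or logical index over present bins.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BinGrid", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x,
    binRow = x@binRow[i], binCol = x@binCol[i],
    counts = x@counts[i, , drop = FALSE],
    binIDs = x@binIDs[i]
  )
})

#' Bin footprint bounds
#'
#' Returns the axis-aligned bounds of every present bin's half-open square
#' footprint, in the grid's micrometre frame.
#'
#' @param grid a [BinGrid-class].
#' @return data.frame with columns `bin_id`, `row`, `col`, `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @export
binBounds <- function(grid) {
  stopifnot(methods::is(grid, "BinGrid"))
  s <- grid@binSize
  data.frame(
    bin_id = grid@binIDs,
    row = grid@binRow,
    col = grid@binCol,
    xmin = grid@origin[1L] + grid@binCol * s,
    ymin = grid@origin[2L] + grid@binRow * s,
    xmax = grid@origin[1L] + (grid@binCol + 1) * s,
    ymax = grid@origin[2L] + (grid@binRow + 1) * s,
    stringsAsFactors = FALSE
  )
}

#' Bin footprint polygons
#'
#' Materialises every present bin's footprint as a 4 x 2 vertex matrix.
#' Footprints are half-open squares, so adjacent bins share edges but never
#' positive-area overlap.
#'
#' @param grid a [BinGrid-class].
#' @return named list of 4 x 2 matrices, one per bin.
#' @export
buildBinPolygons <- function(grid) {
  b <- binBounds(grid)
  out <- lapply(seq_len(nrow(b)), function(i) {
    cbind(
      c(b$xmin[i], b$xmax[i], b$xmax[i], b$xmin[i]),
      c(b$ymin[i], b$ymin[i], b$ymax[i], b$ymax[i])
    )
  })
  names(out) <- b$bin_id
  out
}

setMethod("show", "BinGrid", function(object) {
  cat(sprintf(
    "BinGrid: %d bins (%.2g um) on a %d x %d lattice, %d genes, %s counts\n",
    nBins(object), object@binSize, object@nRows, object@nCols,
    length(object@geneNames), format(totalCounts(object))
  ))
})
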