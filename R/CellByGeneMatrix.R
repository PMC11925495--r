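#' Construct a CellByGeneMatrix
#'
#' @param values cells x genes matrix (coerced to sparse double).
#' @param cellIDs,geneNames dimension identifiers.
#' @param centroids n_cells x 2 matrix of cell centroids (micrometres).
#' @param strategy assignment strategy that produced the values.
#' @param nBinsPerCell distinct contributing bins per cell (0 when unknown).
#' @param cellTypes optional per-cell labels.
#' @return A [CellByGeneMatrix-class] object.
#' @export
CellByGeneMatrix <- function(values, cellIDs, geneNames, centroids,
                             strategy = "naive",
                             nBinsPerCell = integer(length(cellIDs)),
                             cellTypes = rep(NA_character_, length(cellIDs))) {
  values <- .as_dgc(values)
  dimnames(values) <- NULL
  methods::new("CellByGeneMatrix",
    values = values, cellIDs = as.character(cellIDs),
    geneNames = as.character(geneNames),
    centroids = as.matrix(centroids), strategy = strategy,
    nBinsPerCell = as.integer(nBinsPerCell),
    cellTypes = as.character(cellTypes)
  )
}

#' @rdname CellByGeneMatrix-class
#' @aliases cellCounts assignmentStrategy nBinsPerCell cellTypes cellTypes<-
#' @export
setMethod("cellCounts", "CellByGeneMatrix", function(x) {
  m <- x@values
  dimnames(m) <- list(x@cellIDs, x@geneNames)
  m
})

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("cellIDs", "CellByGeneMatrix", function(x) x@cellIDs)

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("geneNames", "CellByGeneMatrix", function(x) x@geneNames)

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("centroids", "CellByGeneMatrix", function(x) x@centroids)

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("assignmentStrategy", "CellByGeneMatrix", function(x) x@strategy)

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("nBinsPerCell", "CellByGeneMatrix", function(x) {
  setNames(x@nBinsPerCell, x@cellIDs)
})

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("cellTypes", "CellByGeneMatrix", function(x) {
  setNames(x@cellTypes, x@cellIDs)
})

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("cellTypes<-", "CellByGeneMatrix", function(x, value) {
  if (!is.null(names(value))) value <- value[x@cellIDs]
  x@cellTypes <- as.character(value)
  methods::validObject(x)
  x
})

#' @rdname CellByGeneMatrix-class
#' @export
setMethod("length", "CellByGeneMatrix", function(x) length(x@cellIDs))

setMethod("show", "CellByGeneMatrix", function(object) {
  n0 <- sum(object@nBinsPerCell == 0L)
  cat(sprintf(
    "CellByGeneMatrix: %d cells x %d genes (strategy '%s'), total %s%s\n",
    length(object@cellIDs), length(object@geneNames), object@strategy,
    format(sum(object@values)),
    if (n0 > 0L) sprintf("; %d cells with no contributing bins", n0) else ""
  ))
  if (any(!is.na(object@cellTypes))) {
    tt <- sort(table(object@cellTypes), decreasing = TRUE)
    cat("  cell types:", paste(sprintf("%s(%d)", names(tt), tt), collapse = " "), "\n")
  }
})

#' Coerce a CellByGeneMatrix to a SingleCellExperiment
#'
#' Builds a `SingleCellExperiment` with genes as rows and cells as columns
#' (Bioconductor orientation), spatial centroids in `colData` and the
#' assignment strategy in `metadata`. Requires the SingleCellExperiment
#' package.
#'
#' @param x a [CellByGeneMatrix-class].
#' @return A `SingleCellExperiment`.
#' @export
asSingleCellExperiment <- function(x) {
  stopifnot(methods::is(x, "CellByGeneMatrix"))
  if (!requireNamespace("SingleCellExperiment", quietly = TRUE)) {
    .stopf("the SingleCellExperiment package is required for this coercion")
  }
  counts <- Matrix::t(cellCounts(x))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      cell_id = x@cellIDs,
      x = x@centroids[, 1L], y = x@centroids[, 2L],
      n_bins = x@nBinsPerCell, cell_type = x@cellTypes,
      row.names = x@cellIDs
    ),
    metadata = list(assignment_strategy = x@strategy)
  )
}
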