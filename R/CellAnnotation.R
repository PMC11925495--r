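#' Construct a CellAnnotation
#'
#' Usually produced by [scoreCellTypes()].
#'
#' @param cellIDs cell identifiers.
#' @param labels per-cell labels.
#' @param scores cells x types score matrix.
#' @param confidence top score minus runner-up per cell.
#' @return A [CellAnnotation-class] object.
#' @export
CellAnnotation <- function(cellIDs, labels, scores, confidence) {
  methods::new("CellAnnotation",
    cellIDs = as.character(cellIDs), labels = as.character(labels),
    scores = as.matrix(scores), confidence = as.numeric(confidence)
  )
}

#' @rdname CellAnnotation-class
#' @export
setMethod("cellIDs", "CellAnnotation", function(x) x@cellIDs)

#' Per-cell labels of a CellAnnotation
#' @rdname CellAnnotation-class
#' @aliases cellLabels typeScores confidence
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname CellAnnotation-class
#' @export
setMethod("cellLabels", "CellAnnotation", function(x) setNames(x@labels, x@cellIDs))

#' @rdname CellAnnotation-class
#' @export
setMethod("typeScores", "CellAnnotation", function(x) {
  s <- x@scores
  rownames(s) <- x@cellIDs
  s
})

#' @rdname CellAnnotation-class
#' @export
setMethod("confidence", "CellAnnotation", function(x) setNames(x@confidence, x@cellIDs))

#' @rdname CellAnnotation-class
#' @export
setMethod("length", "CellAnnotation", function(x) length(x@cellIDs))

setMethod("show", "CellAnnotation", function(object) {
  tt <- sort(table(object@labels), decreasing = TRUE)
  cat(sprintf("CellAnnotation: %d cells, %d scored types\n",
              length(object@cellIDs), ncol(object@scores)))
  cat("  labels:", paste(sprintf("%s(%d)", names(tt), tt), collapse = " "), "\n")
})
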