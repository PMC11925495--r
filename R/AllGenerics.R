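#' @rdname BinGrid-class
#' @param x,object an object.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname BinGrid-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname BinGrid-class
#' @export
setGeneric("binIDs", function(x) standardGeneric("binIDs"))

#' @rdname BinGrid-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname BinGrid-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname BinGrid-class
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname CellOutlines-class
#' @export
setGeneric("cellIDs", function(x) standardGeneric("cellIDs"))

#' @rdname CellOutlines-class
#' @export
setGeneric("polygons", function(x) standardGeneric("polygons"))

#' @rdname CellOutlines-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname CellOutlines-class
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))

#' @rdname OverlapTable-class
#' @export
setGeneric("overlapRecords", function(x) standardGeneric("overlapRecords"))

#' @rdname CellByGeneMatrix-class
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))

#' @rdname CellByGeneMatrix-class
#' @export
setGeneric("assignmentStrategy", function(x) standardGeneric("assignmentStrategy"))

#' @rdname CellByGeneMatrix-class
#' @export
setGeneric("nBinsPerCell", function(x) standardGeneric("nBinsPerCell"))

#' @rdname CellByGeneMatrix-class
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname CellByGeneMatrix-class
#' @param value replacement value.
#' @export
setGeneric("cellTypes<-", function(x, value) standardGeneric("cellTypes<-"))

#' @rdname CellAnnotation-class
#' @export
setGeneric("typeScores", function(x) standardGeneric("typeScores"))

#' @rdname CellAnnotation-class
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))
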