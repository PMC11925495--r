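#' Construct an OverlapTable
#'
#' Usually produced by [spatialJoin()]; the constructor is exposed for
#' building tables by hand in tests and examples.
#'
#' @param records data.frame with columns `bin_id`, `cell_id`, `area`.
#' @param binArea bin footprint area in square micrometres.
#' @return An [OverlapTable-class] object.
#' @export
OverlapTable <- function(records, binArea) {
  records <- data.frame(
    bin_id = as.character(records$bin_id),
    cell_id = as.character(records$cell_id),
    area = as.numeric(records$area),
    stringsAsFactors = FALSE
  )
  methods::new("OverlapTable", records = records, binArea = as.numeric(binArea))
}

#' @rdname OverlapTable-class
#' @aliases overlapRecords
#' @export
setMethod("overlapRecords", "OverlapTable", function(x) x@records)

#' @rdname OverlapTable-class
#' @export
setMethod("length", "OverlapTable", function(x) nrow(x@records))

#' Per-bin index: cell IDs overlapping each bin
#' @param x an [OverlapTable-class].
#' @return named list, bin ID to character vector of cell IDs.
#' @export
cellsPerBin <- function(x) {
  stopifnot(methods::is(x, "OverlapTable"))
  split(x@records$cell_id, x@records$bin_id)
}

#' Per-cell index: bin IDs overlapping each cell
#' @param x an [OverlapTable-class].
#' @return named list, cell ID to character vector of bin IDs.
#' @export
binsPerCell <- function(x) {
  stopifnot(methods::is(x, "OverlapTable"))
  split(x@records$bin_id, x@records$cell_id)
}

setMethod("show", "OverlapTable", function(object) {
  r <- object@records
  nb <- length(unique(r$bin_id))
  shared <- sum(table(r$bin_id) > 1L)
  cat(sprintf(
    "OverlapTable: %d (bin, cell) records over %d bins and %d cells (%d shared bins)\n",
    nrow(r), nb, length(unique(r$cell_id)), shared
  ))
})
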