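#' Construct CellOutlines
#'
#' Cleans each ring (drops a repeated closing vertex and consecutive
#' duplicates), repairs orientation to counter-clockwise, and computes
#' centroids and areas.
#'
#' @param polygons list of n x 2 vertex matrices (micrometres).
#' @param cellIDs unique identifiers; defaults to `cell_1 ... cell_n`.
#' @param onInvalid what to do with a self-intersecting ring: `"warn"`
#'   (keep, with a warning) or `"error"`.
#' @return A [CellOutlines-class] object.
#' @export
CellOutlines <- function(polygons, cellIDs = NULL,
                         onInvalid = c("warn", "error")) {
  onInvalid <- match.arg(onInvalid)
  if (is.null(cellIDs)) cellIDs <- paste0("cell_", seq_along(polygons))
  cellIDs <- as.character(cellIDs)
  if (anyDuplicated(cellIDs)) {
    dup <- unique(cellIDs[duplicated(cellIDs)])
    .stopf("duplicate cell IDs: %s", paste(dup, collapse = ", "))
  }
  polys <- lapply(polygons, function(p) .ensure_ccw(.clean_ring(p)))
  bad <- vapply(polys, function(p) nrow(p) < 3L || .poly_area(p) <= .AREA_TOL, logical(1L))
  if (any(bad)) {
    .stopf("degenerate polygon(s) with no area: %s",
           paste(cellIDs[bad], collapse = ", "))
  }
  selfx <- vapply(polys, .is_self_intersecting, logical(1L))
  if (any(selfx)) {
    txt <- paste(cellIDs[selfx], collapse = ", ")
    if (onInvalid == "error") .stopf("self-intersecting polygon(s): %s", txt)
    .warnf("self-intersecting polygon(s) kept as-is: %s", txt)
  }
  cent <- t(vapply(polys, .poly_centroid, numeric(2L)))
  ar <- vapply(polys, .poly_area, numeric(1L))
  names(polys) <- cellIDs
  methods::new("CellOutlines",
    cellIDs = cellIDs, polygons = polys,
    centroids = cent, areas = ar
  )
}

#' @rdname CellOutlines-class
#' @aliases cellIDs polygons centroids areas
#' @export
setMethod("cellIDs", "CellOutlines", function(x) x@cellIDs)

#' @rdname CellOutlines-class
#' @export
setMethod("polygons", "CellOutlines", function(x) x@polygons)

#' @rdname CellOutlines-class
#' @export
setMethod("centroids", "CellOutlines", function(x) x@centroids)

#' @rdname CellOutlines-class
#' @export
setMethod("areas", "CellOutlines", function(x) x@areas)

#' @rdname CellOutlines-class
#' @export
setMethod("length", "CellOutlines", function(x) length(x@cellIDs))

#' Subset CellOutlines
#' @param x a [CellOutlines-class].
#' @param i index over cells (integer, logical or cell ID).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CellOutlines", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@cellIDs)
  methods::initialize(x,
    cellIDs = x@cellIDs[i], polygons = x@polygons[i],
    centroids = x@centroids[i, , drop = FALSE], areas = x@areas[i]
  )
})

setMethod("show", "CellOutlines", function(object) {
  n <- length(object)
  cat(sprintf("CellOutlines: %d cells", n))
  if (n > 0L) {
    cat(sprintf(
      ", area %.1f-%.1f um^2 (median %.1f)",
      min(object@areas), max(object@areas), stats::median(object@areas)
    ))
  }
  cat("\n")
})
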