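#' Spatial join of bins and cell outlines
#'
#' Computes, for every (bin, cell) pair whose footprints intersect with
#' positive area, the intersection area in square micrometres. This is the
#' geometric core of bin-to-cell assignment: a bin sitting wholly inside one
#' cell yields a single full-area record, while a bin straddling a cell
#' boundary yields one record per overlapped cell. Pairs touching only along
#' an edge or at a point are excluded (areas below 1e-9 um^2 are treated as
#' zero to suppress repair slivers).
#'
#' The regular lattice is its own spatial index: for each cell, candidate
#' bins are enumerated from the polygon's bounding box by lattice
#' arithmetic, then verified by exact rectangle clipping. The result is
#' identical to brute-force all-pairs intersection.
#'
#' @param grid a [BinGrid-class].
#' @param cells a [CellOutlines-class] in the same micrometre frame.
#' @return An [OverlapTable-class].
#' @export
spatialJoin <- function(grid, cells) {
  stopifnot(methods::is(grid, "BinGrid"), methods::is(cells, "CellOutlines"))
  s <- grid@binSize
  ox <- grid@origin[1L]
  oy <- grid@origin[2L]
  nb <- nBins(grid)
  if (nb == 0L || length(cells) == 0L) {
    return(OverlapTable(
      data.frame(bin_id = character(), cell_id = character(), area = numeric()),
      binArea = s * s
    ))
  }
  # key -> bin index lookup over present lattice positions
  keys <- grid@binRow * as.double(grid@nCols) + grid@binCol
  bins <- vector("list", length(cells))
  cls <- vector("list", length(cells))
  ars <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    poly <- cells@polygons[[k]]
    c0 <- max(0L, as.integer(floor((min(poly[, 1L]) - ox) / s)))
    c1 <- min(grid@nCols - 1L, as.integer(floor((max(poly[, 1L]) - ox) / s)))
    r0 <- max(0L, as.integer(floor((min(poly[, 2L]) - oy) / s)))
    r1 <- min(grid@nRows - 1L, as.integer(floor((max(poly[, 2L]) - oy) / s)))
    if (c1 < c0 || r1 < r0) next
    cand_r <- rep(r0:r1, each = c1 - c0 + 1L)
    cand_c <- rep(c0:c1, times = r1 - r0 + 1L)
    idx <- match(cand_r * as.double(grid@nCols) + cand_c, keys)
    pres <- which(!is.na(idx))
    if (!length(pres)) next
    a <- vapply(pres, function(p) {
      x0 <- ox + cand_c[p] * s
      y0 <- oy + cand_r[p] * s
      .rect_clip_area(poly, x0, y0, x0 + s, y0 + s)
    }, numeric(1L))
    hit <- a > .AREA_TOL
    if (!any(hit)) next
    bins[[k]] <- grid@binIDs[idx[pres[hit]]]
    cls[[k]] <- rep(cells@cellIDs[k], sum(hit))
    ars[[k]] <- pmin(a[hit], s * s)
  }
  OverlapTable(
    data.frame(
      bin_id = unlist(bins, use.names = FALSE) %||% character(),
      cell_id = unlist(cls, use.names = FALSE) %||% character(),
      area = unlist(ars, use.names = FALSE) %||% numeric(),
      stringsAsFactors = FALSE
    ),
    binArea = s * s
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand cell outlines outward
#'
#' Dilates each polygon outward by `distance` micrometres with mitre
#' (square) joins, the usual device for approximating whole-cell territory
#' from nucleus segmentations before bin assignment. Expanded polygons may
#' mutually overlap; downstream weighted strategies arbitrate shared
#' territory, so no clipping is performed.
#'
#' @param cells a [CellOutlines-class].
#' @param distance outward offset in micrometres (>= 0); 0 returns the
#'   input unchanged.
#' @return A [CellOutlines-class] with the same IDs.
#' @export
expandOutlines <- function(cells, distance) {
  stopifnot(methods::is(cells, "CellOutlines"))
  if (length(distance) != 1L || is.na(distance) || distance < 0) {
    .stopf("expansion distance must be a single non-negative number")
  }
  if (distance == 0) return(cells)
  CellOutlines(lapply(cells@polygons, .mitre_offset, dist = distance),
               cellIDs = cells@cellIDs)
}

#' Remove bins that intersect no cell
#'
#' Orphan bins (capture squares touching no segmented cell) carry
#' transcripts that cannot be attributed to any cell and are removed from
#' further analysis. The number of removed bins and their total counts are
#' reported via logging.
#'
#' @param grid a [BinGrid-class].
#' @param overlaps the [OverlapTable-class] computed on `grid`.
#' @return The grid restricted to bins present in `overlaps`.
#' @export
filterOrphanBins <- function(grid, overlaps) {
  stopifnot(methods::is(grid, "BinGrid"), methods::is(overlaps, "OverlapTable"))
  keep <- grid@binIDs %in% unique(overlaps@records$bin_id)
  removed <- sum(!keep)
  removed_counts <- if (removed) sum(grid@counts[!keep, , drop = FALSE]) else 0
  .log("info", "orphan-bin filter: removed %d/%d bins carrying %s counts",
       removed, nBins(grid), format(removed_counts))
  if (!any(keep)) .warnf("no bin overlaps any cell outline; returning an empty grid")
  grid[keep]
}
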