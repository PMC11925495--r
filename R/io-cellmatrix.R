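# The cell-by-gene output container: a plain-text directory bundle
# (MatrixMarket values + cells.csv + genes.tsv + metadata.json) that
# round-trips exactly, plus a flat CSV export for viewers.

#' Write a CellByGeneMatrix container
#'
#' Writes a directory with `matrix.mtx` (cells x genes; full double
#' precision for fractional values), `cells.csv` (cell id, centroid, number
#' of contributing bins, cell type), `genes.tsv` and `metadata.json`
#' (assignment strategy, package version). [readCellMatrix()] recovers the
#' object exactly. Use [asSingleCellExperiment()] for an in-memory
#' Bioconductor container.
#'
#' @param m a [CellByGeneMatrix-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCellMatrix <- function(m, dir) {
  stopifnot(methods::is(m, "CellByGeneMatrix"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) .stopf("I/O error: cannot create directory '%s'", dir)
  .write_mtx(m@values, file.path(dir, "matrix.mtx"))
  write.csv(
    data.frame(
      cell_id = m@cellIDs,
      x = sprintf("%.17g", m@centroids[, 1L]),
      y = sprintf("%.17g", m@centroids[, 2L]),
      n_bins = m@nBinsPerCell, cell_type = m@cellTypes
    ),
    file.path(dir, "cells.csv"), row.names = FALSE
  )
  writeLines(m@geneNames, file.path(dir, "genes.tsv"))
  jsonlite::write_json(
    list(strategy = m@strategy,
         package = as.character(utils::packageVersion("BinToCell"))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read a CellByGeneMatrix container
#'
#' @param dir directory written by [writeCellMatrix()].
#' @return A [CellByGeneMatrix-class].
#' @export
readCellMatrix <- function(dir) {
  for (f in c("matrix.mtx", "cells.csv", "genes.tsv", "metadata.json")) {
    if (!file.exists(file.path(dir, f))) {
      .stopf("format error: missing file '%s' in '%s'", f, dir)
    }
  }
  values <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE,
                    colClasses = c(cell_id = "character", cell_type = "character"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  if (nrow(values) != nrow(cells)) {
    .stopf("consistency error: %d cells in cells.csv but matrix has %d rows",
           nrow(cells), nrow(values))
  }
  CellByGeneMatrix(
    values = values, cellIDs = cells$cell_id, geneNames = genes,
    centroids = cbind(cells$x, cells$y), strategy = meta$strategy,
    nBinsPerCell = cells$n_bins, cellTypes = cells$cell_type
  )
}

#' Export a flat per-cell table for visualization
#'
#' One CSV row per cell: `id`, `x`, `y`, `cell_type`, `total_counts` — the
#' layout digital-pathology viewers ingest directly. Unlabeled cells get
#' `"NA"` in the `cell_type` column.
#'
#' @param m a [CellByGeneMatrix-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
exportVisualizationTable <- function(m, path) {
  stopifnot(methods::is(m, "CellByGeneMatrix"))
  ct <- m@cellTypes
  ct[is.na(ct)] <- "NA"
  write.csv(
    data.frame(
      id = m@cellIDs, x = m@centroids[, 1L], y = m@centroids[, 2L],
      cell_type = ct, total_counts = Matrix::rowSums(m@values)
    ),
    path, row.names = FALSE
  )
  invisible(path)
}
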