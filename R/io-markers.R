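#' Read a marker set
#'
#' Accepts a CSV with columns `cell_type`, `gene` (one marker per row) or a
#' JSON object mapping cell type to a gene array. A valid marker set has at
#' least two types, each with at least one marker; markers may be shared
#' between types.
#'
#' @param path CSV or JSON file.
#' @return named list: cell type to character vector of marker genes.
#' @export
readMarkerSet <- function(path) {
  if (!file.exists(path)) .stopf("format error: file '%s' does not exist", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    markers <- lapply(raw, as.character)
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("cell_type", "gene") %in% names(tab))) {
      .stopf("format error: marker CSV needs columns cell_type, gene")
    }
    markers <- split(tab$gene, tab$cell_type)
  }
  validateMarkerSet(markers)
  markers
}

#' @rdname readMarkerSet
#' @param markers named list to validate.
#' @export
validateMarkerSet <- function(markers) {
  if (length(markers) < 2L) .stopf("marker set must define at least 2 cell types")
  if (is.null(names(markers)) || any(names(markers) == "")) {
    .stopf("marker set types must be named")
  }
  if (any(lengths(markers) < 1L)) {
    .stopf("every cell type needs at least one marker gene")
  }
  invisible(TRUE)
}

#' Read a fine-to-coarse label mapping
#'
#' Two-column CSV (`fine`, `coarse`) mapping granular cell-type labels to
#' broader classes (e.g. Epithelial / Stromal / Immune).
#'
#' @param path CSV file.
#' @return named character vector: fine label to coarse label.
#' @export
readLabelMapping <- function(path) {
  if (!file.exists(path)) .stopf("format error: file '%s' does not exist", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) .stopf("format error: label mapping needs two columns")
  setNames(as.character(tab[[2L]]), tab[[1L]])
}
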