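# Readers and writers for the bin-level on-disk layout:
# MatrixMarket counts (bins x genes), barcodes.tsv, features.tsv, and a
# positions table (CSV or Parquet) giving each barcode's lattice indices.

#' Barcode parsers
#'
#' `parseBarcode10x()` understands the Space Ranger style
#' `"s_002um_{row:05d}_{col:05d}-1"`; `parseBarcodeRowCol()` the plain
#' `"{row}_{col}"` fallback. Both return a data.frame with columns `row`,
#' `col` (0-based) with one row per barcode, `NA` where parsing failed.
#' Custom dialects can be supplied to [readVisiumHDCounts()] as any function
#' with this signature.
#'
#' @param barcodes character vector of bin barcodes.
#' @return data.frame with integer columns `row` and `col`.
#' @export
parseBarcode10x <- function(barcodes) {
  m <- regmatches(barcodes,
                  regexec("^s_[0-9]+um_([0-9]{5})_([0-9]{5})(-[0-9]+)?$", barcodes))
  row <- vapply(m, function(x) if (length(x)) as.integer(x[2L]) else NA_integer_, integer(1L))
  col <- vapply(m, function(x) if (length(x)) as.integer(x[3L]) else NA_integer_, integer(1L))
  data.frame(row = row, col = col)
}

#' @rdname parseBarcode10x
#' @export
parseBarcodeRowCol <- function(barcodes) {
  m <- regmatches(barcodes, regexec("^r?([0-9]+)_c?([0-9]+)$", barcodes))
  row <- vapply(m, function(x) if (length(x)) as.integer(x[2L]) else NA_integer_, integer(1L))
  col <- vapply(m, function(x) if (length(x)) as.integer(x[3L]) else NA_integer_, integer(1L))
  data.frame(row = row, col = col)
}

.find_one <- function(dir, patterns, what) {
  for (p in patterns) {
    hit <- list.files(dir, pattern = p, full.names = TRUE)
    if (length(hit) == 1L) return(hit)
    if (length(hit) > 1L) return(sort(hit)[1L])
  }
  .stopf("format error: no %s file found in '%s'", what, dir)
}

.read_positions <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      .stopf("reading Parquet positions requires the arrow package")
    }
    pos <- as.data.frame(arrow::read_parquet(path))
  } else {
    pos <- read.csv(path, stringsAsFactors = FALSE)
  }
  names(pos) <- sub("^pxl_row_in_fullres$", "pxl_row", names(pos))
  names(pos) <- sub("^pxl_col_in_fullres$", "pxl_col", names(pos))
  req <- c("barcode", "array_row", "array_col")
  if (!all(req %in% names(pos))) {
    .stopf("format error: positions file '%s' lacks columns: %s",
           path, paste(setdiff(req, names(pos)), collapse = ", "))
  }
  pos
}

#' Read a Visium HD-style bin-by-gene directory
#'
#' Expects a directory holding a MatrixMarket counts file, barcode and
#' feature TSVs, and a positions table (CSV or Parquet) with columns
#' `barcode`, `array_row`, `array_col` (optionally `in_tissue`, `pxl_row`,
#' `pxl_col`). Physical coordinates are derived from the array indices times
#' `binSize`; when pixel coordinates plus `micronsPerPixel` are supplied the
#' lattice origin is offset so bin (0, 0) sits at its pixel-derived
#' position.
#'
#' @param dir directory containing the files.
#' @param binSize bin side length in micrometres (default 2).
#' @param barcodeParser optional fallback parser (see [parseBarcode10x()])
#'   used to derive lattice indices when no positions file is present.
#' @param micronsPerPixel optional scale to interpret `pxl_row`/`pxl_col`.
#' @return A [BinGrid-class]; total counts equal the MTX sum.
#' @export
readVisiumHDCounts <- function(dir, binSize = 2, barcodeParser = NULL,
                               micronsPerPixel = NULL) {
  if (!dir.exists(dir)) .stopf("format error: directory '%s' does not exist", dir)
  mtx <- .find_one(dir, c("\\.mtx$", "\\.mtx\\.gz$"), "MTX counts")
  bc_f <- .find_one(dir, c("^barcodes\\.tsv", "barcodes.*\\.tsv"), "barcodes TSV")
  ft_f <- .find_one(dir, c("^features\\.tsv", "features.*\\.tsv", "genes.*\\.tsv"),
                    "features TSV")
  counts <- Matrix::readMM(mtx)
  barcodes <- read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  feat <- read.delim(ft_f, header = FALSE, stringsAsFactors = FALSE)
  genes <- if (ncol(feat) >= 2L) feat[[2L]] else feat[[1L]]
  if (nrow(counts) != length(barcodes)) {
    if (ncol(counts) == length(barcodes) && nrow(counts) == length(genes)) {
      counts <- Matrix::t(counts)   # genes x bins dialect
    } else {
      .stopf("consistency error: %d barcodes but counts matrix is %d x %d",
             length(barcodes), nrow(counts), ncol(counts))
    }
  }
  if (ncol(counts) != length(genes)) {
    .stopf("consistency error: %d features but counts matrix has %d columns",
           length(genes), ncol(counts))
  }
  pos_f <- list.files(dir, pattern = "positions.*\\.(csv|parquet)$", full.names = TRUE)
  origin <- c(0, 0)
  if (length(pos_f)) {
    pos <- .read_positions(sort(pos_f)[1L])
    if (anyDuplicated(pos$barcode)) {
      .stopf("consistency error: duplicate barcodes in positions: %s",
             paste(unique(pos$barcode[duplicated(pos$barcode)]), collapse = ", "))
    }
    idx <- match(barcodes, pos$barcode)
    if (anyNA(idx)) {
      .stopf("consistency error: barcodes absent from positions: %s",
             paste(head(barcodes[is.na(idx)], 10L), collapse = ", "))
    }
    row <- as.integer(pos$array_row[idx])
    col <- as.integer(pos$array_col[idx])
    if (!is.null(micronsPerPixel) &&
        all(c("pxl_row", "pxl_col") %in% names(pos))) {
      # pixel coordinates are bin centres, so the lattice corner sits half a
      # bin before the smallest centre
      origin <- c(
        min(pos$pxl_col[idx] * micronsPerPixel - (col + 0.5) * binSize),
        min(pos$pxl_row[idx] * micronsPerPixel - (row + 0.5) * binSize)
      )
    }
  } else {
    parser <- barcodeParser
    if (is.null(parser)) {
      rc <- parseBarcode10x(barcodes)
      if (anyNA(rc$row)) rc <- parseBarcodeRowCol(barcodes)
    } else {
      rc <- parser(barcodes)
    }
    if (anyNA(rc$row)) {
      .stopf("consistency error: no positions file and unparseable barcodes: %s",
             paste(head(barcodes[is.na(rc$row)], 10L), collapse = ", "))
    }
    row <- rc$row
    col <- rc$col
  }
  BinGrid(counts, binRow = row, binCol = col, binSize = binSize,
          origin = origin, binIDs = barcodes, geneNames = genes)
}

# MatrixMarket writer emitting %.17g values so fractional matrices
# round-trip at full double precision (Matrix::writeMM truncates digits).
.write_mtx <- function(m, path) {
  m <- .as_dgc(m)
  tm <- methods::as(m, "TsparseMatrix")
  is_int <- all(tm@x == round(tm@x))
  header <- sprintf("%%%%MatrixMarket matrix coordinate %s general",
                    if (is_int) "integer" else "real")
  vals <- if (is_int) {
    sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(round(tm@x)))
  } else {
    sprintf("%d %d %.17g", tm@i + 1L, tm@j + 1L, tm@x)
  }
  writeLines(c(header,
               sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x)), vals),
             path)
}

#' Write a BinGrid as an MTX/TSV/CSV directory
#'
#' Writes `matrix.mtx` (bins x genes), `barcodes.tsv`, `features.tsv` and
#' `tissue_positions.csv`, the layout [readVisiumHDCounts()] reads back
#' exactly.
#'
#' @param grid a [BinGrid-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBinGrid <- function(grid, dir) {
  stopifnot(methods::is(grid, "BinGrid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_mtx(grid@counts, file.path(dir, "matrix.mtx"))
  writeLines(grid@binIDs, file.path(dir, "barcodes.tsv"))
  writeLines(paste(grid@geneNames, grid@geneNames, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  write.csv(
    data.frame(
      barcode = grid@binIDs, in_tissue = 1L,
      array_row = grid@binRow, array_col = grid@binCol,
      pxl_row = grid@origin[2L] + (grid@binRow + 0.5) * grid@binSize,
      pxl_col = grid@origin[1L] + (grid@binCol + 0.5) * grid@binSize
    ),
    file.path(dir, "tissue_positions.csv"), row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}
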