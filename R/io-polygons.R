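# Cell outline ingestion: GeoJSON polygons and integer label masks.

#' Read cell outlines from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with a unique identifier
#' property (`id`, `cell_id` or `ID`, or the top-level feature `id`).
#' Coordinates are interpreted in micrometres. Ring orientation is repaired;
#' interior rings (holes) are dropped with a warning.
#'
#' @param path GeoJSON file.
#' @param onInvalid policy for self-intersecting rings: `"warn"` or
#'   `"error"`.
#' @return A [CellOutlines-class].
#' @export
readCellPolygons <- function(path, onInvalid = c("warn", "error")) {
  onInvalid <- match.arg(onInvalid)
  if (!file.exists(path)) .stopf("format error: file '%s' does not exist", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  ids <- character(length(feats))
  polys <- vector("list", length(feats))
  holes <- FALSE
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    props <- f$properties
    id <- props$id %||% props$cell_id %||% props$ID %||% f$id
    ids[k] <- if (is.null(id)) sprintf("cell_%d", k) else as.character(id)
    geom <- f$geometry %||% f
    if (!identical(geom$type, "Polygon")) {
      .stopf("format error: feature '%s' has geometry type '%s' (need Polygon)",
             ids[k], geom$type %||% "missing")
    }
    rings <- geom$coordinates
    if (length(rings) > 1L) holes <- TRUE
    ring <- rings[[1L]]
    polys[[k]] <- matrix(unlist(ring, use.names = FALSE), ncol = 2L, byrow = TRUE)
  }
  if (holes) .warnf("interior rings (holes) dropped; only outer rings are kept")
  if (anyDuplicated(ids)) {
    .stopf("duplicate cell IDs in '%s': %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  CellOutlines(polys, cellIDs = ids, onInvalid = onInvalid)
}

#' Write cell outlines to GeoJSON
#'
#' @param cells a [CellOutlines-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCellPolygons <- function(cells, path) {
  stopifnot(methods::is(cells, "CellOutlines"))
  feats <- lapply(seq_along(cells), function(k) {
    p <- cells@polygons[[k]]
    ring <- lapply(c(seq_len(nrow(p)), 1L), function(i) c(p[i, 1L], p[i, 2L]))
    list(
      type = "Feature",
      properties = list(id = cells@cellIDs[k]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an integer label mask from TIFF or PNG
#'
#' Returns the label image as an integer matrix (0 = background, k > 0 =
#' cell k). 16-bit PNGs are rescaled from the unit interval back to integer
#' labels.
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @return integer matrix of labels.
#' @export
readLabelMask <- function(path) {
  if (!file.exists(path)) .stopf("format error: file '%s' does not exist", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      .stopf("reading TIFF masks requires the tiff package")
    }
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      .stopf("reading PNG masks requires the png package")
    }
    img <- png::readPNG(path)
    img <- round(img * 65535)
  } else {
    .stopf("format error: unsupported mask format for '%s'", path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "integer"
  img
}

# 4-connected components of a logical matrix; returns component id per TRUE
# pixel (vector parallel to which(mask)).
.connected_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & comp == 0L)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && comp[q] == 0L) {
          comp[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  comp
}

# Fill enclosed background pockets: background components not reachable from
# the matrix border are interior holes and are absorbed into the pixel set,
# so the traced outline is a single simple ring.
.fill_holes <- function(sel) {
  bg <- .connected_components(!sel)
  nr <- nrow(sel)
  nc <- ncol(sel)
  border <- unique(c(bg[1L, ], bg[nr, ], bg[, 1L], bg[, nc]))
  border <- border[border > 0L]
  sel | (bg > 0L & !(bg %in% border))
}

# Trace the outer boundary of a pixel set as a polygon in pixel units.
# Pixel (i, j) (1-based matrix indices) occupies the square
# [j-1, j) x [i-1, i), so the traced polygon's area equals the pixel count
# exactly. Boundary edges are directed with the interior on the left
# (y-down frame) and chained into a loop; at pinch vertices the sharpest
# left turn is taken so the trace stays on one loop.
.trace_boundary <- function(pix, nr, nc) {
  inside <- new.env(hash = TRUE, size = length(pix) * 2L)
  for (p in pix) assign(as.character(p), TRUE, envir = inside)
  has <- function(i, j) {
    if (i < 1L || i > nr || j < 1L || j > nc) return(FALSE)
    !is.null(inside[[as.character((j - 1L) * nr + i)]])
  }
  # directed edges (x0, y0, x1, y1) in pixel units, interior on the left
  edges <- list()
  for (p in pix) {
    i <- (p - 1L) %% nr + 1L
    j <- (p - 1L) %/% nr + 1L
    x0 <- j - 1L; y0 <- i - 1L
    if (!has(i - 1L, j)) edges[[length(edges) + 1L]] <- c(x0 + 1L, y0, x0, y0)         # top, leftward
    if (!has(i + 1L, j)) edges[[length(edges) + 1L]] <- c(x0, y0 + 1L, x0 + 1L, y0 + 1L) # bottom, rightward
    if (!has(i, j - 1L)) edges[[length(edges) + 1L]] <- c(x0, y0, x0, y0 + 1L)         # left, downward
    if (!has(i, j + 1L)) edges[[length(edges) + 1L]] <- c(x0 + 1L, y0 + 1L, x0 + 1L, y0) # right, upward
  }
  em <- do.call(rbind, edges)
  key <- function(x, y) paste(x, y)
  from <- key(em[, 1L], em[, 2L])
  used <- logical(nrow(em))
  by_from <- split(seq_len(nrow(em)), from)
  loops <- list()
  for (s in seq_len(nrow(em))) {
    if (used[s]) next
    verts <- list(em[s, 1:2])
    cur <- s
    used[s] <- TRUE
    repeat {
      vx <- em[cur, 3L]; vy <- em[cur, 4L]
      verts[[length(verts) + 1L]] <- c(vx, vy)
      cand <- by_from[[key(vx, vy)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # prefer the sharpest left turn relative to the incoming direction
        din <- c(vx - em[cur, 1L], vy - em[cur, 2L])
        turn <- vapply(cand, function(e) {
          dout <- c(em[e, 3L] - em[e, 1L], em[e, 4L] - em[e, 2L])
          atan2(din[1L] * dout[2L] - din[2L] * dout[1L],
                din[1L] * dout[1L] + din[2L] * dout[2L])
        }, numeric(1L))
        cand <- cand[which.min(turn)]
      }
      cur <- cand[1L]
      used[cur] <- TRUE
    }
    verts <- do.call(rbind, verts)
    loops[[length(loops) + 1L]] <- verts[-nrow(verts), , drop = FALSE]
  }
  # outer boundary is the loop with the largest absolute area
  ar <- vapply(loops, .poly_area, numeric(1L))
  loops[[which.max(ar)]]
}

#' Convert a label mask to cell outlines
#'
#' Extracts one polygon per nonzero label. Pixel `(i, j)` is treated as the
#' full square `[j-1, j) x [i-1, i)` in pixel units before scaling by
#' `pixelSize`, so each outline's area equals the label's pixel count times
#' `pixelSize^2` exactly (contours follow pixel edges, not pixel-centre
#' midpoints). If a label's pixels are disconnected, the largest
#' 4-connected component is kept with a warning; enclosed background
#' pockets are filled so every outline is a single simple ring (the filled
#' pixels count toward the area).
#'
#' @param mask integer matrix (0 = background) or a path readable by
#'   [readLabelMask()].
#' @param pixelSize micrometres per pixel (isotropic, > 0).
#' @return A [CellOutlines-class] with IDs `"cell_<label>"`.
#' @export
maskToPolygons <- function(mask, pixelSize = 1) {
  if (is.character(mask)) mask <- readLabelMask(mask)
  if (!is.matrix(mask)) .stopf("mask must be an integer matrix")
  if (any(mask < 0)) .stopf("mask labels must be non-negative")
  if (pixelSize <= 0) .stopf("pixelSize must be > 0")
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs)) {
    return(CellOutlines(list(), cellIDs = character()))
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  polys <- vector("list", length(labs))
  frag <- character()
  for (k in seq_along(labs)) {
    sel <- mask == labs[k]
    comp <- .connected_components(sel)
    ncomp <- max(comp)
    if (ncomp > 1L) {
      sizes <- tabulate(comp[which(sel)], nbins = ncomp)
      sel <- comp == which.max(sizes)
      frag <- c(frag, as.character(labs[k]))
    }
    pix <- which(.fill_holes(sel))
    polys[[k]] <- .trace_boundary(pix, nr, nc) * pixelSize
  }
  if (length(frag)) {
    .warnf("label(s) %s had disconnected pixels; kept the largest component",
           paste(frag, collapse = ", "))
  }
  CellOutlines(polys, cellIDs = paste0("cell_", labs))
}
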