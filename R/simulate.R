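# Parametric ground-truth tissue generator.
#
# Emulates the two benchmark regimes used to evaluate bin-to-cell
# assignment: a dense tissue of small, tightly packed cells in which a
# substantial fraction (~25%) of cell-intersecting bins touch more than one
# cell, and a sparse tissue of large, well-separated cells (each covering
# hundreds of bins) in which almost no bin does. Cells are ellipse-perturbed
# polygons placed by dart throwing; expression follows a per-type marker
# program (marker genes at an elevated rate over a flat baseline); transcript
# points are uniform inside each cell, with optional uniform extracellular
# noise; binning to the 2 um lattice is the degradation operator.

#' Tissue simulation configuration
#'
#' Returns a validated configuration, optionally starting from one of two
#' presets whose parameters are calibrated to the benchmark regimes:
#'
#' * `"dense"`: 220 cells of radius 4-6.5 um packed with 8.5 um minimum
#'   centre spacing in a 170 x 170 um field, so neighbouring polygons abut
#'   and interdigitate and the shared-bin fraction lands near 25%.
#' * `"sparse"`: 30 cells of radius 16-24 um with centre spacing at least
#'   2.5 x the maximum radius in a 560 x 560 um field, so each cell
#'   intersects hundreds of bins and essentially none are shared.
#'
#' @param preset `"dense"`, `"sparse"`, or `NULL` for bare defaults.
#' @param ... named overrides of any field below.
#' @param fieldSize field extents (width, height) in micrometres.
#' @param nCells number of cells to place.
#' @param radiusRange min/max mean cell radius (micrometres).
#' @param minSpacing minimum centre-to-centre distance (micrometres).
#' @param nGenes,nCellTypes,markersPerType gene universe and marker
#'   program layout (programs are disjoint; requires
#'   `nCellTypes * markersPerType <= nGenes`).
#' @param lambdaHi,lambdaLo relative expression rate of a type's marker
#'   genes versus the baseline rate of every gene.
#' @param countsPerCellRange min/max transcripts per cell (drawn uniformly).
#' @param noiseFraction fraction of all transcript points that are
#'   extracellular noise, in `[0, 1)`.
#' @param nucleusFraction linear scale of the nucleus polygon relative to
#'   the cell, in `(0, 1]`.
#' @param binSize bin side length of the degraded observation (micrometres).
#' @param eccentricity maximum ellipse eccentricity of cell shapes.
#' @param vertexNoise relative radial jitter of polygon vertices.
#' @param nVertices vertices per cell polygon.
#' @param seed RNG seed; every stochastic step derives from it.
#' @return named list of class `TissueSimConfig`.
#' @export
tissueSimConfig <- function(preset = NULL, ...,
                            fieldSize = c(100, 100), nCells = 50,
                            radiusRange = c(4, 6), minSpacing = 9,
                            nGenes = 40, nCellTypes = 4, markersPerType = 5,
                            lambdaHi = 12, lambdaLo = 0.4,
                            countsPerCellRange = c(80, 250),
                            noiseFraction = 0.05, nucleusFraction = 0.6,
                            binSize = 2, eccentricity = 0.2,
                            vertexNoise = 0.06, nVertices = 24, seed = 1L) {
  cfg <- list(
    fieldSize = fieldSize, nCells = nCells, radiusRange = radiusRange,
    minSpacing = minSpacing, nGenes = nGenes, nCellTypes = nCellTypes,
    markersPerType = markersPerType, lambdaHi = lambdaHi, lambdaLo = lambdaLo,
    countsPerCellRange = countsPerCellRange, noiseFraction = noiseFraction,
    nucleusFraction = nucleusFraction, binSize = binSize,
    eccentricity = eccentricity, vertexNoise = vertexNoise,
    nVertices = nVertices, seed = seed
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("dense", "sparse"))
    supplied <- intersect(names(match.call())[-1L], names(cfg))
    cfg[names(.sim_presets[[preset]])] <- .sim_presets[[preset]]
    # explicitly supplied arguments win over the preset
    for (nm in supplied) cfg[[nm]] <- get(nm)
    cfg$preset <- preset
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) .stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_sim_config(cfg)
  class(cfg) <- c("TissueSimConfig", "list")
  cfg
}

.sim_presets <- list(
  dense = list(
    fieldSize = c(170, 170), nCells = 220, radiusRange = c(4, 6.5),
    minSpacing = 8.5, nGenes = 60, nCellTypes = 6, markersPerType = 5,
    countsPerCellRange = c(80, 250), noiseFraction = 0.05
  ),
  sparse = list(
    fieldSize = c(560, 560), nCells = 30, radiusRange = c(16, 24),
    minSpacing = 60, nGenes = 40, nCellTypes = 4, markersPerType = 5,
    countsPerCellRange = c(1000, 3000), noiseFraction = 0.05
  )
)

.validate_sim_config <- function(cfg) {
  if (length(cfg$fieldSize) != 2L || any(cfg$fieldSize <= 0)) {
    .stopf("fieldSize must be two positive extents")
  }
  if (cfg$nCells < 1L) .stopf("nCells must be >= 1")
  if (any(cfg$radiusRange <= 0) || diff(cfg$radiusRange) < 0) {
    .stopf("radiusRange must be positive and non-decreasing")
  }
  if (2 * max(cfg$radiusRange) > min(cfg$fieldSize)) {
    .stopf("cell radii do not fit in the field")
  }
  if (cfg$noiseFraction < 0 || cfg$noiseFraction >= 1) {
    .stopf("noiseFraction must be in [0, 1)")
  }
  if (cfg$nucleusFraction <= 0 || cfg$nucleusFraction > 1) {
    .stopf("nucleusFraction must be in (0, 1]")
  }
  if (cfg$binSize <= 0) .stopf("binSize must be > 0")
  if (cfg$nCellTypes * cfg$markersPerType > cfg$nGenes) {
    .stopf("marker programs need nCellTypes * markersPerType <= nGenes")
  }
  invisible(TRUE)
}

# Dart-throwing placement with minimum centre spacing.
.place_centres <- function(cfg) {
  rmax <- max(cfg$radiusRange)
  lo <- c(rmax, rmax)
  hi <- cfg$fieldSize - rmax
  centres <- matrix(NA_real_, cfg$nCells, 2L)
  placed <- 0L
  tries <- 0L
  max_tries <- 400L * cfg$nCells
  while (placed < cfg$nCells && tries < max_tries) {
    tries <- tries + 1L
    p <- c(runif(1L, lo[1L], hi[1L]), runif(1L, lo[2L], hi[2L]))
    if (placed == 0L ||
        min((centres[seq_len(placed), 1L] - p[1L])^2 +
            (centres[seq_len(placed), 2L] - p[2L])^2) >= cfg$minSpacing^2) {
      placed <- placed + 1L
      centres[placed, ] <- p
    }
  }
  if (placed < cfg$nCells) {
    .stopf(paste0("could not place %d cells with %.3g um spacing in a ",
                  "%.3g x %.3g um field; reduce nCells or minSpacing"),
           cfg$nCells, cfg$minSpacing, cfg$fieldSize[1L], cfg$fieldSize[2L])
  }
  centres
}

# Ellipse-perturbed star-shaped polygon around a centre.
.cell_polygon <- function(centre, radius, cfg) {
  nv <- cfg$nVertices
  theta <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  ecc <- runif(1L, 0, cfg$eccentricity)
  phi <- runif(1L, 0, pi)
  a <- radius * (1 + ecc)
  b <- radius / (1 + ecc)
  r_ell <- a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
  r <- r_ell * (1 + runif(nv, -cfg$vertexNoise, cfg$vertexNoise))
  cbind(centre[1L] + r * cos(theta), centre[2L] + r * sin(theta))
}

# Uniform points inside a polygon by rejection sampling in its bbox.
.sample_in_polygon <- function(poly, n) {
  if (n == 0L) return(matrix(numeric(), 0L, 2L))
  bx <- range(poly[, 1L])
  by <- range(poly[, 2L])
  frac <- .poly_area(poly) / ((bx[2L] - bx[1L]) * (by[2L] - by[1L]))
  out <- matrix(numeric(), 0L, 2L)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / max(frac, 0.1) * 1.2) + 16L
    px <- runif(m, bx[1L], bx[2L])
    py <- runif(m, by[1L], by[2L])
    keep <- .points_in_polygon(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a ground-truth tissue
#'
#' Places cells by dart throwing, draws a type and an expression profile per
#' cell (marker genes at `lambdaHi`, all genes at `lambdaLo` baseline, gene
#' counts multinomial given the cell's total), scatters each cell's
#' transcript points uniformly inside its polygon, and adds uniform
#' extracellular noise points. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [tissueSimConfig()].
#' @return A [GroundTruthTissue-class].
#' @export
simulateTissue <- function(cfg) {
  stopifnot(inherits(cfg, "TissueSimConfig"))
  .run_with_seed(cfg$seed, {
    centres <- .place_centres(cfg)
    radii <- runif(cfg$nCells, cfg$radiusRange[1L], cfg$radiusRange[2L])
    polys <- lapply(seq_len(cfg$nCells), function(k) {
      .cell_polygon(centres[k, ], radii[k], cfg)
    })
    ids <- sprintf("cell_%03d", seq_len(cfg$nCells))
    cells <- CellOutlines(polys, cellIDs = ids)
    nuclei <- CellOutlines(lapply(seq_len(cfg$nCells), function(k) {
      p <- cells@polygons[[k]]
      ctr <- cells@centroids[k, ]
      sweep(sweep(p, 2L, ctr) * cfg$nucleusFraction, 2L, ctr, `+`)
    }), cellIDs = ids)
    genes <- sprintf("gene%03d", seq_len(cfg$nGenes))
    types <- paste0("type", seq_len(cfg$nCellTypes))
    marker_idx <- split(
      seq_len(cfg$nCellTypes * cfg$markersPerType),
      rep(seq_len(cfg$nCellTypes), each = cfg$markersPerType)
    )
    rates <- matrix(cfg$lambdaLo, cfg$nCellTypes, cfg$nGenes)
    for (t in seq_len(cfg$nCellTypes)) {
      rates[t, marker_idx[[t]]] <- rates[t, marker_idx[[t]]] + cfg$lambdaHi
    }
    cell_type <- sample(types, cfg$nCells, replace = TRUE)
    totals <- round(runif(cfg$nCells, cfg$countsPerCellRange[1L],
                          cfg$countsPerCellRange[2L]))
    pts <- vector("list", cfg$nCells)
    for (k in seq_len(cfg$nCells)) {
      prob <- rates[match(cell_type[k], types), ]
      gcount <- as.vector(stats::rmultinom(1L, totals[k], prob))
      xy <- .sample_in_polygon(cells@polygons[[k]], totals[k])
      pts[[k]] <- data.frame(
        x = xy[, 1L], y = xy[, 2L],
        gene = rep(genes, gcount), cell_id = ids[k],
        stringsAsFactors = FALSE
      )
    }
    points <- do.call(rbind, pts)
    if (cfg$noiseFraction > 0) {
      n_noise <- round(cfg$noiseFraction / (1 - cfg$noiseFraction) * nrow(points))
      if (n_noise > 0L) {
        noise <- data.frame(
          x = runif(n_noise, 0, cfg$fieldSize[1L]),
          y = runif(n_noise, 0, cfg$fieldSize[2L]),
          gene = sample(genes, n_noise, replace = TRUE),
          cell_id = NA_character_, stringsAsFactors = FALSE
        )
        points <- rbind(points, noise)
      }
    }
    rownames(points) <- NULL
    methods::new("GroundTruthTissue",
      points = points, cells = cells, nuclei = nuclei,
      cellTypes = setNames(cell_type, ids), geneNames = genes,
      fieldSize = as.numeric(cfg$fieldSize)
    )
  })
}

#' Bin transcript points onto a regular lattice
#'
#' The degradation operator: point `(x, y)` falls in bin
#' `(floor(y / s), floor(x / s))` (half-open convention, matching the bin
#' footprints), and only bin membership survives. The returned grid covers
#' the full field lattice, including zero-count bins.
#'
#' @param gt a [GroundTruthTissue-class].
#' @param binSize bin side length in micrometres.
#' @return A [BinGrid-class] whose total equals the in-field point count.
#' @export
binifyTranscripts <- function(gt, binSize = 2) {
  stopifnot(methods::is(gt, "GroundTruthTissue"))
  if (binSize <= 0) .stopf("binSize must be > 0")
  p <- gt@points
  fs <- gt@fieldSize
  n_cols <- as.integer(ceiling(fs[1L] / binSize))
  n_rows <- as.integer(ceiling(fs[2L] / binSize))
  inf <- p$x >= 0 & p$x < fs[1L] & p$y >= 0 & p$y < fs[2L]
  p <- p[inf, , drop = FALSE]
  row <- as.integer(floor(p$y / binSize))
  col <- as.integer(floor(p$x / binSize))
  gi <- match(p$gene, gt@geneNames)
  all_row <- rep(0:(n_rows - 1L), each = n_cols)
  all_col <- rep(0:(n_cols - 1L), times = n_rows)
  bin_slot <- row * n_cols + col + 1L
  counts <- Matrix::sparseMatrix(
    i = bin_slot, j = gi, x = 1,
    dims = c(n_rows * n_cols, length(gt@geneNames)),
    use.last.ij = FALSE
  )
  BinGrid(counts, binRow = all_row, binCol = all_col, binSize = binSize,
          origin = c(0, 0), geneNames = gt@geneNames,
          nRows = n_rows, nCols = n_cols)
}

#' Ground-truth cell-by-gene tally
#'
#' Tallies transcript points per (cell, gene). In `"nucleus"` mode only
#' points falling inside their own cell's nucleus polygon are counted — the
#' reference for nucleus-focused evaluation.
#'
#' @param gt a [GroundTruthTissue-class].
#' @param mode `"whole_cell"` or `"nucleus"`.
#' @return A [CellByGeneMatrix-class] with strategy `"truth"`.
#' @export
trueCellMatrix <- function(gt, mode = c("whole_cell", "nucleus")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(gt, "GroundTruthTissue"))
  p <- gt@points[!is.na(gt@points$cell_id), , drop = FALSE]
  ids <- gt@cells@cellIDs
  if (mode == "nucleus" && nrow(p)) {
    keep <- logical(nrow(p))
    for (k in seq_along(ids)) {
      sel <- which(p$cell_id == ids[k])
      if (length(sel)) {
        keep[sel] <- .points_in_polygon(p$x[sel], p$y[sel],
                                        gt@nuclei@polygons[[k]])
      }
    }
    p <- p[keep, , drop = FALSE]
  }
  ci <- match(p$cell_id, ids)
  gi <- match(p$gene, gt@geneNames)
  counts <- Matrix::sparseMatrix(
    i = ci, j = gi, x = 1,
    dims = c(length(ids), length(gt@geneNames)), use.last.ij = FALSE
  )
  CellByGeneMatrix(
    values = counts, cellIDs = ids, geneNames = gt@geneNames,
    centroids = gt@cells@centroids, strategy = "truth",
    nBinsPerCell = integer(length(ids)),
    cellTypes = unname(gt@cellTypes[ids])
  )
}

#' Generate a complete synthetic dataset
#'
#' Bundles [simulateTissue()] and [binifyTranscripts()] into a
#' [SyntheticDataset-class]: the degraded bin-level observation plus its
#' ground truth, serializable via [writeSyntheticDataset()].
#'
#' @param cfg a [tissueSimConfig()].
#' @return A [SyntheticDataset-class].
#' @export
makeDataset <- function(cfg) {
  truth <- simulateTissue(cfg)
  grid <- binifyTranscripts(truth, binSize = cfg$binSize)
  methods::new("SyntheticDataset", grid = grid, truth = truth,
               config = unclass(cfg))
}

#' True marker table of a simulation configuration
#'
#' The generator assigns type `t` the disjoint marker block
#' `gene[(t-1)*m + 1 .. t*m]` (with `m = markersPerType`). This returns that
#' assignment in the same named-list form [readMarkerSet()] produces,
#' directly usable with [scoreCellTypes()] to benchmark annotation against
#' known truth.
#'
#' @param cfg a [tissueSimConfig()] (or the `config` slot of a
#'   [SyntheticDataset-class]).
#' @return named list: cell type to character vector of marker genes.
#' @export
trueMarkerSet <- function(cfg) {
  genes <- sprintf("gene%03d", seq_len(cfg$nCellTypes * cfg$markersPerType))
  split(genes, rep(paste0("type", seq_len(cfg$nCellTypes)),
                   each = cfg$markersPerType))
}

#' Serialize a synthetic dataset to plain-text layouts
#'
#' Writes the bin grid (MTX/TSV/CSV, see [writeBinGrid()]), whole-cell and
#' nucleus outlines (GeoJSON), the transcript table
#' (`transcripts.csv`: x, y, gene, cell_id), true cell types
#' (`cell_types.csv`) and a config echo (`config.json`).
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(ds, dir) {
  stopifnot(methods::is(ds, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBinGrid(ds@grid, file.path(dir, "bins"))
  writeCellPolygons(ds@truth@cells, file.path(dir, "cells.geojson"))
  writeCellPolygons(ds@truth@nuclei, file.path(dir, "nuclei.geojson"))
  p <- ds@truth@points
  p$x <- sprintf("%.17g", p$x)
  p$y <- sprintf("%.17g", p$y)
  write.csv(p, file.path(dir, "transcripts.csv"), row.names = FALSE)
  write.csv(
    data.frame(cell_id = names(ds@truth@cellTypes),
               cell_type = unname(ds@truth@cellTypes)),
    file.path(dir, "cell_types.csv"), row.names = FALSE
  )
  jsonlite::write_json(ds@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
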