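# End-to-end orchestration: read -> (mask to polygons) -> (expand) ->
# spatial join -> orphan filter -> assignment -> annotation -> outputs.

.config_schema <- list(
  input = c("counts_dir", "outlines", "mask", "mask_pixel_size", "truth_dir"),
  geometry = c("expansion"),
  assignment = c("strategy", "pseudocount", "n_clusters", "seed", "keep_fractional"),
  annotation = c("enabled", "markers", "min_counts", "label_map"),
  output = c("dir"),
  top = c("input", "geometry", "assignment", "annotation", "output",
          "seed", "log_level", "bin_size")
)

.config_defaults <- function() {
  list(
    input = list(counts_dir = NULL, outlines = NULL, mask = NULL,
                 mask_pixel_size = 1, truth_dir = NULL),
    geometry = list(expansion = 0),
    assignment = list(strategy = "weight_by_area", pseudocount = 1,
                      n_clusters = 4L, seed = NULL, keep_fractional = TRUE),
    annotation = list(enabled = FALSE, markers = NULL, min_counts = 5,
                      label_map = NULL),
    output = list(dir = "bintocell_output"),
    seed = 1L,
    log_level = "info",
    bin_size = 2
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), applies defaults, and validates the
#' schema strictly: unknown keys are errors, not warnings. Defaults mirror
#' the recommended configuration: `weight_by_area` assignment and no outline
#' expansion.
#'
#' @param config path to a YAML file, or a nested list.
#' @return validated config list of class `PipelineConfig`.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stopf("config must be a YAML file path or a list")
  unknown <- setdiff(names(config), .config_schema$top)
  if (length(unknown)) {
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- .config_defaults()
  for (section in c("input", "geometry", "assignment", "annotation", "output")) {
    sec <- config[[section]]
    if (is.null(sec)) next
    if (!is.list(sec)) .stopf("config key '%s' must be a mapping", section)
    unknown <- setdiff(names(sec), .config_schema[[section]])
    if (length(unknown)) {
      .stopf("unknown config key(s): %s",
             paste(paste0(section, ".", unknown), collapse = ", "))
    }
    cfg[[section]][names(sec)] <- sec
  }
  for (key in c("seed", "log_level", "bin_size")) {
    if (!is.null(config[[key]])) cfg[[key]] <- config[[key]]
  }
  if (!cfg$assignment$strategy %in%
      c("naive", "weight_by_area", "weight_by_gene", "weight_by_cluster")) {
    .stopf("assignment.strategy: '%s' is not one of naive, weight_by_area, weight_by_gene, weight_by_cluster",
           cfg$assignment$strategy)
  }
  if (cfg$geometry$expansion < 0) .stopf("geometry.expansion must be >= 0")
  if (cfg$assignment$pseudocount < 0) .stopf("assignment.pseudocount must be >= 0")
  if (is.null(cfg$assignment$seed)) cfg$assignment$seed <- cfg$seed
  if (is.null(cfg$input$counts_dir)) .stopf("input.counts_dir is required")
  if (!dir.exists(cfg$input$counts_dir)) {
    .stopf("input.counts_dir '%s' does not exist", cfg$input$counts_dir)
  }
  if (is.null(cfg$input$outlines) && is.null(cfg$input$mask)) {
    .stopf("one of input.outlines or input.mask is required")
  }
  for (key in c("outlines", "mask")) {
    if (!is.null(cfg$input[[key]]) && !file.exists(cfg$input[[key]])) {
      .stopf("input.%s '%s' does not exist", key, cfg$input[[key]])
    }
  }
  if (isTRUE(cfg$annotation$enabled)) {
    if (is.null(cfg$annotation$markers)) {
      .stopf("annotation.markers is required when annotation is enabled")
    }
    if (!file.exists(cfg$annotation$markers)) {
      .stopf("annotation.markers '%s' does not exist", cfg$annotation$markers)
    }
    if (!is.null(cfg$annotation$label_map) && !file.exists(cfg$annotation$label_map)) {
      .stopf("annotation.label_map '%s' does not exist", cfg$annotation$label_map)
    }
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  .log("info", "stage %-14s done in %.2fs", name,
       proc.time()[["elapsed"]] - t0)
  res
}

#' Run the end-to-end pipeline
#'
#' Executes: read bin counts, ingest outlines (GeoJSON) or a label mask,
#' optional outward expansion, spatial join, orphan-bin removal, bin-to-cell
#' assignment, optional marker-score annotation, and writes the cell-by-gene
#' container, the visualization CSV and a JSON run manifest (config echo,
#' stage timings, per-stage counts, conservation check, metrics when ground
#' truth is supplied). Identical config and seed give identical outputs.
#'
#' @param config a YAML path or list accepted by [validateConfig()].
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  old <- options(BinToCell.log = cfg$log_level)
  on.exit(options(old), add = TRUE)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("BinToCell")),
                   stages = list())
  timings <- list()
  tic <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- .stage(manifest, name, expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3L)
    res
  }
  grid <- tic("read_counts", readVisiumHDCounts(cfg$input$counts_dir,
                                                binSize = cfg$bin_size))
  cells <- tic("read_outlines", {
    if (!is.null(cfg$input$outlines)) {
      readCellPolygons(cfg$input$outlines)
    } else {
      maskToPolygons(cfg$input$mask, pixelSize = cfg$input$mask_pixel_size)
    }
  })
  if (cfg$geometry$expansion > 0) {
    cells <- tic("expand", expandOutlines(cells, cfg$geometry$expansion))
  }
  overlaps <- tic("spatial_join", spatialJoin(grid, cells))
  stats <- overlapStatistics(overlaps, grid)
  .log("info", "join: %d/%d bins overlap a cell; shared fraction %.3f",
       stats$n_bins_overlapping, stats$n_bins_total, stats$shared_fraction)
  grid_f <- tic("orphan_filter", filterOrphanBins(grid, overlaps))
  m <- tic("assignment", assignBins(
    grid_f, overlaps, cells,
    strategy = cfg$assignment$strategy,
    pseudocount = cfg$assignment$pseudocount,
    nClusters = cfg$assignment$n_clusters,
    seed = cfg$assignment$seed,
    keepFractional = cfg$assignment$keep_fractional
  ))
  # conservation: weighted strategies keep all counts of overlapping bins,
  # naive keeps the unique-bin counts only
  deg <- table(overlaps@records$bin_id)
  eligible <- if (cfg$assignment$strategy == "naive") {
    names(deg)[deg == 1L]
  } else {
    names(deg)
  }
  expected <- sum(grid_f@counts[grid_f@binIDs %in% eligible, , drop = FALSE])
  conserved <- abs(sum(m@values) - expected) <= 1e-6 * max(1, expected)
  annotation <- NULL
  if (isTRUE(cfg$annotation$enabled)) {
    markers <- readMarkerSet(cfg$annotation$markers)
    annotation <- tic("annotation",
                      scoreCellTypes(m, markers,
                                     minCounts = cfg$annotation$min_counts))
    if (!is.null(cfg$annotation$label_map)) {
      lm <- readLabelMapping(cfg$annotation$label_map)
      annotation <- mapToCoarseLabels(annotation, lm)
    }
    cellTypes(m) <- cellLabels(annotation)
  }
  out_dir <- cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tic("write_outputs", {
    writeCellMatrix(m, file.path(out_dir, "cell_by_gene"))
    exportVisualizationTable(m, file.path(out_dir, "cells_viz.csv"))
  })
  metrics <- NULL
  if (!is.null(cfg$input$truth_dir)) {
    metrics <- tic("evaluate", {
      truth <- .read_truth_matrix(cfg$input$truth_dir, grid@geneNames)
      transcriptAssignmentMetrics(m, truth)
    })
  }
  manifest$stages <- timings
  manifest$counts <- list(
    n_bins_read = nBins(grid),
    n_bins_after_filter = nBins(grid_f),
    n_cells = length(cells),
    shared_bin_fraction = stats$shared_fraction,
    total_counts_in = totalCounts(grid),
    total_counts_assigned = sum(m@values)
  )
  manifest$conservation_check <- if (conserved) "pass" else "fail"
  if (!is.null(metrics)) {
    manifest$assignment_metrics <- metrics[c("precision", "recall", "f1")]
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  .log("info", "pipeline complete: outputs in '%s'", out_dir)
  invisible(manifest)
}

# Ground truth on disk: a transcripts.csv (x, y, gene, cell_id) as written
# by writeSyntheticDataset(), or an equivalent export from an imaging run.
.read_truth_matrix <- function(dir, gene_universe) {
  f <- file.path(dir, "transcripts.csv")
  if (!file.exists(f)) .stopf("truth dir '%s' lacks transcripts.csv", dir)
  p <- read.csv(f, stringsAsFactors = FALSE,
                colClasses = c(cell_id = "character", gene = "character"))
  p <- p[!is.na(p$cell_id) & p$cell_id != "", , drop = FALSE]
  ids <- sort(unique(p$cell_id))
  genes <- union(gene_universe, unique(p$gene))
  counts <- Matrix::sparseMatrix(
    i = match(p$cell_id, ids), j = match(p$gene, genes), x = 1,
    dims = c(length(ids), length(genes))
  )
  dimnames(counts) <- list(ids, genes)
  counts
}
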