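# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately use the dumbest correct algorithm available so
# they cannot share a bug with the package's optimized implementations.

# Brute-force all-pairs spatial join: clip every present bin against every
# cell polygon with the package's exact rectangle clipper, skipping only
# pairs whose bounding boxes are disjoint (for which zero overlap is exact).
# No lattice arithmetic, no candidate lookup.
brute_force_join <- function(grid, cells) {
  s <- binSize(grid)
  ox <- gridOrigin(grid)[1L]
  oy <- gridOrigin(grid)[2L]
  x0 <- ox + grid@binCol * s
  y0 <- oy + grid@binRow * s
  out <- list()
  for (k in seq_along(cells)) {
    p <- polygons(cells)[[k]]
    bb <- c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L]))
    for (b in seq_len(nBins(grid))) {
      if (x0[b] + s <= bb[1L] || x0[b] >= bb[2L] ||
          y0[b] + s <= bb[3L] || y0[b] >= bb[4L]) next
      a <- BinToCell:::.rect_clip_area(p, x0[b], y0[b], x0[b] + s, y0[b] + s)
      if (a > BinToCell:::.AREA_TOL) {
        out[[length(out) + 1L]] <- data.frame(
          bin_id = binIDs(grid)[b], cell_id = cellIDs(cells)[k], area = a,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(bin_id = character(), cell_id = character(),
                      area = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Canonical ordering so joined tables can be compared row by row.
sort_records <- function(df) {
  df <- df[order(df$bin_id, df$cell_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random star-shaped polygon: radial perturbation of a circle with
# well-separated angles, so the ring is always simple.
random_polygon <- function(cx, cy, r, nv = 12L) {
  gaps <- runif(nv, 0.5, 1.5)
  th <- 2 * pi * cumsum(gaps) / sum(gaps)
  rr <- r * runif(nv, 0.6, 1)
  cbind(cx + rr * cos(th), cy + rr * sin(th))
}

# Random join instance: a partial bin grid plus scattered cell polygons.
random_join_instance <- function(n_bins_max = 500L, n_cells_max = 50L,
                                 field = 40) {
  s <- 2
  nrow_g <- ncol_g <- as.integer(field / s)
  n_lattice <- nrow_g * ncol_g
  nb <- sample.int(min(n_bins_max, n_lattice), 1L)
  pos <- sample.int(n_lattice, nb)
  counts <- Matrix::sparseMatrix(
    i = seq_len(nb), j = sample.int(5L, nb, replace = TRUE),
    x = rpois(nb, 3) + 1, dims = c(nb, 5L)
  )
  grid <- BinGrid(
    counts = counts,
    binRow = as.integer((pos - 1L) %/% ncol_g),
    binCol = as.integer((pos - 1L) %% ncol_g),
    origin = runif(2, -3, 3), binSize = s,
    nRows = nrow_g, nCols = ncol_g,
    geneNames = paste0("g", 1:5)
  )
  ncell <- sample.int(n_cells_max, 1L)
  polys <- lapply(seq_len(ncell), function(k) {
    random_polygon(runif(1, 0, field), runif(1, 0, field), runif(1, 2, 6))
  })
  cells <- CellOutlines(polys, cellIDs = sprintf("c%02d", seq_len(ncell)))
  list(grid = grid, cells = cells)
}

# Pixel-count oracle for maskToPolygons: the returned polygon's shoelace
# area must equal the label's pixel count plus any enclosed background
# pockets. The enclosed area is found independently with a scanline-style
# flood fill of the background starting from the matrix border.
filled_pixel_count <- function(mask, label) {
  sel <- mask == label
  nr <- nrow(sel)
  nc <- ncol(sel)
  reached <- matrix(FALSE, nr, nc)
  stack <- c(
    which(!sel[, 1L]) ,
    which(!sel[, nc]) + (nc - 1L) * nr,
    (which(!sel[1L, ]) - 1L) * nr + 1L,
    (which(!sel[nr, ]) - 1L) * nr + nr
  )
  reached[stack] <- TRUE
  while (length(stack)) {
    p <- stack[[1L]]
    stack <- stack[-1L]
    i <- (p - 1L) %% nr + 1L
    j <- (p - 1L) %/% nr + 1L
    nbr <- c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
             if (j > 1L) p - nr, if (j < nc) p + nr)
    nbr <- nbr[!sel[nbr] & !reached[nbr]]
    reached[nbr] <- TRUE
    stack <- c(stack, nbr)
  }
  nr * nc - sum(reached)
}

# Random connected blob (one random walk), guaranteed a single label.
random_walk_blob <- function(nr = 18L, nc = 18L, steps = 70L) {
  m <- matrix(0L, nr, nc)
  i <- nr %/% 2L
  j <- nc %/% 2L
  for (st in seq_len(steps)) {
    m[i, j] <- 1L
    d <- sample.int(4L, 1L)
    i <- min(max(i + c(-1L, 1L, 0L, 0L)[d], 1L), nr)
    j <- min(max(j + c(0L, 0L, -1L, 1L)[d], 1L), nc)
  }
  m
}

# A random-walk blob mask with a given number of labels.
random_blob_mask <- function(nr = 20L, nc = 20L, n_labels = 2L,
                             steps = 60L) {
  m <- matrix(0L, nr, nc)
  for (lab in seq_len(n_labels)) {
    i <- sample.int(nr - 4L, 1L) + 2L
    j <- sample.int(nc - 4L, 1L) + 2L
    for (st in seq_len(steps)) {
      if (m[i, j] == 0L) m[i, j] <- lab
      d <- sample.int(4L, 1L)
      i <- min(max(i + c(-1L, 1L, 0L, 0L)[d], 1L), nr)
      j <- min(max(j + c(0L, 0L, -1L, 1L)[d], 1L), nc)
    }
  }
  m
}

# Hand-built 2x2-grid fixture used by the assignment tests. Geometry is
# irrelevant here: the overlap table is authored directly so the expected
# strategy outputs can be derived by hand arithmetic.
#   bins: b00 unique to A; b01 shared A/B (area 3:1); b10 orphan-free unique
#   to B; b11 shared A/B (area 1:1).
hand_fixture <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1L, 2L, 2L, 3L, 4L),
    j = c(1L, 1L, 2L, 2L, 2L),
    x = c(5, 4, 2, 2, 2),
    dims = c(4L, 2L)
  )
  grid <- BinGrid(
    counts = counts,
    binRow = c(0L, 0L, 1L, 1L), binCol = c(0L, 1L, 0L, 1L),
    origin = c(0, 0), binSize = 2, nRows = 2L, nCols = 2L,
    binIDs = c("b00", "b01", "b10", "b11"), geneNames = c("g1", "g2")
  )
  cells <- CellOutlines(
    list(
      cbind(c(0, 2.5, 2.5, 0), c(0, 0, 2, 2)),
      cbind(c(2.5, 4, 4, 2.5), c(0, 0, 4, 4))
    ),
    cellIDs = c("A", "B")
  )
  overlaps <- BinToCell:::OverlapTable(
    data.frame(
      bin_id = c("b00", "b01", "b01", "b10", "b11", "b11"),
      cell_id = c("A", "A", "B", "B", "A", "B"),
      area = c(4, 3, 1, 4, 2, 2),
      stringsAsFactors = FALSE
    ),
    binArea = 4
  )
  list(grid = grid, cells = cells, overlaps = overlaps)
}

# Build a tiny on-disk synthetic dataset plus pipeline config for the
# end-to-end tests; returns paths.
write_pipeline_fixture <- function(root, seed = 4L,
                                   strategy = "weight_by_gene",
                                   out = "out") {
  ds_dir <- file.path(root, "ds")
  if (!dir.exists(ds_dir)) {
    ds <- makeDataset(tissueSimConfig("dense", seed = seed))
    writeSyntheticDataset(ds, ds_dir)
  }
  cfg <- list(
    input = list(counts_dir = file.path(ds_dir, "bins"),
                 outlines = file.path(ds_dir, "cells.geojson"),
                 truth_dir = ds_dir),
    assignment = list(strategy = strategy),
    output = list(dir = file.path(root, out)),
    seed = 7L, log_level = "warn"
  )
  cfg_path <- file.path(root, paste0(out, ".yaml"))
  yaml::write_yaml(cfg, cfg_path)
  list(ds = ds_dir, config = cfg_path, out = cfg$output$dir)
}
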