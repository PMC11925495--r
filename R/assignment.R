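# Bin-to-cell transcript imputation.
#
# Terminology: a bin is "unique" if it overlaps exactly one cell outline,
# "shared" if it overlaps two or more. All strategies assign unique bins
# wholly to their single cell by summing; they differ only in how shared
# bins are split:
#   naive             - shared bins are discarded,
#   weight_by_area    - split proportionally to intersection area,
#   weight_by_gene    - split per gene, proportionally to each candidate
#                       cell's unique-bin expression profile (smoothed by a
#                       pseudocount),
#   weight_by_cluster - as weight_by_gene but profiles are replaced by the
#                       mean profile of each cell's expression cluster.
# Whenever every candidate's smoothed profile mass for a gene is equal
# (ties, or all-zero profiles), the split falls back to area weights, so
# per-(bin, gene) weights always sum to one and transcript mass over shared
# bins is conserved.

.run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic largest-remainder apportionment of integer total n to
# weights w (sum 1). Ties in remainder broken by candidate order, which the
# caller fixes to cell-ID order.
.largest_remainder <- function(n, w) {
  shares <- w * n
  fl <- floor(shares)
  left <- as.integer(round(n - sum(fl)))
  if (left > 0L) {
    ord <- order(shares - fl, decreasing = TRUE)
    fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  }
  fl
}

# Shared-bin splitting engine. `profiles` is a cells x genes reference
# matrix (NULL means pure area weighting). Returns a cells x genes sparse
# matrix of the shared-bin contributions.
.split_shared_bins <- function(grid, rec, bi, ci, n_cells, profiles,
                               pseudocount, keep_fractional) {
  n_genes <- ncol(grid@counts)
  if (nrow(rec) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_cells, n_genes)))
  }
  # area fallback weights per record
  asum <- stats::ave(rec$area, bi, FUN = sum)
  w_area <- rec$area / asum
  sb <- sort(unique(bi))
  rb <- match(bi, sb)                      # record -> shared-bin slot
  recs_by_bin <- split(seq_len(nrow(rec)), rb)
  X <- grid@counts[sb, , drop = FALSE]
  Xp <- X@p
  Xi <- X@i
  Xx <- X@x
  ti <- tj <- tx <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    k <- (Xp[g] + 1L):Xp[g + 1L]
    if (Xp[g + 1L] == Xp[g]) next
    rows <- Xi[k] + 1L
    vals <- Xx[k]
    sel <- recs_by_bin[as.character(rows)]
    lens <- lengths(sel)
    sel <- unlist(sel, use.names = FALSE)
    grp <- rep(seq_along(rows), lens)     # record -> position in `rows`
    if (is.null(profiles)) {
      w <- w_area[sel]
    } else {
      num <- profiles[ci[sel], g] + pseudocount
      gmax <- vapply(split(num, grp), max, numeric(1L))
      gmin <- vapply(split(num, grp), min, numeric(1L))
      tie <- (gmax - gmin) <= 1e-12
      den <- vapply(split(num, grp), sum, numeric(1L))
      w <- ifelse(tie[grp] | den[grp] <= 0, w_area[sel], num / den[grp])
    }
    contrib <- w * vals[grp]
    if (!keep_fractional) {
      pieces <- split(seq_along(sel), grp)
      for (p in seq_along(pieces)) {
        ii <- pieces[[p]]
        contrib[ii] <- .largest_remainder(vals[p], w[ii] / sum(w[ii]))
      }
    }
    nz <- contrib > 0
    ti[[g]] <- ci[sel][nz]
    tj[[g]] <- rep.int(g, sum(nz))
    tx[[g]] <- contrib[nz]
  }
  Matrix::sparseMatrix(
    i = unlist(ti, use.names = FALSE), j = unlist(tj, use.names = FALSE),
    x = unlist(tx, use.names = FALSE), dims = c(n_cells, n_genes)
  )
}

.assign_core <- function(grid, overlaps, cells, strategy,
                         pseudocount = 1, nClusters = 4L, seed = 1L,
                         keepFractional = TRUE) {
  stopifnot(methods::is(grid, "BinGrid"), methods::is(overlaps, "OverlapTable"),
            methods::is(cells, "CellOutlines"))
  if (pseudocount < 0) .stopf("pseudocount must be >= 0")
  r <- overlaps@records
  bi <- match(r$bin_id, grid@binIDs)
  if (anyNA(bi)) .stopf("overlap table references bins absent from the grid")
  ci <- match(r$cell_id, cells@cellIDs)
  if (anyNA(ci)) .stopf("overlap table references cells absent from the outlines")
  n_cells <- length(cells)
  n_genes <- ncol(grid@counts)
  deg <- tabulate(bi, nbins = nBins(grid))[bi]     # candidates per record's bin
  uniq <- which(deg == 1L)
  shared <- which(deg > 1L)

  # unique bins: full counts to their single cell
  W <- Matrix::sparseMatrix(i = bi[uniq], j = ci[uniq], x = 1,
                            dims = c(nBins(grid), n_cells))
  naive_vals <- .as_dgc(Matrix::t(W) %*% grid@counts)

  vals <- switch(strategy,
    naive = naive_vals,
    weight_by_area = naive_vals + .split_shared_bins(
      grid, r[shared, , drop = FALSE], bi[shared], ci[shared], n_cells,
      profiles = NULL, pseudocount = 0, keep_fractional = keepFractional
    ),
    weight_by_gene = naive_vals + .split_shared_bins(
      grid, r[shared, , drop = FALSE], bi[shared], ci[shared], n_cells,
      profiles = naive_vals, pseudocount = pseudocount,
      keep_fractional = keepFractional
    ),
    weight_by_cluster = {
      profiles <- .cluster_profiles(naive_vals, nClusters, seed)
      naive_vals + .split_shared_bins(
        grid, r[shared, , drop = FALSE], bi[shared], ci[shared], n_cells,
        profiles = profiles, pseudocount = pseudocount,
        keep_fractional = keepFractional
      )
    },
    .stopf("unknown strategy '%s'", strategy)
  )
  contributing <- if (strategy == "naive") uniq else seq_len(nrow(r))
  nb <- tabulate(ci[contributing], nbins = n_cells)
  CellByGeneMatrix(
    values = .as_dgc(vals), cellIDs = cells@cellIDs,
    geneNames = grid@geneNames, centroids = cells@centroids,
    strategy = strategy, nBinsPerCell = nb
  )
}

# Cluster the naive profiles (counts-per-total, log1p, PCA, k-means) and
# return a cells x genes matrix of cluster-mean profiles; cells with empty
# naive profiles keep an all-zero reference row.
.cluster_profiles <- function(naive_vals, nClusters, seed) {
  nClusters <- as.integer(nClusters)
  if (nClusters < 1L) .stopf("n_clusters must be >= 1")
  totals <- Matrix::rowSums(naive_vals)
  nz <- which(totals > 0)
  if (length(nz) < nClusters) {
    .stopf(paste0(
      "only %d cells have nonzero unique-bin profiles but n_clusters = %d; ",
      "reduce n_clusters"
    ), length(nz), nClusters)
  }
  M <- as.matrix(naive_vals[nz, , drop = FALSE] / totals[nz])
  L <- log1p(M)
  ncomp <- max(1L, min(50L, ncol(L) - 1L, length(nz) - 1L))
  cl <- .run_with_seed(seed, {
    pc <- prcomp(L, center = TRUE, scale. = FALSE, rank. = ncomp)
    if (nClusters == 1L) {
      rep(1L, length(nz))
    } else {
      kmeans(pc$x, centers = nClusters, nstart = 10L, iter.max = 100L)$cluster
    }
  })
  means <- rowsum(L, cl) / as.vector(table(cl))
  out <- matrix(0, nrow(naive_vals), ncol(naive_vals))
  out[nz, ] <- means[cl, , drop = FALSE]
  out
}

#' Assign bin counts to cells
#'
#' Converts bin-level transcript counts into a cell-by-gene matrix under one
#' of four imputation strategies. Bins overlapping exactly one cell always
#' contribute their full counts to that cell (a summing aggregation); the
#' strategies differ in the treatment of bins shared between cells — see
#' [assignNaive()], [assignWeightByArea()], [assignWeightByGene()] and
#' [assignWeightByCluster()].
#'
#' @param grid a [BinGrid-class] (typically after [filterOrphanBins()]).
#' @param overlaps the [OverlapTable-class] from [spatialJoin()].
#' @param cells the [CellOutlines-class] used in the join; defines the cell
#'   universe (cells with no overlapping bins are retained as zero rows) and
#'   supplies centroids.
#' @param strategy one of `"naive"`, `"weight_by_area"`, `"weight_by_gene"`,
#'   `"weight_by_cluster"`.
#' @param pseudocount smoothing added to profile mass in the expression- and
#'   cluster-weighted strategies (default 1); guards genes unseen in unique
#'   bins from degenerate all-or-nothing splits.
#' @param nClusters number of k-means clusters for `weight_by_cluster`.
#' @param seed RNG seed for the clustering step; all other strategies are
#'   seed-free.
#' @param keepFractional keep weighted splits as real numbers (default). If
#'   `FALSE`, each shared bin's counts are apportioned to whole transcripts
#'   by deterministic largest-remainder rounding.
#' @return A [CellByGeneMatrix-class].
#' @export
assignBins <- function(grid, overlaps, cells,
                       strategy = c("weight_by_area", "naive",
                                    "weight_by_gene", "weight_by_cluster"),
                       pseudocount = 1, nClusters = 4L, seed = 1L,
                       keepFractional = TRUE) {
  strategy <- match.arg(strategy)
  .assign_core(grid, overlaps, cells, strategy,
               pseudocount = pseudocount, nClusters = nClusters, seed = seed,
               keepFractional = keepFractional)
}

#' Naive assignment: unique bins only
#'
#' Each bin overlapping exactly one cell contributes its full counts to that
#' cell; bins shared between cells are omitted entirely. Maximises precision
#' at the cost of recall wherever cells are tightly packed.
#'
#' @inheritParams assignBins
#' @return A [CellByGeneMatrix-class] with integer-valued entries.
#' @export
assignNaive <- function(grid, overlaps, cells) {
  .assign_core(grid, overlaps, cells, "naive")
}

#' Area-weighted assignment
#'
#' Splits each shared bin's counts across its overlapping cells in
#' proportion to the bin-cell intersection areas; weights per bin sum to 1.
#'
#' @inheritParams assignBins
#' @return A [CellByGeneMatrix-class] (fractional unless `keepFractional =
#'   FALSE`).
#' @export
assignWeightByArea <- function(grid, overlaps, cells, keepFractional = TRUE) {
  .assign_core(grid, overlaps, cells, "weight_by_area",
               keepFractional = keepFractional)
}

#' Expression-weighted assignment
#'
#' Two passes: unique bins build each cell's reference profile (the naive
#' assignment); each shared bin's counts are then split per gene in
#' proportion to the candidate cells' smoothed profile mass for that gene.
#' When all candidates tie (including all-zero profiles), the split falls
#' back to area weights.
#'
#' @inheritParams assignBins
#' @return A [CellByGeneMatrix-class].
#' @export
assignWeightByGene <- function(grid, overlaps, cells, pseudocount = 1,
                               keepFractional = TRUE) {
  .assign_core(grid, overlaps, cells, "weight_by_gene",
               pseudocount = pseudocount, keepFractional = keepFractional)
}

#' Cluster-weighted assignment
#'
#' Clusters the naive cell profiles (counts-per-total normalisation, log1p,
#' PCA to at most 50 components, k-means with a fixed seed) and splits each
#' shared bin's counts per gene in proportion to the candidate cells'
#' cluster-mean profile mass, with the same area-weight fallback on ties.
#'
#' @inheritParams assignBins
#' @return A [CellByGeneMatrix-class].
#' @export
assignWeightByCluster <- function(grid, overlaps, cells, nClusters = 4L,
                                  pseudocount = 1, seed = 1L,
                                  keepFractional = TRUE) {
  .assign_core(grid, overlaps, cells, "weight_by_cluster",
               pseudocount = pseudocount, nClusters = nClusters, seed = seed,
               keepFractional = keepFractional)
}
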