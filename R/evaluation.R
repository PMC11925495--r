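# Evaluation against ground truth: transcript-level precision/recall/F1,
# multi-class annotation metrics, and overlap diagnostics.

# Element-wise minimum of two non-negative sparse matrices:
# min(a, b) = a - max(a - b, 0), computed on the nonzero slot only.
.sparse_pmin <- function(a, b) {
  d <- .as_dgc(a - b)
  if (length(d@x)) d@x <- pmax(d@x, 0)
  .as_dgc(a - d)
}

.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

.aligned_pair <- function(pred, truth) {
  pm <- if (methods::is(pred, "CellByGeneMatrix")) cellCounts(pred) else .as_dgc(pred)
  tm <- if (methods::is(truth, "CellByGeneMatrix")) cellCounts(truth) else .as_dgc(truth)
  if (is.null(rownames(pm)) || is.null(rownames(tm))) {
    .stopf("pred and truth must carry cell IDs as row names")
  }
  if (!length(intersect(rownames(pm), rownames(tm)))) {
    .stopf("pred and truth share no cell IDs; likely an ID scheme mismatch")
  }
  cells <- union(rownames(pm), rownames(tm))
  genes <- union(colnames(pm), colnames(tm))
  expand <- function(m) {
    out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(cells), length(genes)),
                                dimnames = list(cells, genes))
    out[rownames(m), colnames(m)] <- m
    out
  }
  list(pred = expand(pm), truth = expand(tm))
}

#' Transcript-level assignment metrics
#'
#' Scores a predicted cell-by-gene matrix against ground truth using a
#' mass-overlap definition that handles fractional predictions: per (cell,
#' gene) pair, the true-positive mass is `min(pred, truth)`; FP is predicted
#' mass in excess of truth and FN is true mass not predicted. For integer
#' matrices this reduces to per-molecule counting. Cell and gene universes
#' are outer-aligned with zeros; 0/0 ratios are defined as 0.
#'
#' @param pred predicted [CellByGeneMatrix-class] (or a cells x genes matrix
#'   with dimnames).
#' @param truth ground-truth matrix, e.g. from [trueCellMatrix()]; pass the
#'   nucleus-mode tally for nucleus evaluation.
#' @param mode label recorded in the result: `"whole_cell"` or `"nucleus"`.
#' @param pooling `"global"` pools TP/FP/FN over all (cell, gene) pairs;
#'   `"per_cell"` computes precision/recall per cell and averages over cells
#'   with any true or predicted mass.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, `mode`,
#'   `pooling`.
#' @export
transcriptAssignmentMetrics <- function(pred, truth,
                                        mode = c("whole_cell", "nucleus"),
                                        pooling = c("global", "per_cell")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  al <- .aligned_pair(pred, truth)
  tp_m <- .sparse_pmin(al$pred, al$truth)
  if (pooling == "global") {
    tp <- sum(tp_m)
    fp <- sum(al$pred) - tp
    fn <- sum(al$truth) - tp
    out <- .prf(tp, fp, fn)
    return(c(list(tp = tp, fp = fp, fn = fn), out,
             list(mode = mode, pooling = pooling)))
  }
  tpc <- Matrix::rowSums(tp_m)
  pc <- Matrix::rowSums(al$pred)
  tc <- Matrix::rowSums(al$truth)
  use <- pc > 0 | tc > 0
  prec <- ifelse(pc[use] > 0, tpc[use] / pc[use], 0)
  rec <- ifelse(tc[use] > 0, tpc[use] / tc[use], 0)
  precision <- mean(prec)
  recall <- mean(rec)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = sum(tpc), fp = sum(pc) - sum(tpc), fn = sum(tc) - sum(tpc),
       precision = precision, recall = recall, f1 = f1,
       mode = mode, pooling = pooling)
}

#' Multi-class annotation metrics
#'
#' Assesses predicted labels as a multi-class classifier: confusion matrix
#' over the union of label sets (true labels as rows), overall accuracy,
#' per-class precision/recall/F1 and their weighted averages (weights =
#' true-class supports). `"Unknown"` is a legitimate predicted class.
#'
#' @param pred a [CellAnnotation-class] or named character vector of
#'   predicted labels.
#' @param truth named character vector of true labels over the same cells.
#' @return list with `accuracy`, `per_class` (data.frame), `weighted`
#'   (precision/recall/f1), `confusion` (true x predicted matrix), `n`.
#' @export
annotationMetrics <- function(pred, truth) {
  if (methods::is(pred, "CellAnnotation")) pred <- cellLabels(pred)
  if (length(pred) == 0L || length(truth) == 0L) .stopf("empty label input")
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth))) {
      .stopf("pred and truth must cover the same cells")
    }
    truth <- truth[names(pred)]
  }
  if (length(pred) != length(truth)) .stopf("pred and truth lengths differ")
  levs <- sort(union(unique(pred), unique(truth)))
  confusion <- table(
    factor(truth, levels = levs),
    factor(pred, levels = levs),
    dnn = c("true", "predicted")
  )
  confusion <- unclass(confusion)
  n <- sum(confusion)
  accuracy <- sum(diag(confusion)) / n
  support <- rowSums(confusion)
  per_class <- do.call(rbind, lapply(seq_along(levs), function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[, k]) - tp
    fn <- sum(confusion[k, ]) - tp
    m <- .prf(tp, fp, fn)
    data.frame(class = levs[k], support = support[k],
               precision = m$precision, recall = m$recall, f1 = m$f1)
  }))
  rownames(per_class) <- NULL
  w <- support / sum(support)
  weighted <- list(
    precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f1 = sum(w * per_class$f1)
  )
  list(accuracy = accuracy, per_class = per_class, weighted = weighted,
       confusion = confusion, n = n)
}

#' Overlap diagnostics
#'
#' Summarises the spatial join: how many bins intersect at least one cell,
#' how many are shared between two or more, the shared fraction among
#' overlapping bins (the key difficulty parameter separating dense from
#' sparse tissue), and the per-cell distribution of distinct overlapping
#' bins.
#'
#' @param overlaps an [OverlapTable-class].
#' @param grid the [BinGrid-class] the join was computed on.
#' @return list with `n_bins_total`, `n_bins_overlapping`, `n_bins_shared`,
#'   `shared_fraction` (0 when no bin overlaps), and `bins_per_cell`
#'   (named integer vector).
#' @export
overlapStatistics <- function(overlaps, grid) {
  stopifnot(methods::is(overlaps, "OverlapTable"), methods::is(grid, "BinGrid"))
  r <- overlaps@records
  per_bin <- table(r$bin_id)
  n_over <- length(per_bin)
  n_shared <- sum(per_bin > 1L)
  list(
    n_bins_total = nBins(grid),
    n_bins_overlapping = n_over,
    n_bins_shared = n_shared,
    shared_fraction = if (n_over > 0L) n_shared / n_over else 0,
    bins_per_cell = vapply(split(r$bin_id, r$cell_id),
                           function(b) length(unique(b)), integer(1L))
  )
}
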