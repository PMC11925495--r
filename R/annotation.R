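#' Score cell types from marker genes
#'
#' A transparent marker-score annotator: each cell's profile is normalised
#' to counts-per-total and log1p-transformed, every gene is z-scored across
#' cells (population standard deviation with a 1e-8 guard for constant
#' genes), and each type's score is the mean z-score of its marker genes.
#' The label is the top-scoring type; cells whose total counts fall below
#' `minCounts`, or whose top two scores tie exactly, are labelled
#' `"Unknown"`. Confidence is the top score minus the runner-up.
#'
#' Markers absent from the gene universe are dropped with a warning; a type
#' whose markers are all absent is dropped with a warning; if no marker of
#' any type is present, this is an error.
#'
#' @param m a [CellByGeneMatrix-class].
#' @param markers named list mapping cell type to marker genes (see
#'   [readMarkerSet()]).
#' @param minCounts minimum total transcript count for a call (default 5;
#'   per-cell totals in 2 um-bin data are low, so some floor is needed).
#' @return A [CellAnnotation-class].
#' @export
scoreCellTypes <- function(m, markers, minCounts = 5) {
  stopifnot(methods::is(m, "CellByGeneMatrix"))
  validateMarkerSet(markers)
  genes <- m@geneNames
  present <- lapply(markers, intersect, y = genes)
  missing <- mapply(setdiff, markers, present, SIMPLIFY = FALSE)
  if (any(lengths(missing) > 0L)) {
    .warnf("markers absent from the gene universe dropped: %s",
           paste(unique(unlist(missing)), collapse = ", "))
  }
  empty <- lengths(present) == 0L
  if (all(empty)) .stopf("no marker of any cell type is present in the gene universe")
  if (any(empty)) {
    .warnf("cell type(s) with no present markers dropped: %s",
           paste(names(markers)[empty], collapse = ", "))
    present <- present[!empty]
  }
  vals <- m@values
  totals <- Matrix::rowSums(vals)
  prop <- vals
  pos <- totals > 0
  if (any(pos)) prop[pos, ] <- vals[pos, , drop = FALSE] / totals[pos]
  L <- log1p(as.matrix(prop))
  mu <- colMeans(L)
  sdev <- sqrt(colMeans(sweep(L, 2L, mu)^2))   # population SD
  Z <- sweep(sweep(L, 2L, mu), 2L, sdev + 1e-8, "/")
  scores <- vapply(present, function(g) {
    rowMeans(Z[, match(g, genes), drop = FALSE])
  }, numeric(nrow(Z)))
  if (nrow(Z) == 1L) scores <- matrix(scores, nrow = 1L, dimnames = list(NULL, names(present)))
  labels <- character(nrow(scores))
  conf <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    s <- sort(scores[i, ], decreasing = TRUE)
    conf[i] <- if (length(s) > 1L) s[1L] - s[2L] else s[1L]
    tied <- length(s) > 1L && (s[1L] - s[2L]) <= 1e-12
    labels[i] <- if (totals[i] < minCounts || tied) "Unknown" else names(s)[1L]
  }
  CellAnnotation(m@cellIDs, labels, scores, conf)
}

#' Map fine labels to coarse classes
#'
#' Replaces each fine label by its coarse class (e.g. collapsing granular
#' types into Epithelial / Stromal / Immune for comparison with
#' pathologist-level annotations). Fine labels absent from the mapping get
#' `default`; `"Unknown"` is never remapped. Scores and confidence are
#' preserved, so the operation is idempotent on already-coarse labels that
#' map to themselves.
#'
#' @param a a [CellAnnotation-class].
#' @param mapping named character vector, fine label to coarse label (see
#'   [readLabelMapping()]).
#' @param default coarse label for unmapped fine labels.
#' @return A [CellAnnotation-class] with coarse labels.
#' @export
mapToCoarseLabels <- function(a, mapping, default = "Unknown") {
  stopifnot(methods::is(a, "CellAnnotation"))
  lab <- a@labels
  mapped <- unname(mapping[lab])
  mapped[is.na(mapped)] <- default
  mapped[lab == "Unknown"] <- "Unknown"
  CellAnnotation(a@cellIDs, mapped, a@scores, a@confidence)
}
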