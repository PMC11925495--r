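#' @importFrom utils head tail read.csv write.csv read.delim
#' @importFrom stats kmeans prcomp runif rnorm sd setNames
NULL

.stopf <- function(fmt, ..., class = "BinToCell_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Structured per-stage logging; suppressed below the chosen level.
.log_levels <- c(debug = 10L, info = 20L, warn = 30L, quiet = 100L)

.log <- function(level, fmt, ..., verbose = getOption("BinToCell.log", "info")) {
  if (.log_levels[[level]] >= .log_levels[[verbose]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

# Area tolerance: intersections below this are slivers from polygon repair
# and are treated as empty.
.AREA_TOL <- 1e-9

.as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
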