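# Covariation analysis of multiplexed per-cell counts: total-count
# normalization, Pearson correlation distance, and average-linkage
# hierarchical clustering into gene groups.

#' Normalize per-cell counts to total expression
#'
#' Divides each cell's counts by that cell's total, so rows sum to 1. Cells
#' with zero total are dropped with a warning.
#'
#' @param counts cells x targets matrix of non-negative counts.
#' @return normalized matrix with unit row sums.
#' @export
normalizeCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- rowSums(counts)
  if (all(tot == 0)) stop("all cells have zero total counts")
  if (any(tot == 0)) {
    warning(sprintf("dropping %d cell(s) with zero total counts",
                    sum(tot == 0)))
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  counts / tot
}

#' Correlation-distance hierarchical clustering of targets
#'
#' Pearson correlation of each target pair across cells; distance defined as
#' one minus the correlation coefficient; agglomerative clustering with
#' average linkage; tree cut at `nGroups` groups.
#'
#' @param normalized cells x targets matrix (typically from
#'   [normalizeCounts()]).
#' @param nGroups number of gene groups to cut the tree into.
#' @param dropConstant drop zero-variance targets instead of erroring.
#' @return list of class `"ClusterResult"` with `distance` (targets x
#'   targets, `1 - r`), `tree` (an [stats::hclust] object, average linkage),
#'   `groups` (named integer vector) and `dropped` (names of any dropped
#'   constant targets).
#' @examples
#' sim <- simulateCounts(nCells = 50, nTargets = 6,
#'                       groups = rep(1:2, each = 3), seed = 1)
#' cr <- correlationClustering(normalizeCounts(sim$counts), nGroups = 2)
#' cr$groups
#' @export
correlationClustering <- function(normalized, nGroups,
                                  dropConstant = FALSE) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) < 2) stop("need at least 2 targets")
  if (nrow(normalized) < 3) stop("need at least 3 cells")
  if (anyDuplicated(colnames(normalized))) stop("duplicate target names")
  v <- apply(normalized, 2, stats::var)
  dropped <- character()
  if (any(v == 0)) {
    if (!dropConstant)
      stop("constant target column(s): ",
           paste(colnames(normalized)[v == 0], collapse = ", "),
           " (correlation undefined; set dropConstant = TRUE to drop)")
    dropped <- colnames(normalized)[v == 0]
    normalized <- normalized[, v > 0, drop = FALSE]
    if (ncol(normalized) < 2) stop("fewer than 2 non-constant targets")
  }
  if (nGroups < 1 || nGroups > ncol(normalized))
    stop("nGroups must be between 1 and the number of targets")
  r <- stats::cor(normalized)
  d <- 1 - r
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- stats::cutree(tree, k = nGroups)
  structure(list(distance = d, tree = tree, groups = groups,
                 nGroups = nGroups, dropped = dropped),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d targets in %d groups (average linkage, 1 - Pearson r)\n",
              ncol(x$distance), x$nGroups))
  print(split(names(x$groups), x$groups))
  invisible(x)
}
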