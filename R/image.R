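# smFISH image quantification: maximum projection, threshold-based puncta
# detection, two-channel colocalization, per-cell counting with expression
# filters, and multi-round overlay reconstruction.
#
# Conventions: images are numeric matrices (row, col); coordinates are
# 0-based (row, col) pixel positions; cell masks are integer label images
# with 0 = background.

#' Maximum intensity projection of an image stack
#'
#' @param stack 3-D numeric array (rows x cols x planes) or a 2-D matrix
#'   (returned unchanged).
#' @return 2-D matrix of per-pixel maxima over planes.
#' @export
maxZProjection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3)
    stop("stack must be a 2-D matrix or a 3-D array")
  if (dim(stack)[3] < 1) stop("stack has no planes")
  out <- stack[, , 1]
  for (k in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , k])
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so diagonal-touching
# components are merged afterwards with a union-find over label adjacency.
.label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin * 1)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(bin))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0] <- dense[lab[lab > 0]]
  lab
}

#' Detect fluorescent puncta in a 2-D image
#'
#' Binarizes the image at a signal threshold (by default the image mean plus
#' `k` standard deviations), labels 8-connected foreground components, and
#' keeps components with at least `minAreaPx` pixels. Each punctum carries
#' its centroid (0-based row/col), pixel area, and intensity — the maximum
#' value over all pixels the punctum covers. Puncta touching the image
#' border are retained.
#'
#' @param image 2-D numeric matrix with finite values.
#' @param threshold absolute intensity threshold; when `NULL` (default) the
#'   `mean + k * sd` rule is used.
#' @param k multiplier for the adaptive threshold (default 5).
#' @param minAreaPx minimum component area in pixels (default 2).
#' @return data.frame with columns `row`, `col`, `area`, `intensity`; the
#'   threshold used is attached as attribute `"threshold"`.
#' @export
detectPuncta <- function(image, threshold = NULL, k = 5, minAreaPx = 2) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  if (!all(is.finite(image))) stop("image must be finite-valued")
  if (is.null(threshold))
    threshold <- mean(image) + k * stats::sd(image)
  bin <- image > threshold
  empty <- data.frame(row = numeric(), col = numeric(), area = integer(),
                      intensity = numeric())
  if (!any(bin)) return(structure(empty, threshold = threshold))
  lab <- .label8(bin)
  idx <- which(lab > 0)
  ids <- lab[idx]
  rows0 <- (idx - 1) %% nrow(image)        # 0-based row
  cols0 <- (idx - 1) %/% nrow(image)       # 0-based col
  area <- tabulate(ids)
  keep <- which(area >= minAreaPx)
  if (!length(keep)) return(structure(empty, threshold = threshold))
  out <- data.frame(
    row = as.numeric(tapply(rows0, ids, mean)[as.character(keep)]),
    col = as.numeric(tapply(cols0, ids, mean)[as.character(keep)]),
    area = area[keep],
    intensity = as.numeric(tapply(image[idx], ids, max)[as.character(keep)]))
  rownames(out) <- NULL
  structure(out[order(out$row, out$col), , drop = FALSE],
            threshold = threshold)
}

#' Colocalize two puncta lists
#'
#' One-to-one matching by greedy global nearest distance: candidate pairs
#' within `radiusPx` are sorted by distance (ties broken by the first list's
#' row, then col) and assigned greedily, each punctum used at most once.
#' Fractions are reported per channel over that channel's total, so
#' `only + both = 100` within each channel.
#'
#' @param a,b data.frames with `row`/`col` columns (as from
#'   [detectPuncta()]).
#' @param radiusPx matching radius in pixels (default 2).
#' @return list with `matches` (data.frame of indices and distance), counts
#'   `nA`, `nB`, `nBoth`, and percentages `pctBothA`, `pctOnlyA`,
#'   `pctBothB`, `pctOnlyB` (`NA` for an empty channel).
#' @export
colocalize <- function(a, b, radiusPx = 2) {
  if (radiusPx <= 0) stop("radiusPx must be positive")
  nA <- nrow(a); nB <- nrow(b)
  matches <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (nA > 0 && nB > 0) {
    d <- sqrt(outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2)
    cand <- which(d <= radiusPx, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], a$row[cand[, 1]], a$col[cand[, 1]],
                   b$row[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      usedA <- logical(nA); usedB <- logical(nB)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!usedA[i] && !usedB[j]) {
          usedA[i] <- TRUE; usedB[j] <- TRUE
          matches <- rbind(matches,
                           data.frame(i = i, j = j, dist = d[i, j]))
        }
      }
    }
  }
  nBoth <- nrow(matches)
  pct <- function(x, n) if (n > 0) 100 * x / n else NA_real_
  list(matches = matches, nA = nA, nB = nB, nBoth = nBoth,
       pctBothA = pct(nBoth, nA), pctOnlyA = pct(nA - nBoth, nA),
       pctBothB = pct(nBoth, nB), pctOnlyB = pct(nB - nBoth, nB),
       radiusPx = radiusPx)
}

#' Per-cell puncta counts
#'
#' Assigns each punctum to the cell label under its (rounded) centroid.
#' Puncta over background (label 0) are excluded from all cells and tallied
#' separately, so total detections are conserved:
#' `sum(counts) + sum(background) = total puncta`.
#'
#' @param puncta a named list of puncta data.frames, one per target.
#' @param mask integer label matrix (0 = background) with the image's shape.
#' @return integer matrix cells x targets, with the per-target background
#'   tallies attached as attribute `"background"`.
#' @export
perCellCounts <- function(puncta, mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.data.frame(puncta)) puncta <- list(target = puncta)
  if (is.null(names(puncta)) || any(names(puncta) == ""))
    stop("puncta list must be named by target")
  cells <- sort(unique(mask[mask > 0]))
  counts <- matrix(0L, nrow = length(cells), ncol = length(puncta),
                   dimnames = list(paste0("cell_", cells), names(puncta)))
  background <- stats::setNames(integer(length(puncta)), names(puncta))
  for (t in seq_along(puncta)) {
    p <- puncta[[t]]
    if (nrow(p) == 0) next
    r <- round(p$row) + 1; c <- round(p$col) + 1
    if (any(r < 1 | r > nrow(mask) | c < 1 | c > ncol(mask)))
      stop("punctum centroid outside the mask frame")
    lab <- mask[cbind(r, c)]
    background[t] <- sum(lab == 0)
    tab <- table(factor(lab[lab > 0], levels = cells))
    counts[, t] <- as.integer(tab)
  }
  structure(counts, background = background)
}

#' Exclude low-expression cells per target
#'
#' For targets classed `"high"`, cells with fewer than `thresholds["high"]`
#' copies (default 5) are excluded; for `"low"` targets, cells with fewer
#' than `thresholds["low"]` copies (default 2). Excluded cell/target entries
#' become `NA`; cells excluded for every target are dropped.
#'
#' @param counts cells x targets count matrix.
#' @param targetClass named character vector (`"high"`/`"low"`) covering
#'   every column of `counts`.
#' @param thresholds named numeric vector with elements `high` and `low`.
#' @return the filtered matrix (possibly with zero rows).
#' @export
filterCells <- function(counts, targetClass,
                        thresholds = c(high = 5, low = 2)) {
  if (!all(colnames(counts) %in% names(targetClass)))
    stop("every target needs a class")
  cls <- targetClass[colnames(counts)]
  if (!all(cls %in% c("high", "low")))
    stop("unknown target class; use 'high' or 'low'")
  out <- counts
  for (j in seq_len(ncol(out))) {
    cut <- thresholds[[cls[j]]]
    out[out[, j] < cut, j] <- NA
  }
  out[rowSums(!is.na(out)) > 0, , drop = FALSE]
}

#' Combine puncta from all rounds and fluors into one coordinate table
#'
#' All rounds share one coordinate frame (sequential on-scope imaging needs
#' no registration), so reconstruction is a concatenation.
#'
#' @param punctaList list of puncta data.frames.
#' @param target,round,fluor per-element annotations (recycled if length 1).
#' @return data.frame with columns `row`, `col`, `target`, `round`, `fluor`,
#'   `intensity`.
#' @export
overlayReconstruction <- function(punctaList, target = names(punctaList),
                                  round = seq_along(punctaList),
                                  fluor = "fluor1") {
  n <- length(punctaList)
  empty <- data.frame(row = numeric(), col = numeric(),
                      target = character(), round = integer(),
                      fluor = character(), intensity = numeric())
  if (n == 0) return(empty)
  if (is.null(target)) target <- paste0("target_", seq_len(n))
  target <- rep_len(target, n)
  round <- rep_len(round, n)
  fluor <- rep_len(fluor, n)
  parts <- lapply(seq_len(n), function(k) {
    p <- punctaList[[k]]
    if (nrow(p) == 0) return(empty)
    data.frame(row = p$row, col = p$col, target = target[k],
               round = round[k], fluor = fluor[k],
               intensity = if ("intensity" %in% names(p)) p$intensity
                           else NA_real_)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
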