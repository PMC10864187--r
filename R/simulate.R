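# Seeded generators: synthetic multi-channel spot images with ground truth,
# and per-cell count matrices with planted correlation-block structure.
# Every generator is pure given its arguments and seed.

# render isotropic Gaussian spots into an image (rows x cols), positions
# 0-based; amplitude is the peak height above background
.renderSpots <- function(shape, rows, cols, amplitude, psfSigmaPx) {
  img <- matrix(0, shape[1], shape[2])
  if (length(rows) == 0) return(img)
  w <- ceiling(4 * psfSigmaPx)
  for (s in seq_along(rows)) {
    r0 <- rows[s]; c0 <- cols[s]
    rr <- max(0, floor(r0 - w)):min(shape[1] - 1, ceiling(r0 + w))
    cc <- max(0, floor(c0 - w)):min(shape[2] - 1, ceiling(c0 + w))
    g <- amplitude *
      exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * psfSigmaPx^2))
    img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + g
  }
  img
}

# rectangular tile label mask
.tileMask <- function(shape, nCells) {
  rows <- ceiling(seq_len(shape[1]) / (shape[1] / nCells[1]))
  cols <- ceiling(seq_len(shape[2]) / (shape[2] / nCells[2]))
  matrix((rows - 1) * nCells[2], shape[1], shape[2]) +
    matrix(cols, shape[1], shape[2], byrow = TRUE)
}

#' Simulate multi-channel spot images with ground truth
#'
#' Spots are isotropic Gaussian puncta at random positions; a designated
#' fraction of channel-2 spots colocalize with channel-1 spots (sharing the
#' position up to at most 0.5 px of uniform jitter). Noise is Poisson on the
#' total signal plus Gaussian read noise. A rectangular-tile cell mask is
#' included. Identical seeds give identical outputs.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param nSpots spots per channel (scalar, recycled over channels).
#' @param nChannels number of channels (default 1; colocalization requires
#'   2).
#' @param psfSigmaPx Gaussian spot sigma in px.
#' @param amplitude peak spot amplitude above background.
#' @param background mean background level.
#' @param readNoiseSD Gaussian read-noise standard deviation.
#' @param colocFraction fraction of channel-2 spots colocalized with
#'   channel-1 spots.
#' @param minSeparationPx minimum center-to-center distance enforced between
#'   spots of one channel (0 disables; used for detection benchmarks).
#' @param nCells cell-mask tiling `c(rows, cols)`.
#' @param seed RNG seed (mandatory).
#' @return list with `images` (list of matrices), `truth` (data.frame:
#'   `channel`, `row`, `col`, `coloc`), `mask` (label matrix) and `crowded`
#'   (TRUE when expected spot overlaps exceed ~5% of spots).
#' @export
simulateSpotImages <- function(shape = c(256, 256), nSpots = 50,
                               nChannels = 1, psfSigmaPx = 1.5,
                               amplitude = 100, background = 100,
                               readNoiseSD = 2, colocFraction = 0,
                               minSeparationPx = 0, nCells = c(2, 2),
                               seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(shape < 8)) stop("image too small")
  if (colocFraction < 0 || colocFraction > 1)
    stop("colocFraction must be in [0, 1]")
  if (colocFraction > 0 && nChannels < 2)
    stop("colocalization requires 2 channels")
  nSpots <- rep_len(nSpots, nChannels)
  .withSeed(seed, {
    drawPositions <- function(n) {
      rows <- numeric(0); cols <- numeric(0)
      guard <- 0
      while (length(rows) < n && guard < 50 * max(n, 1)) {
        guard <- guard + 1
        r <- stats::runif(1, 2, shape[1] - 3)
        c <- stats::runif(1, 2, shape[2] - 3)
        if (minSeparationPx > 0 && length(rows) &&
            min(sqrt((rows - r)^2 + (cols - c)^2)) < minSeparationPx) next
        rows <- c(rows, r); cols <- c(cols, c)
      }
      if (length(rows) < n)
        stop("could not place spots at the requested separation")
      cbind(rows, cols)
    }
    truth <- NULL
    positions <- vector("list", nChannels)
    for (ch in seq_len(nChannels)) {
      if (ch == 2 && colocFraction > 0) {
        nShared <- round(colocFraction * nSpots[2])
        nShared <- min(nShared, nrow(positions[[1]]))
        shared <- positions[[1]][seq_len(nShared), , drop = FALSE]
        jitter <- matrix(stats::runif(2 * nShared, -0.5, 0.5), ncol = 2)
        own <- if (nSpots[2] > nShared) drawPositions(nSpots[2] - nShared)
               else cbind(numeric(0), numeric(0))
        pos <- rbind(shared + jitter, own)
        coloc <- c(rep(TRUE, nShared), rep(FALSE, nSpots[2] - nShared))
      } else {
        pos <- drawPositions(nSpots[ch])
        coloc <- if (ch == 1 && colocFraction > 0 && nChannels >= 2)
          c(rep(TRUE, min(round(colocFraction * nSpots[2]), nSpots[1])),
            rep(FALSE, max(0, nSpots[1] - round(colocFraction * nSpots[2]))))
          else rep(FALSE, nSpots[ch])
        positions[[ch]] <- pos
      }
      truth <- rbind(truth, data.frame(channel = rep(ch, nrow(pos)),
                                       row = pos[, 1], col = pos[, 2],
                                       coloc = coloc))
    }
    images <- lapply(seq_len(nChannels), function(ch) {
      tr <- truth[truth$channel == ch, ]
      clean <- background +
        .renderSpots(shape, tr$row, tr$col, amplitude, psfSigmaPx)
      noisy <- matrix(stats::rpois(length(clean), lambda = clean),
                      nrow = shape[1]) +
        matrix(stats::rnorm(length(clean), sd = readNoiseSD),
               nrow = shape[1])
      noisy
    })
    area <- pi * (2 * psfSigmaPx)^2
    crowded <- max(nSpots) * area / prod(shape) > 0.05
    list(images = images, truth = truth,
         mask = .tileMask(shape, nCells), crowded = crowded)
  })
}

#' Simulate per-cell count matrices with planted correlation blocks
#'
#' A Gaussian-copula factor model: each cell draws one latent factor per
#' group; target `j` in group `g` gets
#' `x = sqrt(rho) z_g + sqrt(1 - rho) eps`, and counts are the
#' negative-binomial quantile transform of `pnorm(x)`. Targets in the same
#' group share the within-block correlation `rho`; targets in different
#' groups are uncorrelated.
#'
#' @param nCells number of cells.
#' @param nTargets number of targets.
#' @param groups integer vector of planted group labels, length `nTargets`.
#' @param rho latent within-group correlation in \[0, 1).
#' @param mu mean count per target (scalar or length `nTargets`).
#' @param size negative-binomial dispersion (larger = closer to Poisson).
#' @param seed RNG seed (mandatory).
#' @return list with `counts` (cells x targets integer matrix) and `groups`
#'   (the planted labels, named by target).
#' @export
simulateCounts <- function(nCells = 200, nTargets = 15,
                           groups = rep(1:4, length.out = 15), rho = 0.8,
                           mu = 30, size = 10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(groups) != nTargets)
    stop("groups must cover all targets")
  if (rho < 0 || rho >= 1)
    stop("rho must be in [0, 1) (the implied covariance is not positive definite otherwise)")
  mu <- rep_len(mu, nTargets)
  .withSeed(seed, {
    gid <- as.integer(factor(groups))
    z <- matrix(stats::rnorm(nCells * max(gid)), nCells, max(gid))
    eps <- matrix(stats::rnorm(nCells * nTargets), nCells, nTargets)
    x <- sqrt(rho) * z[, gid, drop = FALSE] + sqrt(1 - rho) * eps
    u <- stats::pnorm(x)
    counts <- vapply(seq_len(nTargets),
                     function(j) stats::qnbinom(u[, j], mu = mu[j],
                                                size = size),
                     numeric(nCells))
    counts <- matrix(as.integer(counts), nCells, nTargets)
    colnames(counts) <- paste0("target_", seq_len(nTargets))
    rownames(counts) <- paste0("cell_", seq_len(nCells))
    list(counts = counts,
         groups = stats::setNames(gid, colnames(counts)))
  })
}
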