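# Design-space scan over (Tmb, Tmq), crosstalk, and greedy channel selection.

#' Scan the (Tmb, Tmq) design space
#'
#' Computes the thermal-spectrum summaries (yield, signal temperature, full
#' width at half maximum) of the probe set at every combination of
#' barcode-domain and quencher-domain melting temperature, on a fine internal
#' spectrum grid. Cells with `Tmq > Tmb` are allowed; they simply have low
#' yield.
#'
#' @param tmbRangeC,tmqRangeC axis ranges in deg C (defaults 40-80 and 35-75).
#' @param stepC axis step in deg C (default 1).
#' @param concM,quencherExcess,saltMM,dHBarcode,dHQuencher model settings as
#'   in [thermalProbeSet()].
#' @param spectrumRangeC,spectrumStepC temperature grid for the underlying
#'   spectra (defaults 20-80 deg C at 0.1 deg C).
#' @return a [DesignGrid].
#' @examples
#' g <- gridScan(c(50, 60), c(40, 50), stepC = 5)
#' g@yieldMap
#' @export
gridScan <- function(tmbRangeC = c(40, 80), tmqRangeC = c(35, 75), stepC = 1,
                     concM = 250e-9, quencherExcess = 1.2, saltMM = 195,
                     dHBarcode = .DH_BARCODE, dHQuencher = .DH_QUENCHER,
                     spectrumRangeC = c(20, 80), spectrumStepC = 0.1) {
  if (stepC <= 0) stop("stepC must be positive")
  if (length(tmbRangeC) != 2 || length(tmqRangeC) != 2 ||
      tmbRangeC[1] > tmbRangeC[2] || tmqRangeC[1] > tmqRangeC[2])
    stop("axis ranges must be c(min, max) with min <= max")
  tmb <- seq(tmbRangeC[1], tmbRangeC[2], by = stepC)
  tmq <- seq(tmqRangeC[1], tmqRangeC[2], by = stepC)
  temps <- seq(spectrumRangeC[1], spectrumRangeC[2], by = spectrumStepC)
  tK <- temps + .C2K

  # occupancy matrices over the spectrum grid: one column per axis value
  thetaCols <- function(tmAxis, dH, c0) {
    dS <- dH * 1000 / (tmAxis + .C2K) - .RGAS * log(concM)
    lnK <- outer(-dH * 1000 / (.RGAS * tK), rep(1, length(tmAxis))) +
      matrix(dS / .RGAS, nrow = length(tK), ncol = length(tmAxis),
             byrow = TRUE)
    cK <- c0 * exp(lnK)
    cK / (1 + cK)
  }
  thB <- thetaCols(tmb, dHBarcode, concM)
  oneMinusThQ <- 1 - thetaCols(tmq, dHQuencher, concM * quencherExcess)

  nb <- length(tmb); nq <- length(tmq)
  yieldMap <- tsMap <- widthMap <- matrix(0, nb, nq,
                                          dimnames = list(tmb, tmq))
  for (j in seq_len(nq)) {
    S <- thB * oneMinusThQ[, j]
    imax <- max.col(t(S), ties.method = "first")
    yieldMap[, j] <- S[cbind(imax, seq_len(nb))]
    tsMap[, j] <- temps[imax]
    widthMap[, j] <- vapply(seq_len(nb), function(i) .fwhm(temps, S[, i]),
                            numeric(1))
  }
  new("DesignGrid", tmbAxis = tmb, tmqAxis = tmq, yieldMap = yieldMap,
      tsMap = tsMap, widthMap = widthMap, concM = concM,
      quencherExcess = quencherExcess, saltMM = saltMM,
      dHBarcode = dHBarcode, dHQuencher = dHQuencher,
      spectrumRangeC = spectrumRangeC, spectrumStepC = spectrumStepC)
}

#' Probe set of one design-grid cell
#'
#' @param grid a [DesignGrid].
#' @param tmbC,tmqC the cell's domain melting temperatures (must lie on the
#'   grid axes).
#' @return a [ThermalProbeSet] built with the grid's model settings.
#' @export
gridProbe <- function(grid, tmbC, tmqC) {
  thermalProbeSet(name = sprintf("tmb%g_tmq%g", tmbC, tmqC),
                  tmbC = tmbC, tmqC = tmqC,
                  dHBarcode = grid@dHBarcode, dHQuencher = grid@dHQuencher,
                  concM = grid@concM, quencherExcess = grid@quencherExcess,
                  saltMM = grid@saltMM)
}

.gridSpectrum <- function(grid, tmbC, tmqC) {
  thermalSpectrum(gridProbe(grid, tmbC, tmqC),
                  tMinC = grid@spectrumRangeC[1],
                  tMaxC = grid@spectrumRangeC[2],
                  stepC = grid@spectrumStepC)
}

#' @rdname crosstalk
#' @param method `"spike"` (default): worst-case normalized signal at the
#'   other channel's imaging spike — operationally exact for the sequential
#'   protocol, where imaging only happens at the spike temperatures.
#'   `"integral"`: overlap coefficient of the two unit-area-normalized
#'   spectra (integral of their pointwise minimum).
#' @export
setMethod("crosstalk", signature("ThermalSpectrum", "ThermalSpectrum"),
          function(x, y, method = c("spike", "integral"), ...) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(x@tempsC, y@tempsC)))
    stop("spectra must share one temperature grid")
  if (x@yield <= 0 || y@yield <= 0)
    stop("crosstalk is undefined for a zero-yield spectrum")
  if (method == "integral") {
    sx <- x@signal / sum(x@signal)
    sy <- y@signal / sum(y@signal)
    return(sum(pmin(sx, sy)))
  }
  sxAtY <- stats::approx(x@tempsC, x@signal, xout = y@tsC)$y
  syAtX <- stats::approx(y@tempsC, y@signal, xout = x@tsC)$y
  max(sxAtY / x@yield, syAtX / y@yield)
})

#' Select a maximal panel of compatible thermal channels
#'
#' Greedy sweep from the wash-temperature floor upward: repeatedly admit the
#' candidate grid cell with the lowest signal temperature whose yield is at
#' least `yieldMin` and whose crosstalk with every already-admitted channel
#' is at most `overlapMax`. Ties on signal temperature are broken by higher
#' yield, then smaller width, then lower barcode Tm, so the admitted cell at
#' each signal temperature is the best-yield cell there.
#'
#' @param grid a [DesignGrid].
#' @param yieldMin minimum acceptable signal yield (default 0.8).
#' @param overlapMax maximum acceptable pairwise crosstalk (default 0.12).
#' @param tsFloorC lowest allowed signal temperature, above the
#'   post-hybridization wash (default 37 deg C).
#' @param tsCeilingC highest allowed signal temperature (default 75 deg C).
#' @return a [ChannelPanel]; empty (zero channels) when no cell is feasible.
#' @examples
#' panel <- selectChannels(gridScan())
#' signalTemp(panel)
#' @export
selectChannels <- function(grid, yieldMin = 0.8, overlapMax = 0.12,
                           tsFloorC = 37, tsCeilingC = 75) {
  if (!is(grid, "DesignGrid")) stop("'grid' must be a DesignGrid")
  if (yieldMin <= 0 || yieldMin > 1) stop("yieldMin must be in (0, 1]")
  if (overlapMax < 0 || overlapMax > 1) stop("overlapMax must be in [0, 1]")
  if (tsFloorC >= tsCeilingC) stop("tsFloorC must be below tsCeilingC")
  constraints <- list(yieldMin = yieldMin, overlapMax = overlapMax,
                      tsFloorC = tsFloorC, tsCeilingC = tsCeilingC)

  ok <- which(grid@yieldMap >= yieldMin & grid@tsMap >= tsFloorC &
                grid@tsMap <= tsCeilingC, arr.ind = TRUE)
  if (nrow(ok) == 0) return(.emptyPanel(constraints))
  cand <- data.frame(tmb = grid@tmbAxis[ok[, 1]], tmq = grid@tmqAxis[ok[, 2]],
                     ts = grid@tsMap[ok], yield = grid@yieldMap[ok],
                     width = grid@widthMap[ok])
  cand <- cand[order(cand$ts, -cand$yield, cand$width, cand$tmb), ]

  selSpec <- list(); selRow <- list()
  for (i in seq_len(nrow(cand))) {
    sp <- .gridSpectrum(grid, cand$tmb[i], cand$tmq[i])
    compatible <- all(vapply(selSpec,
                             function(s) crosstalk(sp, s) <= overlapMax,
                             logical(1)))
    if (compatible) {
      selSpec[[length(selSpec) + 1]] <- sp
      selRow[[length(selRow) + 1]] <- cand[i, ]
    }
  }
  sel <- do.call(rbind, selRow)
  n <- nrow(sel)
  ov <- diag(n)
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      ov[i, j] <- ov[j, i] <- crosstalk(selSpec[[i]], selSpec[[j]])
  probeList <- lapply(seq_len(n),
                      function(i) gridProbe(grid, sel$tmb[i], sel$tmq[i]))
  new("ChannelPanel", probes = probeList, tmbC = sel$tmb, tmqC = sel$tmq,
      signalTempsC = vapply(selSpec, signalTemp, numeric(1)),
      yield = sel$yield, widthC = sel$width, overlap = ov,
      constraintsUsed = constraints)
}

.emptyPanel <- function(constraints) {
  new("ChannelPanel", probes = list(), tmbC = numeric(), tmqC = numeric(),
      signalTempsC = numeric(), yield = numeric(), widthC = numeric(),
      overlap = matrix(numeric(), 0, 0), constraintsUsed = constraints)
}

#' Re-verify a channel panel against its constraints
#'
#' Recomputes every spectrum from the panel's probe sets and re-evaluates the
#' yield, crosstalk and signal-temperature constraints from scratch, so a
#' selection cannot self-certify.
#'
#' @param panel a [ChannelPanel].
#' @param tMinC,tMaxC,stepC spectrum grid used for re-evaluation.
#' @return `TRUE` when every constraint holds, otherwise `FALSE` with a
#'   `"failures"` attribute describing the violated constraints.
#' @export
verifyPanel <- function(panel, tMinC = 20, tMaxC = 80, stepC = 0.1) {
  cons <- panel@constraintsUsed
  specs <- lapply(probes(panel), thermalSpectrum,
                  tMinC = tMinC, tMaxC = tMaxC, stepC = stepC)
  fails <- character()
  n <- length(specs)
  if (n == 0) return(TRUE)
  y <- vapply(specs, signalYield, numeric(1))
  ts <- vapply(specs, signalTemp, numeric(1))
  if (any(y < cons$yieldMin)) fails <- c(fails, "yield below yieldMin")
  if (any(ts < cons$tsFloorC | ts > cons$tsCeilingC))
    fails <- c(fails, "signal temperature outside [tsFloorC, tsCeilingC]")
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (crosstalk(specs[[i]], specs[[j]]) > cons$overlapMax) {
        fails <- c(fails, "pairwise crosstalk above overlapMax")
        break
      }
  out <- length(fails) == 0
  if (!out) attr(out, "failures") <- unique(fails)
  out
}

#' @rdname accessors
#' @export
setMethod("probes", "ChannelPanel", function(object) object@probes)

#' @rdname accessors
#' @export
setMethod("overlapMatrix", "ChannelPanel", function(object) object@overlap)

#' @rdname accessors
#' @export
setMethod("signalTemp", "ChannelPanel", function(object) object@signalTempsC)

#' @rdname accessors
#' @export
setMethod("signalYield", "ChannelPanel", function(object) object@yield)

#' @rdname accessors
#' @export
setMethod("spectrumWidth", "ChannelPanel", function(object) object@widthC)

setMethod("show", "ChannelPanel", function(object) {
  n <- length(object@probes)
  cat(sprintf("ChannelPanel with %d thermal channel%s\n", n,
              if (n == 1) "" else "s"))
  if (n) {
    df <- data.frame(tmbC = object@tmbC, tmqC = object@tmqC,
                     tsC = object@signalTempsC, yield = round(object@yield, 3),
                     widthC = round(object@widthC, 1))
    print(df, row.names = FALSE)
    off <- object@overlap[upper.tri(object@overlap)]
    if (length(off))
      cat(sprintf("max pairwise crosstalk: %.3f\n", max(off)))
  }
})

setMethod("show", "DesignGrid", function(object) {
  cat(sprintf(
    "DesignGrid: Tmb %g-%g C x Tmq %g-%g C (%d x %d cells), c = %.0f nM\n",
    min(object@tmbAxis), max(object@tmbAxis),
    min(object@tmqAxis), max(object@tmqAxis),
    length(object@tmbAxis), length(object@tmqAxis), object@concM * 1e9))
})
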