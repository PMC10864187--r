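# Thermal spectra: the modeled signal of a two-domain probe set versus
# temperature, and the sequential-spike protocol signal matrix.

# Default domain enthalpies when a domain is specified by Tm alone. These
# are typical unified nearest-neighbor magnitudes for the domain lengths
# used in practice: 18-25 nt barcode duplexes (~ -160 kcal/mol) and
# 12-16 nt quencher duplexes (~ -110 kcal/mol).
.DH_BARCODE <- -160
.DH_QUENCHER <- -110

#' Construct a thermal probe set
#'
#' A probe set may be specified by its two domain melting temperatures (at
#' the reference concentration), by explicit domain sequences, or by
#' ready-made [DuplexThermo] objects. Exactly one specification per domain
#' must be given.
#'
#' @param name probe set label.
#' @param tmbC,tmqC barcode- and quencher-domain melting temperatures in
#'   deg C (at `concM`).
#' @param barcodeSeq,quencherSeq domain duplex sequences; when given, the
#'   thermodynamics come from the nearest-neighbor model instead of `tm*C`.
#' @param barcode,quencher explicit [DuplexThermo] objects (override both).
#' @param dHBarcode,dHQuencher domain enthalpies (kcal/mol) used when only a
#'   Tm is given; defaults -160 and -110.
#' @param concM reference imager concentration in M.
#' @param quencherExcess quencher:imager ratio; the quencher occupancy is
#'   evaluated at `concM * quencherExcess`.
#' @param fluor fluorophore label.
#' @param saltMM monovalent salt in mM.
#' @return a [ThermalProbeSet].
#' @examples
#' p <- thermalProbeSet("example", tmbC = 61, tmqC = 53)
#' signalTemp(thermalSpectrum(p))
#' @export
thermalProbeSet <- function(name = "probe", tmbC = NULL, tmqC = NULL,
                            barcodeSeq = NULL, quencherSeq = NULL,
                            barcode = NULL, quencher = NULL,
                            dHBarcode = .DH_BARCODE, dHQuencher = .DH_QUENCHER,
                            concM = 250e-9, quencherExcess = 1.2,
                            fluor = "Alexa647", saltMM = 195) {
  cond <- bindingConditions(strandConcM = concM, saltMM = saltMM)
  if (is.null(barcode)) {
    barcode <- if (!is.null(barcodeSeq)) {
      duplexThermoFromSequence(barcodeSeq, saltMM = saltMM)
    } else if (!is.null(tmbC)) {
      thermoFromTm(tmbC, dHBarcode, cond)
    } else stop("barcode domain needs tmbC, barcodeSeq or barcode")
  }
  if (is.null(quencher)) {
    quencher <- if (!is.null(quencherSeq)) {
      duplexThermoFromSequence(quencherSeq, saltMM = saltMM)
    } else if (!is.null(tmqC)) {
      thermoFromTm(tmqC, dHQuencher, cond)
    } else stop("quencher domain needs tmqC, quencherSeq or quencher")
  }
  new("ThermalProbeSet", name = name, barcode = barcode, quencher = quencher,
      concM = concM, quencherExcess = quencherExcess, fluor = fluor,
      saltMM = saltMM)
}

#' @rdname accessors
#' @export
setMethod("tmB", "ThermalProbeSet", function(object) {
  .tmC(object@barcode@dH, object@barcode@dS, object@concM)
})

#' @rdname accessors
#' @export
setMethod("tmQ", "ThermalProbeSet", function(object) {
  .tmC(object@quencher@dH, object@quencher@dS, object@concM)
})

#' Modeled signal of a probe set at given temperatures
#'
#' Independent-duplex model: the imager occupancy on the barcode times the
#' probability that the quencher is dissociated,
#' `signal(T) = theta_barcode(T) (1 - theta_quencher(T))`, with the quencher
#' evaluated at its excess concentration.
#'
#' @param probe a [ThermalProbeSet].
#' @param tempC temperature(s) in deg C.
#' @return signal value(s) in \[0, 1\].
#' @export
probeSignal <- function(probe, tempC) {
  thb <- .theta(probe@barcode@dH, probe@barcode@dS, probe@concM, tempC)
  thq <- .theta(probe@quencher@dH, probe@quencher@dS,
                probe@concM * probe@quencherExcess, tempC)
  thb * (1 - thq)
}

# interpolated full width at half maximum of a sampled unimodal curve;
# clamped at the grid edges when a half-max crossing is outside the grid.
.fwhm <- function(temps, signal) {
  ymax <- max(signal)
  if (ymax <= 0) return(0)
  h <- ymax / 2
  imax <- which.max(signal)
  left <- temps[1]
  if (imax > 1) {
    below <- which(signal[seq_len(imax - 1)] < h)
    if (length(below)) {
      i <- max(below)
      left <- temps[i] + (h - signal[i]) * (temps[i + 1] - temps[i]) /
        (signal[i + 1] - signal[i])
    }
  }
  n <- length(temps)
  right <- temps[n]
  if (imax < n) {
    below <- which(signal[(imax + 1):n] < h)
    if (length(below)) {
      i <- imax + min(below)
      right <- temps[i - 1] + (signal[i - 1] - h) * (temps[i] - temps[i - 1]) /
        (signal[i - 1] - signal[i])
    }
  }
  right - left
}

#' @rdname thermalSpectrum
#' @param tMinC,tMaxC,stepC temperature grid (defaults 20-80 deg C, 0.1 deg C).
#' @export
setMethod("thermalSpectrum", "ThermalProbeSet",
          function(object, tMinC = 20, tMaxC = 80, stepC = 0.1) {
  if (tMinC >= tMaxC) stop("tMinC must be below tMaxC")
  if (stepC <= 0) stop("stepC must be positive")
  temps <- seq(tMinC, tMaxC, by = stepC)
  if (length(temps) < 3) stop("temperature grid must have at least 3 points")
  sig <- probeSignal(object, temps)
  new("ThermalSpectrum", tempsC = temps, signal = sig,
      tsC = temps[which.max(sig)], yield = max(sig),
      widthC = .fwhm(temps, sig))
})

#' @rdname accessors
#' @export
setMethod("signalTemp", "ThermalSpectrum", function(object) object@tsC)

#' @rdname accessors
#' @export
setMethod("signalYield", "ThermalSpectrum", function(object) object@yield)

#' @rdname accessors
#' @export
setMethod("spectrumWidth", "ThermalSpectrum", function(object) object@widthC)

setMethod("show", "ThermalSpectrum", function(object) {
  cat(sprintf(
    "ThermalSpectrum: %d points (%.1f-%.1f C), Ts = %.1f C, yield = %.3f, width = %.1f C\n",
    length(object@tempsC), min(object@tempsC), max(object@tempsC),
    object@tsC, object@yield, object@widthC))
})

setMethod("show", "ThermalProbeSet", function(object) {
  cat(sprintf(
    "ThermalProbeSet '%s' (%s): Tmb = %.1f C, Tmq = %.1f C at %.0f nM\n",
    object@name, object@fluor, tmB(object), tmQ(object), object@concM * 1e9))
})

#' Predicted signal matrix of a sequential heating protocol
#'
#' Under the sequential-spike protocol, dissociated strands stay diffuse and
#' do not re-equilibrate on cool-down, so the fluorescence imaged after spike
#' `j` equals each probe's equilibrium signal at the spike temperature.
#' Spikes must therefore be applied in strictly increasing order.
#'
#' @param panel a list of [ThermalProbeSet] or a [ChannelPanel].
#' @param spikeTempsC strictly increasing spike temperatures in deg C.
#' @return matrix of signal values, probes x spikes.
#' @export
protocolSignalMatrix <- function(panel, spikeTempsC) {
  if (is(panel, "ChannelPanel")) panel <- probes(panel)
  if (is.unsorted(spikeTempsC, strictly = TRUE))
    stop("spike temperatures must be strictly increasing")
  m <- matrix(unlist(lapply(panel, probeSignal, tempC = spikeTempsC)),
              nrow = length(panel), byrow = TRUE)
  dimnames(m) <- list(vapply(panel, function(p) p@name, character(1)),
                      sprintf("%.1fC", spikeTempsC))
  m
}
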