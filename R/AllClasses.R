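#' @import methods
NULL

#' Two-state duplex thermodynamic parameters
#'
#' Holds the van't Hoff enthalpy and entropy of a DNA duplex under the
#' all-or-none (two-state) model. Parameters either come from a
#' nearest-neighbor sum over the duplex sequence (`source = "from_sequence"`)
#' or are back-derived from a stated melting temperature
#' (`source = "from_tm"`).
#'
#' @slot dH duplex formation enthalpy in kcal/mol; negative for any stable
#'   duplex.
#' @slot dS duplex formation entropy in cal/(mol K); negative.
#' @slot source `"from_sequence"` or `"from_tm"`.
#' @export
setClass("DuplexThermo",
         representation(dH = "numeric", dS = "numeric", source = "character"),
         prototype(source = "from_tm"))

setValidity("DuplexThermo", function(object) {
  msg <- character()
  if (length(object@dH) != 1 || !is.finite(object@dH))
    msg <- c(msg, "dH must be a single finite number")
  if (length(object@dS) != 1 || !is.finite(object@dS))
    msg <- c(msg, "dS must be a single finite number")
  if (length(msg) == 0 && object@dH >= 0)
    msg <- c(msg, "dH must be negative for a valid duplex")
  if (length(msg) == 0 && object@dS >= 0)
    msg <- c(msg, "dS must be negative for a valid duplex")
  if (!object@source %in% c("from_sequence", "from_tm"))
    msg <- c(msg, "source must be 'from_sequence' or 'from_tm'")
  if (length(msg)) msg else TRUE
})

#' Solution conditions for duplex binding
#'
#' @slot strandConcM molar concentration of the free (fluorescent or
#'   quencher) strand.
#' @slot saltMM monovalent salt in mM.
#' @slot tempC temperature(s) in degrees Celsius; may be a vector when
#'   evaluating occupancy over a grid.
#' @export
setClass("BindingConditions",
         representation(strandConcM = "numeric", saltMM = "numeric",
                        tempC = "numeric"))

setValidity("BindingConditions", function(object) {
  msg <- character()
  if (length(object@strandConcM) != 1 || object@strandConcM <= 0)
    msg <- c(msg, "strandConcM must be a single positive number")
  if (length(object@saltMM) != 1 || object@saltMM <= 0)
    msg <- c(msg, "saltMM must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' A two-domain thermal probe set
#'
#' One imager/quencher probe set: the imager binds a barcode overhang
#' (duplex melting temperature `Tmb`) and is pre-hybridized to a quencher
#' strand (duplex melting temperature `Tmq < Tmb`). Fluorescence is emitted
#' between the two melting transitions.
#'
#' @slot name probe set label.
#' @slot barcode [DuplexThermo] of the imager/barcode duplex.
#' @slot quencher [DuplexThermo] of the quencher/imager duplex.
#' @slot concM reference probe concentration in M (imager strand).
#' @slot quencherExcess quencher:imager concentration ratio (>= 1).
#' @slot fluor fluorophore label.
#' @slot saltMM monovalent salt in mM.
#' @export
setClass("ThermalProbeSet",
         representation(name = "character", barcode = "DuplexThermo",
                        quencher = "DuplexThermo", concM = "numeric",
                        quencherExcess = "numeric", fluor = "character",
                        saltMM = "numeric"))

setValidity("ThermalProbeSet", function(object) {
  msg <- character()
  if (object@concM <= 0) msg <- c(msg, "concM must be positive")
  if (object@quencherExcess < 1)
    msg <- c(msg, "quencherExcess must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Thermal spectrum of a probe set
#'
#' Modeled fluorescence signal versus temperature, with the derived summary
#' quantities: signal temperature (argmax), yield (maximum) and full width at
#' half maximum.
#'
#' @slot tempsC ascending, uniformly spaced temperature grid in deg C.
#' @slot signal modeled signal in \[0, 1\] per grid point.
#' @slot tsC signal temperature (grid argmax) in deg C.
#' @slot yield maximum signal.
#' @slot widthC full width at half maximum in deg C (interpolated).
#' @export
setClass("ThermalSpectrum",
         representation(tempsC = "numeric", signal = "numeric",
                        tsC = "numeric", yield = "numeric",
                        widthC = "numeric"))

setValidity("ThermalSpectrum", function(object) {
  msg <- character()
  if (length(object@tempsC) != length(object@signal))
    msg <- c(msg, "tempsC and signal lengths differ")
  if (any(object@signal < -1e-12 | object@signal > 1 + 1e-12))
    msg <- c(msg, "signal must lie in [0, 1]")
  if (length(object@tempsC) &&
      (object@tsC < min(object@tempsC) || object@tsC > max(object@tempsC)))
    msg <- c(msg, "tsC outside the temperature grid")
  if (length(msg)) msg else TRUE
})

#' Design-space scan over domain melting temperatures
#'
#' Summary maps (yield, signal temperature, width) of the thermal spectrum
#' for every combination of barcode-domain and quencher-domain melting
#' temperature, plus the model settings needed to rebuild any cell's probe
#' set and spectrum.
#'
#' @slot tmbAxis barcode-domain Tm axis in deg C.
#' @slot tmqAxis quencher-domain Tm axis in deg C.
#' @slot yieldMap,tsMap,widthMap matrices (tmb x tmq).
#' @slot concM,quencherExcess,saltMM,dHBarcode,dHQuencher model settings.
#' @slot spectrumRangeC,spectrumStepC temperature grid used for spectra.
#' @export
setClass("DesignGrid",
         representation(tmbAxis = "numeric", tmqAxis = "numeric",
                        yieldMap = "matrix", tsMap = "matrix",
                        widthMap = "matrix", concM = "numeric",
                        quencherExcess = "numeric", saltMM = "numeric",
                        dHBarcode = "numeric", dHQuencher = "numeric",
                        spectrumRangeC = "numeric", spectrumStepC = "numeric"))

setValidity("DesignGrid", function(object) {
  msg <- character()
  dm <- c(length(object@tmbAxis), length(object@tmqAxis))
  for (nm in c("yieldMap", "tsMap", "widthMap"))
    if (!identical(dim(slot(object, nm)), as.integer(dm)))
      msg <- c(msg, paste(nm, "dimensions do not match the axes"))
  if (any(object@yieldMap < -1e-12 | object@yieldMap > 1 + 1e-12))
    msg <- c(msg, "yieldMap must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A selected panel of mutually compatible thermal channels
#'
#' @slot probes list of [ThermalProbeSet], ordered by signal temperature.
#' @slot tmbC,tmqC the grid cell (domain Tms) of each channel.
#' @slot signalTempsC per-channel signal temperature.
#' @slot yield,widthC per-channel spectrum summaries.
#' @slot overlap symmetric crosstalk matrix with unit diagonal.
#' @slot constraintsUsed list with yieldMin, overlapMax, tsFloorC, tsCeilingC.
#' @export
setClass("ChannelPanel",
         representation(probes = "list", tmbC = "numeric", tmqC = "numeric",
                        signalTempsC = "numeric", yield = "numeric",
                        widthC = "numeric", overlap = "matrix",
                        constraintsUsed = "list"))

setValidity("ChannelPanel", function(object) {
  msg <- character()
  n <- length(object@probes)
  if (n > 0) {
    if (is.unsorted(object@signalTempsC, strictly = TRUE))
      msg <- c(msg, "signal temperatures must be strictly increasing")
    if (!identical(dim(object@overlap), c(n, n)))
      msg <- c(msg, "overlap matrix dimensions do not match panel size")
    else if (any(abs(diag(object@overlap) - 1) > 1e-9))
      msg <- c(msg, "overlap matrix must have unit diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' First-order hybridization rate model for one duplex
#'
#' Association at rate `kOn` (temperature independent) and dissociation at
#' `kOff(T) = kOn / K(T)`, where `K(T)` is the two-state equilibrium constant
#' of the duplex.
#'
#' @slot kOn association rate in 1/(M s).
#' @slot thermo [DuplexThermo] of the duplex.
#' @export
setClass("RateModel",
         representation(kOn = "numeric", thermo = "DuplexThermo"))

setValidity("RateModel", function(object) {
  if (length(object@kOn) != 1 || object@kOn <= 0)
    "kOn must be a single positive number" else TRUE
})

#' Pairwise cross-hybridization report for a strand panel
#'
#' @slot tmC symmetric matrix of the strongest off-target hybrid Tm (deg C)
#'   between each pair of strands; `-Inf` when no stable hybrid exists;
#'   diagonal is `NA` (cognate pairs are excluded).
#' @slot thresholdTmC pass threshold in deg C.
#' @slot pass logical matrix, `tmC < thresholdTmC` off the diagonal.
#' @export
setClass("OrthogonalityReport",
         representation(tmC = "matrix", thresholdTmC = "numeric",
                        pass = "matrix"))
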