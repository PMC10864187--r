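#' Melting temperature of a duplex
#'
#' Temperature at which the bound fraction equals 0.5 under the free-ligand
#' convention, `Tm = dH / (dS + R ln c)` (in K, returned in deg C).
#'
#' @param object a [DuplexThermo] or [ThermalProbeSet].
#' @param ... further arguments (e.g. `cond`, a [BindingConditions]).
#' @return temperature in deg C.
#' @export
setGeneric("meltingTemperature",
           function(object, ...) standardGeneric("meltingTemperature"))

#' Equilibrium bound fraction of a duplex
#'
#' Two-state occupancy `theta(T) = c K(T) / (1 + c K(T))` with
#' `K(T) = exp(-(dH - T dS) / (R T))`, the free strand at concentration `c`
#' and the tethered partner at negligible concentration.
#'
#' @param object a [DuplexThermo].
#' @param cond a [BindingConditions]; its `tempC` may be a vector.
#' @return bound fraction(s) in \[0, 1\].
#' @export
setGeneric("fractionBound",
           function(object, cond) standardGeneric("fractionBound"))

#' Thermal spectrum of a probe set
#'
#' @param object a [ThermalProbeSet].
#' @param ... grid arguments `tMinC`, `tMaxC`, `stepC`.
#' @return a [ThermalSpectrum].
#' @export
setGeneric("thermalSpectrum",
           function(object, ...) standardGeneric("thermalSpectrum"))

#' Crosstalk between two thermal spectra
#'
#' Worst-case normalized signal of one probe at the other's imaging spike:
#' `max(s_i(ts_j)/yield_i, s_j(ts_i)/yield_j)`.
#'
#' @param x,y [ThermalSpectrum] objects on the same temperature grid.
#' @param ... unused.
#' @return a value in \[0, 1\].
#' @export
setGeneric("crosstalk", function(x, y, ...) standardGeneric("crosstalk"))

#' @rdname accessors
#' @export
setGeneric("signalTemp", function(object) standardGeneric("signalTemp"))

#' @rdname accessors
#' @export
setGeneric("signalYield", function(object) standardGeneric("signalYield"))

#' @rdname accessors
#' @export
setGeneric("spectrumWidth", function(object) standardGeneric("spectrumWidth"))

#' Accessors for thermal probe and spectrum objects
#'
#' `signalTemp`, `signalYield` and `spectrumWidth` return the summary
#' quantities of a [ThermalSpectrum] (or, for a [ChannelPanel], the
#' per-channel vectors). `probes` returns the probe sets of a panel,
#' `overlapMatrix` its pairwise crosstalk matrix. `tmB`/`tmQ` return the
#' domain melting temperatures of a [ThermalProbeSet] at its reference
#' concentration.
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probes", function(object) standardGeneric("probes"))

#' @rdname accessors
#' @export
setGeneric("overlapMatrix", function(object) standardGeneric("overlapMatrix"))

#' @rdname accessors
#' @export
setGeneric("tmB", function(object) standardGeneric("tmB"))

#' @rdname accessors
#' @export
setGeneric("tmQ", function(object) standardGeneric("tmQ"))

#' Dissociation rate of a duplex at a temperature
#'
#' @param object a [RateModel].
#' @param tempC temperature(s) in deg C.
#' @return `kOff` in 1/s.
#' @export
setGeneric("kOff", function(object, tempC) standardGeneric("kOff"))
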