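# Hybridization kinetics: quencher melt-off during a heating spike and
# imager/quencher rebinding during imaging. First-order two-state model,
#   d theta / dt = kOn c (1 - theta) - kOff(T(t)) theta,
# with all temperature dependence in kOff(T) = kOn / K(T).

#' Construct a rate model for one duplex
#'
#' @param thermo a [DuplexThermo].
#' @param kOn association rate in 1/(M s); default 1e6, a standard
#'   oligonucleotide association magnitude. Temperature independent.
#' @return a [RateModel].
#' @export
rateModel <- function(thermo, kOn = 1e6) {
  new("RateModel", kOn = kOn, thermo = thermo)
}

#' @rdname kOff
#' @export
setMethod("kOff", "RateModel", function(object, tempC) {
  tK <- tempC + .C2K
  lnK <- -(object@thermo@dH * 1000 - tK * object@thermo@dS) / (.RGAS * tK)
  object@kOn / exp(lnK)
})

#' Temperature protocol for a heating-spike experiment
#'
#' Piecewise-linear slide temperature: from `startC`, each segment ramps to
#' its target over `rampS` seconds and holds for `holdS` seconds.
#'
#' @param targetsC spike setpoints in deg C.
#' @param rampS ramp duration(s) in s (default 5, recycled).
#' @param holdS hold duration(s) in s (default 5, recycled).
#' @param startC starting temperature in deg C (default 23, room
#'   temperature).
#' @return a list with the breakpoint times and temperatures, and a
#'   `tempAt(t)` interpolator.
#' @export
tempProtocol <- function(targetsC, rampS = 5, holdS = 5, startC = 23) {
  if (length(targetsC) < 1) stop("at least one segment is required")
  rampS <- rep_len(rampS, length(targetsC))
  holdS <- rep_len(holdS, length(targetsC))
  if (any(rampS < 0) || any(holdS < 0))
    stop("ramp and hold durations must be non-negative")
  times <- 0
  temps <- startC
  for (k in seq_along(targetsC)) {
    t1 <- times[length(times)] + max(rampS[k], 1e-9)
    times <- c(times, t1)
    temps <- c(temps, targetsC[k])
    if (holdS[k] > 0) {
      times <- c(times, t1 + holdS[k])
      temps <- c(temps, targetsC[k])
    }
  }
  fn <- stats::approxfun(times, temps, rule = 2)
  structure(list(timesS = times, tempsC = temps, tempAt = fn,
                 startC = startC),
            class = "tempProtocol")
}

#' Simulate probe kinetics over a temperature protocol
#'
#' Integrates the bound fractions of the barcode (imager) duplex and the
#' quencher duplex through a piecewise-linear temperature protocol with a
#' stiff-safe integrator. `freeConcM` is the concentration of free strand
#' available for rebinding (effectively zero after the pre-imaging wash).
#'
#' @param probe a [ThermalProbeSet].
#' @param protocol a [tempProtocol()].
#' @param kOn association rate in 1/(M s).
#' @param freeConcM free-strand concentration during the protocol in M.
#' @param theta0 initial bound fractions `c(barcode, quencher)`; default is
#'   the equilibrium occupancy at the protocol start temperature at the
#'   probe's reference concentrations (fully assembled probe).
#' @param sampleHz output sampling rate (default 10 Hz).
#' @param atol,rtol integrator tolerances.
#' @return data.frame with columns `timeS`, `tempC`, `thetaBarcode`,
#'   `thetaQuencher`.
#' @export
simulateProtocol <- function(probe, protocol, kOn = 1e6, freeConcM = 0,
                             theta0 = NULL, sampleHz = 10,
                             atol = 1e-9, rtol = 1e-8) {
  if (freeConcM < 0) stop("freeConcM must be non-negative")
  if (is.null(theta0)) {
    theta0 <- c(
      .theta(probe@barcode@dH, probe@barcode@dS, probe@concM,
             protocol$startC),
      .theta(probe@quencher@dH, probe@quencher@dS,
             probe@concM * probe@quencherExcess, protocol$startC))
  }
  rb <- rateModel(probe@barcode, kOn)
  rq <- rateModel(probe@quencher, kOn)
  tEnd <- max(protocol$timesS)
  times <- seq(0, tEnd, by = 1 / sampleHz)
  if (times[length(times)] < tEnd) times <- c(times, tEnd)
  deriv <- function(t, y, parms) {
    tc <- protocol$tempAt(t)
    list(c(kOn * freeConcM * (1 - y[1]) - kOff(rb, tc) * y[1],
           kOn * freeConcM * (1 - y[2]) - kOff(rq, tc) * y[2]))
  }
  sol <- deSolve::lsoda(y = theta0, times = times, func = deriv,
                        parms = NULL, atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; see deSolve diagnostics")
  data.frame(timeS = sol[, 1], tempC = protocol$tempAt(sol[, 1]),
             thetaBarcode = pmin(pmax(sol[, 2], 0), 1),
             thetaQuencher = pmin(pmax(sol[, 3], 0), 1))
}

#' Fraction of strands rebound after imaging at low concentration
#'
#' Pseudo-first-order estimate `1 - exp(-kOn c t)`, capped by the
#' equilibrium occupancy at the imaging temperature. At the femtomolar to
#' picomolar concentrations of dissociated strands this is negligible even
#' over 24 h.
#'
#' @param rates a [RateModel].
#' @param freeConcM free-strand concentration in M.
#' @param durationS elapsed time in s.
#' @param tempC imaging temperature in deg C.
#' @return rebound fraction in \[0, 1\].
#' @examples
#' rm53 <- rateModel(thermoFromTm(53, -110, bindingConditions()))
#' rebindingFraction(rm53, 1e-15, 24 * 3600, 30)
#' @export
rebindingFraction <- function(rates, freeConcM, durationS, tempC = 30) {
  if (durationS < 0) stop("durationS must be non-negative")
  if (freeConcM < 0) stop("freeConcM must be non-negative")
  if (freeConcM == 0) return(0)
  kinetic <- 1 - exp(-rates@kOn * freeConcM * durationS)
  eq <- .theta(rates@thermo@dH, rates@thermo@dS, freeConcM, tempC)
  min(kinetic, eq)
}

#' Time for a duplex to dissociate to a target bound fraction
#'
#' Closed-form solution of the first-order kinetics at a fixed temperature:
#' `theta(t) = thetaInf + (theta0 - thetaInf) exp(-(kOn c + kOff) t)` with
#' `thetaInf = kOn c / (kOn c + kOff)`. With `freeConcM = 0` this is the
#' pure exponential decay `theta0 exp(-kOff t)`.
#'
#' @param rates a [RateModel].
#' @param tempC hold temperature in deg C.
#' @param from initial bound fraction (default 1).
#' @param to target bound fraction.
#' @param freeConcM free-strand concentration in M (default 0).
#' @return time in s.
#' @export
dissociationTime <- function(rates, tempC, from = 1, to = 0.01,
                             freeConcM = 0) {
  koff <- kOff(rates, tempC)
  rate <- rates@kOn * freeConcM + koff
  thetaInf <- rates@kOn * freeConcM / rate
  if (to <= thetaInf)
    stop("target bound fraction is at or below the equilibrium occupancy")
  log((from - thetaInf) / (to - thetaInf)) / rate
}

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel: kOn = %.2e /(M s), duplex dH = %.1f kcal/mol\n",
              object@kOn, object@thermo@dH))
})
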