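# Nearest-neighbor duplex thermodynamics and the two-state melting model.
# All enthalpies are kcal/mol, entropies cal/(mol K); temperatures are deg C
# at every interface and Kelvin internally. R = 1.987 cal/(mol K).

.RGAS <- 1.987
.C2K <- 273.15

# Unified nearest-neighbor parameters for Watson-Crick stacks in 1 M NaCl,
# keyed by the 5'->3' dinucleotide of the top strand (the complementary
# bottom-strand stack has identical parameters and is listed explicitly so
# lookups never need reversal).
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# initiation terms per terminal base pair
.INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
.SYM_DS <- -1.4          # self-complementary duplex entropy penalty
.SALT_DS_COEF <- 0.368   # cal/(mol K) per phosphate-pair per ln[Na+]

#' @export
#' @rdname duplexThermo
duplexThermo <- function(dH, dS, source = "from_tm") {
  new("DuplexThermo", dH = dH, dS = dS, source = source)
}

#' Construct duplex thermodynamic parameters
#'
#' `duplexThermo()` wraps explicit van't Hoff parameters.
#' `duplexThermoFromSequence()` sums unified nearest-neighbor stack
#' parameters over a perfectly complementary duplex, adds the terminal
#' initiation terms (and the symmetry entropy when the sequence is
#' self-complementary), and applies the monovalent-salt entropy correction
#' `dS += 0.368 (n-1) ln([Na+])`.
#' `thermoFromTm()` back-derives the entropy so that the resulting duplex
#' melts exactly at `tmC` under `cond`: `dS = dH/Tm - R ln c`.
#'
#' @param dH enthalpy in kcal/mol (negative).
#' @param dS entropy in cal/(mol K) (negative).
#' @param source provenance tag, `"from_sequence"` or `"from_tm"`.
#' @param seq DNA sequence (A/C/G/T), length >= 2.
#' @param saltMM monovalent salt in mM.
#' @param tmC target melting temperature in deg C.
#' @param cond a [BindingConditions] giving the free-strand concentration.
#' @return a [DuplexThermo].
#' @examples
#' bindTo53 <- thermoFromTm(53, dH = -110, cond = bindingConditions())
#' meltingTemperature(bindTo53, bindingConditions())
#' @rdname duplexThermo
#' @export
duplexThermoFromSequence <- function(seq, saltMM = 195) {
  if (length(seq) != 1 || is.na(seq))
    stop("'seq' must be a single DNA string")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2)
    stop("duplex sequence must be at least 2 nt long")
  bases <- strsplit(seq, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("sequence contains characters outside {A,C,G,T}")
  stacks <- paste0(bases[-n], bases[-1])
  dH <- sum(.NN_DH[stacks]) + .INIT_DH[bases[1]] + .INIT_DH[bases[n]]
  dS <- sum(.NN_DS[stacks]) + .INIT_DS[bases[1]] + .INIT_DS[bases[n]]
  if (seq == reverseComplement(seq)) dS <- dS + .SYM_DS
  dS <- dS + .SALT_DS_COEF * (n - 1) * log(saltMM / 1000)
  duplexThermo(unname(dH), unname(dS), source = "from_sequence")
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A/C/G/T).
#' @return the reverse complement string.
#' @export
reverseComplement <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(seq)), "")[[1]]),
        collapse = "")
}

#' Binding conditions
#'
#' @param strandConcM free-strand concentration in M (default 250 nM, the
#'   reference probe concentration).
#' @param saltMM monovalent salt in mM (default 195, a PBS/SSC-scale value).
#' @param tempC temperature(s) in deg C.
#' @return a [BindingConditions].
#' @export
bindingConditions <- function(strandConcM = 250e-9, saltMM = 195,
                              tempC = 37) {
  new("BindingConditions", strandConcM = strandConcM, saltMM = saltMM,
      tempC = tempC)
}

# theta(T) vectorized over tempC, for raw parameters
.theta <- function(dH, dS, concM, tempC) {
  tK <- tempC + .C2K
  lnK <- -(dH * 1000 - tK * dS) / (.RGAS * tK)
  cK <- concM * exp(lnK)
  cK / (1 + cK)
}

.tmC <- function(dH, dS, concM) {
  denom <- dS + .RGAS * log(concM)
  if (denom >= 0)
    stop("nonphysical parameters: dS + R ln c must be negative")
  dH * 1000 / denom - .C2K
}

#' @rdname meltingTemperature
#' @param cond a [BindingConditions].
#' @export
setMethod("meltingTemperature", "DuplexThermo", function(object, cond) {
  .tmC(object@dH, object@dS, cond@strandConcM)
})

#' @rdname fractionBound
#' @export
setMethod("fractionBound", "DuplexThermo", function(object, cond) {
  .theta(object@dH, object@dS, cond@strandConcM, cond@tempC)
})

#' @rdname duplexThermo
#' @export
thermoFromTm <- function(tmC, dH, cond = bindingConditions()) {
  if (dH >= 0) stop("dH must be negative")
  dS <- dH * 1000 / (tmC + .C2K) - .RGAS * log(cond@strandConcM)
  duplexThermo(dH, dS, source = "from_tm")
}

setMethod("show", "DuplexThermo", function(object) {
  cat(sprintf("DuplexThermo (%s): dH = %.1f kcal/mol, dS = %.1f cal/(mol K)\n",
              object@source, object@dH, object@dS))
})
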