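# Domain sequence generation toward a target melting temperature, and
# pairwise cross-hybridization screening of a strand panel.

.BASES <- c("A", "C", "G", "T")

.gcFraction <- function(bases) mean(bases %in% c("G", "C"))

.maxHomopolymer <- function(bases) max(rle(bases)$lengths)

.seqTm <- function(bases, cond) {
  th <- duplexThermoFromSequence(paste(bases, collapse = ""),
                                 saltMM = cond@saltMM)
  .tmC(th@dH, th@dS, cond@strandConcM)
}

.constraintsOK <- function(bases, gcMin, gcMax, maxHomopolymer) {
  gc <- .gcFraction(bases)
  gc >= gcMin && gc <= gcMax && .maxHomopolymer(bases) <= maxHomopolymer
}

# run code with a private RNG stream so generators are pure given their seed
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a domain sequence hitting a target melting temperature
#'
#' Rejection sampling of random sequences under GC-content and homopolymer
#' constraints, followed by a seeded local base-swap hill climb toward the
#' target Tm. The returned sequence satisfies every constraint and
#' `|Tm - targetTmC| <= tolC`; the same seed always returns the same
#' sequence. Infeasible specifications raise an error after a bounded number
#' of attempts.
#'
#' @param targetTmC target duplex melting temperature in deg C.
#' @param tolC acceptance tolerance in deg C (default 1).
#' @param lengthMin,lengthMax sequence length bounds in nt.
#' @param gcMin,gcMax GC-fraction bounds.
#' @param maxHomopolymer longest allowed single-base run.
#' @param seed RNG seed (mandatory; the generator is pure given the spec and
#'   seed).
#' @param cond [BindingConditions] under which Tm is evaluated.
#' @param maxAttempts restarts before declaring the spec infeasible.
#' @return a DNA string.
#' @examples
#' designDomain(53, lengthMin = 10, lengthMax = 16, seed = 7)
#' @export
designDomain <- function(targetTmC, tolC = 1, lengthMin = 10, lengthMax = 25,
                         gcMin = 0.3, gcMax = 0.7, maxHomopolymer = 4,
                         seed = 1, cond = bindingConditions(),
                         maxAttempts = 200) {
  if (lengthMin > lengthMax || lengthMin < 2)
    stop("invalid length bounds")
  if (tolC <= 0) stop("tolC must be positive")
  if (gcMin < 0 || gcMax > 1 || gcMin > gcMax) stop("invalid GC bounds")
  .withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      len <- if (lengthMin == lengthMax) lengthMin else
        sample(lengthMin:lengthMax, 1)
      bases <- NULL
      for (k in seq_len(50)) {
        cand <- sample(.BASES, len, replace = TRUE)
        if (.constraintsOK(cand, gcMin, gcMax, maxHomopolymer)) {
          bases <- cand
          break
        }
      }
      if (is.null(bases)) next
      err <- abs(.seqTm(bases, cond) - targetTmC)
      for (step in seq_len(300)) {
        if (err <= tolC) return(paste(bases, collapse = ""))
        pos <- sample(len, 1)
        newBase <- sample(setdiff(.BASES, bases[pos]), 1)
        prop <- bases
        prop[pos] <- newBase
        if (!.constraintsOK(prop, gcMin, gcMax, maxHomopolymer)) next
        propErr <- abs(.seqTm(prop, cond) - targetTmC)
        if (propErr < err) {
          bases <- prop
          err <- propErr
        }
      }
      if (err <= tolC) return(paste(bases, collapse = ""))
    }
    stop(sprintf(
      "no sequence satisfying the constraints found after %d attempts (target %.1f C may be infeasible)",
      maxAttempts, targetTmC))
  })
}

# strongest (highest-Tm) perfectly complementary contiguous segment between
# two strands, over all alignments and both strand orientations
.maxHybridTm <- function(a, b, cond) {
  best <- -Inf
  for (target in c(reverseComplement(b), b)) {
    na <- nchar(a)
    for (start in seq_len(na - 1)) {
      maxLen <- min(na - start + 1, nchar(target))
      if (maxLen < 2) next
      for (len in 2:maxLen) {
        seg <- substr(a, start, start + len - 1)
        if (!grepl(seg, target, fixed = TRUE)) break
        th <- duplexThermoFromSequence(seg, saltMM = cond@saltMM)
        denom <- th@dS + .RGAS * log(cond@strandConcM)
        tm <- if (denom >= 0) -Inf else th@dH * 1000 / denom - .C2K
        best <- max(best, tm)
      }
    }
  }
  best
}

#' Screen a strand panel for cross-hybridization
#'
#' For every non-cognate pair of strands, finds the strongest perfectly
#' complementary contiguous segment over all alignments and both
#' orientations, and reports its nearest-neighbor-predicted melting
#' temperature. A pair passes when that Tm is below `thresholdTmC`
#' (typically the panel's wash temperature). The result is invariant to
#' strand order and to reverse-complementing any input.
#'
#' @param strands named character vector of DNA sequences (>= 2 strands,
#'   unique names).
#' @param thresholdTmC pass threshold in deg C (default 37).
#' @param cond [BindingConditions] for the Tm evaluation.
#' @return an [OrthogonalityReport].
#' @export
orthogonalityScreen <- function(strands, thresholdTmC = 37,
                                cond = bindingConditions()) {
  if (length(strands) < 2) stop("need at least 2 strands")
  nms <- names(strands)
  if (is.null(nms) || anyNA(nms) || any(nms == ""))
    stop("strands must be named")
  if (anyDuplicated(nms)) stop("duplicate strand names")
  strands <- toupper(strands)
  n <- length(strands)
  tm <- matrix(NA_real_, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tm[i, j] <- tm[j, i] <- .maxHybridTm(strands[[i]], strands[[j]], cond)
  pass <- tm < thresholdTmC
  diag(pass) <- NA
  new("OrthogonalityReport", tmC = tm, thresholdTmC = thresholdTmC,
      pass = pass)
}

setMethod("show", "OrthogonalityReport", function(object) {
  off <- object@tmC[upper.tri(object@tmC)]
  cat(sprintf(
    "OrthogonalityReport: %d strands, worst off-target Tm = %.1f C (threshold %.1f C), %s\n",
    nrow(object@tmC), max(off), object@thresholdTmC,
    if (all(object@pass[upper.tri(object@pass)])) "all pairs pass"
    else "some pairs FAIL"))
})
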