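# Independent oracles used across the suite. These deliberately re-derive
# quantities with their own naive implementations and their own copies of
# published constants, so they share no code with the package internals.

# --- nearest-neighbor duplex thermodynamics, naive per-stack loop ----------
# unified Watson-Crick stack parameters (1 M NaCl), dH kcal/mol, dS cal/(mol K)
oracleStackDH <- list(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
                      CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
oracleStackDS <- list(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
                      GT = -22.4, CT = -21.0, GA = -22.2, CG = -27.2,
                      GC = -24.4, GG = -19.9)

oracleRevComp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# canonicalize a stack to the keyed orientation: a 5'->3' dinucleotide XY on
# the top strand is thermodynamically identical to the bottom-strand stack,
# i.e. the reverse complement read 5'->3'
oracleStack <- function(dinuc) {
  if (!is.null(oracleStackDH[[dinuc]])) return(dinuc)
  oracleRevComp(dinuc)
}

oracleDuplex <- function(seq, saltMM = 195) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  dH <- 0; dS <- 0
  for (i in seq_len(n - 1)) {
    key <- oracleStack(paste0(b[i], b[i + 1]))
    dH <- dH + oracleStackDH[[key]]
    dS <- dS + oracleStackDS[[key]]
  }
  for (end in c(b[1], b[n])) {
    if (end %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  if (seq == oracleRevComp(seq)) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1) * log(saltMM / 1000)
  list(dH = dH, dS = dS)
}

oracleTm <- function(dH, dS, concM) {
  dH * 1000 / (dS + 1.987 * log(concM)) - 273.15
}

# --- strongest cross-hybrid between two strands, exhaustive ----------------
# enumerates every contiguous segment of `a` (length >= 2), both strand
# orientations of `b`, and every alignment; reports the best oracle Tm
oracleMaxHybridTm <- function(a, b, concM = 250e-9, saltMM = 195) {
  best <- -Inf
  for (bb in c(b, oracleRevComp(b))) {
    rcb <- oracleRevComp(bb)
    na <- nchar(a)
    for (start in 1:(na - 1)) {
      for (stop in (start + 1):na) {
        seg <- substr(a, start, stop)
        if (grepl(seg, rcb, fixed = TRUE)) {
          th <- oracleDuplex(seg, saltMM)
          denom <- th$dS + 1.987 * log(concM)
          if (denom < 0)
            best <- max(best, th$dH * 1000 / denom - 273.15)
        }
      }
    }
  }
  best
}

# --- misc ------------------------------------------------------------------
naiveMaxProjection <- function(stack) {
  out <- matrix(-Inf, dim(stack)[1], dim(stack)[2])
  for (i in seq_len(dim(stack)[1]))
    for (j in seq_len(dim(stack)[2]))
      for (k in seq_len(dim(stack)[3]))
        out[i, j] <- max(out[i, j], stack[i, j, k])
  out
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# exhaustive maximum feasible channel count on a small design grid
oracleMaxPanelSize <- function(grid, yieldMin, overlapMax, tsFloorC,
                               tsCeilingC) {
  ok <- which(grid@yieldMap >= yieldMin & grid@tsMap >= tsFloorC &
                grid@tsMap <= tsCeilingC, arr.ind = TRUE)
  n <- nrow(ok)
  if (n == 0) return(0L)
  specs <- lapply(seq_len(n), function(k)
    thermalSpectrum(gridProbe(grid, grid@tmbAxis[ok[k, 1]],
                              grid@tmqAxis[ok[k, 2]])))
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j)
      compat[i, j] <- crosstalk(specs[[i]], specs[[j]]) <= overlapMax
  for (size in n:1) {
    for (sub in utils::combn(n, size, simplify = FALSE)) {
      if (all(compat[sub, sub])) return(size)
    }
  }
  0L
}
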