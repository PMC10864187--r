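# Readers and writers for panel tables (TSV), spectra (CSV + JSON sidecar),
# FASTA sequence sets, count matrices and TIFF images. All tables use '.'
# decimals and a fixed column order so reruns are byte-identical.

.PANEL_COLS <- c("name", "domain", "sequence", "tm_C", "dH_kcal", "conc_M",
                 "fluor")

#' Read a probe panel table
#'
#' The table is TSV with one row per probe domain: columns `name`, `domain`
#' (`barcode` or `quencher`), and per domain either a `sequence` (preferred;
#' thermodynamics from the nearest-neighbor model) or a `tm_C` (with
#' optional `dH_kcal`). Optional columns `conc_M` and `fluor` apply per
#' probe. When both sequence and `tm_C` are present and the nearest-neighbor
#' Tm disagrees by more than 2 deg C, a warning is raised.
#'
#' @param path TSV file path.
#' @param quencherExcess quencher:imager ratio applied to every probe.
#' @param saltMM monovalent salt in mM.
#' @return list of [ThermalProbeSet].
#' @export
readPanelTable <- function(path, quencherExcess = 1.2, saltMM = 195) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("name", "domain"))
    if (!col %in% names(tab))
      stop(sprintf("panel table is missing required column '%s'", col))
  if (!any(c("sequence", "tm_C") %in% names(tab)))
    stop("panel table needs a 'sequence' or 'tm_C' column")
  if (!all(tab$domain %in% c("barcode", "quencher")))
    stop("domain must be 'barcode' or 'quencher'")
  getcol <- function(row, col, default = NA) {
    if (col %in% names(tab) && !is.na(tab[row, col]) &&
        !identical(tab[row, col], "")) tab[row, col] else default
  }
  lapply(split(seq_len(nrow(tab)), tab$name)[unique(tab$name)], function(rows) {
    doms <- tab$domain[rows]
    if (!setequal(doms, c("barcode", "quencher")))
      stop("each probe needs exactly one barcode and one quencher row")
    concM <- as.numeric(getcol(rows[1], "conc_M", 250e-9))
    fluor <- as.character(getcol(rows[1], "fluor", "Alexa647"))
    cond <- bindingConditions(strandConcM = concM, saltMM = saltMM)
    mk <- function(row, defaultDH) {
      seqv <- getcol(row, "sequence", NA)
      tmv <- suppressWarnings(as.numeric(getcol(row, "tm_C", NA)))
      dhv <- suppressWarnings(as.numeric(getcol(row, "dH_kcal", defaultDH)))
      if (!is.na(seqv)) {
        th <- duplexThermoFromSequence(seqv, saltMM = saltMM)
        if (!is.na(tmv)) {
          nnTm <- .tmC(th@dH, th@dS, concM)
          if (abs(nnTm - tmv) > 2)
            warning(sprintf(
              "probe '%s' %s: sequence Tm %.1f C disagrees with stated tm_C %.1f C",
              tab$name[row], tab$domain[row], nnTm, tmv))
        }
        th
      } else if (!is.na(tmv)) {
        thermoFromTm(tmv, dhv, cond)
      } else stop(sprintf("probe '%s' %s row needs sequence or tm_C",
                          tab$name[row], tab$domain[row]))
    }
    bRow <- rows[doms == "barcode"]; qRow <- rows[doms == "quencher"]
    new("ThermalProbeSet", name = tab$name[bRow],
        barcode = mk(bRow, .DH_BARCODE), quencher = mk(qRow, .DH_QUENCHER),
        concM = concM, quencherExcess = quencherExcess, fluor = fluor,
        saltMM = saltMM)
  })
}

#' Write a probe panel table
#'
#' Inverse of [readPanelTable()]: two rows per probe (barcode and quencher),
#' with each domain's melting temperature and enthalpy at the probe's
#' reference concentration.
#'
#' @param panel list of [ThermalProbeSet] or a [ChannelPanel].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePanelTable <- function(panel, path) {
  if (is(panel, "ChannelPanel")) panel <- probes(panel)
  rows <- lapply(panel, function(p) {
    data.frame(name = p@name, domain = c("barcode", "quencher"),
               sequence = NA_character_,
               tm_C = c(tmB(p), tmQ(p)),
               dH_kcal = c(p@barcode@dH, p@quencher@dH),
               conc_M = p@concM, fluor = p@fluor)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a thermal spectrum
#'
#' Writes the curve as CSV (`temp_C`, `signal`) and the summaries
#' (`ts_C`, `yield`, `width_C`) as a JSON sidecar next to it.
#'
#' @param spectrum a [ThermalSpectrum].
#' @param path output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(temp_C = spectrum@tempsC,
                              signal = spectrum@signal),
                   path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(ts_C = spectrum@tsC, yield = spectrum@yield,
                            width_C = spectrum@widthC),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write DNA sequence sets as FASTA
#'
#' Thin wrappers over Biostrings for named character vectors.
#'
#' @param x named character vector of DNA sequences.
#' @param path FASTA file path.
#' @return `readFastaStrands` returns a named character vector.
#' @rdname fastaIO
#' @export
writeFastaStrands <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname fastaIO
#' @export
readFastaStrands <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Read and write TIFF images as numeric matrices
#'
#' Intensities are stored as 32-bit floats scaled to the TIFF unit range and
#' restored on read via the `scale` attribute written alongside.
#'
#' @param image numeric matrix (or 3-D array for a stack).
#' @param path TIFF path.
#' @rdname tiffIO
#' @export
writeImageTiff <- function(image, path) {
  mx <- max(image, 1e-12)
  tiff::writeTIFF(image / mx, path, bits.per.sample = 32L,
                  reduce = TRUE)
  jsonlite::write_json(list(scale = mx), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tiffIO
#' @export
readImageTiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  scl <- 1
  side <- paste0(path, ".json")
  if (file.exists(side)) scl <- jsonlite::read_json(side)$scale
  if (length(img) == 1) return(img[[1]] * scl)
  array(unlist(img), dim = c(dim(img[[1]]), length(img))) * scl
}

#' Write a label mask as TIFF
#'
#' Labels are stored as integer grey levels (16-bit).
#'
#' @param mask integer label matrix.
#' @param path TIFF path.
#' @rdname tiffIO
#' @export
writeMaskTiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiffIO
#' @export
readMaskTiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}
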