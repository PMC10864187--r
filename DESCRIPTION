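Package: thermalFISH
Title: Design and Analysis of Temperature-Multiplexed DNA Probes for Sequential FISH Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing DNA probe sets that fluoresce only inside
    programmed temperature windows (thermal channels) and for quantifying the
    single-molecule FISH images used to validate them. Implements two-state
    nearest-neighbor duplex thermodynamics, thermal-spectrum prediction for
    two-domain imager/quencher probes, systematic scans of the barcode/quencher
    melting-temperature design space with crosstalk-constrained channel
    selection, dissociation and rebinding kinetics, domain sequence generation
    with orthogonality screening, puncta detection and colocalization in spot
    images, per-cell transcript counting, and correlation-distance hierarchical
    clustering of multiplexed per-cell counts. Includes seeded simulators for
    spot images and count matrices so that every stage can be exercised and
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    tiff,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
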