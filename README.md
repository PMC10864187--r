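# thermalFISH

Design and analysis of temperature-multiplexed DNA probes for sequential
FISH imaging.

## What problem this solves

Sequential multiplexed FISH usually cycles its imaging rounds by buffer
exchange — slow, fluidically fragile, and hard on the sample. A
fluidics-free alternative encodes the rounds in temperature: each target
carries a two-domain DNA probe set in which a fluorescent **imager** strand
binds a barcode overhang (duplex melting temperature `Tmb`) and is
pre-hybridized to a **quencher** strand (melting temperature `Tmq < Tmb`).
Below `Tmq` the probe is dark; a brief heating spike into the window between
the two transitions melts off the quencher while the imager stays bound, and
the spot fluoresces — even after cooling, because the dissociated strands
are too dilute to rebind. A hotter spike removes the imager and retires the
channel. Increasing spikes therefore read out one **thermal channel** after
another.

`thermalFISH` is for anyone designing such probe panels or quantifying the
smFISH images that validate them. It provides:

* **Duplex thermodynamics** (`duplexThermoFromSequence`, `thermoFromTm`,
  `meltingTemperature`, `fractionBound`): unified nearest-neighbor sums with
  salt correction, and the two-state occupancy
  `theta(T) = cK/(1 + cK)`, `K(T) = exp(-(dH - T dS)/(R T))`, so that
  `Tm = dH/(dS + R ln c)`.
* **Thermal spectra** (`thermalSpectrum`): the probe signal
  `s(T) = theta_barcode(T) (1 - theta_quencher(T))` with its signal
  temperature `Ts` (argmax), yield (max) and width (FWHM), plus the
  sequential-protocol signal matrix (`protocolSignalMatrix`).
* **Panel design** (`gridScan`, `crosstalk`, `selectChannels`,
  `verifyPanel`): scan the `(Tmb, Tmq)` design space, quantify
  inter-channel crosstalk, and greedily select a maximal set of channels
  with yield ≥ 0.8, pairwise crosstalk ≤ 0.12 and signal temperatures above
  the 37 °C wash floor.
* **Kinetics** (`simulateProtocol`, `dissociationTime`,
  `rebindingFraction`): ODE and closed-form switching kinetics with
  `kOff(T) = kOn/K(T)`.
* **Sequence design** (`designDomain`, `orthogonalityScreen`): seeded
  generation of domain sequences hitting target melting temperatures and a
  brute-force cross-hybridization screen.
* **Image quantification** (`maxZProjection`, `detectPuncta`, `colocalize`,
  `perCellCounts`, `filterCells`, `overlayReconstruction`) and
  **expression analysis** (`normalizeCounts`, `correlationClustering`) for
  multiplexed per-cell counts.
* **Seeded simulators** (`simulateSpotImages`, `simulateCounts`) so every
  stage is testable without microscope data, and a CLI
  (`inst/cli/thermalfish.R`) exposing the main operations as subcommands.

## Worked example

```r
library(thermalFISH)

# the validation probe set: quencher melts at 53 C, barcode at 61 C
probe <- thermalProbeSet("APC", tmbC = 61, tmqC = 53)
thermalSpectrum(probe)
#> ThermalSpectrum: 601 points (20.0-80.0 C), Ts = 57.5 C, yield = 0.829, width = 8.7 C
```

The probe is predicted to fluoresce after a spike to about 57 °C — between
its two domain melting temperatures — with 83 % of full signal and an
~8.7 °C-wide channel. Scanning the whole design space and selecting
channels under the default design rules:

```r
panel <- selectChannels(gridScan())
panel
#> ChannelPanel with 5 thermal channels
#>  tmbC tmqC  tsC yield widthC
#>    42   35 38.9 0.822    7.7
#>    50   43 46.9 0.804    7.9
#>    59   51 55.5 0.833    8.7
#>    68   60 64.5 0.814    8.9
#>    78   69 74.1 0.836    9.8
#> max pairwise crosstalk: 0.105
```

Five channels fit between the wash floor and 75 °C, every yield clears 0.8,
and the worst pairwise crosstalk is 0.105 — below the 0.12 design bound.
Switching speed at the 57 °C spike:

```r
rm53 <- rateModel(thermoFromTm(53, -75, bindingConditions()))
dissociationTime(rm53, 57)   # seconds to 1% bound
#> [1] 4.532725
```

so the quencher is 99 % dissociated in under 5 s, while rebinding at
imaging concentrations stays negligible
(`rebindingFraction(rm53, 1e-15, 24*3600, 30)` is ~9e-5 over 24 h at 1 fM).

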