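---
title: "Designing and validating thermal channels for sequential FISH imaging"
author: "thermalFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating thermal channels for sequential FISH imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalFISH)
```

# The problem

Sequential multiplexed FISH normally cycles fluorescent labels by buffer
exchange, which is slow and fluidically awkward. An alternative is to encode
the imaging rounds in *temperature*: each target carries a two-domain DNA
probe set — a fluorescent **imager** strand bound to a barcode overhang
(duplex melting temperature $T_{mb}$) and pre-hybridized to a **quencher**
strand (melting temperature $T_{mq} < T_{mb}$). Below $T_{mq}$ the probe is
dark; after a brief heating spike into the window between the two melting
transitions, the quencher melts off while the imager stays bound, and the
spot fluoresces — including after cooling back to the imaging temperature,
because the dissociated strands are too dilute to rebind. A spike above
$T_{mb}$ removes the imager and extinguishes the channel. Applying spikes in
increasing order therefore reads out one **thermal channel** after another
with no fluidics at all.

This package implements the computational machinery behind that scheme:
the duplex thermodynamics, the thermal-spectrum model, the design-space scan
and channel selection, dissociation/rebinding kinetics, domain sequence
generation with orthogonality screening, the image quantification used to
validate channels, and seeded simulators that make every stage testable.

# The thermodynamic model

## Two-state duplexes under the free-ligand convention

Each domain duplex is treated as all-or-none with van't Hoff parameters
$\Delta H < 0$ (kcal/mol) and $\Delta S < 0$ (cal/(mol K)). The in-situ
partner (barcode, or the imager's quencher-binding site) is at negligible
concentration while the free strand is at concentration $c$, so the bound
fraction is

$$\theta(T) = \frac{c\,K(T)}{1 + c\,K(T)}, \qquad
K(T) = \exp\!\left(-\frac{\Delta H - T\Delta S}{RT}\right),$$

with $R = 1.987$ cal/(mol K) and $T$ in Kelvin (all interfaces use °C).
Setting $\theta = 1/2$ gives the closed form
$T_m = \Delta H / (\Delta S + R\ln c)$. `thermoFromTm()` inverts this
exactly, so probe sets can be specified by domain $T_m$ alone, as the design
heatmaps are parameterized.

Sequence-specified domains use the unified nearest-neighbor stack table with
terminal initiation terms, the self-complementarity entropy correction, and
the standard monovalent-salt entropy correction
$\Delta S \mathrel{+}= 0.368\,(n-1)\ln[\mathrm{Na}^+]$. Reference
conditions are 250 nM probe and 195 mM monovalent salt (PBS/SSC scale).
Mismatch and dangling-end corrections, divalent salt, and secondary
structure are out of scope.

## The thermal spectrum

The two domains do not overlap, so their equilibria are treated as
independent and the modeled signal is the product

$$s(T) = \theta_b(T)\,\bigl(1 - \theta_q(T)\bigr),$$

where $\theta_q$ is evaluated at the quencher's excess concentration
(1.2 : 1 by default, matching how the probes are assembled). Contact
quenching is treated as complete; residual background and photophysics are
not modeled. A `ThermalSpectrum` records $s(T)$ on a uniform grid (default
20–80 °C at 0.1 °C; refining to 0.01 °C moves the summaries by less than
0.1 °C) together with the signal temperature $T_s$ (argmax), the yield
(maximum, reported as the raw curve maximum without renormalization), and
the full width at half maximum $W$ from interpolated half-max crossings.

Because the dissociated strands persist in a dilute metastable state, the
signal imaged at ~30 °C after a spike equals the equilibrium signal *at the
spike temperature*; `protocolSignalMatrix()` encodes this sequential
irreversibility and therefore only accepts strictly increasing spike lists.

## Default domain enthalpies

When a domain is given by $T_m$ only, an enthalpy must be assumed; it sets
the steepness of the melting transition and hence the spectrum width. The
defaults are $\Delta H = -160$ kcal/mol for the barcode domain and
$-110$ kcal/mol for the quencher domain — typical unified nearest-neighbor
magnitudes for the 18–25 nt and 12–16 nt duplexes these domains use (about
$-8$ kcal/mol per stack). Two properties anchor the choice and are enforced
by the test suite: the 53 °C/61 °C worked example peaks at 57 °C, and the
full design scan packs five mutually compatible channels into 37–75 °C.
Substantially shallower enthalpies (e.g. $-75$/$-95$) still reproduce the
57 °C example but broaden every spectrum to the point where no five-channel
design satisfying the crosstalk rule exists, contradicting the validated
design; the defaults were fixed once on the length-based rationale and are
configurable per probe.

# Channel design

`gridScan()` evaluates the spectrum summaries over all combinations of
barcode $T_m$ (40–80 °C) and quencher $T_m$ (35–75 °C) at 1 °C resolution
(spectra on the 0.1 °C sub-grid). High separation $T_{mb}-T_{mq}$ gives high
yield but wide spectra; the usable designs sit on the diagonal band with
yield above 0.8 and relatively narrow width.

Crosstalk between two channels is defined operationally: imaging only ever
happens at the spike temperatures, so the default metric is the worst-case
normalized signal of one probe at the other's spike,
$\max\bigl(s_i(T_{s,j})/y_i,\; s_j(T_{s,i})/y_j\bigr)$. An integral overlap
coefficient (pointwise minimum of the unit-area-normalized spectra) is
available via `crosstalk(x, y, method = "integral")` for grid-free
comparisons.

`selectChannels()` performs a greedy sweep upward from the wash-temperature
floor (37 °C by default, so the coolest channel survives post-hybridization
washing; ceiling 75 °C): repeatedly admit the candidate cell with the lowest
$T_s$ whose yield is at least 0.8 and whose crosstalk with every admitted
channel is at most 0.12, breaking $T_s$ ties by yield, then width, then
lower $T_{mb}$. The sweep is deterministic, and because crosstalk decays
with channel separation the greedy solution matches exhaustive subset search
on coarse grids (verified in the tests). Selected panels are re-verified
from raw spectra by `verifyPanel()` — selection cannot self-certify. Under
the default rules the scan yields five channels with signal temperatures
near 39, 47, 56, 65 and 74 °C, maximum pairwise crosstalk ≈ 0.105 and
minimum yield ≈ 0.80; tightening `overlapMax` to 0.05 still leaves a
four-channel panel.

# Kinetics

Channel switching rests on two rates: quencher melt-off during the spike
must be fast, and rebinding at imaging temperature must be negligible. Both
follow from first-order kinetics
$d\theta/dt = k_{on} c (1-\theta) - k_{off}(T)\theta$ with a
temperature-independent $k_{on} = 10^6\ \mathrm{M^{-1}s^{-1}}$ (a standard
oligonucleotide association magnitude; the true value is not critical
because both conclusions are robust over orders of magnitude) and all
temperature dependence in $k_{off}(T) = k_{on}/K(T)$. `simulateProtocol()`
integrates both duplexes through a piecewise-linear temperature protocol
(~5 s ramp to the setpoint, ~20 s cool-down in practice) with a stiff-safe
integrator (absolute tolerance $10^{-9}$, fixed 10 Hz output grid); its
fixed points match the closed-form occupancy to $10^{-6}$, and with no free
strand the trajectory matches quadrature of $k_{off}$ to $10^{-8}$.

At a 57 °C spike a quencher with $T_{mq} = 53$ °C has
$k_{off} \approx 1\ \mathrm{s^{-1}}$, so 99 % dissociation takes ≈ 4.5 s —
within the ~5 s the heater needs to reach the setpoint. Conversely, at the
femtomolar–picomolar concentrations of dissociated strands,
$1 - e^{-k_{on} c t}$ stays below $10^{-4}$ over 24 h at 1 fM, so rebound
signal is negligible (`rebindingFraction()` caps the estimate at the
equilibrium occupancy).

# Sequence design and orthogonality

`designDomain()` generates domain sequences by rejection sampling under
GC-content (0.3–0.7) and homopolymer (≤ 4) constraints followed by a local
base-swap hill climb until the nearest-neighbor $T_m$ is within tolerance of
the target. All randomness sits behind an explicit seed; infeasible
specifications fail loudly after a bounded number of restarts rather than
returning a weak sequence. This simple generator stands where an ensemble
designer would in a full pipeline; its outputs are validated only through
the screen below, and `writeFastaStrands()` exports candidates for external
transcriptome screening.

`orthogonalityScreen()` scores every non-cognate strand pair by the
strongest perfectly complementary contiguous segment over all alignments and
both orientations (no loops or bulges — a conservative, brute-forceable
criterion) and reports its predicted $T_m$; pairs pass below the wash
temperature. Note the worst-case segment can melt *above* the full-duplex
$T_m$ when trimming AT-rich ends: the screen maximizes over all segments.

# Image quantification

The validation pipeline mirrors standard smFISH practice: maximum Z
projection; binarization at a signal threshold (default mean + 5 SD of the
image, absolute override available); 8-connected components of at least
2 px become puncta carrying centroid (0-based row/col), area, and the
maximum pixel value they cover; border puncta are retained. Two-channel
colocalization matches puncta one-to-one by greedy global nearest distance
within 2 px (ties by distance, then row, then col), so per-channel
fractions conserve: only + both = 100 %. Per-cell counting assigns each
centroid to the label-image cell under it (background tallied separately,
conserving totals), and the expression filters drop cells below 5 copies
for high-expression targets and below 2 copies for low-expression targets.
Rounds share one coordinate frame (no registration), so multi-round
reconstruction is a concatenation. Cell segmentation itself is out of
scope — masks are supplied as label images.

Per-cell counts are normalized to each cell's total, correlated pairwise
(Pearson, on the normalized fractions — not log-transformed), converted to
distances $d = 1 - r$, clustered agglomeratively with average linkage, and
cut at a requested group count (no automatic cut selection). Zero-variance
targets are flagged and must be dropped explicitly.

# Synthetic data and what passing tests show

`simulateSpotImages()` renders isotropic Gaussian puncta (σ = 1.5 px) at
random positions with Poisson noise on the total signal plus Gaussian read
noise, optional planted colocalization between two channels (shared
positions jittered by at most 0.5 px), and a rectangular-tile cell mask.
`simulateCounts()` plants correlation blocks through a Gaussian-copula
factor model mapped to negative-binomial counts (mean 30, size 10 by
default). Both are pure functions of their spec and seed.

Benchmarks use amplitude 100 on background 100 (SNR ≈ 10 against the
Poisson shot noise), 100–200 spots in 512 × 512 frames placed with an 8 px
minimum separation so that detection performance is measured rather than
spot collision, and 200 cells × 15 targets with within-block latent
correlation 0.8 for clustering recovery. Under these conditions detection
recall and precision reach 0.98, planted colocalization is recovered within
its binomial interval, and the planted 4-block structure is recovered
exactly (adjusted Rand index 1). These simulations omit autofluorescence,
uneven illumination, optical sectioning and segmentation error, so passing
them demonstrates correctness of the algorithms, not performance on real
tissue; statistics measured on real microscopy data (e.g. experimental
colocalization percentages) are deliberately not benchmark targets here.

# Numerical choices and limitations

* Temperatures are °C at every interface and Kelvin internally; all
  formulas use $R = 1.987$ cal/(mol K).
* Width uses linear interpolation of the half-max crossings and clamps at
  the grid edge if a crossing lies outside the grid.
* Grid argmax ties (exactly equal signal at two temperatures) resolve to
  the lower temperature; selection ties resolve by yield, width, then
  $T_{mb}$ — all deterministic.
* The equilibrium formulation treats the three strands as two independent
  duplexes; coupling between barcode and quencher occupancy is second
  order for non-overlapping domains and is ignored.
* The crosstalk bound of a *selected* panel is exact under the model, but
  the model itself ignores quenching inefficiency (>95 % in practice) and
  spectral bleed-through between fluorophores.
* Degenerate inputs fail explicitly: empty/1-nt sequences, non-physical
  parameters ($\Delta S + R\ln c \ge 0$), non-increasing spike lists,
  zero-yield spectra in crosstalk, all-zero count matrices.

# Session info

```{r}
sessionInfo()
```
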