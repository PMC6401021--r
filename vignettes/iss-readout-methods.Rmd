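---
title: "Methods: simulating and reading out in situ sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reading out in situ sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issread)
```

This vignette is the package's account of its own methods: the models
behind the synthetic-data generator, the readout algorithms and their
parameters, the numerical choices made where the design was genuinely
open, and what the passing test suite does and does not establish about
real microscope data.

## The readout model

An in situ sequencing acquisition is a stack indexed
`[cycle, channel, row, col]` with six channel roles: `DAPI` (nuclei),
`ANCHOR` (a fluorescent primer common to all rolling circle products,
RCPs), and one channel per base-specific sequencing probe
(`A`, `C`, `G`, `T`).  The analysis chain is:

* **Detection** on the anchor channel of the reference cycle: white
  top-hat (disc radius 3 px) to suppress slowly varying background, a
  global threshold at `k` median absolute deviations above the median
  of the top-hat image (`threshold_k`, default 5), connected
  components of at least `min_area` = 4 px, and a watershed on the
  top-hat intensity to split merged components around local maxima.
* **SNR** per spot: mean anchor intensity over the spot mask divided by
  the mean over an annulus extending 8 px outward from the mask
  (Euclidean distance), excluding every detected spot's mask.  The
  8-px surround convention is one of several possible readings of "its
  surrounding within an eight pixels region"; an annulus of 8-px
  extent is the most common convention for small-spot photometry and
  the width is exposed as `annulus_width`.
* **Registration**: per-cycle integer rigid shifts against cycle 1 by
  FFT cross-correlation of the anchor channel.  Sub-pixel refinement is
  deliberately out of scope; the simulator's jitter is integer-valued,
  which keeps the registration problem well-posed at this scale.
* **Intensity extraction**: per cycle, the spot mask and its annulus
  are moved by the cycle's shift; the measurement is the mean
  base-channel intensity over the mask minus the **median** over the
  annulus in the same channel (median rather than mean, to be robust
  against neighbouring spots leaking into the surround).
* **Base calling**: the called base is the arg-max channel and the call
  quality is `max(signals)/sum(signals)` after clipping negatives to
  zero.  For four non-negative channels with positive total this lies
  in [0.25, 1]: 1 when one channel carries everything, 0.25 when all
  four are equal.  An exact tie is flagged ambiguous (the
  alphabetically first tied base is reported, for reporting only); an
  all-zero vector gets quality 0.
* **Read assembly and decoding**: bases concatenate cycle by cycle; a
  spot is discarded if its quality drops below the threshold at *any*
  cycle, if any call is ambiguous, or if a cycle is missing.  Survivors
  are decoded by exact match against the codebook — no error
  correction, matching the plain exact-match decoding of low-plex
  designs.  The default threshold is 0.5; the value used by the
  original ISS analysis pipeline is unpublished, so 0.5 is a package
  default, not a claim.  Ambiguous-call discarding is this package's
  reading of quality filtering: a tie carries no base information, so
  letting a tie-broken base survive a quality threshold would
  manufacture certainty.
* **Metrics**: RCP yield (spots per cell), reads per cell
  (expected/unexpected separately), sequencing accuracy
  `expected/(expected + unexpected)` with discarded reads excluded
  from both numerator and denominator, per-cycle per-base mean
  quality, stacked per-base quality against a control, stripping
  efficiency, and performance efficiency (PE).

### Performance efficiency and the stacked quality bar

PE normalizes an on-chip (device-run) metric to its matched off-chip
(manual) control.  Two aggregations are computed and always reported
together: the mean of per-replicate matched ratios (`mean(on_i/off_i)`,
the default) and the ratio of means.  These genuinely differ —
per-replicate normalization can exceed the ratio of the pooled means —
which is why both are labelled explicitly in the `iss_pe` row.

The stacked quality bar averages RCP quality within each called-base
group, downscales each group mean by four, stacks the four
contributions and normalizes to the control.  Under the default
`"stack"` normalization every contribution is divided by the control's
stack total, so the contributions sum to the normalized total and a
total of 1 means base calling as robust as the control.  A
`"per-group"` normalization (each base against the control's same
base) is available because the stacked-bar construction admits both
readings; for balanced conditions they coincide.  Note that identical
on/off conditions always stack to exactly 1, but the four
contributions are each 0.25 only when the four group means are equal —
which is the design expectation for orthogonal barcodes, not an
algebraic identity.

### Stripping efficiency

No standard formula exists for stripping efficiency, so the package
defines it operationally: one minus the ratio of mean
background-subtracted base-channel spot signal after stripping to the
same quantity before, clipped to [0, 1].  On simulated pre/post pairs
this recovers `1 - strip_residue` to within ±0.05 across residues
0.05–0.4 (the acceptance suite sweeps five values).

## The synthetic-data generator

The generator emulates a mouse-embryonic-fibroblast experiment in which
four padlock probes with **orthogonal** four-letter barcodes (at every
barcode position each base occurs exactly once: `ACGT`, `CGTA`,
`GTAC`, `TACG`) all report one transcript.  Its defaults are the
package's standing study conditions:

| parameter | default | why |
|---|---|---|
| `pixel_size` | 0.32 µm/px | typical 20–40× epifluorescence sampling |
| `spot_sigma` | 1.5 px | renders ~1 µm spots, the physical RCP size |
| `field_size` | 384 × 384 px | a 123 µm field holding ~8 fibroblasts |
| `nucleus_radius` | 14 ± 2 px | ~4.5 µm nuclear radius |
| `cell_radius` | 40 px | ~13 µm RCP spread around each nucleus |
| `rcps_per_cell` | Poisson(40) | tens of transcripts per cell |
| `amplitude` | lognormal(log 6000, 0.35) | puts mean anchor SNR in 8–11 |
| `background_level` | 200 counts | camera offset + autofluorescence |
| `read_noise_sd` | 10 counts | additive camera noise |
| `crosstalk` | 0.85 diag / 0.05 off | spectral bleed-through |
| `strip_residue` | 0.1 | incomplete probe stripping |
| `dropout_prob` | 0.01/cycle | spots failing to restain |
| `jitter_sd` | 1 px | stage repositioning between cycles |

Two figures are calibrated rather than taken from a published value,
because none is published: spot density and brightness.  Brightness was
chosen once so the detected mean anchor SNR lands in the qualitative
8–11 range reported for such assays; geometry was chosen to match the
physical dimensions of fibroblasts at the stated pixel size.  Neither
is revisited per experiment.

The noise model is the standard camera model: Poisson shot noise on
signal plus background, then additive Gaussian read noise, then
quantization to 16-bit integer counts (which also makes the TIFF round
trip lossless).  Base-channel signal is built per cycle as the true
base's Gaussian spots mixed through the crosstalk matrix (rows = true
base, columns = observed channel), plus `strip_residue` times the
previous cycle's *mixed* base signal — the carry-over therefore
compounds geometrically across cycles, which is what makes per-cycle
quality visibly decay when the residue is large.

All randomness flows through one seeded stream with a documented draw
order (cell geometry, spot counts, placements, barcodes, amplitudes,
jitter, dropout, then per-plane noise), so tests can replay any prefix
of the stream as an independent oracle.  Identical configurations are
bit-identical.  When `min_spot_separation > 0` the placement step
switches to rejection sampling so that resolution-controlled fields
(every pair of spots separated) can be produced; this inserts extra
uniform draws into the stream and is documented in the function help.

### What the generator does *not* emulate

No optical aberrations, z-structure, uneven illumination, structured
tissue autofluorescence, cell-shape realism (nuclei are disks, RCP
placement is an isotropic disk around each nucleus), or
molecular-level enzyme kinetics.  Consequently, passing tests show
that the readout algorithms are *correct* (they recover what the
generative model planted, degrade monotonically with each nuisance
parameter, and agree with brute-force oracles), not that the specific
default thresholds are optimal for any particular microscope.  On real
data, segmentation of touching irregular nuclei and illumination
gradients are the first things that would need attention.

## Numerical choices and degenerate inputs

* Coordinates are **1-based** `(row, col)` throughout, as is idiomatic
  in R; `x` is the row and `y` the column index.
* The detection threshold `median + k·MAD` degenerates on noise-free
  fixtures where the MAD of the top-hat image is zero; the fallback is
  `median + 2 % of the dynamic range`, which keeps blank images at
  zero detections while noise-free spots remain detectable.
* The watershed split tolerance is a fraction (default 0.05) of the
  top-hat maximum.  Two Gaussians closer than ~2σ form a single local
  maximum and are reported merged — by construction, not failure; the
  pair-resolution test documents the boundary.
* A spot whose surround annulus is empty or zero-mean gets `snr = NA`
  and an explicit flag rather than an invented ratio; empty per-cycle
  quality groups are reported `NA`, not zero.
* Featureless images give zero estimated shift with a `confident =
  FALSE` flag.
* Zero-denominator metrics (yield with zero cells, accuracy with no
  survivors, PE against a zero control) raise errors or exclude the
  pair with a warning rather than returning infinities.

## The transport module

The mass-transport arguments for running the assay in a shallow
chamber reduce to four closed forms: chamber volume (slab `L·W·H`,
cylinder `π(d/2)²·H`; 1 mm³ = 1 µL), characteristic diffusion time
`x²/(αD)`, Stokes–Einstein diffusivity from molar mass (hydrodynamic
radius of the equivalent sphere at 0.73 cm³/g), and the stranded
fraction `1 − min(H, √(αD·t½))/H` for enzyme spread uniformly over a
chamber of height `H` above the sample.

The convention prefactor α defaults to 1 (`x = √(Dt)`).  This choice
is deliberate: for a phi29-class polymerase (D = 70 µm²/s, half-life
18 min at 30 °C) in an 0.8 mm-deep manual chamber it yields a stranded
fraction of 0.656 — "almost two thirds" — whereas α = 2 would give
0.514, which no longer matches that description.  α is exposed on
every function for users who prefer a mean-squared-displacement
convention.  The treatment is one-dimensional along the chamber
height; lateral transport and depletion kinetics are out of scope.

## Problem sizes

The test suite and acceptance script run on 192–384 px fields with
4–8 cells and 40–80 spots per condition, 10–20 seeds for the
expectation-level properties, 220 replicate micro-fields for the
Poisson goodness-of-fit, and 10,000 spots for the null-accuracy check.
These sizes give every stochastic assertion a comfortable margin
(3–5 σ) while keeping a full run around a minute.
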