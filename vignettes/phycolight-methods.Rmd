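---
title: "Methods: pigment-based algal group classification and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pigment-based algal group classification and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycolight)
```

## The measurement model

`phycolight` analyzes emission spectra from a multi-excitation LED
fluorometer. Each sample yields an excitation–emission matrix (EEM): one
emission spectrum (counts vs wavelength, arbitrary units) per LED, with a
default excitation set of 371, 402, 523, 572, 595, and 612 nm, plus an
optional broadband absorbance spectrum. All downstream arithmetic works on
*window peak intensities*: the maximum of the blank-corrected spectrum
inside a fixed wavelength window bracketing each pigment's emission peak.

The central assumptions are:

1. **Linearity.** Each pigment's peak intensity is proportional to cell
   concentration over the calibrated range. Departures at high optical
   density are attributed to the inner-filter effect and corrected
   multiplicatively (below).
2. **Resolvable peaks.** Each pigment present contributes a distinct local
   maximum inside its window. This is what licenses scalar peak
   arithmetic; its enforcement is described under *Shoulder rejection*.
3. **Scaling-factor ratios.** Within a taxon, the ratios among
   phycocyanin (PC), phycoerythrin (PE), and chlorophyll-a (chl) peak
   intensities are deterministic functions of the excitation and emission
   wavelengths:
   S~α~ = 3·λ~em~(PC)/λ~ex~ − 2 (PC/chl, cyanobacteria),
   S~β~ = 2·λ~em~(PE)/λ~ex~ − 1 (PE/PC, red algae),
   S~γ~ = S~α~ − 1 (PC/chl, red algae), and S~δ~ = S~β~·S~γ~ (PE/chl,
   red algae). These are empirical, dimensionless models; the package
   treats them as valid at the excitations where they were demonstrated
   (523/595/612 nm for S~α~/S~γ~, 402/523 nm for S~β~) and emits a
   calibration-domain warning elsewhere. Contexts that drive a factor to
   zero or below (emission at or below excitation) make division-based
   predictions undefined and raise a hard error rather than returning an
   infinity.

## The deconvolution hierarchy

`deconvolve_quantify()` quantifies a mixture at a single
phycobilin-exciting analysis wavelength (default 523 nm) in a fixed
order dictated by pigment specificity:

1. **Red algae** from the PE window peak via the red calibration
   (PE is unique to red algae).
2. **Cyanobacteria** from the PC window peak after removing the red-algal
   PC share I~PE~/S~β~.
3. **Green algae** from the chl-a window peak after removing the
   cyanobacterial share (PC excess ÷ S~α~) and the red-algal share
   (I~PE~ ÷ S~δ~).

The hierarchy, the clamping of negative residuals at zero (with a
`residual_clamped` flag), and the flag semantics are design choices of
this package; the underlying share arithmetic follows the scaling-factor
model. Shares plus residuals equal the measured window intensities
exactly before clamping, so the decomposition conserves intensity.

Residuals at or below k·σ~blank~ (default k = 3, the conventional
spectroscopic detection threshold; σ~blank~ is the blank's standard
deviation in counts) are reported as zero cells with a `below_noise`
flag: evidence below the noise floor is non-detection, not a small
positive concentration. Detection (`detect_groups()`) applies the same
share arithmetic to decide which groups are present, and flags Cyl-type
cyanobacteria when the 619 nm marker window also holds a peak.
Golden-brown algae (diatoms) are detected and quantified only by their
fucoxanthin absorbance bands at 449 and 486 nm, via through-origin
Beer–Lambert calibrations; both bands are inverted and reported with
their mean.

When no phycobilins are detected, green algae can instead be calibrated
and quantified directly at 402 nm (the chl-a Soret excitation), where
their signal is strongest; the residual-chl route is only needed in the
presence of cyanobacteria or red algae, and the scaling-factor contexts
are demonstrated at the phycobilin excitations.

### Shoulder rejection

With adjacent emission bands, a strong neighbor's flank can exceed the
target pigment's own peak at a window edge (for example, a large chl-a
band places ~20 % of its height at the upper edge of the PC window).
Detection and deconvolution therefore read each window with a local-max
rule: the highest *interior local maximum* is used; if the window
contains no local maximum at all, the signal there is a shoulder of a
neighboring band and the pigment is scored absent (intensity zero).
`find_peak()` itself keeps the plain window-argmax contract (ties broken
toward the lowest wavelength) for calibration series built from pure
cultures, where no competing band interferes. No smoothing is applied
before peak reading; peak positions are reported at grid resolution.

## Inner-filter correction

At high optical density the excitation beam is attenuated on its way into
the detection volume and the emission re-absorbed on its way out,
depressing fluorescence below the calibration line. The correction is

I~corr~ = I~obs~ · 10^(OD~ex~ + OD~em~),  OD = ε · l · C,

with absorptivities ε per (cells/mL) per cm from through-origin
Beer–Lambert fits (`fit_absorptivity()`) or the genus registry, and
path lengths defaulting to 0.87 cm (excitation) and 0.9 cm (emission) —
the modeled instrument's geometry; both are configurable. The OD terms
are taken as exactly ε·l·C with no additional geometric factor. Because
the concentration is not known before inversion, `deconvolve_quantify()`
applies the correction as a short fixed-point iteration (invert, compute
OD at the estimate, correct, re-invert; six rounds, far past convergence
at the ODs of interest, which are ≲ 0.1). Correction precedes
calibration inversion throughout.

## Cell geometry and volume normalization

Per-cell fluorescence scales with cell size, so calibrations are
normalized by the cell-size volume ratio V/V~max~ (mean over
fully-grown cell volume), letting one calibration serve growing and
mature cultures; an optional reference-volume factor re-uses one genus's
calibration for another (e.g. an *Anabaena* calibration applied to
*Microcystis* with the ratio 446/568.8 ≈ 0.78). Volumes come from simple
solids on measured cell dimensions: sphere πd³/6, ellipsoid πd₁d₂d₃/6,
cylinder πd²L/4. Two registry genera store fixed volumes instead:
*Ankistrodesmus* (1902 µm³; its cylinder-with-conical-ends shape is not
computable from the recorded diameter and length alone) and *Cyclotella*
(572 µm³; the short-cylinder formula on the recorded 10.3 × 6.8 µm size
gives ≈ 567 µm³, and the recorded value is kept authoritative). The
registry's two-ratio normalization (V/V~max~ plus a cross-genus
reference) is composed multiplicatively; the reference term is off by
default because its composition order with V/V~max~ is ambiguous in the
source material.

Dry weight maps linearly onto volume-normalized cell counts
(`dry_weight_from_counts()`): counts are multiplied by V/V~max~ before
the linear map, which collapses growing and fully grown cultures onto a
single counts-to-dry-weight line.

## Calibration conventions

- `fit_line()` (ordinary least squares via `stats::lm`) reports an
  intercept by default: measured fluorescence calibrations have gradients
  near but not exactly through the origin, and forcing them through zero
  would hide blank-subtraction bias.
- Beer–Lambert absorbance fits are through-origin: A(0) = 0 is physical.
- Inverted concentrations below zero are clamped to zero with a warning
  (physical floor); predictions outside the fitted concentration range
  warn about extrapolation. Inversion of a zero-slope calibration
  (|slope| < 10⁻¹²) is an error.

Two percent-comparison conventions appear in practice and both are
provided: `percent_difference()` uses the mean of the two values as
denominator (reproducing comparisons such as 644 vs 643 nm → 0.16 % and
4.54×10⁵ vs 4.56×10⁵ cells/mL → 0.44 %), while `percent_lower()` uses
the reference value as denominator (reproducing "0.9042 is 5.5 % lower
than 0.9568", which the mean convention would give as 5.7 %). The
package keeps the convention explicit in the function name rather than a
hidden default.

## The synthetic-data generator

The simulator exists so every operation above is testable without an
instrument. It emulates:

- **Gaussian emission bands** at the registry emission wavelengths:
  dissolved pigments at 644 (PC), 576 (PE), 677 nm (chl); in vivo
  red-shifted bands per genus (e.g. *Anabaena* PC 656–658 nm depending on
  excitation, *Cylindrospermum* 659–666 nm with its 619 nm marker,
  *Porphyridium* PE 580 / PC 660 / chl 683 nm, green algae chl 686 nm);
  the three humic-acid background bands at 444/499/522 nm; and
  fucoxanthin absorbance bands at 449/486 nm with Beer–Lambert peak
  heights ε·l·C.
- **Linear concentration response**, V/V~max~ volume scaling, optional
  inner-filter attenuation 10^−(OD~ex~+OD~em~), and seeded noise
  (additive Gaussian, defaulting to 0.5 % of the largest clean peak when
  enabled, plus a multiplicative term) applied last. Seeds are explicit;
  identical seeds give bit-identical spectra.
- **Scaling-consistent amplitudes**: in vivo PC/PE/chl band ratios are
  generated from the scaling-factor equations at each excitation, so
  closed-loop tests recover concentrations using only the equations —
  generation and analysis share no code path. Where genus PC centers
  shift with excitation, the registry stores the two recorded anchors
  (402 and 612 nm) and interpolates linearly between them.

Band widths and per-cell amplitudes are synthetic constants, not
measured values. In vivo and dissolved bands default to 15 nm FWHM. This
width was chosen so that the adjacent PC (≈ 656–666 nm) and chl-a
(683–686 nm) bands remain resolved, as they visibly are on the modeled
instrument: at 20 nm FWHM a chl-a band leaves ≈ 43 % of its height at
672 nm, the upper edge of the PC window, so in green-dominant mixtures
the window maximum is a chl shoulder and scalar peak arithmetic breaks
down — contradicting the clearly separated peaks the method relies on.
The broad humic bands use 60/40/35 nm; absorbance bands 20 nm. Per-cell
amplitudes are proportional to cell volume (2×10⁻⁶ counts per cells/mL
per µm³), and dry weight per cell is 10⁻¹⁰ mg per µm³ of cell volume.
For closed-loop recovery tests, `scaling_consistent_models()` builds
group-level models whose phycobilin bands sit exactly at the analysis
context's wavelengths (chl at 683 nm for all groups), since the
deconvolution context carries a single emission wavelength per
phycobilin.

What the simulator does **not** emulate — and hence what passing tests do
not establish about field data: Raman and elastic scatter lines, detector
saturation and wavelength-dependent instrument response, pigment packaging
and photoacclimation (variable per-cell pigment quotas), temperature
dependence, and deviations of real bands from Gaussian shape. Humic
background is simulated but no background subtraction is performed at
modest concentrations (≤ 5 mg/L), where window-local interference with
the phycobilin and chl windows is small; a higher-background correction
would require the window-local baseline machinery to be enabled
explicitly.

## Numerical choices

- FWHM of an excitation source (`qualify_source()`) locates each
  half-maximum crossing by linear interpolation between bracketing grid
  points; a peak whose flanks never fall below half maximum is truncated
  by the grid and raises an error.
- Peak ties break toward the lowest wavelength, making argmax
  deterministic on plateaus.
- Degenerate inputs error early: non-monotone wavelength grids,
  mismatched grids or excitations in blank subtraction, calibration with
  fewer than two distinct concentrations, non-positive cell dimensions,
  emission at or below excitation in a scaling context.
- Cross-integration-time comparisons are refused rather than silently
  rescaled: intensities are arbitrary counts, and the caller must rescale
  explicitly.
- File readers reject malformed inputs (duplicated wavelength rows are
  reported with their line number) instead of repairing them.

## Problem sizes

The bundled tests run the full pipeline at the scales the workflows are
meant for: mixtures of three groups at 5×10⁵ / 2×10⁵ / 1×10⁵ cells/mL on
a 200–850 nm grid at 1 nm; calibration series of 4–8 standards;
100 seeded replicates for the noisy-recovery property; 10⁴ random
contexts for the scaling-factor identities. These sizes were chosen as
representative of routine monitoring samples and give stable statistics
for the property-based checks.

## Known limitations

- The scalar peak-arithmetic deconvolution cannot separate two taxa whose
  diagnostic pigment peaks coincide (e.g. two cyanobacteria genera); the
  619 nm marker distinguishes only the Cyl-type lineage.
- S~α~ and S~γ~ assign different PC/chl ratios to cyanobacteria and red
  algae; the package applies them per taxon without reconciling the
  discrepancy, as the underlying model does.
- A ~9.6 nm blue shift of the dissolved-phycocyanin peak under 523 nm
  excitation in mixtures is captured by the window width but not
  corrected or modeled.
- Full-spectrum least-squares unmixing, chlorophyll-b pigments, and
  broader matrix-effect compensation beyond the inner-filter formula are
  out of scope.
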