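# phycolight

Classification and quantification of algal groups from multi-excitation
LED-induced fluorescence and broadband absorbance spectra.

## The problem

Monitoring which algal groups dominate a water body — and at what cell
concentration — matters both ecologically and practically: chlorophytes
feed aquatic food webs, while cyanobacteria such as *Microcystis* drive
toxic harmful algal blooms. Multi-excitation fluorescence instruments can
make this determination in vivo, without microscopy, because the major
groups carry diagnostic pigments with distinct emission peaks:

| group | diagnostic signal |
|---|---|
| red algae | phycoerythrin, ~576–580 nm emission |
| cyanobacteria | phycocyanin, ~644–666 nm emission (Cyl-type genera add a 619 nm marker) |
| green algae | chlorophyll-a only, ~677 nm dissolved / 683–686 nm in vivo |
| golden-brown algae (diatoms) | fucoxanthin absorbance bands at 449 and 486 nm |

`phycolight` implements the full analysis chain for such an instrument:
blank correction and windowed peak extraction; excitation-source
qualification (center wavelength and FWHM); cell-geometry volume
computation with V/V<sub>max</sub> intensity normalization so one
calibration serves growing and fully grown cultures; linear and
Beer–Lambert calibration fitting; inner-filter-effect correction;
pigment-signature group detection; hierarchical spectral deconvolution of
mixtures into per-group cells/mL; and a seeded synthetic-spectra simulator
so the entire pipeline is testable without an instrument.

## The model at the core

The method rests on empirical, excitation-wavelength-dependent scaling
factors relating the pigment peak intensities *I* of phycocyanin (PC),
phycoerythrin (PE), and chlorophyll-a (chl):

- S<sub>α</sub> = I<sub>PC</sub>/I<sub>chl</sub> = 3 λ<sub>em</sub>(PC)/λ<sub>ex</sub> − 2  (cyanobacteria)
- S<sub>β</sub> = I<sub>PE</sub>/I<sub>PC</sub> = 2 λ<sub>em</sub>(PE)/λ<sub>ex</sub> − 1  (red algae)
- S<sub>γ</sub> = I<sub>PC</sub>/I<sub>chl</sub> = 3 [λ<sub>em</sub>(PC)/λ<sub>ex</sub> − 1] = S<sub>α</sub> − 1  (red algae)
- S<sub>δ</sub> = I<sub>PE</sub>/I<sub>chl</sub> = S<sub>β</sub> S<sub>γ</sub>

Given a mixed-sample spectrum at a phycobilin-exciting wavelength
(default 523 nm), `deconvolve_quantify()` proceeds red → cyanobacteria →
green: the PE peak calibrates red algae directly; the red-algal PC share
I<sub>PE</sub>/S<sub>β</sub> is removed from the PC peak before the
cyanobacterial calibration is inverted; and the cyanobacterial
(÷ S<sub>α</sub>) and red-algal (÷ S<sub>δ</sub>) chl-a shares are removed
from the chl-a peak before green algae are quantified from the residual.
High-optical-density samples are corrected for the inner-filter effect,
I<sub>corr</sub> = I<sub>obs</sub> · 10^(OD<sub>ex</sub> + OD<sub>em</sub>),
with optical densities from Beer–Lambert absorptivities (A = εlC).

## Worked example

Simulate a three-group mixture (green 5×10⁵, cyanobacteria 2×10⁵, red
1×10⁵ cells/mL) with 1 % measurement noise, calibrate from simulated pure
cultures, then detect and quantify:

```r
library(phycolight)

ctx <- scaling_context(523, 660, 580)   # ex 523 nm; PC 660, PE 580 nm
models <- scaling_consistent_models(ctx)
w <- default_pigment_windows()
cal <- list(
  red = fit_line(c(0, 5e4, 1e5, 2e5), generate_calibration_series(
    models$red, c(0, 5e4, 1e5, 2e5), 523, w$phycoerythrin)$intensity),
  cyanobacteria = fit_line(c(0, 1e5, 2e5, 4e5), generate_calibration_series(
    models$cyanobacteria, c(0, 1e5, 2e5, 4e5), 523, w$phycocyanin)$intensity),
  green = fit_line(c(0, 2e5, 5e5, 8e5), generate_calibration_series(
    models$green, c(0, 2e5, 5e5, 8e5), 523, w$chlorophyll_a)$intensity))

ee <- simulate_mixture_eem(models[c("green", "cyanobacteria", "red")],
                           c(5e5, 2e5, 1e5), 523,
                           noise = noise_model(additive_sigma = 0,
                                               multiplicative_cv = 0.01,
                                               seed = 42))
detect_groups(ee, blank_sigma = 1, ctx = ctx)
#>           group       pigment emission_nm intensity threshold cyl_marker
#> 1           red phycoerythrin         580  54.43932         3         NA
#> 2 cyanobacteria   phycocyanin         660 222.04990         3      FALSE
#> 3         green chlorophyll_a         683 673.46137         3         NA

q <- deconvolve_quantify(ee, cal, ctx, blank_sigma = 1)
q[, c("group", "cells_per_ml", "residual_clamped", "below_noise")]
#>           group cells_per_ml residual_clamped below_noise
#> 1           red     100813.6            FALSE       FALSE
#> 2 cyanobacteria     199108.8            FALSE       FALSE
#> 3         green     492642.3            FALSE       FALSE
```

All three concentrations are recovered within ~1.5 % of the generating
values; flags report when a residual had to be clamped at zero or fell
below the 3σ noise floor. A command-line front end wraps the same
functions (`inst/scripts/phycolight`), with subcommands `simulate`,
`qualify-leds`, `calibrate`, `scale`, `correct-if`, `classify`, and
`mix-check`.

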