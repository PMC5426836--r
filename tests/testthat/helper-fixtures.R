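# Shared fixture builders. Everything is generated in code; no stored data.

# closed-form OLS oracle from sums, independent of stats::lm
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# standard analysis context: phycobilin-exciting wavelength with the
# in vivo phycocyanin / phycoerythrin emission wavelengths
analysis_ctx <- function(ex = 523) scaling_context(ex, 660, 580)

# scaling-consistent group models plus calibrations fitted from simulated
# pure-culture series at the analysis excitation
closed_loop_setup <- function(ex = 523) {
  ctx <- analysis_ctx(ex)
  models <- scaling_consistent_models(ctx)
  w <- default_pigment_windows()
  series <- function(model, window, concs) {
    tab <- generate_calibration_series(model, concs, ex, window)
    fit_line(tab$concentration, tab$intensity)
  }
  calibrations <- list(
    red = series(models$red, w$phycoerythrin, c(0, 5e4, 1e5, 2e5)),
    cyanobacteria = series(models$cyanobacteria, w$phycocyanin,
                           c(0, 1e5, 2e5, 4e5)),
    green = series(models$green, w$chlorophyll_a, c(0, 2e5, 5e5, 8e5)))
  list(ctx = ctx, models = models, calibrations = calibrations,
       windows = w)
}

gaussian_spectrum <- function(center, sigma, grid = seq(500, 800, 1),
                              amplitude = 100, offset = 0, ex = 523) {
  emission_spectrum(grid,
                    amplitude * exp(-(grid - center)^2 / (2 * sigma^2)) +
                      offset,
                    excitation_nm = ex, blank_corrected = TRUE)
}
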