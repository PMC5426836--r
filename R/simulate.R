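# Synthetic spectra simulator. Emission bands are Gaussians placed at the
# registry emission wavelengths; band amplitudes scale linearly with cell
# concentration (or mg/L for dissolved pigments) and with the cell-size
# volume ratio V/Vmax; excitation response factors either come from a
# user-supplied map or, in scaling-consistent models, are derived from the
# pigment-ratio equations so that parameter-recovery tests exercise the
# analysis without sharing code paths with it.
#
# Band widths and per-cell amplitudes are synthetic choices (the source
# instrument publishes band shapes only as figures): in vivo and dissolved
# bands default to 15 nm FWHM (adjacent phycocyanin/chlorophyll-a bands 23
# nm apart must stay resolved for window peak arithmetic to apply, as they
# visibly are on the instrument), the broad humic bands to 60/40/35 nm, and
# per-cell amplitudes are proportional to cell volume.

FWHM_IN_VIVO_NM <- 15
FWHM_DISSOLVED_NM <- 15
AMP_PER_VOLUME <- 2e-6  # counts per (cells/mL) per um^3, synthetic

#' Gaussian emission band
#'
#' @param pigment_id label
#' @param center_nm emission center (nm), or a named numeric vector of
#'   per-excitation anchors interpolated by [pigment_center()]
#' @param fwhm_nm full width at half maximum (nm)
#' @param amplitude_per_cell peak counts per unit concentration at the
#'   reference excitation
#' @param excitation_response named numeric map, excitation nm -> relative
#'   amplitude factor
#' @return object of class `pigment_band`
#' @export
pigment_band <- function(pigment_id, center_nm, fwhm_nm,
                         amplitude_per_cell, excitation_response) {
  if (fwhm_nm <= 0) stop("fwhm_nm must be > 0", call. = FALSE)
  if (amplitude_per_cell < 0)
    stop("amplitude_per_cell must be >= 0", call. = FALSE)
  if (any(excitation_response < 0))
    stop("excitation response factors must be >= 0", call. = FALSE)
  structure(list(pigment_id = pigment_id, center_nm = center_nm,
                 fwhm_nm = fwhm_nm,
                 amplitude_per_cell = amplitude_per_cell,
                 excitation_response = excitation_response),
            class = "pigment_band")
}

band_factor <- function(band, excitation_nm) {
  key <- as.character(excitation_nm)
  r <- band$excitation_response
  if (!key %in% names(r))
    stop("model has no excitation response at ", excitation_nm, " nm",
         call. = FALSE)
  unname(r[[key]])
}

gaussian_profile <- function(grid, center_nm, fwhm_nm) {
  exp(-4 * log(2) * ((grid - center_nm) / fwhm_nm)^2)
}

#' Spectral model of an alga (or dissolved pigment standard)
#'
#' @param genus label
#' @param group algal group label (or `"dissolved"`, `"humic"`)
#' @param bands list of [pigment_band] objects
#' @param geometry a [cell_geometry] (optional for dissolved standards)
#' @param vmax_um3 maximum (fully grown) cell volume (um^3)
#' @param dry_weight_per_cell mg per cell (synthetic constant)
#' @param conc_units `"cells_per_mL"` or `"mg_per_L"`
#' @param abs_bands optional list of absorbance bands, each
#'   `c(center_nm=, eps=)` with `eps` in (concentration unit)^-1 cm^-1
#' @return object of class `alga_model`
#' @export
alga_model <- function(genus, group, bands, geometry = NULL,
                       vmax_um3 = NULL, dry_weight_per_cell = NULL,
                       conc_units = "cells_per_mL", abs_bands = NULL) {
  if (!length(bands) && is.null(abs_bands))
    stop("model needs at least one band", call. = FALSE)
  stopifnot(all(vapply(bands, inherits, TRUE, "pigment_band")))
  structure(list(genus = genus, group = group, bands = bands,
                 geometry = geometry, vmax_um3 = vmax_um3,
                 dry_weight_per_cell = dry_weight_per_cell,
                 conc_units = conc_units, abs_bands = abs_bands),
            class = "alga_model")
}

# excitation response of a chl-a band consistent with the PC/chl ratio
# equations, given the PC band's response map and per-excitation PC centers
scaled_chl_response <- function(pc_response, pc_anchors, via = "alpha") {
  ex <- as.numeric(names(pc_response))
  r <- vapply(ex, function(e) {
    ctx <- scaling_context(e, pigment_center(pc_anchors, e))
    s <- if (via == "alpha") s_alpha(ctx, warn_domain = FALSE)
         else s_gamma(ctx, warn_domain = FALSE)
    pc_response[[as.character(e)]] / s
  }, numeric(1))
  stats::setNames(r, names(pc_response))
}

#' Built-in spectral models for the registry genera
#'
#' Models for the six cultivated genera, the field-reference genus, the
#' dissolved pigment standards, and humic acid. In vivo phycobilin/chl-a
#' amplitude ratios are generated from the scaling-factor equations
#' (scaling-consistent); per-cell amplitudes are proportional to cell
#' volume and dry weight per cell is 1e-10 mg per um^3 of cell volume. All
#' excitation-response factors and band widths are synthetic constants, not
#' measured values.
#'
#' @param registry a genus registry, see [default_genus_registry()]
#' @return named list of [alga_model] objects
#' @export
default_alga_models <- function(registry = default_genus_registry()) {
  exs <- c(371, 402, 523, 572, 595, 612)
  nm <- function(v) stats::setNames(v, as.character(exs))
  r_pc_cyano <- nm(c(0.2, 0.5, 0.6, 0.9, 1.0, 1.0))
  r_pe_red   <- nm(c(0.2, 0.6, 1.0, 0.8, 0.5, 0.3))
  r_chl_green <- nm(c(0.4, 1.0, 0.25, 0.2, 0.25, 0.35))
  r_marker   <- nm(c(0.3, 1.0, 0.4, 0.3, 0.3, 0.3))
  r_humic    <- nm(c(1.0, 0.8, 0.2, 0.1, 0.05, 0.05))

  amp <- function(g) registry[[g]]$volume_um3 * AMP_PER_VOLUME
  dw <- function(g) registry[[g]]$volume_um3 * 1e-10  # mg/cell, synthetic

  cyano_model <- function(g, marker = FALSE) {
    reg <- registry[[g]]
    pc <- reg$pigments$phycocyanin
    bands <- list(
      pigment_band("phycocyanin", pc, FWHM_IN_VIVO_NM, amp(g), r_pc_cyano),
      pigment_band("chlorophyll_a", reg$pigments$chlorophyll_a,
                   FWHM_IN_VIVO_NM, amp(g),
                   scaled_chl_response(r_pc_cyano, pc, "alpha")))
    if (marker)
      bands <- c(bands, list(pigment_band("cyl_619", 619, 12,
                                          0.15 * amp(g), r_marker)))
    alga_model(g, "cyanobacteria", bands, reg$geometry, reg$vmax_um3, dw(g))
  }

  red_model <- function(g) {
    reg <- registry[[g]]
    pe <- reg$pigments$phycoerythrin
    pc <- reg$pigments$phycocyanin
    # PE/PC and PE/chl ratios follow the beta and delta equations per
    # excitation at the genus emission wavelengths; the model only responds
    # at excitations below the phycoerythrin emission
    rex <- exs[exs < min(pe)]
    r_pe <- r_pe_red[as.character(rex)]
    r_pc <- vapply(rex, function(e) {
      ctx <- scaling_context(e, pigment_center(pc, e), pigment_center(pe, e))
      r_pe[[as.character(e)]] / s_beta(ctx, warn_domain = FALSE)
    }, numeric(1))
    r_chl <- vapply(rex, function(e) {
      ctx <- scaling_context(e, pigment_center(pc, e), pigment_center(pe, e))
      r_pe[[as.character(e)]] / s_delta(ctx, warn_domain = FALSE)
    }, numeric(1))
    snm <- function(v) stats::setNames(v, as.character(rex))
    alga_model(g, "red", list(
      pigment_band("phycoerythrin", pe, FWHM_IN_VIVO_NM, amp(g), r_pe),
      pigment_band("phycocyanin", pc, FWHM_IN_VIVO_NM, amp(g), snm(r_pc)),
      pigment_band("chlorophyll_a", reg$pigments$chlorophyll_a,
                   FWHM_IN_VIVO_NM, amp(g), snm(r_chl))),
      reg$geometry, reg$vmax_um3, dw(g))
  }

  green_model <- function(g) {
    reg <- registry[[g]]
    alga_model(g, "green", list(
      pigment_band("chlorophyll_a", reg$pigments$chlorophyll_a,
                   FWHM_IN_VIVO_NM, amp(g), r_chl_green)),
      reg$geometry, reg$vmax_um3, dw(g))
  }

  models <- list(
    anki = green_model("anki"),
    chlor = green_model("chlor"),
    ana = cyano_model("ana"),
    cyl = cyano_model("cyl", marker = TRUE),
    porp = red_model("porp"),
    microcystis = cyano_model("microcystis"),
    cyc = alga_model("cyc", "golden_brown", list(),
                     registry$cyc$geometry, registry$cyc$vmax_um3,
                     dw("cyc"), abs_bands = registry$cyc$abs_bands),
    # dissolved pigment standards, amplitudes in counts per mg/L (synthetic)
    chlorophyll_a = alga_model("chlorophyll_a", "dissolved", list(
      pigment_band("chlorophyll_a", 677, FWHM_DISSOLVED_NM, 1000,
                   nm(rep(1, 6)))), conc_units = "mg_per_L"),
    phycocyanin = alga_model("phycocyanin", "dissolved", list(
      pigment_band("phycocyanin", 644, FWHM_DISSOLVED_NM, 1200,
                   nm(rep(1, 6)))), conc_units = "mg_per_L"),
    phycoerythrin = alga_model("phycoerythrin", "dissolved", list(
      pigment_band("phycoerythrin", 576, FWHM_DISSOLVED_NM, 1500,
                   nm(rep(1, 6)))), conc_units = "mg_per_L"),
    humic = alga_model("humic", "humic", list(
      pigment_band("humic_444", 444, 60, 120, r_humic),
      pigment_band("humic_499", 499, 40, 100, r_humic),
      pigment_band("humic_522", 522, 35, 80, r_humic)),
      conc_units = "mg_per_L"))
  models
}

#' Scaling-consistent group models sharing one emission context
#'
#' Builds green / cyanobacteria / red group models whose phycobilin bands
#' sit exactly at the wavelengths of one [scaling_context] (chlorophyll-a at
#' 683 nm for all groups) and whose amplitude ratios at every excitation are
#' generated from the scaling-factor equations. Used for closed-loop
#' parameter-recovery: the deconvolution re-derives the ratios from peaks,
#' sharing only the equations with the generator.
#'
#' @param ctx a [scaling_context]
#' @param excitation_set excitations the models respond to (nm)
#' @param amp_green,amp_cyano,amp_red primary-pigment amplitude per cell
#' @return named list with elements `green`, `cyanobacteria`, `red`
#' @export
scaling_consistent_models <- function(ctx,
                                      excitation_set = c(402, 523, 595, 612),
                                      amp_green = 1.05e-3,
                                      amp_cyano = 8.9e-4,
                                      amp_red = 5.4e-4) {
  stopifnot(inherits(ctx, "scaling_context"))
  nm <- function(v, ex) stats::setNames(v, as.character(ex))
  ones <- function(ex) nm(rep(1, length(ex)), ex)
  # a group only responds at excitations below its emitting bands
  cy_ex <- excitation_set[excitation_set < ctx$lambda_em_pc_nm]
  red_ex <- excitation_set[excitation_set < ctx$lambda_em_pe_nm]
  sa <- vapply(cy_ex, function(e)
    s_alpha(scaling_context(e, ctx$lambda_em_pc_nm), FALSE), numeric(1))
  sb <- vapply(red_ex, function(e)
    s_beta(scaling_context(e, ctx$lambda_em_pc_nm, ctx$lambda_em_pe_nm),
           FALSE), numeric(1))
  sd_ <- vapply(red_ex, function(e)
    s_delta(scaling_context(e, ctx$lambda_em_pc_nm, ctx$lambda_em_pe_nm),
            FALSE), numeric(1))
  list(
    green = alga_model("green_ref", "green", list(
      pigment_band("chlorophyll_a", 683, FWHM_IN_VIVO_NM, amp_green,
                   ones(excitation_set)))),
    cyanobacteria = alga_model("cyano_ref", "cyanobacteria", list(
      pigment_band("phycocyanin", ctx$lambda_em_pc_nm, FWHM_IN_VIVO_NM,
                   amp_cyano, ones(cy_ex)),
      pigment_band("chlorophyll_a", 683, FWHM_IN_VIVO_NM, amp_cyano,
                   nm(1 / sa, cy_ex)))),
    red = alga_model("red_ref", "red", list(
      pigment_band("phycoerythrin", ctx$lambda_em_pe_nm, FWHM_IN_VIVO_NM,
                   amp_red, ones(red_ex)),
      pigment_band("phycocyanin", ctx$lambda_em_pc_nm, FWHM_IN_VIVO_NM,
                   amp_red, nm(1 / sb, red_ex)),
      pigment_band("chlorophyll_a", 683, FWHM_IN_VIVO_NM, amp_red,
                   nm(1 / sd_, red_ex)))))
}

# ---- noise ----------------------------------------------------------------

#' Noise model for the simulator
#'
#' Additive Gaussian noise plus a multiplicative term. When
#' `additive_sigma` is `NULL`, it defaults at simulation time to 0.5% of
#' the largest clean peak of the spectrum being generated. Seeds are
#' explicit; a spectrum's noise stream is derived deterministically from
#' `(seed, excitation)`.
#'
#' @param additive_sigma additive standard deviation (counts), or `NULL`
#' @param multiplicative_cv coefficient of variation of the multiplicative
#'   term (fraction)
#' @param seed integer seed
#' @return object of class `noise_model`
#' @export
noise_model <- function(additive_sigma = NULL, multiplicative_cv = 0,
                        seed = 1) {
  if (!is.null(additive_sigma) && additive_sigma < 0)
    stop("additive_sigma must be >= 0", call. = FALSE)
  if (multiplicative_cv < 0) stop("multiplicative_cv must be >= 0",
                                  call. = FALSE)
  structure(list(additive_sigma = additive_sigma,
                 multiplicative_cv = multiplicative_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(clean, noise, excitation_nm, stream_offset = 0L) {
  if (is.null(noise)) return(clean)
  sigma <- noise$additive_sigma
  if (is.null(sigma)) sigma <- 0.005 * max(clean, 0)
  if (sigma == 0 && noise$multiplicative_cv == 0) return(clean)
  set.seed(noise$seed + round(excitation_nm) + 7919L * stream_offset)
  y <- clean
  if (noise$multiplicative_cv > 0)
    y <- y * (1 + noise$multiplicative_cv * stats::rnorm(length(y)))
  if (sigma > 0) y <- y + stats::rnorm(length(y), sd = sigma)
  y
}

# ---- simulation operations ------------------------------------------------

clean_emission <- function(model, cells_per_ml, excitation_nm, grid,
                           v_um3 = NULL) {
  vfac <- 1
  if (!is.null(model$vmax_um3)) {
    v <- if (is.null(v_um3)) model$vmax_um3 else v_um3
    vfac <- v / model$vmax_um3
  }
  y <- numeric(length(grid))
  for (b in model$bands) {
    center <- pigment_center(b$center_nm, excitation_nm)
    y <- y + b$amplitude_per_cell * band_factor(b, excitation_nm) *
      cells_per_ml * vfac * gaussian_profile(grid, center, b$fwhm_nm)
  }
  y
}

#' Simulate an emission spectrum
#'
#' Sums the model's Gaussian bands, scaled by concentration, excitation
#' response, and the cell-size volume ratio V/Vmax; optionally attenuates
#' the whole spectrum by the inner-filter factor `10^-(OD_ex + OD_em)` at
#' the sample's concentration; applies seeded noise last. Output is marked
#' blank-corrected (the simulator generates background-free signal).
#'
#' @param model an [alga_model]
#' @param cells_per_ml concentration (cells/mL, or mg/L for dissolved
#'   standards)
#' @param excitation_nm excitation wavelength; must be in the model's
#'   response map
#' @param grid wavelength axis (default [default_grid()])
#' @param noise a [noise_model] or `NULL` (noise off)
#' @param inner_filter an [inner_filter_params] or `NULL` (off)
#' @param v_um3 mean cell volume of the simulated culture (default: fully
#'   grown, `vmax_um3`)
#' @return an [emission_spectrum]
#' @export
simulate_emission <- function(model, cells_per_ml, excitation_nm,
                              grid = default_grid(), noise = NULL,
                              inner_filter = NULL, v_um3 = NULL) {
  stopifnot(inherits(model, "alga_model"))
  if (cells_per_ml < 0) stop("concentration must be >= 0", call. = FALSE)
  y <- clean_emission(model, cells_per_ml, excitation_nm, grid, v_um3)
  if (!is.null(inner_filter)) {
    od <- sample_optical_densities(inner_filter, cells_per_ml)
    y <- y * 10^-(od$od_ex + od$od_em)
  }
  y <- apply_noise(y, noise, excitation_nm)
  emission_spectrum(grid, y, excitation_nm, blank_corrected = TRUE,
                    meta = list(genus = model$genus,
                                cells_per_ml = cells_per_ml))
}

#' Simulate an excitation-emission matrix
#'
#' One [simulate_emission()] per excitation on a shared grid; the noise
#' stream is deterministic per `(seed, excitation)`.
#'
#' @inheritParams simulate_emission
#' @param excitation_set excitation wavelengths (nm)
#' @return an [eem]
#' @export
simulate_eem <- function(model, cells_per_ml, excitation_set,
                         grid = default_grid(), noise = NULL,
                         inner_filter = NULL, v_um3 = NULL) {
  eem(lapply(excitation_set, function(ex)
    simulate_emission(model, cells_per_ml, ex, grid, noise, inner_filter,
                      v_um3)))
}

#' Simulate an EEM of a multi-component mixture
#'
#' Component contributions are summed on the clean (pre-noise) spectra at
#' each excitation; noise is then applied to the summed spectrum.
#'
#' @param models list of [alga_model] objects
#' @param cells vector of concentrations, one per model
#' @inheritParams simulate_eem
#' @return an [eem]
#' @export
simulate_mixture_eem <- function(models, cells, excitation_set,
                                 grid = default_grid(), noise = NULL,
                                 inner_filter = NULL) {
  stopifnot(length(models) == length(cells))
  eem(lapply(excitation_set, function(ex) {
    y <- numeric(length(grid))
    for (i in seq_along(models))
      y <- y + clean_emission(models[[i]], cells[i], ex, grid)
    if (!is.null(inner_filter)) {
      od <- sample_optical_densities(inner_filter, sum(cells))
      y <- y * 10^-(od$od_ex + od$od_em)
    }
    emission_spectrum(grid, apply_noise(y, noise, ex),
                      ex, blank_corrected = TRUE)
  }))
}

#' Simulate an absorbance spectrum
#'
#' Gaussian absorbance bands with Beer-Lambert peak heights
#' `A = eps * l * C` from the model's absorptivities.
#'
#' @inheritParams simulate_emission
#' @param pathlength_cm absorbance path length (cm)
#' @param fwhm_nm absorbance band width (nm), synthetic constant
#' @return an [absorbance_spectrum]
#' @export
simulate_absorbance <- function(model, cells_per_ml,
                                grid = default_grid(), noise = NULL,
                                pathlength_cm = 0.9, fwhm_nm = 20) {
  stopifnot(inherits(model, "alga_model"))
  if (is.null(model$abs_bands))
    stop("model has no absorbance bands", call. = FALSE)
  a <- numeric(length(grid))
  for (b in model$abs_bands)
    a <- a + b[["eps"]] * pathlength_cm * cells_per_ml *
      gaussian_profile(grid, b[["center_nm"]], fwhm_nm)
  a <- apply_noise(a, noise, 0)
  absorbance_spectrum(grid, a)
}

#' Generate a calibration series
#'
#' Simulates an emission spectrum at each concentration and extracts the
#' window peak intensity, yielding the table a calibration fit consumes.
#'
#' @inheritParams simulate_emission
#' @param concentrations concentrations of the standards
#' @param window [pigment_window] for the peak read out
#' @return data.frame with columns `concentration`, `intensity`
#' @export
generate_calibration_series <- function(model, concentrations, excitation_nm,
                                        window, grid = default_grid(),
                                        noise = NULL, inner_filter = NULL,
                                        v_um3 = NULL) {
  intensity <- vapply(seq_along(concentrations), function(i) {
    n <- noise
    if (!is.null(n)) n$seed <- n$seed + i  # independent stream per standard
    sp <- simulate_emission(model, concentrations[i], excitation_nm, grid,
                            n, inner_filter, v_um3)
    find_peak(sp, window)$intensity
  }, numeric(1))
  data.frame(concentration = concentrations, intensity = intensity)
}

#' Simulate pure-component spectra and their physical mixture
#'
#' The mixture is the pointwise sum of the clean component spectra; noise
#' is applied independently to each component and to the mixture.
#'
#' @inheritParams simulate_mixture_eem
#' @param excitation_nm single excitation wavelength (nm)
#' @return list with `components` (list of [emission_spectrum]) and
#'   `mixture` (an [emission_spectrum])
#' @export
simulate_mixture <- function(models, cells, excitation_nm,
                             grid = default_grid(), noise = NULL) {
  stopifnot(length(models) == length(cells))
  clean <- lapply(seq_along(models), function(i)
    clean_emission(models[[i]], cells[i], excitation_nm, grid))
  components <- lapply(seq_along(clean), function(i)
    emission_spectrum(grid, apply_noise(clean[[i]], noise, excitation_nm,
                                        stream_offset = i),
                      excitation_nm, blank_corrected = TRUE))
  mixture <- emission_spectrum(
    grid, apply_noise(Reduce(`+`, clean), noise, excitation_nm),
    excitation_nm, blank_corrected = TRUE)
  list(components = components, mixture = mixture)
}
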