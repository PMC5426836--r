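# End-to-end method: pigment-signature detection of algal groups and
# hierarchical quantification. The deconvolution order (red -> cyanobacteria
# -> green) follows the pigment dependency chain: phycoerythrin is unique to
# red algae; red algae also fluoresce at the phycocyanin wavelength, so the
# red contribution (predicted from the PE peak via the beta factor) is
# removed before cyanobacteria are quantified; both phycobilin-bearing
# groups contribute chlorophyll-a (predicted via the alpha and delta
# factors), so green algae are quantified from the chl-a residual.
# Residuals driven below zero by noise are clamped and flagged.

# Window measurement with shoulder rejection: a neighboring band's tail can
# exceed the pigment's own peak at a window edge, so prefer the highest
# local maximum inside the window and fall back to the plain window maximum
# (find_peak) only when the window holds no local maximum at all.
window_peak <- function(spectrum, window) {
  idx <- window_indices(spectrum, window)
  y <- spectrum$intensity
  n <- length(y)
  is_local_max <- vapply(idx, function(i) {
    l <- if (i > 1L) y[i - 1L] else -Inf
    r <- if (i < n) y[i + 1L] else -Inf
    y[i] >= l && y[i] >= r && (y[i] > l || y[i] > r)
  }, logical(1))
  loc <- idx[is_local_max]
  i <- if (length(loc)) loc[which.max(y[loc])] else idx[which.max(y[idx])]
  structure(list(pigment_id = window$pigment_id,
                 emission_nm = spectrum$wavelength_nm[i],
                 intensity = y[i],
                 excitation_nm = spectrum$excitation_nm,
                 is_local_max = length(loc) > 0),
            class = "pigment_peak")
}

# A reading with no local maximum in its window is a shoulder, not a peak:
# the pigment is treated as absent (intensity zero). This is the premise of
# scalar peak arithmetic — each pigment must present a resolvable peak.
peak_or_zero <- function(peak) {
  if (isTRUE(peak$is_local_max)) peak$intensity else 0
}

measure_windows <- function(spectrum, windows) {
  lapply(windows, function(w) window_peak(spectrum, w))
}

pick_excitation <- function(eem_obj, prefer = 523) {
  ex <- eem_excitations(eem_obj)
  if (any(abs(ex - prefer) < 1e-6)) return(prefer)
  ex[1]
}

#' Detect which algal groups are present
#'
#' A pigment peak counts as present when its window maximum exceeds
#' `k * blank_sigma` (default k = 3, the usual spectroscopic detection
#' threshold). Evidence rules: red algae from phycoerythrin; cyanobacteria
#' from the phycocyanin excess over the red-algal contribution predicted by
#' the beta factor (flagged Cyl-like when the 619 nm marker is present);
#' green algae from the chlorophyll-a excess over the phycobilin-predicted
#' contributions; golden-brown algae from the two fucoxanthin absorbance
#' bands.
#'
#' @param eem_obj an [eem] of blank-corrected spectra
#' @param abs_spec optional [absorbance_spectrum]
#' @param blank_sigma standard deviation of the blank (counts)
#' @param k detection threshold multiplier
#' @param ctx [scaling_context] for the phycobilin predictions; defaults to
#'   phycocyanin 660 / phycoerythrin 580 nm at the analysis excitation
#' @param windows pigment windows, see [default_pigment_windows()]
#' @param abs_sigma absorbance noise level (AU) for the fucoxanthin test
#' @param excitation_nm analysis excitation (default 523 nm if present in
#'   the EEM, else its first excitation)
#' @return data.frame with one row per detected group: `group`, `pigment`,
#'   `emission_nm`, `intensity`, `threshold`, `cyl_marker`
#' @export
detect_groups <- function(eem_obj, abs_spec = NULL, blank_sigma = 0, k = 3,
                          ctx = NULL, windows = default_pigment_windows(),
                          abs_sigma = 1e-3, excitation_nm = NULL) {
  stopifnot(inherits(eem_obj, "eem"))
  ex <- if (is.null(excitation_nm)) pick_excitation(eem_obj) else excitation_nm
  sp <- eem_spectrum(eem_obj, ex)
  if (is.null(ctx)) ctx <- scaling_context(ex, 660, 580)
  thr <- k * blank_sigma
  pk <- measure_windows(sp, windows[c("phycoerythrin", "phycocyanin",
                                      "chlorophyll_a", "cyl_619")])
  i_pe <- peak_or_zero(pk$phycoerythrin)
  i_pc <- peak_or_zero(pk$phycocyanin)
  i_chl <- peak_or_zero(pk$chlorophyll_a)

  rows <- list()
  add <- function(group, peak, marker = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, pigment = peak$pigment_id,
      emission_nm = peak$emission_nm, intensity = peak$intensity,
      threshold = thr, cyl_marker = marker, stringsAsFactors = FALSE)
  }

  red <- i_pe > thr
  if (red) add("red", pk$phycoerythrin)

  pc_red <- if (red)
    predict_phycocyanin_from_phycoerythrin(i_pe, ctx, warn_domain = FALSE)
  else 0
  pc_excess <- i_pc - pc_red
  if (pc_excess > thr) {
    marker <- peak_or_zero(pk$cyl_619) > thr
    add("cyanobacteria", pk$phycocyanin, marker)
  }

  chl_pred <- 0
  if (pc_excess > thr)
    chl_pred <- chl_pred +
      predict_chla_from_phycocyanin(pc_excess, ctx, "alpha",
                                    warn_domain = FALSE)
  if (red)
    chl_pred <- chl_pred + i_pe / check_factor_positive(
      s_delta(ctx, warn_domain = FALSE), "s_delta")
  if (i_chl - chl_pred > thr) add("green", pk$chlorophyll_a)

  if (!is.null(abs_spec)) {
    p449 <- find_absorbance_peak(abs_spec, windows$fucoxanthin_449)
    p486 <- find_absorbance_peak(abs_spec, windows$fucoxanthin_486)
    if (p449$absorbance > k * abs_sigma && p486$absorbance > k * abs_sigma)
      rows[[length(rows) + 1]] <- data.frame(
        group = "golden_brown", pigment = "fucoxanthin",
        emission_nm = p449$wavelength_nm, intensity = p449$absorbance,
        threshold = k * abs_sigma, cyl_marker = NA, stringsAsFactors = FALSE)
  }

  if (!length(rows))
    return(data.frame(group = character(), pigment = character(),
                      emission_nm = numeric(), intensity = numeric(),
                      threshold = numeric(), cyl_marker = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

quant_row <- function(group, cells, peak_nm, measured, share, residual,
                      clamped, below_noise, status = "ok", message = "") {
  data.frame(group = group, cells_per_ml = cells, peak_nm = peak_nm,
             measured_intensity = measured, share_subtracted = share,
             residual_intensity = residual, residual_clamped = clamped,
             below_noise = below_noise, status = status, message = message,
             stringsAsFactors = FALSE)
}

#' Hierarchical deconvolution of a mixed sample into group concentrations
#'
#' At a phycobilin-exciting analysis wavelength (default 523 nm), in order:
#' (1) the phycoerythrin window peak gives red-algae cells through the red
#' calibration (inner-filter-corrected when `ifp` is supplied); (2) the
#' red-algal phycocyanin share `I_pe / S_beta` is removed from the
#' phycocyanin window peak and the excess gives cyanobacteria cells;
#' (3) the cyanobacterial (`/ S_alpha`) and red-algal (`/ S_delta`)
#' chlorophyll-a shares are removed from the chl-a window peak and the
#' residual gives green-algae cells. Negative residuals are clamped to zero
#' and flagged; residuals at or below `k * blank_sigma` are flagged
#' `below_noise`. Shares plus residuals equal the measured window
#' intensities exactly (pre-clamping).
#'
#' @param eem_obj an [eem] of blank-corrected spectra
#' @param calibrations named list of [calibration_curve][fit_line] objects for
#'   `"red"` (phycoerythrin), `"cyanobacteria"` (phycocyanin), `"green"`
#'   (chlorophyll-a), each fitted at the analysis excitation; a missing
#'   entry produces a per-group error row, other groups are still
#'   quantified
#' @param ctx a [scaling_context] at the analysis excitation
#' @param ifp optional [inner_filter_params] for the phycoerythrin
#'   measurement (applied iteratively: invert, compute optical densities at
#'   the estimate, correct, re-invert)
#' @param windows pigment windows
#' @param blank_sigma blank standard deviation (counts)
#' @param k below-noise threshold multiplier
#' @return data.frame with one row per group: cells/mL, measured window
#'   intensity, subtracted share, residual, clamp and noise flags
#' @export
deconvolve_quantify <- function(eem_obj, calibrations, ctx, ifp = NULL,
                                windows = default_pigment_windows(),
                                blank_sigma = 0, k = 3) {
  stopifnot(inherits(eem_obj, "eem"), inherits(ctx, "scaling_context"))
  sp <- eem_spectrum(eem_obj, ctx$lambda_ex_nm)
  thr <- k * blank_sigma
  pk <- measure_windows(sp, windows[c("phycoerythrin", "phycocyanin",
                                      "chlorophyll_a")])
  i_pe <- max(peak_or_zero(pk$phycoerythrin), 0)
  i_pc <- max(peak_or_zero(pk$phycocyanin), 0)
  i_chl <- max(peak_or_zero(pk$chlorophyll_a), 0)

  invert_for <- function(group, y) {
    curve <- calibrations[[group]]
    if (is.null(curve))
      stop("no calibration for group '", group, "'", call. = FALSE)
    suppressWarnings(invert_calibration(curve, y))
  }

  rows <- list()

  # (1) red algae from phycoerythrin
  i_pe_used <- i_pe
  red_cells <- NA_real_
  red_err <- NULL
  red_below <- i_pe <= thr
  red_res <- tryCatch({
    if (red_below) {
      i_pe_used <- 0
      0
    } else {
      cells <- invert_for("red", i_pe_used)
      if (!is.null(ifp) && i_pe_used > 0) {
        for (iter in 1:6) {   # fixed-point: OD depends on the estimate
          od <- sample_optical_densities(ifp, cells)
          i_pe_used <- correct_inner_filter(i_pe, od$od_ex, od$od_em)
          cells <- invert_for("red", i_pe_used)
        }
      }
      cells
    }
  }, error = function(e) { red_err <<- conditionMessage(e); NA_real_ })
  red_cells <- red_res
  rows$red <- quant_row("red", red_cells, pk$phycoerythrin$emission_nm,
                        i_pe, 0, i_pe_used, FALSE, red_below,
                        if (is.null(red_err)) "ok" else "error",
                        if (is.null(red_err)) "" else red_err)

  # (2) cyanobacteria from the phycocyanin excess
  pc_red_share <- if (i_pe_used > 0)
    i_pe_used / check_factor_positive(s_beta(ctx, warn_domain = FALSE),
                                      "s_beta")
  else 0
  pc_resid <- i_pc - pc_red_share
  pc_clamped <- pc_resid < 0
  pc_cyano <- max(pc_resid, 0)
  cy_below <- pc_cyano <= thr
  cy_err <- NULL
  cy_cells <- tryCatch(
    if (cy_below) 0 else invert_for("cyanobacteria", pc_cyano),
    error = function(e) { cy_err <<- conditionMessage(e); NA_real_ })
  rows$cyanobacteria <- quant_row(
    "cyanobacteria", cy_cells, pk$phycocyanin$emission_nm, i_pc,
    pc_red_share, pc_resid, pc_clamped, cy_below,
    if (is.null(cy_err)) "ok" else "error",
    if (is.null(cy_err)) "" else cy_err)

  # (3) green algae from the chlorophyll-a residual
  chl_cy_share <- if (pc_cyano > 0)
    predict_chla_from_phycocyanin(pc_cyano, ctx, "alpha",
                                  warn_domain = FALSE)
  else 0
  chl_red_share <- if (i_pe_used > 0)
    i_pe_used / check_factor_positive(s_delta(ctx, warn_domain = FALSE),
                                      "s_delta")
  else 0
  chl_resid <- i_chl - chl_cy_share - chl_red_share
  chl_clamped <- chl_resid < 0
  chl_green <- max(chl_resid, 0)
  gr_below <- chl_green <= thr
  gr_err <- NULL
  gr_cells <- tryCatch(
    if (gr_below) 0 else invert_for("green", chl_green),
    error = function(e) { gr_err <<- conditionMessage(e); NA_real_ })
  rows$green <- quant_row(
    "green", gr_cells, pk$chlorophyll_a$emission_nm, i_chl,
    chl_cy_share + chl_red_share, chl_resid, chl_clamped, gr_below,
    if (is.null(gr_err)) "ok" else "error",
    if (is.null(gr_err)) "" else gr_err)

  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Quantify golden-brown algae from fucoxanthin absorbance
#'
#' Inverts a Beer-Lambert calibration at each fucoxanthin band (449 and
#' 486 nm) and reports both estimates and their mean.
#'
#' @param abs_spec an [absorbance_spectrum]
#' @param calibrations named list of [calibration_curve][fit_line] objects keyed
#'   `"fucoxanthin_449"` and `"fucoxanthin_486"` (absorbance vs cells/mL)
#' @param windows pigment windows
#' @return list with per-band cells/mL, their `mean`, and the band peaks
#' @export
quantify_absorbance <- function(abs_spec, calibrations,
                                windows = default_pigment_windows()) {
  bands <- c("fucoxanthin_449", "fucoxanthin_486")
  est <- lapply(bands, function(b) {
    pk <- find_absorbance_peak(abs_spec, windows[[b]])
    curve <- calibrations[[b]]
    if (is.null(curve))
      stop("no calibration for band '", b, "'", call. = FALSE)
    list(peak = pk,
         cells_per_ml = suppressWarnings(
           invert_calibration(curve, pk$absorbance)))
  })
  names(est) <- bands
  cells <- vapply(est, `[[`, numeric(1), "cells_per_ml")
  list(per_band = cells, mean = mean(cells),
       peaks = lapply(est, `[[`, "peak"))
}

#' Additivity check of a mixture against its pure components
#'
#' Sums the pure-component spectra pointwise and compares window peak
#' intensities of the sum against those of the measured mixture, returning
#' the percent difference per pigment window (NA where either peak is not
#' positive).
#'
#' @param components list of [emission_spectrum] objects (common grid and
#'   excitation)
#' @param mixture an [emission_spectrum]
#' @param windows pigment windows to compare
#' @return named numeric vector of percent differences
#' @export
mixture_additivity <- function(components, mixture,
                               windows = default_pigment_windows()) {
  stopifnot(length(components) >= 1,
            inherits(mixture, "emission_spectrum"))
  for (s in components) {
    stopifnot(inherits(s, "emission_spectrum"))
    if (!same_grid(s, mixture))
      stop("components and mixture must share one grid", call. = FALSE)
    if (abs(s$excitation_nm - mixture$excitation_nm) > 1e-6)
      stop("components and mixture must share one excitation",
           call. = FALSE)
  }
  total <- mixture
  total$intensity <- Reduce(`+`, lapply(components, `[[`, "intensity"))
  rng <- range(mixture$wavelength_nm)
  vapply(windows, function(w) {
    if (w$hi_nm < rng[1] || w$lo_nm > rng[2]) return(NA_real_)
    a <- find_peak(total, w)$intensity
    b <- find_peak(mixture, w)$intensity
    if (a <= 0 || b <= 0) return(NA_real_)
    percent_difference(a, b)
  }, numeric(1))
}

#' Field-sample quantification via a reference genus's calibrations
#'
#' Quantifies a cyanobacteria-dominated sample at 612 nm excitation twice,
#' independently through the phycocyanin and the chlorophyll-a calibration
#' of a reference genus, scaling each estimate by the cell-volume ratio
#' (reference volume over target volume). Reports both estimates, their
#' percent difference, and (when a reference count is supplied) each
#' route's percent difference from it.
#'
#' @param eem_obj an [eem] containing the analysis excitation
#' @param calibrations named list with [calibration_curve][fit_line] entries
#'   `"phycocyanin"` and `"chlorophyll_a"` fitted for the reference genus
#' @param reference_v_um3 reference-genus mean cell volume (um^3)
#' @param target_v_um3 target-genus mean cell volume (um^3)
#' @param excitation_nm analysis excitation (default 612 nm)
#' @param windows pigment windows
#' @param reference_count optional independent cell count (cells/mL)
#' @return list with `cells_via_phycocyanin`, `cells_via_chlorophyll_a`,
#'   `volume_ratio`, `percent_difference_routes`, and optionally
#'   `percent_difference_vs_reference`
#' @export
field_sample_workflow <- function(eem_obj, calibrations, reference_v_um3,
                                  target_v_um3, excitation_nm = 612,
                                  windows = default_pigment_windows(),
                                  reference_count = NULL) {
  stopifnot(inherits(eem_obj, "eem"))
  if (reference_v_um3 <= 0 || target_v_um3 <= 0)
    stop("cell volumes must be positive", call. = FALSE)
  sp <- eem_spectrum(eem_obj, excitation_nm)
  ratio <- reference_v_um3 / target_v_um3
  est <- function(window_id, cal_id) {
    pk <- find_peak(sp, windows[[window_id]])
    curve <- calibrations[[cal_id]]
    if (is.null(curve))
      stop("no calibration '", cal_id, "'", call. = FALSE)
    suppressWarnings(invert_calibration(curve, pk$intensity)) * ratio
  }
  via_pc <- est("phycocyanin", "phycocyanin")
  via_chl <- est("chlorophyll_a", "chlorophyll_a")
  out <- list(cells_via_phycocyanin = via_pc,
              cells_via_chlorophyll_a = via_chl,
              volume_ratio = ratio,
              percent_difference_routes = percent_difference(via_pc,
                                                             via_chl))
  if (!is.null(reference_count))
    out$percent_difference_vs_reference <- c(
      phycocyanin = percent_difference(via_pc, reference_count),
      chlorophyll_a = percent_difference(via_chl, reference_count))
  out
}
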