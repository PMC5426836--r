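# Inner-filter-effect correction: at high optical density the excitation
# beam is attenuated on its way in and the emitted light re-absorbed on its
# way out, depressing fluorescence below the linear calibration. The
# correction multiplies the observed intensity by the antilog of the summed
# path-length-corrected optical densities.

#' Inner-filter parameters
#'
#' Absorptivities at the excitation and emission wavelengths together with
#' the excitation and emission optical path lengths. Defaults are the
#' instrument geometry the package models: 0.87 cm excitation and 0.9 cm
#' emission path.
#'
#' @param eps_ex absorptivity at the excitation wavelength,
#'   (cells/mL)^-1 cm^-1 or (mg/L)^-1 cm^-1
#' @param eps_em absorptivity at the emission wavelength (same units)
#' @param l_ex_cm excitation path length (cm)
#' @param l_em_cm emission path length (cm)
#' @return object of class `inner_filter_params`
#' @export
inner_filter_params <- function(eps_ex, eps_em, l_ex_cm = 0.87,
                                l_em_cm = 0.9) {
  vals <- c(eps_ex, eps_em, l_ex_cm, l_em_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inner-filter parameters must be positive", call. = FALSE)
  structure(list(eps_ex = eps_ex, eps_em = eps_em,
                 l_ex_cm = l_ex_cm, l_em_cm = l_em_cm),
            class = "inner_filter_params")
}

#' Beer-Lambert optical density
#'
#' `OD = eps * pathlength * conc` (dimensionless).
#'
#' @param eps absorptivity, per concentration unit per cm
#' @param pathlength_cm optical path length (cm)
#' @param conc concentration (cells/mL or mg/L)
#' @return optical density
#' @export
optical_density <- function(eps, pathlength_cm, conc) {
  if (any(c(eps, pathlength_cm, conc) < 0))
    stop("optical_density needs non-negative inputs", call. = FALSE)
  eps * pathlength_cm * conc
}

#' Excitation and emission optical densities for a sample
#'
#' @param ifp an [inner_filter_params]
#' @param conc concentration
#' @return list with `od_ex`, `od_em`
#' @export
sample_optical_densities <- function(ifp, conc) {
  stopifnot(inherits(ifp, "inner_filter_params"))
  list(od_ex = optical_density(ifp$eps_ex, ifp$l_ex_cm, conc),
       od_em = optical_density(ifp$eps_em, ifp$l_em_cm, conc))
}

#' Inner-filter correction of an observed fluorescence intensity
#'
#' `I_corr = I_obs * 10^(OD_ex + OD_em)`. Exact inverse of the attenuation
#' `10^-(OD_ex + OD_em)` the effect applies.
#'
#' @param i_obs observed intensity (counts, >= 0)
#' @param od_ex,od_em path-length-corrected optical densities (>= 0)
#' @return corrected intensity (counts)
#' @export
correct_inner_filter <- function(i_obs, od_ex, od_em) {
  if (any(i_obs < 0)) stop("i_obs must be >= 0", call. = FALSE)
  if (any(c(od_ex, od_em) < 0))
    stop("optical densities must be >= 0", call. = FALSE)
  i_obs * 10^(od_ex + od_em)
}

#' Deviation of an observation from calibration linearity
#'
#' `100 * (predicted - observed) / predicted`, positive when the observed
#' response falls below the fitted line (the inner-filter signature at high
#' concentration).
#'
#' @param curve a [calibration_curve][fit_line] fitted on the linear sub-range
#' @param x concentration of the evaluated point
#' @param y observed response at `x`
#' @return signed percent deviation
#' @export
linearity_deviation <- function(curve, x, y) {
  pred <- predict_calibration(curve, x, warn_extrapolation = FALSE)
  if (any(pred <= 0))
    stop("predicted response must be positive", call. = FALSE)
  100 * (pred - y) / pred
}
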