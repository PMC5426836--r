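# Cell geometry, V/Vmax normalization, and linear / Beer-Lambert calibration.

#' Describe a cell's geometric shape
#'
#' Shapes used for mean-cell-volume computation: `sphere` (diameter),
#' `ellipsoid` (three axis diameters), `cylinder` (diameter and length), or
#' `fixed` for genera whose printed volume is not derivable from printed
#' dimensions (e.g. a cylinder with conical ends of unstated cone length).
#'
#' @param shape one of `"sphere"`, `"ellipsoid"`, `"cylinder"`, `"fixed"`
#' @param dimensions_um numeric vector of dimensions in micrometers:
#'   sphere `d`; ellipsoid `c(d1, d2, d3)`; cylinder `c(d, L)`
#' @param fixed_volume_um3 stored volume in cubic micrometers (shape `fixed`)
#' @return object of class `cell_geometry`
#' @export
cell_geometry <- function(shape, dimensions_um = NULL,
                          fixed_volume_um3 = NULL) {
  shape <- match.arg(shape, c("sphere", "ellipsoid", "cylinder", "fixed"))
  if (shape == "fixed") {
    if (is.null(fixed_volume_um3) || fixed_volume_um3 <= 0)
      stop("shape 'fixed' requires a positive fixed_volume_um3",
           call. = FALSE)
  } else {
    need <- c(sphere = 1L, ellipsoid = 3L, cylinder = 2L)[[shape]]
    if (length(dimensions_um) != need)
      stop(shape, " needs ", need, " dimension(s)", call. = FALSE)
    if (any(!is.finite(dimensions_um)) || any(dimensions_um <= 0))
      stop("all dimensions must be positive", call. = FALSE)
  }
  structure(list(shape = shape, dimensions_um = dimensions_um,
                 fixed_volume_um3 = fixed_volume_um3),
            class = "cell_geometry")
}

#' Mean cell volume from geometry
#'
#' Sphere \eqn{\pi d^3 / 6}; ellipsoid \eqn{\pi d_1 d_2 d_3 / 6} (axes given
#' as diameters); cylinder \eqn{\pi d^2 L / 4}; `fixed` returns the stored
#' value.
#'
#' @param geometry a [cell_geometry]
#' @return volume in cubic micrometers
#' @export
cell_volume <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  d <- geometry$dimensions_um
  switch(geometry$shape,
         sphere    = pi * d[1]^3 / 6,
         ellipsoid = pi * d[1] * d[2] * d[3] / 6,
         cylinder  = pi * d[1]^2 * d[2] / 4,
         fixed     = geometry$fixed_volume_um3)
}

#' Cell-size normalization context
#'
#' Holds the mean cell volume `V` of the measured culture, the maximum
#' (fully grown) cell volume `Vmax`, and an optional cross-genus reference
#' volume used when one genus's calibration is applied to another.
#'
#' @param v_um3 mean cell volume (µm³), `0 < v_um3 <= vmax_um3`
#' @param vmax_um3 maximum cell volume (µm³)
#' @param reference_v_um3 optional reference-genus volume (µm³)
#' @return object of class `normalization_context`
#' @export
normalization_context <- function(v_um3, vmax_um3,
                                  reference_v_um3 = NULL) {
  if (!is.numeric(v_um3) || v_um3 <= 0 || v_um3 > vmax_um3)
    stop("need 0 < v_um3 <= vmax_um3", call. = FALSE)
  if (!is.null(reference_v_um3) && reference_v_um3 <= 0)
    stop("reference_v_um3 must be positive", call. = FALSE)
  structure(list(v_um3 = v_um3, vmax_um3 = vmax_um3,
                 reference_v_um3 = reference_v_um3),
            class = "normalization_context")
}

#' V/Vmax intensity normalization
#'
#' Scales a fluorescence peak intensity by `vmax / v` so that one
#' calibration serves growing and fully grown cultures, and optionally by
#' `reference_v / v` when re-using a reference genus's calibration for a
#' different cell size. [denormalize_intensity()] is the exact inverse.
#'
#' @param intensity counts
#' @param ctx a [normalization_context]
#' @return normalized counts
#' @export
normalize_intensity <- function(intensity, ctx) {
  stopifnot(inherits(ctx, "normalization_context"))
  f <- ctx$vmax_um3 / ctx$v_um3
  if (!is.null(ctx$reference_v_um3)) f <- f * ctx$reference_v_um3 / ctx$v_um3
  intensity * f
}

#' @rdname normalize_intensity
#' @export
denormalize_intensity <- function(intensity, ctx) {
  stopifnot(inherits(ctx, "normalization_context"))
  f <- ctx$vmax_um3 / ctx$v_um3
  if (!is.null(ctx$reference_v_um3)) f <- f * ctx$reference_v_um3 / ctx$v_um3
  intensity / f
}

# ---- linear calibration ---------------------------------------------------

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response on concentration via [stats::lm()].
#' Intercepts are reported by default; a through-origin fit is available for
#' physically zero-anchored responses (Beer-Lambert absorbance).
#'
#' @param x concentrations (cells/mL or mg/L)
#' @param y responses (counts or AU)
#' @param through_origin force intercept 0?
#' @param x_units,y_units axis labels carried with the curve
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `r2`, `x_range`, units
#' @export
fit_line <- function(x, y, through_origin = FALSE,
                     x_units = "cells_per_mL", y_units = "counts") {
  if (length(x) != length(y) || length(x) < 2)
    stop("need >= 2 (x, y) pairs", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate x: need >= 2 distinct concentrations", call. = FALSE)
  if (through_origin && all(x == 0))
    stop("through-origin fit needs a nonzero concentration", call. = FALSE)
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  structure(list(
    slope = unname(if (through_origin) co[["x"]] else co[["x"]]),
    intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
    r2 = r2, x_range = range(x),
    x_units = x_units, y_units = y_units,
    through_origin = through_origin),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> y = %.6g x + %.6g  (R2 %.4f, x in [%g, %g] %s)\n",
    x$slope, x$intercept, x$r2, x$x_range[1], x$x_range[2], x$x_units))
  invisible(x)
}

#' Predict a response from a calibration curve
#'
#' `y = slope * x + intercept`. Concentrations outside the fitted range are
#' allowed but flagged with a warning (extrapolation).
#'
#' @param curve a [calibration_curve][fit_line]
#' @param x concentration
#' @param warn_extrapolation warn when `x` is outside the fitted range?
#' @return predicted response
#' @export
predict_calibration <- function(curve, x, warn_extrapolation = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (warn_extrapolation &&
      any(x < curve$x_range[1] | x > curve$x_range[2]))
    warning("prediction outside the calibrated concentration range",
            call. = FALSE)
  curve$slope * x + curve$intercept
}

#' Invert a calibration curve
#'
#' `x = (y - intercept) / slope`. Inversions below the intercept would give
#' negative concentrations; these are clamped to zero with a warning (a
#' physical floor).
#'
#' @param curve a [calibration_curve][fit_line]
#' @param y observed response
#' @param clamp clamp negative concentrations to 0?
#' @return concentration
#' @export
invert_calibration <- function(curve, y, clamp = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (abs(curve$slope) < 1e-12)
    stop("cannot invert a calibration with zero slope", call. = FALSE)
  x <- (y - curve$intercept) / curve$slope
  if (clamp && any(x < 0)) {
    warning("inverted concentration below zero; clamped to 0",
            call. = FALSE)
    x <- pmax(x, 0)
  }
  x
}

#' Fit a Beer-Lambert absorptivity
#'
#' Through-origin regression of absorbance on concentration (`A = eps * l *
#' C`); the absorptivity is the fitted slope divided by the optical path
#' length.
#'
#' @param absorbance absorbance values (AU)
#' @param conc concentrations (cells/mL or mg/L)
#' @param pathlength_cm optical path length in cm
#' @return object of class `beer_lambert_params` with `epsilon` (per
#'   concentration unit per cm), `pathlength_cm`, `r2`
#' @export
fit_absorptivity <- function(absorbance, conc, pathlength_cm) {
  if (pathlength_cm <= 0) stop("pathlength_cm must be > 0", call. = FALSE)
  curve <- fit_line(conc, absorbance, through_origin = TRUE,
                    x_units = "concentration", y_units = "AU")
  structure(list(epsilon = curve$slope / pathlength_cm,
                 pathlength_cm = pathlength_cm, r2 = curve$r2),
            class = "beer_lambert_params")
}

# ---- dry weight -----------------------------------------------------------

#' Dry weight from cell counts via a volume-normalized calibration
#'
#' Cell counts of growing cultures are first normalized by the cell-size
#' volume ratio `V / Vmax` (growing cells carry less mass than fully grown
#' ones), then mapped through a linear counts-to-dry-weight calibration
#' fitted on normalized counts. [counts_from_dry_weight()] is the inverse.
#'
#' @param counts cells/mL
#' @param ctx a [normalization_context]
#' @param curve a [calibration_curve][fit_line] of dry weight (mg/L) on normalized
#'   counts
#' @return dry weight in mg/L
#' @export
dry_weight_from_counts <- function(counts, ctx, curve) {
  stopifnot(inherits(ctx, "normalization_context"))
  predict_calibration(curve, counts * ctx$v_um3 / ctx$vmax_um3,
                      warn_extrapolation = FALSE)
}

#' @rdname dry_weight_from_counts
#' @param dry_weight_mg_l dry weight in mg/L
#' @export
counts_from_dry_weight <- function(dry_weight_mg_l, ctx, curve) {
  stopifnot(inherits(ctx, "normalization_context"))
  invert_calibration(curve, dry_weight_mg_l, clamp = FALSE) *
    ctx$vmax_um3 / ctx$v_um3
}
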