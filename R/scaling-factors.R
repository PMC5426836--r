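# Excitation-wavelength-dependent scaling factors relating the peak
# intensities of phycocyanin (PC), phycoerythrin (PE) and chlorophyll-a.
# These are empirical, dimensionless ratio models, demonstrated on the
# instrument at a limited excitation set; evaluation elsewhere is allowed
# but flagged.

ALPHA_DOMAIN_NM <- c(523, 595, 612)  # excitations where the PC/chl ratio model holds
BETA_DOMAIN_NM  <- c(402, 523)       # excitations where the PE/PC ratio model holds

#' Scaling-factor context
#'
#' Wavelengths feeding the four scaling factors: the excitation wavelength
#' and the in vivo emission wavelengths of phycocyanin and phycoerythrin.
#' Emission must lie above excitation (Stokes shift).
#'
#' @param lambda_ex_nm excitation wavelength (nm)
#' @param lambda_em_pc_nm phycocyanin emission wavelength (nm)
#' @param lambda_em_pe_nm phycoerythrin emission wavelength (nm); optional
#'   when only the PC/chl-a factors are needed
#' @return object of class `scaling_context`
#' @export
scaling_context <- function(lambda_ex_nm, lambda_em_pc_nm,
                            lambda_em_pe_nm = NULL) {
  vals <- c(lambda_ex_nm, lambda_em_pc_nm, lambda_em_pe_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all wavelengths must be positive", call. = FALSE)
  if (lambda_em_pc_nm < lambda_ex_nm)
    stop("phycocyanin emission must be >= excitation (Stokes shift)",
         call. = FALSE)
  if (!is.null(lambda_em_pe_nm) && lambda_em_pe_nm < lambda_ex_nm)
    stop("phycoerythrin emission must be >= excitation (Stokes shift)",
         call. = FALSE)
  structure(list(lambda_ex_nm = lambda_ex_nm,
                 lambda_em_pc_nm = lambda_em_pc_nm,
                 lambda_em_pe_nm = lambda_em_pe_nm),
            class = "scaling_context")
}

domain_warning <- function(ctx, domain, factor, warn) {
  if (warn && !any(abs(ctx$lambda_ex_nm - domain) < 1e-6))
    warning(factor, " evaluated outside its demonstrated excitation set (",
            paste(domain, collapse = ", "), " nm)", call. = FALSE)
}

#' Scaling factors among pigment peak intensities
#'
#' Dimensionless ratios of pigment fluorescence peak intensities as linear
#' functions of emission over excitation wavelength:
#' \itemize{
#'   \item `s_alpha`: PC/chl-a in cyanobacteria,
#'     \eqn{3\lambda_{em}(PC)/\lambda_{ex} - 2}
#'   \item `s_beta`: PE/PC in red algae,
#'     \eqn{2\lambda_{em}(PE)/\lambda_{ex} - 1}
#'   \item `s_gamma`: PC/chl-a in red algae,
#'     \eqn{3[\lambda_{em}(PC)/\lambda_{ex} - 1] = S_\alpha - 1}
#'   \item `s_delta`: PE/chl-a in red algae, \eqn{S_\beta S_\gamma}
#' }
#' The models are empirical and demonstrated at excitations 523/595/612 nm
#' (`s_alpha`, `s_gamma`) and 402/523 nm (`s_beta`); evaluation elsewhere
#' emits a calibration-domain warning.
#'
#' @param ctx a [scaling_context]
#' @param warn_domain warn outside the demonstrated excitation set?
#' @return the dimensionless scaling factor
#' @export
s_alpha <- function(ctx, warn_domain = TRUE) {
  stopifnot(inherits(ctx, "scaling_context"))
  domain_warning(ctx, ALPHA_DOMAIN_NM, "s_alpha", warn_domain)
  3 * ctx$lambda_em_pc_nm / ctx$lambda_ex_nm - 2
}

#' @rdname s_alpha
#' @export
s_beta <- function(ctx, warn_domain = TRUE) {
  stopifnot(inherits(ctx, "scaling_context"))
  if (is.null(ctx$lambda_em_pe_nm))
    stop("s_beta needs a phycoerythrin emission wavelength", call. = FALSE)
  domain_warning(ctx, BETA_DOMAIN_NM, "s_beta", warn_domain)
  2 * ctx$lambda_em_pe_nm / ctx$lambda_ex_nm - 1
}

#' @rdname s_alpha
#' @export
s_gamma <- function(ctx, warn_domain = TRUE) {
  stopifnot(inherits(ctx, "scaling_context"))
  domain_warning(ctx, ALPHA_DOMAIN_NM, "s_gamma", warn_domain)
  3 * (ctx$lambda_em_pc_nm / ctx$lambda_ex_nm - 1)
}

#' @rdname s_alpha
#' @export
s_delta <- function(ctx, warn_domain = TRUE) {
  s_beta(ctx, warn_domain) * s_gamma(ctx, warn_domain)
}

check_factor_positive <- function(s, name) {
  if (!is.finite(s) || s <= 0)
    stop(name, " is ", format(s), " at this context; the ratio model is ",
         "invalid here (emission too close to excitation) and ",
         "division-based prediction is undefined", call. = FALSE)
  s
}

#' Predict a chlorophyll-a peak intensity from a phycocyanin peak
#'
#' Divides the phycocyanin peak intensity by the PC/chl-a scaling factor:
#' `s_alpha` for cyanobacteria, `s_gamma` for red algae.
#'
#' @param i_pc phycocyanin peak intensity (counts, >= 0)
#' @param ctx a [scaling_context]
#' @param via `"alpha"` (cyanobacteria) or `"gamma"` (red algae)
#' @param warn_domain warn outside the demonstrated excitation set?
#' @return predicted chlorophyll-a peak intensity (counts)
#' @export
predict_chla_from_phycocyanin <- function(i_pc, ctx, via = c("alpha", "gamma"),
                                          warn_domain = TRUE) {
  via <- match.arg(via)
  if (any(i_pc < 0)) stop("i_pc must be >= 0", call. = FALSE)
  s <- if (via == "alpha") s_alpha(ctx, warn_domain) else
    s_gamma(ctx, warn_domain)
  i_pc / check_factor_positive(s, paste0("s_", via))
}

#' Predict a phycocyanin peak intensity from a phycoerythrin peak
#'
#' Divides the phycoerythrin peak intensity by the PE/PC scaling factor
#' `s_beta` (red algae).
#'
#' @param i_pe phycoerythrin peak intensity (counts, >= 0)
#' @param ctx a [scaling_context]
#' @param warn_domain warn outside the demonstrated excitation set?
#' @return predicted phycocyanin peak intensity (counts)
#' @export
predict_phycocyanin_from_phycoerythrin <- function(i_pe, ctx,
                                                   warn_domain = TRUE) {
  if (any(i_pe < 0)) stop("i_pe must be >= 0", call. = FALSE)
  i_pe / check_factor_positive(s_beta(ctx, warn_domain), "s_beta")
}
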