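# Genus registry: cell geometry, printed mean volumes, pigment emission
# wavelengths, and Beer-Lambert absorptivities for the six cultivated
# genera plus the field-sample reference genus.
#
# Geometry-derived volumes are computed from printed mean cell sizes.
# Two genera store printed volumes as fixed constants: Anki's cylinder-with-
# conical-ends volume (1902 um^3) is not derivable from the printed diameter
# and length alone (cone length unstated), and Cyc's printed 572 um^3
# differs from the short-cylinder computation on the printed 10.3 x 6.8 um
# size (~567 um^3); the printed values are kept authoritative.

#' Genus registry
#'
#' Per-genus cell geometry, mean/maximum cell volume (um^3), algal group,
#' pigment emission wavelengths, and (where applicable) Beer-Lambert
#' absorptivities. Phycocyanin emission centers of *Anabaena* and
#' *Cylindrospermum* shift with excitation (402 nm excitation: 658/666 nm;
#' 612 nm: 656/659 nm); the registry stores both anchors and
#' [pigment_center()] interpolates linearly in excitation between them.
#'
#' @return named list of genus entries
#' @export
default_genus_registry <- function() {
  list(
    anki = list(
      genus = "anki", group = "green",
      geometry = cell_geometry("fixed", fixed_volume_um3 = 1902),
      volume_um3 = 1902, vmax_um3 = 1902,
      pigments = list(chlorophyll_a = c(`402` = 686, `612` = 686))),
    chlor = list(
      genus = "chlor", group = "green",
      geometry = cell_geometry("sphere", 10),
      volume_um3 = cell_volume(cell_geometry("sphere", 10)),
      vmax_um3 = cell_volume(cell_geometry("sphere", 10)),
      pigments = list(chlorophyll_a = c(`402` = 686, `612` = 686))),
    ana = list(
      genus = "ana", group = "cyanobacteria",
      geometry = cell_geometry("ellipsoid", c(11.48, 8.61, 8.61)),
      volume_um3 = cell_volume(cell_geometry("ellipsoid",
                                             c(11.48, 8.61, 8.61))),
      vmax_um3 = cell_volume(cell_geometry("ellipsoid",
                                           c(11.48, 8.61, 8.61))),
      pigments = list(phycocyanin = c(`402` = 658, `612` = 656),
                      chlorophyll_a = c(`402` = 683, `612` = 683))),
    cyl = list(
      genus = "cyl", group = "cyanobacteria",
      geometry = cell_geometry("ellipsoid", c(8.61, 5.74, 5.74)),
      volume_um3 = cell_volume(cell_geometry("ellipsoid",
                                             c(8.61, 5.74, 5.74))),
      vmax_um3 = cell_volume(cell_geometry("ellipsoid",
                                           c(8.61, 5.74, 5.74))),
      pigments = list(phycocyanin = c(`402` = 666, `612` = 659),
                      chlorophyll_a = c(`402` = 683, `612` = 683),
                      cyl_619 = c(`402` = 619, `612` = 619))),
    porp = list(
      genus = "porp", group = "red",
      geometry = cell_geometry("sphere", 8),
      volume_um3 = cell_volume(cell_geometry("sphere", 8)),
      vmax_um3 = cell_volume(cell_geometry("sphere", 8)),
      pigments = list(phycoerythrin = c(`402` = 580, `612` = 580),
                      phycocyanin = c(`402` = 660, `612` = 660),
                      chlorophyll_a = c(`402` = 683, `612` = 683)),
      # absorptivities in (cells/mL)^-1 cm^-1 at 523 nm (excitation) and
      # 580 nm (phycoerythrin emission)
      absorptivity = c(`523` = 2.0719e-7, `580` = 1.9743e-7)),
    cyc = list(
      genus = "cyc", group = "golden_brown",
      geometry = cell_geometry("fixed", fixed_volume_um3 = 572),
      volume_um3 = 572, vmax_um3 = 572,
      # fucoxanthin absorbance bands; absorptivities in (cells/mL)^-1 cm^-1
      abs_bands = list(c(center_nm = 449, eps = 2.05e-8),
                       c(center_nm = 486, eps = 1.54e-8))),
    microcystis = list(
      genus = "microcystis", group = "cyanobacteria",
      geometry = cell_geometry("sphere", 10.28),
      volume_um3 = cell_volume(cell_geometry("sphere", 10.28)),
      vmax_um3 = cell_volume(cell_geometry("sphere", 10.28)),
      pigments = list(phycocyanin = c(`402` = 659, `612` = 659),
                      chlorophyll_a = c(`402` = 683, `612` = 683)))
  )
}

#' Pigment emission center at a given excitation
#'
#' Linearly interpolates a pigment's emission center between the registry's
#' excitation anchors (clamping outside their range). Pigments with a single
#' stored center return it unchanged.
#'
#' @param anchors named numeric vector, names = excitation nm
#' @param excitation_nm excitation wavelength (nm)
#' @return emission center (nm)
#' @export
pigment_center <- function(anchors, excitation_nm) {
  if (length(anchors) == 1) return(unname(anchors))
  ex <- as.numeric(names(anchors))
  unname(stats::approx(ex, anchors, xout = excitation_nm, rule = 2)$y)
}

#' Read a genus registry from YAML or JSON
#'
#' User-supplied registries follow the structure of
#' [default_genus_registry()] with `shape`/`dimensions_um`/
#' `fixed_volume_um3` in place of the `cell_geometry` object.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return named list of genus entries
#' @export
read_registry <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  lapply(raw, function(g) {
    if (is.null(g$group)) stop("registry entry missing 'group'", call. = FALSE)
    if (!is.null(g$shape)) {
      g$geometry <- cell_geometry(g$shape,
                                  dimensions_um = g$dimensions_um,
                                  fixed_volume_um3 = g$fixed_volume_um3)
      if (is.null(g$volume_um3)) g$volume_um3 <- cell_volume(g$geometry)
      if (is.null(g$vmax_um3)) g$vmax_um3 <- g$volume_um3
    }
    g$pigments <- lapply(g$pigments, function(p) {
      if (is.list(p)) unlist(p) else p
    })
    g
  })
}
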