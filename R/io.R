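# CSV dialects: a comment/metadata header block of "# key=value" lines
# followed by a regular CSV table. Readers validate and reject malformed
# files rather than repairing them.

read_meta_header <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  header_end <- if (any(!is_meta)) min(which(!is_meta)) - 1L else length(lines)
  meta <- list()
  for (ln in lines[seq_len(header_end)]) {
    kv <- sub("^#\\s*", "", ln)
    if (!grepl("=", kv)) next
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (!is.na(num)) num else trimws(val)
  }
  list(meta = meta, skip = header_end)
}

check_wavelength_column <- function(w, path) {
  d <- which(diff(w) <= 0)
  if (length(d)) {
    what <- if (w[d[1] + 1] == w[d[1]]) "duplicated" else "non-monotone"
    stop(what, " wavelength at data line ", d[1] + 1L, " of ", path,
         call. = FALSE)
  }
}

format_num <- function(x) formatC(x, format = "g", digits = 10)

#' Write / read an emission spectrum file
#'
#' Two-column CSV (`wavelength_nm,intensity`) preceded by a `# key=value`
#' metadata block carrying at least `excitation_nm` and `integration_s`.
#' Round trip preserves values to 9+ significant digits and unknown
#' metadata keys.
#'
#' @param spectrum an [emission_spectrum]
#' @param path file path
#' @return `read_spectrum` returns an [emission_spectrum];
#'   `write_spectrum` returns `path` invisibly
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# excitation_nm=%s", format_num(spectrum$excitation_nm)),
    sprintf("# integration_s=%s", format_num(spectrum$integration_s)),
    sprintf("# blank_corrected=%s", spectrum$blank_corrected),
    vapply(names(spectrum$meta), function(k)
      sprintf("# %s=%s", k, as.character(spectrum$meta[[k]])),
      character(1)),
    "wavelength_nm,intensity",
    paste(format_num(spectrum$wavelength_nm),
          format_num(spectrum$intensity), sep = ",")), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  h <- read_meta_header(path)
  if (is.null(h$meta$excitation_nm))
    stop("spectrum file missing '# excitation_nm=' metadata: ", path,
         call. = FALSE)
  tab <- utils::read.csv(path, skip = h$skip, comment.char = "")
  if (!all(c("wavelength_nm", "intensity") %in% names(tab)))
    stop("expected columns wavelength_nm,intensity in ", path,
         call. = FALSE)
  check_wavelength_column(tab$wavelength_nm, path)
  known <- c("excitation_nm", "integration_s", "blank_corrected")
  emission_spectrum(
    tab$wavelength_nm, tab$intensity,
    excitation_nm = h$meta$excitation_nm,
    integration_s = if (is.null(h$meta$integration_s)) 10
                    else h$meta$integration_s,
    blank_corrected = isTRUE(h$meta$blank_corrected == "TRUE" |
                             h$meta$blank_corrected == TRUE),
    meta = h$meta[setdiff(names(h$meta), known)])
}

#' Write / read an excitation-emission matrix file
#'
#' Wide CSV: first column `wavelength_nm`, one intensity column per
#' excitation labelled `ex<nnn>`.
#'
#' @param eem_obj an [eem]
#' @param path file path
#' @return `read_eem` returns an [eem]; `write_eem` returns `path`
#'   invisibly
#' @export
write_eem <- function(eem_obj, path) {
  stopifnot(inherits(eem_obj, "eem"))
  first <- eem_obj$spectra[[1]]
  tab <- data.frame(wavelength_nm = first$wavelength_nm)
  for (s in eem_obj$spectra)
    tab[[sprintf("ex%g", s$excitation_nm)]] <- s$intensity
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# integration_s=%s", format_num(first$integration_s)),
             con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_eem
#' @export
read_eem <- function(path) {
  h <- read_meta_header(path)
  tab <- utils::read.csv(path, skip = h$skip, comment.char = "")
  if (names(tab)[1] != "wavelength_nm")
    stop("first column must be wavelength_nm in ", path, call. = FALSE)
  excols <- grep("^ex[0-9.]+$", names(tab), value = TRUE)
  if (!length(excols))
    stop("no ex<nnn> excitation columns in ", path, call. = FALSE)
  check_wavelength_column(tab$wavelength_nm, path)
  ts <- if (is.null(h$meta$integration_s)) 10 else h$meta$integration_s
  eem(lapply(excols, function(cn)
    emission_spectrum(tab$wavelength_nm, tab[[cn]],
                      excitation_nm = as.numeric(sub("^ex", "", cn)),
                      integration_s = ts, blank_corrected = TRUE)))
}

#' Write / read an absorbance spectrum file
#'
#' Two-column CSV `wavelength_nm,absorbance_au`.
#'
#' @param abs_spec an [absorbance_spectrum]
#' @param path file path
#' @return `read_absorbance` returns an [absorbance_spectrum]
#' @export
write_absorbance <- function(abs_spec, path) {
  stopifnot(inherits(abs_spec, "absorbance_spectrum"))
  utils::write.table(
    data.frame(wavelength_nm = format_num(abs_spec$wavelength_nm),
               absorbance_au = format_num(abs_spec$absorbance)),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_absorbance
#' @export
read_absorbance <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "absorbance_au") %in% names(tab)))
    stop("expected columns wavelength_nm,absorbance_au in ", path,
         call. = FALSE)
  check_wavelength_column(tab$wavelength_nm, path)
  absorbance_spectrum(tab$wavelength_nm, tab$absorbance_au)
}

#' Write / read a calibration table
#'
#' Two-column CSV `x,y` with unit metadata in the header block.
#'
#' @param tab data.frame with concentration and response columns (the
#'   first two columns are used)
#' @param path file path
#' @param x_units,y_units axis labels
#' @param excitation_nm optional excitation tag
#' @return `read_calibration_table` returns a data.frame with columns
#'   `x`, `y` and attributes `x_units`, `y_units`, `excitation_nm`
#' @export
write_calibration_table <- function(tab, path, x_units = "cells_per_mL",
                                    y_units = "counts",
                                    excitation_nm = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# x_units=%s", x_units),
           sprintf("# y_units=%s", y_units))
  if (!is.null(excitation_nm))
    hdr <- c(hdr, sprintf("# excitation_nm=%s", format_num(excitation_nm)))
  writeLines(c(hdr, "x,y",
               paste(format_num(tab[[1]]), format_num(tab[[2]]),
                     sep = ",")), con)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  h <- read_meta_header(path)
  tab <- utils::read.csv(path, skip = h$skip, comment.char = "")
  if (!all(c("x", "y") %in% names(tab)))
    stop("expected columns x,y in ", path, call. = FALSE)
  attr(tab, "x_units") <- h$meta$x_units
  attr(tab, "y_units") <- h$meta$y_units
  attr(tab, "excitation_nm") <- h$meta$excitation_nm
  tab
}

#' Write a structured run report
#'
#' JSON serialization of a named list of results (group quantifications,
#' evidence peaks, scaling factors, warnings, config echo).
#'
#' @param report named list
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
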