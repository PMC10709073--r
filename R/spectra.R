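# Wavelength grid, white-reference calibration, resampling and spectra I/O.

#' Canonical wavelength grid
#'
#' The instrument grid assumed by every downstream model: 1-nm sampling from
#' 350 to 2500 nm, i.e. 2,151 bands covering the VNIR and SWIR regions where
#' pigment, water and dry-matter absorption features sit.
#'
#' @return Numeric vector of 2,151 wavelengths in nm.
#' @export
#' @examples
#' g <- canonical_grid()
#' length(g)  # 2151
canonical_grid <- function() {
  as.numeric(350:2500)
}

#' Construct a raw instrument scan
#'
#' A raw scan is the uncalibrated signal recorded over a wavelength grid,
#' e.g. a sample scan or the white-reference panel scan.
#'
#' @param wavelengths strictly increasing wavelengths in nm.
#' @param values nonnegative, finite instrument counts, one per wavelength.
#' @return An object of class `raw_scan` with elements `wavelengths` and
#'   `values`.
#' @export
raw_scan <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  stop_if(length(wavelengths) < 1L, "raw_scan: empty wavelength grid")
  stop_if(any(!is.finite(wavelengths)), "raw_scan: non-finite wavelengths")
  stop_if(any(diff(wavelengths) <= 0),
          "raw_scan: wavelengths must be strictly increasing")
  stop_if(length(values) != length(wavelengths),
          "raw_scan: %d values for %d wavelengths",
          length(values), length(wavelengths))
  stop_if(any(!is.finite(values)), "raw_scan: non-finite values")
  stop_if(any(values < 0), "raw_scan: negative instrument counts")
  structure(list(wavelengths = wavelengths, values = values),
            class = "raw_scan")
}

#' Construct a reflectance spectrum
#'
#' Reflectance is the unitless ratio of sample to white-reference signal.
#' Values slightly above 1 can arise from calibration noise and are retained
#' up to 1.5; anything above that is treated as a calibration failure rather
#' than silently clipped, because clipping would bias the regression models.
#'
#' @param wavelengths strictly increasing wavelengths in nm.
#' @param reflectance finite values in \[0, 1.5\], one per wavelength.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  stop_if(length(reflectance) != length(wavelengths),
          "reflectance_spectrum: %d values for %d wavelengths",
          length(reflectance), length(wavelengths))
  stop_if(any(diff(wavelengths) <= 0),
          "reflectance_spectrum: wavelengths must be strictly increasing")
  stop_if(any(!is.finite(reflectance)),
          "reflectance_spectrum: non-finite reflectance")
  bad <- which(reflectance < 0 | reflectance > 1.5)
  stop_if(length(bad) > 0,
          "reflectance_spectrum: value %.4g at %g nm outside [0, 1.5] (calibration failure)",
          reflectance[bad[1]], wavelengths[bad[1]])
  structure(list(wavelengths = wavelengths, reflectance = reflectance),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d bands, %g-%g nm, mean R = %.3f\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              mean(x$reflectance)))
  invisible(x)
}

#' White-reference calibration
#'
#' Converts a raw sample scan to reflectance by dividing, band by band, by a
#' scan of the white reference panel taken in the same chamber under the same
#' illumination.
#'
#' @param sample `raw_scan` of the sample.
#' @param white `raw_scan` of the white reference panel, on an identical
#'   grid, with strictly positive values.
#' @return A `reflectance_spectrum`.
#' @export
#' @examples
#' g <- 400:410
#' w <- raw_scan(g, rep(1000, length(g)))
#' s <- raw_scan(g, rep(500, length(g)))
#' calibrate_reflectance(s, w)$reflectance  # all 0.5
calibrate_reflectance <- function(sample, white) {
  stopifnot(inherits(sample, "raw_scan"), inherits(white, "raw_scan"))
  stop_if(length(sample$wavelengths) != length(white$wavelengths) ||
            any(sample$wavelengths != white$wavelengths),
          "calibrate_reflectance: sample and white reference grids differ")
  bad <- which(white$values <= 0)
  stop_if(length(bad) > 0,
          "calibrate_reflectance: white reference value %.4g at %g nm is not positive",
          white$values[bad[1]], white$wavelengths[bad[1]])
  reflectance_spectrum(sample$wavelengths, sample$values / white$values)
}

#' Calibrate a matrix of raw scans against an embedded white-reference row
#'
#' Spectra files for dark-chamber raw scans use the same wide layout as
#' reflectance files, with the panel scan stored under the reserved id
#' `"WHITE_REF"`.  This helper divides every other row by the panel row.
#'
#' @param raw numeric matrix of raw scans; rownames are segment ids and must
#'   include `white_id`; colnames are wavelengths.
#' @param white_id reserved row id of the white panel scan.
#' @return Reflectance matrix with the panel row removed.
#' @export
calibrate_scan_matrix <- function(raw, white_id = "WHITE_REF") {
  stop_if(is.null(rownames(raw)) || !(white_id %in% rownames(raw)),
          "calibrate_scan_matrix: no '%s' row in the scan matrix", white_id)
  wl <- as.numeric(colnames(raw))
  white <- raw_scan(wl, raw[white_id, ])
  keep <- setdiff(rownames(raw), white_id)
  out <- matrix(NA_real_, length(keep), ncol(raw),
                dimnames = list(keep, colnames(raw)))
  for (id in keep) {
    out[id, ] <- calibrate_reflectance(raw_scan(wl, raw[id, ]), white)$reflectance
  }
  out
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; values at wavelengths shared by both grids are
#' passed through unchanged.  Extrapolation outside the source range is
#' refused.
#'
#' @param spectrum a `reflectance_spectrum`.
#' @param target numeric target grid (nm), strictly increasing.
#' @return A `reflectance_spectrum` on `target`.
#' @export
resample_to_grid <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  target <- as.numeric(target)
  stop_if(any(diff(target) <= 0),
          "resample_to_grid: target grid must be strictly increasing")
  src <- spectrum$wavelengths
  stop_if(min(target) < min(src) || max(target) > max(src),
          "resample_to_grid: target range [%g, %g] nm exceeds source range [%g, %g] nm (no extrapolation)",
          min(target), max(target), min(src), max(src))
  vals <- stats::approx(src, spectrum$reflectance, xout = target,
                        method = "linear", ties = "ordered")$y
  reflectance_spectrum(target, vals)
}

#' Read a wide spectra CSV
#'
#' Expected layout: first column `segment_id`, remaining columns named by
#' integer wavelength in nm, one row per segment.  This is the format emitted
#' by [write_spectra_csv()] and by the simulator.
#'
#' @param path file path.
#' @return Numeric matrix, one row per segment (rownames = segment ids),
#'   colnames = wavelengths.  An empty file yields a 0-row matrix.
#' @export
read_spectra_csv <- function(path) {
  stop_if(!file.exists(path), "read_spectra_csv: no such file: %s", path)
  if (file.size(path) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1L))
  stop_if(names(dt)[1] != "segment_id",
          "read_spectra_csv: first column must be 'segment_id', got '%s'",
          names(dt)[1])
  wl <- suppressWarnings(as.numeric(names(dt)[-1]))
  stop_if(length(wl) > 0 && any(!is.finite(wl)),
          "read_spectra_csv: non-numeric wavelength header at column %d",
          which(!is.finite(wl))[1] + 1L)
  stop_if(length(wl) > 1 && any(diff(wl) <= 0),
          "read_spectra_csv: wavelength header is not strictly increasing at column %d",
          which(diff(wl) <= 0)[1] + 2L)
  ids <- dt[[1]]
  if (nrow(dt) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(wl),
                  dimnames = list(NULL, names(dt)[-1])))
  }
  mat <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(dt[[bad + 1L]]))))[1]
    stop_if(TRUE, "read_spectra_csv: non-numeric cell at row %d, column %d",
            badrow, bad + 1L)
  }
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          "read_spectra_csv: missing or non-numeric cell at row %d, column %d",
          bad[1, 1], bad[1, 2] + 1L)
  rownames(mat) <- ids
  colnames(mat) <- names(dt)[-1]
  mat
}

#' Write a wide spectra CSV
#'
#' Inverse of [read_spectra_csv()]; numbers are written with full round-trip
#' precision so that `read_spectra_csv(write_spectra_csv(x))` reproduces `x`
#' exactly.
#'
#' @param spectra numeric matrix with segment-id rownames and wavelength
#'   colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(is.matrix(spectra), is.numeric(spectra))
  stop_if(is.null(rownames(spectra)), "write_spectra_csv: spectra need rownames")
  stop_if(is.null(colnames(spectra)), "write_spectra_csv: spectra need wavelength colnames")
  header <- paste(c("segment_id", colnames(spectra)), collapse = ",")
  body <- vapply(seq_len(nrow(spectra)), function(i) {
    paste(c(rownames(spectra)[i], sprintf("%.17g", spectra[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
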