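#' Absorbance spectrum
#'
#' A per-sample absorbance spectrum A(lambda) (dimensionless, 1 cm path
#' assumed), used to build the multiplicative inner-filter-effect correction
#' matrix. Wavelengths must be strictly increasing; negative readings are
#' baseline noise and are clipped to zero by default (set
#' `negative = "reject"` to error instead).
#'
#' @param sample_id Sample identifier.
#' @param wavelengths Numeric vector (nm).
#' @param absorbance Numeric vector, same length.
#' @param negative `"clip"` (default) or `"reject"`.
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(sample_id, wavelengths, absorbance,
                                negative = c("clip", "reject")) {
  negative <- match.arg(negative)
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.numeric(wavelengths), is.numeric(absorbance),
            length(wavelengths) == length(absorbance),
            length(wavelengths) >= 1)
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  absorbance <- as.numeric(absorbance[ord])
  if (anyDuplicated(wavelengths)) {
    stop("duplicate wavelengths in absorbance spectrum for sample '",
         sample_id, "'", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance values must be finite", call. = FALSE)
  }
  if (any(absorbance < 0)) {
    if (negative == "reject") {
      stop("negative absorbance in sample '", sample_id, "'", call. = FALSE)
    }
    absorbance <- pmax(absorbance, 0)
  }
  structure(list(sample_id = sample_id, wavelengths = wavelengths,
                 absorbance = absorbance),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> sample '%s': %d points, %g-%g nm\n",
              x$sample_id, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read a 2-column absorbance CSV
#'
#' Expects header `wavelength_nm,absorbance`. Rows may be unsorted; the
#' spectrum is returned sorted ascending.
#'
#' @inheritParams absorbance_spectrum
#' @param path Path to CSV.
#' @return An [absorbance_spectrum()].
#' @export
read_absorbance <- function(path, sample_id = NULL,
                            negative = c("clip", "reject")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "absorbance")
  if (!all(need %in% names(df))) {
    stop("absorbance CSV must have header 'wavelength_nm,absorbance': ",
         path, call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  absorbance_spectrum(sample_id, df$wavelength_nm, df$absorbance,
                      negative = match.arg(negative))
}

#' Write an absorbance spectrum to CSV
#' @param x An [absorbance_spectrum()].
#' @param path Output path.
#' @export
write_absorbance <- function(x, path) {
  stopifnot(inherits(x, "absorbance_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = x$wavelengths,
                              absorbance = x$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate an absorbance spectrum at arbitrary wavelengths
#'
#' Linear interpolation between measured points. Wavelengths outside the
#' measured range return 0 with a warning: long-wavelength absorbance of a
#' dilute culture is negligible, and extrapolating baseline noise would be
#' worse than assuming transparency.
#'
#' @param spec An [absorbance_spectrum()].
#' @param wavelength Numeric vector of query wavelengths (nm).
#' @return Numeric vector of absorbances.
#' @examples
#' s <- absorbance_spectrum("a", c(600, 700), c(0.2, 0.4))
#' interpolate_absorbance(s, 650) # 0.3
#' @export
interpolate_absorbance <- function(spec, wavelength) {
  stopifnot(inherits(spec, "absorbance_spectrum"), is.numeric(wavelength))
  if (length(spec$wavelengths) == 0) stop("empty absorbance spectrum", call. = FALSE)
  outside <- wavelength < min(spec$wavelengths) | wavelength > max(spec$wavelengths)
  if (any(outside)) {
    warning(sum(outside), " wavelength(s) outside the measured absorbance ",
            "range for sample '", spec$sample_id, "'; absorbance taken as 0",
            call. = FALSE)
  }
  if (length(spec$wavelengths) == 1) {
    out <- ifelse(outside, 0, spec$absorbance)
    return(as.numeric(out))
  }
  out <- stats::approx(spec$wavelengths, spec$absorbance, xout = wavelength,
                       rule = 1)$y
  out[outside] <- 0
  as.numeric(out)
}
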