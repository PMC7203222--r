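#' Uniform wavelength grid
#'
#' A strictly increasing, uniformly spaced set of wavelengths (nm), the axis
#' type shared by all EEM objects. The spectrofluorometer acquisition this
#' package targets scans excitation 250--790 nm and emission 260--800 nm in
#' 5 nm steps, giving 109 points on each axis.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm); `(stop - start) / step` must be an
#'   integer. A single-point axis (`stop == start`) is allowed, e.g. for a
#'   fixed-excitation emission scan.
#' @param step Grid spacing (nm), positive.
#' @return An object of class `wavelength_grid`: a list with fields `start`,
#'   `stop`, `step` and the derived `values`.
#' @examples
#' ex <- wavelength_grid(250, 790, 5)
#' length(ex$values) # 109
#' @export
wavelength_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (stop < start) stop("`stop` must not precede `start`", call. = FALSE)
  n_steps <- (stop - start) / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("(stop - start) / step must be an integer; got ", n_steps,
         call. = FALSE)
  }
  values <- start + step * seq(0, round(n_steps))
  structure(list(start = start, stop = stop, step = step, values = values),
            class = "wavelength_grid")
}

#' Construct a wavelength grid from its values
#'
#' Validates that the values are strictly increasing and uniformly spaced
#' (used when an axis is read from a file header rather than declared).
#'
#' @param values Numeric vector of wavelengths (nm).
#' @param tol Relative tolerance on spacing uniformity.
#' @return A `wavelength_grid`.
#' @export
wavelength_grid_from_values <- function(values, tol = 1e-6) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("a grid needs at least 1 wavelength", call. = FALSE)
  if (anyNA(values)) stop("grid values must all parse as numbers", call. = FALSE)
  if (length(values) == 1) {
    # single-point axis: the spacing is undefined, record a nominal 1 nm step
    return(wavelength_grid(values, values, 1))
  }
  d <- diff(values)
  if (any(d <= 0)) stop("grid values must be strictly increasing", call. = FALSE)
  step <- d[1]
  if (any(abs(d - step) > tol * step)) {
    stop("grid spacing is not uniform", call. = FALSE)
  }
  wavelength_grid(values[1], values[length(values)], step)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, length(x$values)))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

grids_equal <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) <= tol)
}
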