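#' Excitation-emission matrix (EEM)
#'
#' One sample's fluorescence landscape: intensity over an emission x
#' excitation wavelength grid plus an explicit missing-cell mask. Matrices
#' are oriented `[emission rows x excitation columns]` throughout the
#' package, matching the usual heat-map display (excitation on the x-axis,
#' emission on the y-axis). Missing cells are tracked by the logical mask
#' and carry `NA` intensity, so a legitimate intensity of zero (e.g. after
#' sub-diagonal zeroing) is never conflated with "not measured".
#'
#' @param sample_id Sample identifier (scalar character).
#' @param ex_grid,em_grid Excitation / emission [wavelength_grid()]s.
#' @param intensity Numeric matrix `[em x ex]` of fluorescence counts
#'   (arbitrary units); `NA` entries are taken as missing.
#' @param missing Optional logical matrix of the same shape; defaults to
#'   `is.na(intensity)`. Cells flagged missing are forced to `NA`.
#' @return An object of class `eem`.
#' @export
eem <- function(sample_id, ex_grid, em_grid, intensity, missing = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            inherits(ex_grid, "wavelength_grid"),
            inherits(em_grid, "wavelength_grid"),
            is.matrix(intensity))
  J <- length(em_grid$values)
  K <- length(ex_grid$values)
  if (!all(dim(intensity) == c(J, K))) {
    stop(sprintf("intensity must be %d x %d (em x ex); got %d x %d",
                 J, K, nrow(intensity), ncol(intensity)), call. = FALSE)
  }
  storage.mode(intensity) <- "double"
  if (is.null(missing)) {
    missing <- is.na(intensity)
  } else {
    stopifnot(is.matrix(missing), all(dim(missing) == dim(intensity)))
    storage.mode(missing) <- "logical"
    missing <- missing | is.na(intensity)
  }
  intensity[missing] <- NA_real_
  if (any(!is.finite(intensity[!missing]))) {
    stop("non-missing intensities must be finite", call. = FALSE)
  }
  dimnames(intensity) <- dimnames(missing) <-
    list(em = format(em_grid$values), ex = format(ex_grid$values))
  structure(list(sample_id = sample_id, ex_grid = ex_grid, em_grid = em_grid,
                 intensity = intensity, missing = missing),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> sample '%s': %d em x %d ex, %d missing cell(s)\n",
              x$sample_id, nrow(x$intensity), ncol(x$intensity),
              sum(x$missing)))
  invisible(x)
}

#' Read an EEM from a CSV grid
#'
#' The dialect is a rectangular CSV: cell (1,1) blank or a label such as
#' `em\\ex`; the remainder of the first row holds the excitation
#' wavelengths (nm, ascending); the first column holds the emission
#' wavelengths (nm, ascending); the body holds intensities. Blank or
#' non-numeric body cells become missing.
#'
#' @param path Path to the CSV file.
#' @param sample_id Sample id; defaults to the file name without extension.
#' @return An [eem()].
#' @export
read_eem <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, blank.lines.skip = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 2) {
    stop("malformed EEM grid (need a header row, a header column and a body): ",
         path, call. = FALSE)
  }
  ex_vals <- suppressWarnings(as.numeric(raw[1, -1]))
  em_vals <- suppressWarnings(as.numeric(raw[-1, 1]))
  if (anyNA(ex_vals) || anyNA(em_vals)) {
    stop("malformed EEM header: wavelengths did not parse as numbers in ",
         path, call. = FALSE)
  }
  ex_grid <- tryCatch(wavelength_grid_from_values(ex_vals),
                      error = function(e) stop("excitation grid: ",
                                               conditionMessage(e), call. = FALSE))
  em_grid <- tryCatch(wavelength_grid_from_values(em_vals),
                      error = function(e) stop("emission grid: ",
                                               conditionMessage(e), call. = FALSE))
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  intensity <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  eem(sample_id, ex_grid, em_grid, intensity)
}

#' Write an EEM to a CSV grid
#'
#' Inverse of [read_eem()]: missing cells are written blank.
#'
#' @param x An [eem()] (or a coefficient map: any em x ex matrix object with
#'   the same fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  body <- format_num(x$intensity)
  body[x$missing] <- ""
  header <- c("em\\ex", format_num(x$ex_grid$values))
  rows <- cbind(format_num(x$em_grid$values), body)
  lines <- c(paste(header, collapse = ","),
             apply(rows, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(as.vector(x), function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  if (is.matrix(x)) out <- matrix(out, nrow = nrow(x))
  out
}
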