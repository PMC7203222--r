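#' Response table
#'
#' Per-sample measured outputs to be predicted from the fluorescence
#' landscape. The canonical culture-monitoring schema has columns
#' `cell_concentration` (cells/mL), `chlorophyll` (mg/cell) and
#' `fa_total`, `fa_saturated`, `fa_unsaturated` (% g/g dry weight), but any
#' numeric columns are accepted. Blank entries mean "not measured", so the
#' usable sample count may differ per variable. A per-column `log10_applied`
#' flag records whether values are on the log10 modelling scale.
#'
#' @param sample_id Character vector of unique ids.
#' @param ... Named numeric vectors (one per response variable), or a single
#'   data.frame of them.
#' @param log10_applied Named logical vector (default all `FALSE`).
#' @return An object of class `response_table` (a data.frame with attributes
#'   `log10_applied`).
#' @export
response_table <- function(sample_id, ..., log10_applied = NULL) {
  vars <- list(...)
  if (length(vars) == 1 && is.data.frame(vars[[1]]) && is.null(names(vars)[1])) {
    vars <- as.list(vars[[1]])
  }
  stopifnot(length(vars) >= 1, !is.null(names(vars)), all(nzchar(names(vars))))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v) || length(v) != length(sample_id)) {
      stop("column '", nm, "' must be numeric with one entry per sample",
           call. = FALSE)
    }
  }
  df <- data.frame(sample_id = sample_id, vars, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.null(log10_applied)) {
    log10_applied <- stats::setNames(rep(FALSE, length(vars)), names(vars))
  }
  stopifnot(is.logical(log10_applied),
            setequal(names(log10_applied), names(vars)))
  attr(df, "log10_applied") <- log10_applied[names(vars)]
  class(df) <- c("response_table", "data.frame")
  df
}

response_vars <- function(responses) {
  setdiff(names(responses), "sample_id")
}

#' @export
print.response_table <- function(x, ...) {
  vars <- response_vars(x)
  flags <- attr(x, "log10_applied")
  cat(sprintf("<response_table> %d sample(s), %d variable(s)\n",
              nrow(x), length(vars)))
  for (nm in vars) {
    cat(sprintf("  %s: n = %d%s\n", nm, sum(!is.na(x[[nm]])),
                if (isTRUE(flags[[nm]])) " (log10 scale)" else ""))
  }
  invisible(x)
}

#' Read a response CSV
#'
#' Header `sample_id,<var>,<var>,...`; blanks = not measured.
#'
#' @param path Path to CSV.
#' @return A [response_table()] (raw scale, no log10 applied).
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("response CSV must start with a 'sample_id' column: ", path,
         call. = FALSE)
  }
  do.call(response_table,
          c(list(sample_id = as.character(df$sample_id)),
            as.list(df[-1])))
}

#' Write a response table to CSV
#' @param x A [response_table()].
#' @param path Output path.
#' @export
write_response_table <- function(x, path) {
  stopifnot(inherits(x, "response_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Log10-transform response columns
#'
#' Responses spanning decades (cell counts, pigment content, lipid
#' fractions) are modelled on the log10 scale to normalise their
#' distributions; all model metrics are then reported on that scale.
#'
#' @param responses A [response_table()].
#' @param columns Character vector of columns to transform (default: all).
#' @return The table with transformed columns and `log10_applied` flags set.
#' @export
log10_transform <- function(responses, columns = response_vars(responses)) {
  stopifnot(inherits(responses, "response_table"),
            all(columns %in% response_vars(responses)))
  flags <- attr(responses, "log10_applied")
  for (nm in columns) {
    if (isTRUE(flags[[nm]])) {
      stop("column '", nm, "' is already on the log10 scale", call. = FALSE)
    }
    v <- responses[[nm]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop("log10 transform needs strictly positive values; column '", nm,
           "' is non-positive for sample(s) ",
           paste(responses$sample_id[bad], collapse = ", "), call. = FALSE)
    }
    responses[[nm]] <- log10(v)
    flags[[nm]] <- TRUE
  }
  attr(responses, "log10_applied") <- flags
  responses
}

#' Invert a log10 transform
#'
#' @inheritParams log10_transform
#' @return The table back on the raw scale for the selected columns.
#' @export
inverse_log10_transform <- function(responses, columns = response_vars(responses)) {
  stopifnot(inherits(responses, "response_table"),
            all(columns %in% response_vars(responses)))
  flags <- attr(responses, "log10_applied")
  for (nm in columns) {
    if (!isTRUE(flags[[nm]])) {
      stop("column '", nm, "' is not on the log10 scale", call. = FALSE)
    }
    responses[[nm]] <- 10^responses[[nm]]
    flags[[nm]] <- FALSE
  }
  attr(responses, "log10_applied") <- flags
  responses
}
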