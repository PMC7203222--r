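#' Chlorophyll-a from methanol-extract absorbances (modified Arnaud equation)
#'
#' Converts spectrophotometric readings of a methanol extract into a
#' chlorophyll-a concentration:
#' `Chla = (16.72 * A665 - 9.16 * A652) * dilution_factor` (mg/L).
#' The result is linear in all three inputs. A negative result is returned
#' as-is with a warning -- it indicates a failed extract, and clamping
#' would hide the assay failure.
#'
#' @param a665,a652 Absorbance at 665 / 652 nm (finite; vectors recycle as
#'   usual).
#' @param dilution_factor Dilution applied before reading (> 0, default 1).
#' @return Chlorophyll-a concentration(s) in mg/L.
#' @examples
#' arnaud_chlorophyll(1.0, 0.0, 1)   # 16.72
#' arnaud_chlorophyll(0.8, 0.3, 2)   # 21.256
#' @export
arnaud_chlorophyll <- function(a665, a652, dilution_factor = 1) {
  stopifnot(is.numeric(a665), is.numeric(a652), is.numeric(dilution_factor))
  if (any(!is.finite(a665)) || any(!is.finite(a652)) ||
      any(!is.finite(dilution_factor))) {
    stop("absorbances and dilution factor must be finite", call. = FALSE)
  }
  if (any(dilution_factor <= 0)) {
    stop("dilution_factor must be positive", call. = FALSE)
  }
  out <- (16.72 * a665 - 9.16 * a652) * dilution_factor
  if (any(out < 0)) {
    warning(sum(out < 0), " negative chlorophyll value(s): check the extract",
            call. = FALSE)
  }
  out
}

#' Batch chlorophyll calculation over a CSV
#'
#' Reads a CSV with columns `sample_id,a665,a652,dilution` and writes it
#' back with an added `chlorophyll_mg_l` column.
#'
#' @param in_path Input CSV path.
#' @param out_path Output CSV path.
#' @return The output data.frame, invisibly.
#' @export
batch_chlorophyll <- function(in_path, out_path) {
  df <- utils::read.csv(in_path, check.names = FALSE)
  need <- c("sample_id", "a665", "a652", "dilution")
  if (!all(need %in% names(df))) {
    stop("chlorophyll CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$chlorophyll_mg_l <- arnaud_chlorophyll(df$a665, df$a652, df$dilution)
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
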