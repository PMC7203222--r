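#' Pre-processing configuration
#'
#' Settings for the EEM cleaning chain applied before multiway modelling.
#' Water-dominated culture samples carry intense elastic (Rayleigh) scatter
#' ridges along `em = ex` (first order) and `em = 2 ex` (second order) that
#' say nothing about the fluorophores; the first-order ridge is excised to
#' missing, the second-order ridge is bridged by interpolation, and the
#' physically empty region `em < ex` is zeroed. Re-absorption at high
#' optical density (the inner filter effect, IFE) is undone multiplicatively
#' from the sample's absorbance spectrum.
#'
#' Scatter band halfwidths are instrument- and slit-dependent; +/-15 nm is a
#' common choice for a 5 nm grid and is the default for both orders.
#'
#' @param first_order_halfwidth Halfwidth (nm) of the `|em - ex|` excision
#'   band. Default 15.
#' @param second_order_halfwidth Halfwidth (nm) of the `|em - 2 ex|`
#'   interpolation band. Default 15.
#' @param apply_ife Apply the inner-filter correction (default `TRUE`).
#' @param ife_absorbance_threshold Skip the IFE correction for a sample
#'   whose maximum absorbance does not exceed this value (default 0:
#'   correct whenever any absorbance is present).
#' @param order `"ife_first"` (default) corrects IFE on the raw intensities
#'   before any scatter handling, so second-order interpolation bridges
#'   already-corrected values; `"scatter_first"` applies the scatter chain
#'   first.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(first_order_halfwidth = 15,
                              second_order_halfwidth = 15,
                              apply_ife = TRUE,
                              ife_absorbance_threshold = 0,
                              order = c("ife_first", "scatter_first")) {
  stopifnot(is.numeric(first_order_halfwidth), first_order_halfwidth >= 0,
            is.numeric(second_order_halfwidth), second_order_halfwidth >= 0,
            is.logical(apply_ife),
            is.numeric(ife_absorbance_threshold), ife_absorbance_threshold >= 0)
  structure(list(first_order_halfwidth = first_order_halfwidth,
                 second_order_halfwidth = second_order_halfwidth,
                 apply_ife = apply_ife,
                 ife_absorbance_threshold = ife_absorbance_threshold,
                 order = match.arg(order)),
            class = "preprocess_config")
}

ife_factor_matrix <- function(eem_obj, spec, sign = +1) {
  a_em <- interpolate_absorbance(spec, eem_obj$em_grid$values)
  a_ex <- interpolate_absorbance(spec, eem_obj$ex_grid$values)
  10^(sign * outer(a_em, a_ex, `+`) / 2)
}

#' Inner-filter-effect correction
#'
#' Multiplies every non-missing cell by `10^((A(ex) + A(em)) / 2)`, the
#' standard absorbance-based correction for primary (excitation) and
#' secondary (emission) re-absorption, with A the sample's absorbance at
#' the cell's wavelengths (linearly interpolated). Missing cells are left
#' untouched. If `max(A) <= ife_absorbance_threshold` the EEM is returned
#' unchanged (correction not needed for a sufficiently transparent sample).
#'
#' @param x An [eem()].
#' @param spec The sample's [absorbance_spectrum()].
#' @param config A [preprocess_config()].
#' @return The corrected [eem()].
#' @export
correct_inner_filter <- function(x, spec, config = preprocess_config()) {
  stopifnot(inherits(x, "eem"), inherits(config, "preprocess_config"))
  if (!config$apply_ife) return(x)
  if (is.null(spec)) {
    stop("inner-filter correction requires an absorbance spectrum for sample '",
         x$sample_id, "'", call. = FALSE)
  }
  stopifnot(inherits(spec, "absorbance_spectrum"))
  if (max(spec$absorbance) <= config$ife_absorbance_threshold) return(x)
  fac <- ife_factor_matrix(x, spec, sign = +1)
  x$intensity <- ifelse(x$missing, NA_real_, x$intensity * fac)
  x
}

rayleigh_band <- function(eem_obj, order, halfwidth) {
  # TRUE over cells within `halfwidth` nm of the order-n Rayleigh line
  # em = n * ex; membership decided per cell so non-multiple halfwidths work.
  em <- eem_obj$em_grid$values
  ex <- eem_obj$ex_grid$values
  abs(outer(em, order * ex, `-`)) <= halfwidth + 1e-9
}

#' Excise the first-order Rayleigh ridge
#'
#' Cells with `|em - ex| <= halfwidth` are removed and replaced by empty
#' values (missing); everything else is untouched. Idempotent.
#'
#' @param x An [eem()].
#' @param halfwidth Band halfwidth in nm.
#' @return The [eem()] with the band marked missing.
#' @export
excise_first_order_rayleigh <- function(x, halfwidth = 15) {
  stopifnot(inherits(x, "eem"), is.numeric(halfwidth), halfwidth >= 0)
  band <- rayleigh_band(x, 1, halfwidth)
  x$missing <- x$missing | band
  x$intensity[band] <- NA_real_
  attr(x, "n_excised") <- sum(band)
  x
}

#' Interpolate across the second-order Rayleigh ridge
#'
#' Cells with `|em - 2 ex| <= halfwidth` are replaced, per excitation
#' column, by a 1-D linear interpolation along the emission axis between the
#' nearest non-missing neighbours outside the band. Where a boundary
#' neighbour is unavailable (the band touches the grid edge) the affected
#' cells become missing instead. Columns whose band lies entirely off the
#' emission range are unchanged.
#'
#' @inheritParams excise_first_order_rayleigh
#' @return The [eem()] with the band bridged.
#' @export
interpolate_second_order_rayleigh <- function(x, halfwidth = 15) {
  stopifnot(inherits(x, "eem"), is.numeric(halfwidth), halfwidth >= 0)
  em <- x$em_grid$values
  n_interp <- 0L
  for (k in seq_along(x$ex_grid$values)) {
    in_band <- abs(em - 2 * x$ex_grid$values[k]) <= halfwidth + 1e-9
    if (!any(in_band)) next
    rows <- which(in_band)
    below <- which(!in_band & seq_along(em) < min(rows) & !x$missing[, k])
    above <- which(!in_band & seq_along(em) > max(rows) & !x$missing[, k])
    if (length(below) && length(above)) {
      lo <- max(below)
      hi <- min(above)
      w <- (em[rows] - em[lo]) / (em[hi] - em[lo])
      x$intensity[rows, k] <- (1 - w) * x$intensity[lo, k] +
        w * x$intensity[hi, k]
      x$missing[rows, k] <- FALSE
      n_interp <- n_interp + length(rows)
    } else {
      x$intensity[rows, k] <- NA_real_
      x$missing[rows, k] <- TRUE
    }
  }
  attr(x, "n_interpolated") <- n_interp
  x
}

#' Zero the sub-diagonal (em < ex) region
#'
#' Emission strictly shorter than the excitation wavelength cannot be
#' fluorescence; those cells are set to intensity 0 and marked non-missing
#' (zero is a legitimate modelled value there). The diagonal `em = ex`
#' itself is not touched -- it belongs to the first-order scatter band.
#' Where the first-order missing band dips below the diagonal, zeroing
#' wins, so the final spectra show a clean zeroed lower triangle.
#' Idempotent.
#'
#' @param x An [eem()].
#' @return The [eem()] with the lower triangle zeroed.
#' @export
zero_below_diagonal <- function(x) {
  stopifnot(inherits(x, "eem"))
  sub <- outer(x$em_grid$values, x$ex_grid$values, `<`)
  x$intensity[sub] <- 0
  x$missing[sub] <- FALSE
  attr(x, "n_zeroed") <- sum(sub)
  x
}

#' Pre-process one sample
#'
#' Applies the full cleaning chain. With the default `order = "ife_first"`
#' the stages are: inner-filter correction, first-order Rayleigh excision,
#' second-order Rayleigh interpolation, sub-diagonal zeroing. IFE is placed
#' first because the correction is multiplicative on raw measured
#' intensities and interpolation should bridge corrected values.
#'
#' @param x An [eem()].
#' @param spec The sample's [absorbance_spectrum()] (may be `NULL` when
#'   `config$apply_ife` is `FALSE`).
#' @param config A [preprocess_config()].
#' @return The cleaned [eem()], with a `preprocess_log` attribute giving
#'   per-stage cell counts (`n_excised`, `n_interpolated`, `n_zeroed`).
#' @export
preprocess_sample <- function(x, spec = NULL, config = preprocess_config()) {
  stopifnot(inherits(x, "eem"), inherits(config, "preprocess_config"))
  scatter <- function(e) {
    e <- excise_first_order_rayleigh(e, config$first_order_halfwidth)
    n_exc <- attr(e, "n_excised")
    e <- interpolate_second_order_rayleigh(e, config$second_order_halfwidth)
    n_int <- attr(e, "n_interpolated")
    e <- zero_below_diagonal(e)
    n_zero <- attr(e, "n_zeroed")
    attr(e, "preprocess_log") <- list(n_excised = n_exc,
                                      n_interpolated = n_int,
                                      n_zeroed = n_zero)
    e
  }
  if (config$order == "ife_first") {
    x <- correct_inner_filter(x, spec, config)
    x <- scatter(x)
  } else {
    x <- scatter(x)
    log <- attr(x, "preprocess_log")
    x <- correct_inner_filter(x, spec, config)
    attr(x, "preprocess_log") <- log
  }
  x
}

#' Pre-process and assemble a whole dataset
#'
#' Runs [preprocess_sample()] on every sample and stacks the results with
#' [assemble_dataset()], so all samples are cleaned together on identical
#' grids. A failure in any sample aborts with that sample's id in the
#' message.
#'
#' @param eems List of [eem()] objects, or an [eem_manifest()] / manifest
#'   path (in which case EEMs and absorbance spectra are loaded from disk).
#' @param specs List of [absorbance_spectrum()] or `NULL` per sample
#'   (ignored when `eems` is a manifest).
#' @param config A [preprocess_config()].
#' @param verbose Log per-stage cell counts with `message()`.
#' @return An `eem_dataset` of cleaned samples.
#' @export
preprocess_dataset <- function(eems, specs = NULL,
                               config = preprocess_config(),
                               verbose = FALSE) {
  if (inherits(eems, "eem_manifest") || is.character(eems)) {
    loaded <- load_manifest(eems)
    eems <- loaded$eems
    specs <- loaded$specs
  }
  stopifnot(is.list(eems), length(eems) >= 1)
  if (is.null(specs)) specs <- vector("list", length(eems))
  stopifnot(length(specs) == length(eems))
  cleaned <- vector("list", length(eems))
  for (i in seq_along(eems)) {
    cleaned[[i]] <- tryCatch(
      preprocess_sample(eems[[i]], specs[[i]], config),
      error = function(e) {
        stop("pre-processing failed for sample '", eems[[i]]$sample_id,
             "': ", conditionMessage(e), call. = FALSE)
      })
    if (verbose) {
      log <- attr(cleaned[[i]], "preprocess_log")
      message(sprintf("sample '%s': excised %d, interpolated %d, zeroed %d cells",
                      eems[[i]]$sample_id, log$n_excised, log$n_interpolated,
                      log$n_zeroed))
    }
  }
  assemble_dataset(cleaned)
}
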