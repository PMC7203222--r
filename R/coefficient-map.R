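#' Fold an N-PLS model into a regression-coefficient map
#'
#' The fitted model is linear in the (centered) intensities, so it can be
#' folded into a single coefficient per excitation-emission cell plus an
#' intercept -- the map that shows which spectral regions drive the
#' prediction (e.g. the pigment band above 600 nm emission, or the
#' protein-like region below 400 nm). The map is derived analytically by
#' propagating each LV's rank-1 weight through the deflation recursion:
#' with `r_f = vec(wJ_f o wK_f)` restricted to included cells, the score
#' functional of LV `f` is
#' `v_f = (I - r_1 r_1') ... (I - r_{f-1} r_{f-1}') r_f`
#' and the map is `sum_f b_f v_f`. For a 1-LV model this reduces to the
#' outer product `b_1 (wJ o wK)`.
#'
#' @param model An `npls_model`.
#' @param n_lvs Model size to fold (default: the fitted size).
#' @return An object of class `coefficient_map`: `values` (`[em x ex]`,
#'   response units per intensity unit, `NA` over excluded cells),
#'   `intercept` (so that `intercept + sum(values * raw_intensity)` over
#'   included cells equals the model prediction), `y_center`, the grids and
#'   the response label.
#' @export
coefficient_map <- function(model, n_lvs = model$n_lvs) {
  stopifnot(inherits(model, "npls_model"), n_lvs >= 1, n_lvs <= model$n_lvs)
  idx <- which(model$included_mask)
  r_list <- lapply(seq_len(n_lvs), function(f) {
    (model$em_weights[, f] %o% model$ex_weights[, f])[idx]
  })
  b <- model$coef_history[[n_lvs]]
  beta <- numeric(length(idx))
  for (f in seq_len(n_lvs)) {
    u <- r_list[[f]]
    for (g in rev(seq_len(f - 1))) {
      u <- u - r_list[[g]] * sum(r_list[[g]] * u)
    }
    beta <- beta + b[f] * u
  }
  values <- matrix(NA_real_, nrow(model$included_mask),
                   ncol(model$included_mask))
  values[idx] <- beta
  intercept <- model$y_center - sum(beta * model$x_center[idx])
  structure(list(values = values, intercept = intercept,
                 y_center = model$y_center,
                 included_mask = model$included_mask,
                 ex_grid = model$ex_grid, em_grid = model$em_grid,
                 response_name = model$response_name),
            class = "coefficient_map")
}

#' @export
print.coefficient_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<coefficient_map> '%s': %d x %d, coefficients in [%.4g, %.4g]\n",
              x$response_name, nrow(x$values), ncol(x$values), rng[1], rng[2]))
  invisible(x)
}

#' Predict from a coefficient map
#'
#' Applies the folded linear model directly:
#' `intercept + sum(values * intensity)` over included cells. Must agree
#' with [predict.npls_model()] at the size the map was folded from.
#'
#' @param map A [coefficient_map()].
#' @param dataset An `eem_dataset` on the map's grids.
#' @return Numeric vector of predictions.
#' @export
predict_map <- function(map, dataset) {
  stopifnot(inherits(map, "coefficient_map"), inherits(dataset, "eem_dataset"))
  if (!grids_equal(dataset$ex_grid, map$ex_grid) ||
      !grids_equal(dataset$em_grid, map$em_grid)) {
    stop("dataset is on a different wavelength grid than the map", call. = FALSE)
  }
  idx <- which(map$included_mask)
  Xu <- matrix(dataset$tensor, nrow = length(dataset$samples))[, idx, drop = FALSE]
  # a missing included cell propagates NA into that sample's prediction
  map$intercept + drop(Xu %*% map$values[idx])
}

#' Export a coefficient map as an EEM CSV grid
#'
#' The map is written in the same grid dialect as an EEM (excluded cells
#' blank), so it round-trips through [read_eem()] and can be drawn with any
#' heat-map tool.
#'
#' @param map A [coefficient_map()].
#' @param path Output path.
#' @export
write_coefficient_map <- function(map, path) {
  stopifnot(inherits(map, "coefficient_map"))
  as_eem <- eem(map$response_name, map$ex_grid, map$em_grid, map$values)
  write_eem(as_eem, path)
}
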