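#' Fit a tri-linear N-PLS (tri-PLS1) regression
#'
#' Multiway partial least squares for a single response on a three-way
#' `[sample x emission x excitation]` array. Each latent variable (LV) is a
#' rank-1 excitation x emission weight pair whose sample scores best
#' covary with the response, respecting the tri-linear structure of EEM
#' data instead of unfolding it.
#'
#' The algorithm is the classical tri-PLS1 with deflation: the tensor is
#' centered over samples (cell-wise) and the response mean-centered; for
#' each LV `f` the covariance matrix `Z[j,k] = sum_i y_i X[i,j,k]` (current
#' residuals, included cells only) is formed and its dominant singular pair
#' taken as the emission/excitation weights `(wJ_f, wK_f)`; scores are
#' `t_i = sum_jk X[i,j,k] wJ_j wK_k`; the inner coefficients `b` are
#' re-estimated at every `f` by ordinary least squares of the centered
#' response on all scores so far; X is deflated by `t (wJ o wK)` and y by
#' `T b`. Weights have unit Euclidean norm; the sign indeterminacy of the
#' SVD is resolved by making the largest-magnitude element of each
#' emission weight positive (flipping the paired excitation weight with
#' it), so repeated fits are bit-identical.
#'
#' Cells flagged in the dataset's global missing mask -- plus any cell that
#' is `NA` in at least one training sample -- are excluded from centering
#' and from every inner product. No scaling is applied to the spectral
#' cells (standard practice for spectral data).
#'
#' @param dataset An `eem_dataset` (see [assemble_dataset()]).
#' @param y Numeric response vector, one finite value per sample, on the
#'   modelling (possibly log10) scale.
#' @param n_lvs Number of latent variables F (`1 <= F <= samples - 1`). If
#'   a score collapses numerically before F LVs are extracted the model is
#'   truncated at the last usable LV with a warning.
#' @param response_name Label stored with the model.
#' @param log10_applied Whether `y` is on the log10 scale (metadata only).
#' @return An object of class `npls_model` with fields `n_lvs`,
#'   `em_weights` (J x F), `ex_weights` (K x F), `scores` (I x F),
#'   `inner_coefficients` (b at F), `coef_history` (b re-estimated at each
#'   F' <= F, enabling sequential prediction at any model size),
#'   `x_center` (`[em x ex]`, `NA` over excluded cells), `y_center`,
#'   `included_mask`, `fitted`, the grids and labels.
#' @export
fit_npls <- function(dataset, y, n_lvs, response_name = "response",
                     log10_applied = FALSE) {
  stopifnot(inherits(dataset, "eem_dataset"), is.numeric(y))
  n <- length(dataset$samples)
  if (length(y) != n) {
    stop("`y` must have one value per sample (", n, "); got ", length(y),
         call. = FALSE)
  }
  if (any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  if (stats::sd(y) == 0) stop("`y` is constant; nothing to regress", call. = FALSE)
  stopifnot(is.numeric(n_lvs), length(n_lvs) == 1, n_lvs >= 1)
  n_lvs <- as.integer(n_lvs)
  if (n_lvs > n - 1) {
    stop("n_lvs must be at most samples - 1 (", n - 1, ")", call. = FALSE)
  }

  J <- dim(dataset$tensor)[2]
  K <- dim(dataset$tensor)[3]
  sample_na <- apply(dataset$tensor, c(2, 3), function(v) any(is.na(v)))
  included <- !(dataset$global_missing | sample_na)
  if (!any(included)) stop("no included cells left to model", call. = FALSE)
  idx <- which(included)                       # column-major over [em x ex]

  Xu <- matrix(dataset$tensor, nrow = n)[, idx, drop = FALSE]  # I x P
  x_mean <- colMeans(Xu)
  Xu <- sweep(Xu, 2, x_mean)
  y_center <- mean(y)
  y0 <- y - y_center

  em_w <- matrix(0, J, 0)
  ex_w <- matrix(0, K, 0)
  Tm <- matrix(0, n, 0)
  r_list <- list()
  coef_history <- list()
  y_res <- y0
  Z <- matrix(0, J, K)
  t_scale <- NULL

  f <- 0L
  while (f < n_lvs) {
    Z[] <- 0
    Z[idx] <- crossprod(Xu, y_res)
    sv <- svd(Z, nu = 1, nv = 1)
    wJ <- sv$u[, 1]
    wK <- sv$v[, 1]
    if (wJ[which.max(abs(wJ))] < 0) {  # deterministic sign: dominant em weight positive
      wJ <- -wJ
      wK <- -wK
    }
    r <- (wJ %o% wK)[idx]
    t_f <- drop(Xu %*% r)
    t_norm <- sqrt(sum(t_f^2))
    if (is.null(t_scale)) t_scale <- t_norm
    if (!is.finite(t_norm) || t_norm <= 1e-12 * max(t_scale, 1)) {
      warning("score norm collapsed at LV ", f + 1,
              "; model truncated at ", f, " LV(s)", call. = FALSE)
      break
    }
    f <- f + 1L
    em_w <- cbind(em_w, wJ)
    ex_w <- cbind(ex_w, wK)
    Tm <- cbind(Tm, t_f)
    r_list[[f]] <- r
    b <- qr.coef(qr(Tm), y0)
    b[is.na(b)] <- 0
    coef_history[[f]] <- b
    y_res <- y0 - drop(Tm %*% b)
    Xu <- Xu - t_f %*% t(r)
  }
  if (f == 0L) stop("could not extract any latent variable", call. = FALSE)

  b_final <- coef_history[[f]]
  fitted <- y_center + drop(Tm %*% b_final)
  x_center <- matrix(NA_real_, J, K)
  x_center[idx] <- x_mean

  colnames(em_w) <- colnames(ex_w) <- colnames(Tm) <- paste0("LV", seq_len(f))
  structure(list(n_lvs = f,
                 em_weights = em_w, ex_weights = ex_w,
                 scores = Tm,
                 inner_coefficients = b_final,
                 coef_history = coef_history,
                 x_center = x_center, y_center = y_center,
                 included_mask = included,
                 fitted = fitted,
                 ex_grid = dataset$ex_grid, em_grid = dataset$em_grid,
                 samples = dataset$samples,
                 response_name = response_name,
                 log10_applied = log10_applied),
            class = "npls_model")
}

#' @export
print.npls_model <- function(x, ...) {
  cat(sprintf("<npls_model> '%s'%s: %d LV(s), %d training sample(s), %d modelled cell(s)\n",
              x$response_name, if (x$log10_applied) " (log10 scale)" else "",
              x$n_lvs, nrow(x$scores), sum(x$included_mask)))
  invisible(x)
}

#' Predict responses for new EEM samples
#'
#' Computes scores sequentially with the stored weights and deflation
#' structure, then applies the inner regression coefficients. Predicting on
#' the training dataset reproduces the fitted values exactly. Cells that
#' are missing in the new data but included in the model are treated as
#' equal to the training mean (zero after centering), with a warning.
#'
#' @param object An `npls_model`.
#' @param newdata An `eem_dataset` on the model's grids.
#' @param n_lvs Model size to predict with (default: the fitted size; any
#'   smaller value uses the inner coefficients re-estimated at that size).
#' @param ... Unused.
#' @return Numeric vector of predictions on the modelling scale.
#' @export
predict.npls_model <- function(object, newdata, n_lvs = object$n_lvs, ...) {
  stopifnot(inherits(newdata, "eem_dataset"))
  if (!grids_equal(newdata$ex_grid, object$ex_grid) ||
      !grids_equal(newdata$em_grid, object$em_grid)) {
    stop("new data is on a different wavelength grid than the model",
         call. = FALSE)
  }
  stopifnot(n_lvs >= 1, n_lvs <= object$n_lvs)
  idx <- which(object$included_mask)
  n <- length(newdata$samples)
  Xu <- matrix(newdata$tensor, nrow = n)[, idx, drop = FALSE]
  n_na <- sum(is.na(Xu))
  Xu <- sweep(Xu, 2, object$x_center[idx])
  if (n_na > 0) {
    warning(n_na, " cell(s) missing in new data but included in the model; ",
            "treated as the training mean", call. = FALSE)
    Xu[is.na(Xu)] <- 0
  }
  Tm <- matrix(0, n, n_lvs)
  for (f in seq_len(n_lvs)) {
    r <- (object$em_weights[, f] %o% object$ex_weights[, f])[idx]
    t_f <- drop(Xu %*% r)
    Tm[, f] <- t_f
    Xu <- Xu - t_f %*% t(r)
  }
  object$y_center + drop(Tm %*% object$coef_history[[n_lvs]])
}

#' Serialize / restore an N-PLS model
#'
#' The model is written as a single JSON document (arrays at full double
#' precision) so cross-validation results can be reproduced and audited.
#'
#' @param model An `npls_model`.
#' @param path Output path.
#' @export
write_npls_model <- function(model, path) {
  stopifnot(inherits(model, "npls_model"))
  payload <- list(
    n_lvs = model$n_lvs,
    em_weights = model$em_weights, ex_weights = model$ex_weights,
    scores = model$scores,
    inner_coefficients = model$inner_coefficients,
    coef_history = model$coef_history,
    x_center = model$x_center, y_center = model$y_center,
    included_mask = model$included_mask,
    fitted = model$fitted,
    ex_grid = model$ex_grid[c("start", "stop", "step")],
    em_grid = model$em_grid[c("start", "stop", "step")],
    samples = model$samples,
    response_name = model$response_name,
    log10_applied = model$log10_applied)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_npls_model
#' @param path Path to a JSON file written by `write_npls_model()`.
#' @export
read_npls_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  as_mat <- function(m, mode = "double") {
    m <- as.matrix(m)
    storage.mode(m) <- mode
    dimnames(m) <- NULL
    m
  }
  grid <- function(g) wavelength_grid(g$start, g$stop, g$step)
  structure(list(n_lvs = as.integer(p$n_lvs),
                 em_weights = as_mat(p$em_weights),
                 ex_weights = as_mat(p$ex_weights),
                 scores = as_mat(p$scores),
                 inner_coefficients = as.numeric(p$inner_coefficients),
                 coef_history = lapply(p$coef_history, as.numeric),
                 x_center = as_mat(p$x_center),
                 y_center = as.numeric(p$y_center),
                 included_mask = as_mat(p$included_mask, "logical"),
                 fitted = as.numeric(p$fitted),
                 ex_grid = grid(p$ex_grid), em_grid = grid(p$em_grid),
                 samples = as.character(p$samples),
                 response_name = p$response_name,
                 log10_applied = isTRUE(p$log10_applied)),
            class = "npls_model")
}
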