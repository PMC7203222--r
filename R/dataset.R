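#' Stack EEMs into a three-way dataset
#'
#' Combines per-sample EEMs measured on identical grids into one
#' `[sample x emission x excitation]` array, the input form taken by
#' [fit_npls()]. The global missing mask is the union of the per-sample
#' masks; after scatter pre-processing the excised first-order band is
#' identical across samples, so the union coincides with each sample's band
#' there.
#'
#' @param eems Non-empty list of [eem()] objects on identical grids.
#' @return An object of class `eem_dataset`: `samples` (ids), `ex_grid`,
#'   `em_grid`, `tensor` (3-way array), `global_missing` (`[em x ex]`).
#' @export
assemble_dataset <- function(eems) {
  if (!is.list(eems) || length(eems) == 0) {
    stop("`eems` must be a non-empty list of eem objects", call. = FALSE)
  }
  for (e in eems) stopifnot(inherits(e, "eem"))
  ref <- eems[[1]]
  for (e in eems[-1]) {
    if (!grids_equal(e$ex_grid, ref$ex_grid) ||
        !grids_equal(e$em_grid, ref$em_grid)) {
      stop("sample '", e$sample_id, "' is on a different wavelength grid ",
           "than sample '", ref$sample_id, "'", call. = FALSE)
    }
  }
  samples <- vapply(eems, function(e) e$sample_id, character(1))
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  J <- length(ref$em_grid$values)
  K <- length(ref$ex_grid$values)
  tensor <- array(NA_real_, dim = c(length(eems), J, K),
                  dimnames = list(sample = samples,
                                  em = format(ref$em_grid$values),
                                  ex = format(ref$ex_grid$values)))
  global_missing <- matrix(FALSE, J, K)
  for (i in seq_along(eems)) {
    tensor[i, , ] <- eems[[i]]$intensity
    global_missing <- global_missing | eems[[i]]$missing
  }
  structure(list(samples = samples, ex_grid = ref$ex_grid,
                 em_grid = ref$em_grid, tensor = tensor,
                 global_missing = global_missing),
            class = "eem_dataset")
}

#' @export
print.eem_dataset <- function(x, ...) {
  cat(sprintf("<eem_dataset> %d sample(s), %d em x %d ex, %d globally missing cell(s)\n",
              length(x$samples), dim(x$tensor)[2], dim(x$tensor)[3],
              sum(x$global_missing)))
  invisible(x)
}

#' Extract one sample of a dataset as an EEM
#'
#' @param dataset An `eem_dataset`.
#' @param i Sample index or id.
#' @return The [eem()] for that sample (per-sample mask recovered from `NA`
#'   cells of its tensor slice).
#' @export
eem_slice <- function(dataset, i) {
  stopifnot(inherits(dataset, "eem_dataset"))
  if (is.character(i)) i <- match(i, dataset$samples)
  stopifnot(length(i) == 1, !is.na(i), i >= 1, i <= length(dataset$samples))
  eem(dataset$samples[i], dataset$ex_grid, dataset$em_grid,
      dataset$tensor[i, , ])
}

#' Subset a dataset by sample
#'
#' Keeps the parent `global_missing` mask so that models fitted on a subset
#' (e.g. a cross-validation fold) stay aligned with the full dataset's
#' modelled-cell set.
#'
#' @param dataset An `eem_dataset`.
#' @param idx Integer or logical sample index vector.
#' @return An `eem_dataset` over the selected samples.
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "eem_dataset"))
  if (is.logical(idx)) idx <- which(idx)
  stopifnot(length(idx) >= 1, all(idx >= 1), all(idx <= length(dataset$samples)))
  out <- dataset
  out$samples <- dataset$samples[idx]
  out$tensor <- dataset$tensor[idx, , , drop = FALSE]
  out
}
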