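#' Dataset manifest
#'
#' A manifest ties sample ids to their on-disk EEM and (optional) absorbance
#' files, plus culture metadata (temperature, nitrogen supply, light cycle).
#' Serialized as a JSON array of records.
#'
#' @param sample_id Character vector of unique ids.
#' @param eem_path Character vector of EEM CSV paths.
#' @param absorbance_path Optional character vector of absorbance CSV paths
#'   (`NA` where absent).
#' @param metadata Optional data.frame of per-sample metadata.
#' @return An object of class `eem_manifest` (a data.frame).
#' @export
eem_manifest <- function(sample_id, eem_path, absorbance_path = NULL,
                         metadata = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  stopifnot(length(eem_path) == length(sample_id))
  if (is.null(absorbance_path)) absorbance_path <- rep(NA_character_, length(sample_id))
  stopifnot(length(absorbance_path) == length(sample_id))
  df <- data.frame(sample_id = sample_id,
                   eem_path = as.character(eem_path),
                   absorbance_path = as.character(absorbance_path),
                   stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    stopifnot(is.data.frame(metadata), nrow(metadata) == length(sample_id))
    df <- cbind(df, metadata)
  }
  class(df) <- c("eem_manifest", "data.frame")
  df
}

#' Read a JSON manifest
#'
#' @param path Path to the JSON file; relative `eem_path` / `absorbance_path`
#'   entries are resolved against the manifest's directory.
#' @param check_files Verify that referenced files exist (default `TRUE`).
#' @return An [eem_manifest()].
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(recs) || !all(c("sample_id", "eem_path") %in% names(recs))) {
    stop("manifest must be a JSON array of {sample_id, eem_path, ...} records: ",
         path, call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                                ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                       file.path(base, p)))
  recs$eem_path <- resolve(recs$eem_path)
  if (!"absorbance_path" %in% names(recs)) recs$absorbance_path <- NA_character_
  recs$absorbance_path <- resolve(recs$absorbance_path)
  meta_cols <- setdiff(names(recs), c("sample_id", "eem_path", "absorbance_path"))
  m <- eem_manifest(recs$sample_id, recs$eem_path, recs$absorbance_path,
                    if (length(meta_cols)) recs[meta_cols] else NULL)
  if (check_files) {
    for (i in seq_len(nrow(m))) {
      if (!file.exists(m$eem_path[i])) {
        stop("manifest references a missing EEM file for sample '",
             m$sample_id[i], "': ", m$eem_path[i], call. = FALSE)
      }
      ap <- m$absorbance_path[i]
      if (!is.na(ap) && !file.exists(ap)) {
        stop("manifest references a missing absorbance file for sample '",
             m$sample_id[i], "': ", ap, call. = FALSE)
      }
    }
  }
  m
}

#' Write a manifest to JSON
#' @param x An [eem_manifest()].
#' @param path Output path.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "eem_manifest"))
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Load the EEMs and absorbance spectra a manifest points to
#'
#' @param manifest An [eem_manifest()] or the path to one.
#' @return A list with `eems` (list of [eem()]) and `specs` (list of
#'   [absorbance_spectrum()] or `NULL` per sample).
#' @export
load_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "eem_manifest"))
  eems <- vector("list", nrow(manifest))
  specs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    eems[[i]] <- read_eem(manifest$eem_path[i], manifest$sample_id[i])
    ap <- manifest$absorbance_path[i]
    if (!is.na(ap)) {
      specs[[i]] <- read_absorbance(ap, manifest$sample_id[i])
    }
  }
  list(eems = eems, specs = specs)
}
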