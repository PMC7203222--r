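#' Read a pipeline configuration
#'
#' A single YAML (or JSON) file drives the end-to-end workflow. Recognised
#' top-level fields: `paths` (`manifest`, `responses`, `output_dir`),
#' `preprocess` (arguments of [preprocess_config()]), `cv`
#' (`n_folds`, `seed`, `max_lvs`), `responses` (`columns` to model,
#' `log10_columns`), `simulate` (arguments of [simulation_config()] other
#' than grids/fluorophores). A seed is mandatory: all randomness in a run
#' flows from it.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return The validated configuration list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$cv)) config$cv <- list()
  if (is.null(config$cv$n_folds)) config$cv$n_folds <- 4
  if (is.null(config$cv$max_lvs)) config$cv$max_lvs <- 12
  if (is.null(config$cv$seed)) {
    stop("config must set cv.seed (all randomness flows from it)", call. = FALSE)
  }
  config$preprocess <- do.call(preprocess_config,
                               if (is.null(config$preprocess)) list()
                               else config$preprocess)
  structure(config, class = c("pipeline_config", "list"))
}

#' Simulate a dataset bundle from a config
#'
#' Wraps [simulate_eem_dataset()] + [write_simulation_bundle()]: reads the
#' `simulate` section of the config (the seed defaults to `cv.seed`) and
#' writes the CSV bundle under `paths.output_dir`. Rerunning the same
#' config reproduces the bundle byte-for-byte.
#'
#' @param config Path or list, see [read_pipeline_config()].
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_pipeline_config(config)
  out_dir <- config$paths$output_dir
  if (is.null(out_dir)) stop("config must set paths.output_dir", call. = FALSE)
  args <- if (is.null(config$simulate)) list() else config$simulate
  if (is.null(args$seed)) args$seed <- config$cv$seed
  sim <- simulate_eem_dataset(do.call(simulation_config, args))
  write_simulation_bundle(sim, out_dir)
}

#' Run the double-cross-validated modelling pipeline
#'
#' Loads the manifest, pre-processes all samples together, log10-transforms
#' the configured response columns and runs [run_double_cv()] once per
#' response. A sample lacking a response is excluded from that response's
#' model only, so the modelled `n` can differ per variable. Per-response
#' failures are isolated: the error is recorded and the remaining responses
#' still run. Reports (JSON + out-of-fold CSV) are written under
#' `paths.output_dir`.
#'
#' @param config Path or list, see [read_pipeline_config()].
#' @return Named list of `double_cv_report`s (or `try-error` records),
#'   invisibly; also written to disk.
#' @export
run_cv <- function(config) {
  config <- read_pipeline_config(config)
  stopifnot(!is.null(config$paths$manifest), !is.null(config$paths$responses))
  out_dir <- config$paths$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dataset <- preprocess_dataset(config$paths$manifest,
                                config = config$preprocess)
  responses <- read_response_table(config$paths$responses)
  columns <- config$responses$columns
  if (is.null(columns)) columns <- response_vars(responses)
  log_cols <- config$responses$log10_columns
  if (is.null(log_cols)) log_cols <- columns
  responses <- log10_transform(responses, intersect(log_cols, columns))

  ord <- match(dataset$samples, responses$sample_id)
  if (anyNA(ord)) {
    stop("response table lacks sample(s): ",
         paste(dataset$samples[is.na(ord)], collapse = ", "), call. = FALSE)
  }
  responses <- responses[ord, , drop = FALSE]

  reports <- list()
  for (nm in columns) {
    reports[[nm]] <- tryCatch({
      keep <- which(!is.na(responses[[nm]]))
      if (length(keep) < config$cv$n_folds) {
        stop("only ", length(keep), " sample(s) measured for '", nm, "'")
      }
      rep_ <- run_double_cv(dataset_subset(dataset, keep), responses[[nm]][keep],
                            n_folds = config$cv$n_folds, seed = config$cv$seed,
                            max_lvs = config$cv$max_lvs, response_name = nm)
      if (!is.null(out_dir)) {
        write_cv_report(rep_, file.path(out_dir, paste0("cv_", nm, ".json")))
      }
      rep_
    }, error = function(e) {
      warning("response '", nm, "' failed: ", conditionMessage(e), call. = FALSE)
      structure(list(message = conditionMessage(e)), class = "try-error")
    })
  }
  invisible(reports)
}

#' Fit and export the final full-data models
#'
#' For each response with a usable cross-validation report, fits the
#' full-data model at the cross-validated number of LVs (see
#' [fit_final_model()]) and exports the serialized model plus its
#' regression-coefficient map as an EEM-grid CSV (ready for heat-map
#' display).
#'
#' @param config Path or list, see [read_pipeline_config()].
#' @param reports Output of [run_cv()] (rerun internally when omitted).
#' @return Named list of [fit_final_model()] results, invisibly.
#' @export
run_train_final <- function(config, reports = NULL) {
  config <- read_pipeline_config(config)
  if (is.null(reports)) reports <- run_cv(config)
  out_dir <- config$paths$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dataset <- preprocess_dataset(config$paths$manifest,
                                config = config$preprocess)
  responses <- read_response_table(config$paths$responses)
  columns <- names(reports)
  log_cols <- config$responses$log10_columns
  if (is.null(log_cols)) log_cols <- columns
  responses <- log10_transform(responses, intersect(log_cols, columns))
  ord <- match(dataset$samples, responses$sample_id)
  responses <- responses[ord, , drop = FALSE]

  finals <- list()
  for (nm in columns) {
    if (inherits(reports[[nm]], "try-error")) next
    keep <- which(!is.na(responses[[nm]]))
    finals[[nm]] <- fit_final_model(dataset_subset(dataset, keep),
                                    responses[[nm]][keep],
                                    report = reports[[nm]],
                                    response_name = nm,
                                    log10_applied = nm %in% log_cols)
    if (!is.null(out_dir)) {
      write_npls_model(finals[[nm]]$model,
                       file.path(out_dir, paste0("model_", nm, ".json")))
      write_coefficient_map(finals[[nm]]$map,
                            file.path(out_dir, paste0("coefmap_", nm, ".csv")))
    }
  }
  invisible(finals)
}
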