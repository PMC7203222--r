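#' Synthetic fluorophore definition
#'
#' A fluorophore is emulated as a rank-1 landscape: the outer product of a
#' Gaussian excitation profile and a Gaussian emission profile, each
#' normalised to peak 1, scaled by `brightness`. Real pigment spectra are
#' multi-peaked; the single-Gaussian shape is an analytic simplification
#' that preserves the tri-linear structure the models assume.
#'
#' @param name Component label.
#' @param ex_mean,ex_sd Excitation peak and width (nm); `ex_sd > 0`.
#' @param em_mean,em_sd Emission peak and width (nm); `em_mean > ex_mean`
#'   (Stokes shift), `em_sd > 0`.
#' @param brightness Intensity at the peak per unit concentration.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, ex_mean, ex_sd, em_mean, em_sd, brightness) {
  stopifnot(is.character(name), length(name) == 1,
            ex_sd > 0, em_sd > 0, brightness > 0)
  if (em_mean <= ex_mean) {
    stop("emission peak must lie above the excitation peak (Stokes shift)",
         call. = FALSE)
  }
  structure(list(name = name, ex_mean = ex_mean, ex_sd = ex_sd,
                 em_mean = em_mean, em_sd = em_sd, brightness = brightness),
            class = "fluorophore")
}

#' Default three-component culture mixture
#'
#' A chlorophyll-like pigment (long-wavelength emission band above 600 nm),
#' a protein-like fluorophore (excitation and emission below 400 nm,
#' aromatic amino acids) and an accessory pigment, mirroring the two
#' spectral regions that dominate a microalgal culture's landscape.
#'
#' @return A named list of three [fluorophore()]s.
#' @export
default_fluorophores <- function() {
  list(pigment = fluorophore("pigment", 440, 40, 683, 12, 1000),
       protein = fluorophore("protein", 280, 12, 340, 25, 600),
       accessory = fluorophore("accessory", 490, 30, 660, 20, 800))
}

#' Rank-1 landscape of one fluorophore
#'
#' @param spec A [fluorophore()].
#' @param ex_grid,em_grid [wavelength_grid()]s.
#' @return A `[em x ex]` matrix; value `brightness` at the peak cell.
#' @export
component_profile <- function(spec, ex_grid, em_grid) {
  stopifnot(inherits(spec, "fluorophore"),
            inherits(ex_grid, "wavelength_grid"),
            inherits(em_grid, "wavelength_grid"))
  g_em <- exp(-0.5 * ((em_grid$values - spec$em_mean) / spec$em_sd)^2)
  g_ex <- exp(-0.5 * ((ex_grid$values - spec$ex_mean) / spec$ex_sd)^2)
  spec$brightness * (g_em %o% g_ex)
}

#' Simulation configuration
#'
#' Defines the study conditions a synthetic dataset emulates: the
#' acquisition grids (default 250--790 nm excitation, 260--800 nm emission,
#' 5 nm steps), a tri-linear fluorophore mixture, log-uniform component
#' concentrations, component-wise Gaussian absorbance (driving a synthetic
#' inner-filter attenuation that [correct_inner_filter()] can undo),
#' additive first- and second-order Rayleigh ridges, white measurement
#' noise, and a response that is log-linear in the component
#' concentrations.
#'
#' Default conditions: 60 samples; concentrations log-uniform on
#' `[0.5, 3]` per component (a ~6-fold within-batch range over which the
#' log-linear response is still nearly linear in the spectra); scatter
#' ridge amplitude 10x the brightest fluorophore (scatter dominates raw
#' culture spectra) with sd 5 nm, second order at a quarter of that;
#' relative noise 0.02 of the peak clean intensity (SNR 50); response
#' `log10(raw) = 1 + log10(pigment concentration) + N(0, 0.02)`.
#'
#' @param ex_grid,em_grid Acquisition grids.
#' @param fluorophores Named list of [fluorophore()]s.
#' @param n_samples Number of samples.
#' @param conc_range Length-2 numeric (shared) or per-component list of
#'   log-uniform concentration bounds.
#' @param scatter List with `first`/`second`, each `list(amplitude, sd)`.
#'   Amplitudes default to `10 * max(brightness)` and a quarter of that.
#' @param absorbance_per_conc Peak absorbance contributed by one
#'   concentration unit of each component (Gaussian in wavelength at the
#'   component's excitation peak). Default 0.05 (dilute culture).
#' @param apply_ife Attenuate the signal by the synthetic inner filter
#'   effect (default `TRUE`).
#' @param noise_sd_rel Noise sd relative to the dataset's peak clean
#'   intensity.
#' @param response_model `list(name, intercept, coefficients, noise_sd)`;
#'   `coefficients` is a named-per-component vector acting on log10
#'   concentrations; the raw response is `10^(linear predictor + noise)`.
#' @param seed Integer seed (mandatory).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(ex_grid = wavelength_grid(250, 790, 5),
                              em_grid = wavelength_grid(260, 800, 5),
                              fluorophores = default_fluorophores(),
                              n_samples = 60,
                              conc_range = c(0.5, 3),
                              scatter = NULL,
                              absorbance_per_conc = 0.05,
                              apply_ife = TRUE,
                              noise_sd_rel = 0.02,
                              response_model = NULL,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(ex_grid, "wavelength_grid"),
            inherits(em_grid, "wavelength_grid"),
            is.list(fluorophores), length(fluorophores) >= 1,
            n_samples >= 2, noise_sd_rel >= 0, absorbance_per_conc >= 0)
  for (f in fluorophores) stopifnot(inherits(f, "fluorophore"))
  if (is.null(names(fluorophores))) {
    names(fluorophores) <- vapply(fluorophores, `[[`, character(1), "name")
  }
  if (!is.list(conc_range)) {
    conc_range <- rep(list(conc_range), length(fluorophores))
    names(conc_range) <- names(fluorophores)
  }
  for (cr in conc_range) stopifnot(length(cr) == 2, all(cr > 0), cr[2] > cr[1])
  peak <- max(vapply(fluorophores, `[[`, numeric(1), "brightness"))
  if (is.null(scatter)) {
    scatter <- list(first = list(amplitude = 10 * peak, sd = 5),
                    second = list(amplitude = 2.5 * peak, sd = 5))
  }
  stopifnot(all(c("first", "second") %in% names(scatter)))
  if (is.null(response_model)) {
    coefs <- stats::setNames(rep(0, length(fluorophores)), names(fluorophores))
    coefs[[1]] <- 1
    response_model <- list(name = "pigment_response", intercept = 1,
                           coefficients = coefs, noise_sd = 0.02)
  }
  stopifnot(all(names(response_model$coefficients) %in% names(fluorophores)))
  structure(list(ex_grid = ex_grid, em_grid = em_grid,
                 fluorophores = fluorophores, n_samples = as.integer(n_samples),
                 conc_range = conc_range, scatter = scatter,
                 absorbance_per_conc = absorbance_per_conc,
                 apply_ife = apply_ife, noise_sd_rel = noise_sd_rel,
                 response_model = response_model, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Synthetic inner-filter attenuation
#'
#' Multiplies every cell by `10^(-(A(ex) + A(em)) / 2)`: the exact inverse
#' of [correct_inner_filter()], emulating re-absorption within a
#' concentrated sample.
#'
#' @param x An [eem()].
#' @param spec The sample's [absorbance_spectrum()].
#' @return The attenuated [eem()].
#' @export
attenuate_inner_filter <- function(x, spec) {
  stopifnot(inherits(x, "eem"), inherits(spec, "absorbance_spectrum"))
  fac <- ife_factor_matrix(x, spec, sign = -1)
  x$intensity <- x$intensity * fac
  x
}

#' Simulate a synthetic EEM dataset with ground truth
#'
#' Draws component concentrations log-uniform, assembles clean tri-linear
#' landscapes, attenuates them by the synthetic inner filter effect
#' (component absorbances are Gaussian bands around each excitation peak),
#' adds first- and second-order Rayleigh ridges (per-sample amplitude
#' jittered by +/-10%) and white noise, and computes responses that are
#' log-linear in the concentrations. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list: `eems` (list of [eem()]), `specs` (list of
#'   [absorbance_spectrum()]), `responses` (raw-scale [response_table()]),
#'   `truth` (list with `concentrations`, `clean` tensor (pre-attenuation),
#'   `attenuated` tensor, `response_log10` before noise, `noise_sd`),
#'   `config`.
#' @export
simulate_eem_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  comps <- config$fluorophores
  C <- length(comps)
  J <- length(config$em_grid$values)
  K <- length(config$ex_grid$values)
  profiles <- lapply(comps, component_profile,
                     ex_grid = config$ex_grid, em_grid = config$em_grid)

  abs_wl <- seq(min(config$ex_grid$start, config$em_grid$start),
                max(config$ex_grid$stop, config$em_grid$stop),
                by = min(config$ex_grid$step, config$em_grid$step))
  abs_shapes <- vapply(comps, function(f) {
    config$absorbance_per_conc * exp(-0.5 * ((abs_wl - f$ex_mean) / f$ex_sd)^2)
  }, numeric(length(abs_wl)))

  em <- config$em_grid$values
  ex <- config$ex_grid$values
  ridge1_shape <- exp(-0.5 * (outer(em, ex, `-`) / config$scatter$first$sd)^2)
  ridge2_shape <- exp(-0.5 * (outer(em, 2 * ex, `-`) / config$scatter$second$sd)^2)

  rm_ <- config$response_model
  coefs <- stats::setNames(rep(0, C), names(comps))
  coefs[names(rm_$coefficients)] <- rm_$coefficients

  withr::with_seed(config$seed, {
    conc <- vapply(names(comps), function(nm) {
      b <- config$conc_range[[nm]]
      10^stats::runif(n, log10(b[1]), log10(b[2]))
    }, numeric(n))
    if (n == 1) conc <- matrix(conc, nrow = 1, dimnames = list(NULL, names(comps)))
    jit1 <- config$scatter$first$amplitude * stats::runif(n, 0.9, 1.1)
    jit2 <- config$scatter$second$amplitude * stats::runif(n, 0.9, 1.1)
    y_noise <- stats::rnorm(n, 0, rm_$noise_sd)

    clean <- array(0, dim = c(n, J, K))
    for (i in seq_len(n)) {
      for (cc in seq_len(C)) {
        clean[i, , ] <- clean[i, , ] + conc[i, cc] * profiles[[cc]]
      }
    }
    noise_sd <- config$noise_sd_rel * max(clean)

    ids <- sprintf("sample_%03d", seq_len(n))
    eems <- vector("list", n)
    specs <- vector("list", n)
    attenuated <- array(0, dim = c(n, J, K))
    for (i in seq_len(n)) {
      a <- drop(abs_shapes %*% conc[i, ])
      specs[[i]] <- absorbance_spectrum(ids[i], abs_wl, a)
      base_eem <- eem(ids[i], config$ex_grid, config$em_grid, clean[i, , ])
      att <- if (config$apply_ife) {
        attenuate_inner_filter(base_eem, specs[[i]])$intensity
      } else {
        clean[i, , ]
      }
      attenuated[i, , ] <- att
      intensity <- att + jit1[i] * ridge1_shape + jit2[i] * ridge2_shape
      if (noise_sd > 0) {
        intensity <- intensity + matrix(stats::rnorm(J * K, 0, noise_sd), J, K)
      }
      eems[[i]] <- eem(ids[i], config$ex_grid, config$em_grid, intensity)
    }
  })

  y_log <- rm_$intercept + drop(log10(conc) %*% coefs)
  raw <- 10^(y_log + y_noise)
  responses <- do.call(response_table,
                       c(list(sample_id = ids),
                         stats::setNames(list(raw), rm_$name)))
  list(eems = eems, specs = specs, responses = responses,
       truth = list(concentrations = conc, clean = clean,
                    attenuated = attenuated, response_log10 = y_log,
                    noise_sd = noise_sd),
       config = config)
}

#' Write a simulated dataset as a CSV bundle
#'
#' Produces the on-disk layout the pipeline consumes: one EEM grid CSV and
#' one absorbance CSV per sample, `responses.csv`, `manifest.json` and
#' `ground_truth.json` (concentrations and noise-free responses).
#'
#' @param sim Output of [simulate_eem_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir) {
  stopifnot(is.list(sim), !is.null(sim$eems))
  dir.create(file.path(dir, "eems"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "absorbance"), recursive = TRUE, showWarnings = FALSE)
  n <- length(sim$eems)
  ids <- vapply(sim$eems, function(e) e$sample_id, character(1))
  eem_rel <- file.path("eems", paste0(ids, ".csv"))
  abs_rel <- file.path("absorbance", paste0(ids, ".csv"))
  for (i in seq_len(n)) {
    write_eem(sim$eems[[i]], file.path(dir, eem_rel[i]))
    write_absorbance(sim$specs[[i]], file.path(dir, abs_rel[i]))
  }
  write_response_table(sim$responses, file.path(dir, "responses.csv"))
  manifest <- eem_manifest(ids, eem_rel, abs_rel)
  manifest_path <- file.path(dir, "manifest.json")
  write_manifest(manifest, manifest_path)
  jsonlite::write_json(
    list(concentrations = as.data.frame(sim$truth$concentrations),
         sample_id = ids,
         response_log10 = sim$truth$response_log10,
         noise_sd = sim$truth$noise_sd,
         seed = sim$config$seed),
    file.path(dir, "ground_truth.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}
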