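# Small in-code fixtures shared across test files.

toy_ex_grid <- function() wavelength_grid(300, 340, 10)   # 5 points
toy_em_grid <- function() wavelength_grid(350, 400, 10)   # 6 points

# Gaussian profile helper over a grid
gauss <- function(grid, mean, sd) exp(-0.5 * ((grid$values - mean) / sd)^2)

# A deterministic rank-R tri-linear dataset with y an exact linear function
# of the component concentrations. Profiles are moderately separated
# Gaussians so the R score directions are independent.
make_rank_r_dataset <- function(rank, n = 12, seed = 42,
                                ex_grid = wavelength_grid(300, 390, 10),
                                em_grid = wavelength_grid(400, 500, 10)) {
  stopifnot(rank >= 1, rank <= 3)
  ex_means <- c(315, 355, 385)[seq_len(rank)]
  em_means <- c(420, 460, 490)[seq_len(rank)]
  withr::with_seed(seed, {
    conc <- matrix(runif(n * rank, 1, 5), n, rank)
  })
  # fixed response map so datasets drawn with different seeds share the
  # same ground-truth relation (training vs held-out comparisons)
  coefs <- c(1.6, 0.9, 2.3)[seq_len(rank)]
  profiles <- lapply(seq_len(rank), function(r) {
    gauss(em_grid, em_means[r], 12) %o% gauss(ex_grid, ex_means[r], 10)
  })
  eems <- lapply(seq_len(n), function(i) {
    m <- Reduce(`+`, Map(function(p, c) c * p, profiles, conc[i, ]))
    eem(sprintf("s%02d", i), ex_grid, em_grid, m)
  })
  list(dataset = assemble_dataset(eems), y = drop(conc %*% coefs),
       conc = conc, profiles = profiles, coefs = coefs)
}

# A random dense dataset (no structure) for oracle comparisons.
make_random_dataset <- function(n, J, K, seed,
                                ex_start = 300, em_start = 400, step = 10) {
  ex_grid <- wavelength_grid(ex_start, ex_start + step * (K - 1), step)
  em_grid <- wavelength_grid(em_start, em_start + step * (J - 1), step)
  withr::with_seed(seed, {
    tensors <- lapply(seq_len(n), function(i) matrix(rnorm(J * K), J, K))
    y <- rnorm(n)
  })
  eems <- lapply(seq_len(n), function(i) {
    eem(sprintf("s%02d", i), ex_grid, em_grid, tensors[[i]])
  })
  list(dataset = assemble_dataset(eems), y = y)
}

# Write a tiny EEM CSV grid by hand (exercises the reader independently of
# write_eem).
write_toy_eem_csv <- function(path, ex = c(300, 310, 320),
                              em = c(400, 410, 420),
                              body = matrix(as.numeric(1:9), 3, 3),
                              blank_cells = NULL) {
  chr <- matrix(as.character(body), nrow(body), ncol(body))
  if (!is.null(blank_cells)) {
    for (rc in blank_cells) chr[rc[1], rc[2]] <- ""
  }
  lines <- c(paste(c("em\\ex", ex), collapse = ","),
             vapply(seq_along(em), function(j) {
               paste(c(em[j], chr[j, ]), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  path
}
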