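flat_eem <- function(value = 100, ex = wavelength_grid(250, 400, 5),
                     em = wavelength_grid(260, 700, 5)) {
  eem("flat", ex, em, matrix(value, length(em$values), length(ex$values)))
}

test_that("inner-filter correction multiplies by 10^((A(ex)+A(em))/2)", {
  e <- flat_eem(100)
  # A == 0 everywhere -> identity
  z <- absorbance_spectrum("flat", c(250, 700), c(0, 0))
  expect_equal(correct_inner_filter(e, z)$intensity, e$intensity)

  # constant A = 1 -> factor 10^((1+1)/2) = 10 at every cell
  s1 <- absorbance_spectrum("flat", c(250, 700), c(1, 1))
  expect_equal(unname(correct_inner_filter(flat_eem(5), s1)$intensity[1, 1]), 50)

  # A(ex) = 0.2, A(em) = 0.1 at intensity 100 -> 100 * 10^0.15
  ex <- wavelength_grid(300, 300, 5)
  em <- wavelength_grid(400, 400, 5)
  cell <- eem("c", ex, em, matrix(100, 1, 1))
  s <- absorbance_spectrum("c", c(300, 400), c(0.2, 0.1))
  expect_equal(unname(correct_inner_filter(cell, s)$intensity[1, 1]),
               141.2538, tolerance = 1e-6)

  # threshold: a transparent sample is returned unchanged
  cfg <- preprocess_config(ife_absorbance_threshold = 0.5)
  s_low <- absorbance_spectrum("c", c(300, 400), c(0.3, 0.3))
  expect_equal(correct_inner_filter(cell, s_low, cfg)$intensity,
               cell$intensity)

  # missing cells stay missing and unvalued
  e_miss <- flat_eem(100)
  e_miss$intensity[3, 3] <- NA
  e_miss$missing[3, 3] <- TRUE
  out <- correct_inner_filter(e_miss, s1)
  expect_true(out$missing[3, 3] && is.na(out$intensity[3, 3]))
})

test_that("inner-filter correction is monotone in absorbance", {
  e <- flat_eem(100)
  lo <- absorbance_spectrum("flat", c(250, 500, 700), c(0.1, 0.2, 0.1))
  hi <- absorbance_spectrum("flat", c(250, 500, 700), c(0.1, 0.5, 0.1))
  a <- correct_inner_filter(e, lo)$intensity
  b <- correct_inner_filter(e, hi)$intensity
  expect_true(all(b >= a))
})

test_that("first-order Rayleigh excision follows the |em - ex| band rule", {
  ex <- wavelength_grid(290, 310, 10)
  em <- wavelength_grid(280, 330, 10)
  e <- eem("r", ex, em, matrix(7, 6, 3))
  out <- excise_first_order_rayleigh(e, 15)
  # cell (ex=300, em=310): |10| <= 15 -> missing
  expect_true(out$missing[which(em$values == 310), which(ex$values == 300)])
  # cell (ex=300, em=320): |20| > 15 -> untouched
  expect_false(out$missing[which(em$values == 320), which(ex$values == 300)])
  expect_equal(out$intensity[which(em$values == 320), which(ex$values == 300)],
               7, ignore_attr = TRUE)
  # halfwidth 0 -> only the exact diagonal
  out0 <- excise_first_order_rayleigh(e, 0)
  expect_equal(sum(out0$missing),
               sum(outer(em$values, ex$values, `==`)))
  # idempotence
  expect_identical(excise_first_order_rayleigh(out, 15)$intensity,
                   out$intensity)
  expect_identical(excise_first_order_rayleigh(out, 15)$missing, out$missing)
})

test_that("second-order Rayleigh band is bridged linearly along emission", {
  ex <- wavelength_grid(300, 300, 5)
  em <- wavelength_grid(560, 640, 5)
  e <- eem("r2", ex, em, matrix(0, length(em$values), 1))
  e$intensity[em$values == 580, 1] <- 2
  e$intensity[em$values == 620, 1] <- 4
  out <- interpolate_second_order_rayleigh(e, 15)
  # band covers em in [585, 615]; neighbours are em=580 (2.0) and em=620 (4.0)
  expect_equal(unname(out$intensity[em$values == 600, 1]), 3.0)
  expect_equal(unname(out$intensity[em$values == 585, 1]), 2.25)
  expect_equal(unname(out$intensity[em$values == 615, 1]), 3.75)
  expect_false(any(out$missing[abs(em$values - 600) <= 15, 1]))

  # band entirely above the emission range -> column untouched
  ex_hi <- wavelength_grid(500, 500, 5)
  e_hi <- eem("r2", ex_hi, em, matrix(1, length(em$values), 1))
  out_hi <- interpolate_second_order_rayleigh(e_hi, 15)
  expect_equal(out_hi$intensity, e_hi$intensity)

  # band touching the grid edge (no upper neighbour) -> cells become missing
  em_edge <- wavelength_grid(560, 610, 5)
  e_edge <- eem("r2", ex, em_edge, matrix(1, length(em_edge$values), 1))
  out_edge <- interpolate_second_order_rayleigh(e_edge, 15)
  expect_true(all(out_edge$missing[abs(em_edge$values - 600) <= 15, 1]))
})

test_that("sub-diagonal zeroing is strict, overriding, and idempotent", {
  ex <- wavelength_grid(290, 310, 10)
  em <- wavelength_grid(280, 330, 10)
  e <- eem("z", ex, em, matrix(7.3, 6, 3))
  out <- zero_below_diagonal(e)
  expect_equal(unname(out$intensity[which(em$values == 300),
                                    which(ex$values == 310)]), 0)
  # em == ex is NOT "shorter" -> untouched
  expect_equal(unname(out$intensity[which(em$values == 300),
                                    which(ex$values == 300)]), 7.3)
  # zeroing wins over a previously excised sub-diagonal missing cell
  e2 <- excise_first_order_rayleigh(e, 15)
  out2 <- zero_below_diagonal(e2)
  sub <- outer(em$values, ex$values, `<`)
  expect_true(all(out2$intensity[sub] == 0))
  expect_false(any(out2$missing[sub]))
  # idempotence
  again <- zero_below_diagonal(out2)
  expect_identical(again$intensity, out2$intensity)
  expect_identical(again$missing, out2$missing)
})

test_that("off-band cells are bit-identical through the scatter operations", {
  withr::with_seed(5, {
    ex <- wavelength_grid(250, 400, 5)
    em <- wavelength_grid(260, 700, 5)
    e <- eem("x", ex, em, matrix(rexp(length(em$values) * length(ex$values)),
                                 length(em$values), length(ex$values)))
  })
  hw <- 15
  band1 <- abs(outer(em$values, ex$values, `-`)) <= hw
  band2 <- abs(outer(em$values, 2 * ex$values, `-`)) <= hw
  out <- interpolate_second_order_rayleigh(
    excise_first_order_rayleigh(e, hw), hw)
  off <- !band1 & !band2
  expect_identical(out$intensity[off], e$intensity[off])
})

test_that("the stage chain accounts for every cell exactly once", {
  # ex stops at 330 so the second-order band (em <= 2*330 + 15) never
  # touches the emission grid edge and is always bridged, never blanked
  ex <- wavelength_grid(250, 330, 5)
  em <- wavelength_grid(260, 700, 5)
  J <- length(em$values); K <- length(ex$values)
  withr::with_seed(6, {
    e <- eem("x", ex, em, matrix(rexp(J * K), J, K))
  })
  s <- absorbance_spectrum("x", c(250, 700), c(0.1, 0.05))
  out <- preprocess_sample(e, s)
  log <- attr(out, "preprocess_log")
  expect_gt(log$n_excised, 0)
  expect_gt(log$n_interpolated, 0)
  expect_gt(log$n_zeroed, 0)
  # partition: missing + zeroed + valued = grid size
  n_missing <- sum(out$missing)
  n_zero <- sum(out$intensity == 0, na.rm = TRUE)
  n_valued <- sum(!out$missing & out$intensity != 0)
  expect_equal(n_missing + n_zero + n_valued, J * K)
  # the final mask is exactly the first-order band minus the zeroed triangle
  band1 <- abs(outer(em$values, ex$values, `-`)) <= 15
  sub <- outer(em$values, ex$values, `<`)
  expect_equal(out$missing, band1 & !sub, ignore_attr = TRUE)
})

test_that("preprocess_dataset cleans samples jointly and identically", {
  ex <- wavelength_grid(250, 400, 5)
  em <- wavelength_grid(260, 700, 5)
  J <- length(em$values); K <- length(ex$values)
  base <- matrix(3, J, K)
  eems <- lapply(c("a", "b", "c"), function(id) eem(id, ex, em, base))
  ds <- preprocess_dataset(eems, config = preprocess_config(apply_ife = FALSE))
  expect_equal(ds$tensor[1, , ], ds$tensor[2, , ], ignore_attr = TRUE)
  expect_equal(ds$tensor[2, , ], ds$tensor[3, , ], ignore_attr = TRUE)
  # first-order band identical across samples: global mask equals per-sample
  expect_equal(ds$global_missing, eem_slice(ds, 1)$missing,
               ignore_attr = TRUE)

  # two-sample toy set with hand-computed IFE factors
  ex1 <- wavelength_grid(300, 310, 10)
  em1 <- wavelength_grid(400, 410, 10)
  e1 <- eem("s1", ex1, em1, matrix(10, 2, 2))
  e2 <- eem("s2", ex1, em1, matrix(20, 2, 2))
  s1 <- absorbance_spectrum("s1", c(300, 410), c(0.2, 0.2))
  s2 <- absorbance_spectrum("s2", c(300, 410), c(0.4, 0.4))
  cfg <- preprocess_config(first_order_halfwidth = 0,
                           second_order_halfwidth = 0)
  ds2 <- preprocess_dataset(list(e1, e2), list(s1, s2), cfg)
  expect_equal(unname(ds2$tensor[1, 1, 1]), 10 * 10^0.2) # spreadsheet value
  expect_equal(unname(ds2$tensor[2, 1, 1]), 20 * 10^0.4)

  # failure names the offending sample
  expect_error(
    preprocess_dataset(list(e1), config = preprocess_config(apply_ife = TRUE)),
    "s1")
})

test_that("preprocessing recovers the clean signal of a synthetic sample", {
  cfg <- simulation_config(n_samples = 3, seed = 11, noise_sd_rel = 0.001)
  sim <- simulate_eem_dataset(cfg)
  pp <- preprocess_sample(sim$eems[[1]], sim$specs[[1]])
  clean <- sim$truth$clean[1, , ]
  em <- cfg$em_grid$values; ex <- cfg$ex_grid$values
  band1 <- abs(outer(em, ex, `-`)) <= 20
  band2 <- abs(outer(em, 2 * ex, `-`)) <= 20
  sub <- outer(em, ex, `<`)
  off <- !band1 & !band2 & !sub & !pp$missing
  # off the scatter bands the cleaned EEM matches the generator's clean
  # component sum to within a few noise standard deviations
  resid <- abs(pp$intensity[off] - clean[off])
  # IFE correction amplifies noise by at most 10^(max A); bound generously
  expect_lt(max(resid), 6 * sim$truth$noise_sd * 10^0.5)
})
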