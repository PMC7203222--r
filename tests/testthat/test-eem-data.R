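test_that("wavelength grid arithmetic matches the acquisition ranges", {
  ex <- wavelength_grid(250, 790, 5)
  em <- wavelength_grid(260, 800, 5)
  # independent count: (stop - start) / step + 1
  expect_equal(length(ex$values), (790 - 250) / 5 + 1)
  expect_equal(length(em$values), (800 - 260) / 5 + 1)
  expect_true(all(diff(ex$values) == 5))
  expect_error(wavelength_grid(250, 792, 5), "integer")
  expect_error(wavelength_grid(250, 790, -5), "positive")
  expect_error(wavelength_grid_from_values(c(250, 255, 265)), "uniform")
  expect_error(wavelength_grid_from_values(c(250, 250)), "increasing")
})

test_that("EEM CSV grids read, round-trip, and flag blank cells missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_eem_csv(path)
  e <- read_eem(path, "toy")
  expect_s3_class(e, "eem")
  expect_false(any(e$missing))
  expect_equal(unname(e$intensity[2, 3]), 8) # column-major body 1..9

  write_toy_eem_csv(path, blank_cells = list(c(1, 2)))
  e2 <- read_eem(path, "toy")
  expect_true(e2$missing[1, 2])
  expect_true(is.na(e2$intensity[1, 2]))
  expect_equal(sum(e2$missing), 1)

  # write_eem then read_eem is the identity on grids, intensity and mask
  out <- withr::local_tempfile(fileext = ".csv")
  write_eem(e2, out)
  e3 <- read_eem(out, "toy")
  expect_equal(e3$ex_grid$values, e2$ex_grid$values, tolerance = 1e-9)
  expect_equal(e3$em_grid$values, e2$em_grid$values, tolerance = 1e-9)
  expect_equal(e3$intensity, e2$intensity, tolerance = 1e-9)
  expect_identical(e3$missing, e2$missing)
})

test_that("malformed or non-uniform EEM headers are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("em\\ex,300,abc", "400,1,2", "410,3,4"), path)
  expect_error(read_eem(path), "did not parse")
  writeLines(c("em\\ex,300,310,325", "400,1,2,3", "410,4,5,6"), path)
  expect_error(read_eem(path), "uniform")
  writeLines("just one line", path)
  expect_error(read_eem(path), "malformed")
})

test_that("paper-scale grid headers give 109 x 109 EEMs", {
  path <- withr::local_tempfile(fileext = ".csv")
  ex <- seq(250, 790, 5)
  em <- seq(260, 800, 5)
  body <- matrix(0, length(em), length(ex))
  write_toy_eem_csv(path, ex = ex, em = em, body = body)
  e <- read_eem(path)
  expect_identical(dim(e$intensity), c(109L, 109L))
})

test_that("absorbance spectra validate, sort, and clip or reject negatives", {
  s <- absorbance_spectrum("a", c(300, 250), c(0.2, 0.5))
  expect_equal(s$wavelengths, c(250, 300)) # sorted ascending
  expect_equal(s$absorbance, c(0.5, 0.2))
  expect_error(absorbance_spectrum("a", c(250, 250), c(1, 2)), "duplicate")
  expect_equal(absorbance_spectrum("a", 250, -0.1)$absorbance, 0) # clip policy
  expect_error(absorbance_spectrum("a", 250, -0.1, negative = "reject"),
               "negative")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,absorbance", "300,0.2", "250,0.5"), path)
  s2 <- read_absorbance(path, "a")
  expect_equal(s2$wavelengths, c(250, 300))
  writeLines(c("lambda,abs", "300,0.2"), path)
  expect_error(read_absorbance(path), "header")
})

test_that("absorbance interpolation is linear inside, zero with warning outside", {
  s <- absorbance_spectrum("a", c(600, 700), c(0.2, 0.4))
  expect_equal(interpolate_absorbance(s, 650), 0.3) # hand: midpoint
  expect_equal(interpolate_absorbance(s, 600), 0.2) # knot value
  expect_warning(out <- interpolate_absorbance(s, 800), "outside")
  expect_equal(out, 0)
  expect_equal(suppressWarnings(interpolate_absorbance(s, c(600, 625, 900))),
               c(0.2, 0.25, 0))
})

test_that("assemble_dataset stacks samples and unions missing masks", {
  ex <- toy_ex_grid(); em <- toy_em_grid()
  m <- matrix(1, length(em$values), length(ex$values))
  a <- eem("A", ex, em, m)
  b <- eem("B", ex, em, m * 2)
  ds <- assemble_dataset(list(a, b))
  expect_false(any(ds$global_missing))
  expect_identical(dim(ds$tensor), c(2L, 6L, 5L))

  ma <- m; ma[1, 1] <- NA
  mb <- m; mb[2, 2] <- NA
  ds2 <- assemble_dataset(list(eem("A", ex, em, ma), eem("B", ex, em, mb)))
  expect_true(ds2$global_missing[1, 1] && ds2$global_missing[2, 2])
  expect_equal(sum(ds2$global_missing), 2)

  # single EEM -> first dimension 1; slicing reproduces the sample exactly
  ds1 <- assemble_dataset(list(a))
  expect_identical(dim(ds1$tensor)[1], 1L)
  back <- eem_slice(ds2, "A")
  expect_equal(unname(back$intensity), unname(ma))

  ex2 <- wavelength_grid(200, 240, 10)
  expect_error(assemble_dataset(list(a, eem("C", ex2, em, m))), "C")
})

test_that("response tables track per-column log10 state and round-trip CSV", {
  rt <- response_table(c("s1", "s2", "s3"),
                       cell_concentration = c(1e6, 1e7, NA),
                       chlorophyll = c(0.5, 3.7, 1e6))
  expect_equal(sum(!is.na(rt$cell_concentration)), 2)
  tr <- log10_transform(rt, "chlorophyll")
  expect_true(attr(tr, "log10_applied")[["chlorophyll"]])
  expect_equal(tr$chlorophyll, log10(c(0.5, 3.7, 1e6)))
  back <- inverse_log10_transform(tr, "chlorophyll")
  expect_equal(back$chlorophyll, c(0.5, 3.7, 1e6)) # round trip
  expect_equal(log10_transform(response_table("a", v = 100))$v, 2)
  expect_equal(log10_transform(response_table("a", v = 1))$v, 0)

  rt_bad <- response_table(c("s1", "s2"), v = c(1, -2))
  expect_error(log10_transform(rt_bad), "s2")

  path <- withr::local_tempfile(fileext = ".csv")
  write_response_table(rt, path)
  rt2 <- read_response_table(path)
  expect_equal(rt2$cell_concentration, rt$cell_concentration)
  expect_true(is.na(rt2$cell_concentration[3]))
})

test_that("manifests round-trip JSON and validate referenced files", {
  dir <- withr::local_tempdir()
  eem_path <- file.path(dir, "a.csv")
  write_toy_eem_csv(eem_path)
  m <- eem_manifest("A", "a.csv",
                    metadata = data.frame(temperature = 25,
                                          nitrogen_supply = "present",
                                          light_cycle = "16/8"))
  mp <- file.path(dir, "manifest.json")
  write_manifest(m, mp)
  m2 <- read_manifest(mp)
  expect_equal(m2$sample_id, "A")
  expect_equal(m2$temperature, 25)
  loaded <- load_manifest(m2)
  expect_s3_class(loaded$eems[[1]], "eem")

  m_bad <- eem_manifest("B", "missing.csv")
  write_manifest(m_bad, mp)
  expect_error(read_manifest(mp), "missing EEM file")
})
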