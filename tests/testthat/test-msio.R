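test_that("feature tables round-trip through CSV to printed precision", {
  path <- withr::local_tempfile(fileext = ".csv")
  f <- tiny_features()
  write_feature_table(f, path)
  back <- read_feature_table(path)
  expect_identical(nrow(back), nrow(f))
  expect_equal(back$mz, f$mz, tolerance = 1e-6)
  expect_equal(back$rt_min, f$rt_min, tolerance = 1e-4)
  expect_identical(back$sample_id, f$sample_id)
})

test_that("malformed feature tables are rejected, naming the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  f <- tiny_features()
  utils::write.csv(f[, setdiff(names(f), "snr")], path, row.names = FALSE)
  expect_error(read_feature_table(path), "snr")
  f2 <- tiny_features(); f2$rt_min[1] <- -1
  expect_error(validate_features(f2), "rt_min")
  f3 <- tiny_features(); f3$matrix <- "plasma"
  expect_error(validate_features(f3), "unknown matrix")
})

test_that("MGF spectra round-trip and rt is converted to minutes", {
  path <- withr::local_tempfile(fileext = ".mgf")
  sp <- spectrum(347.1714, rt_min = 2.97,
                 peaks = cbind(c(217.0608, 145.0396), c(100, 60)),
                 collision_energy = 25, title = "one")
  write_spectra_mgf(list(sp), path)
  back <- read_spectra(path, "MGF")
  expect_length(back, 1)
  expect_equal(back[[1]]$precursor_mz, 347.1714, tolerance = 1e-6)
  expect_equal(back[[1]]$rt_min, 2.97, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks[, "mz"], c(145.0396, 217.0608),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back[[1]]$collision_energy, 25)
})

test_that("RTINSECONDS is divided by 60 and peak lists are sorted on load", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=347.1714", "RTINSECONDS=178.2",
               "300.1 5", "100.2 10", "END IONS"), path)
  sp <- read_spectra(path)[[1]]
  expect_equal(sp$rt_min, 2.97, tolerance = 1e-9)
  expect_false(is.unsorted(sp$peaks[, "mz"]))
})

test_that("malformed MGF blocks are rejected", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=347.1714", "100.2 abc", "END IONS"),
             path)
  expect_error(read_spectra(path), "malformed MGF")
  writeLines(c("BEGIN IONS", "100.2 10"), path)
  expect_error(read_spectra(path), "without END IONS")
  writeLines(c("BEGIN IONS", "RTINSECONDS=10", "END IONS"), path)
  expect_error(read_spectra(path), "PEPMASS")
})

test_that("reports round-trip through TSV and JSON", {
  rows <- data.frame(
    ID = c("A10", "A8"), rt_min = c(2.97, 2.91),
    transformation = c("cleavage 3TMS + carboxylic acid formation (S)",
                       "cleavage 3TMS + terminal hydroxylation (S)"),
    formula = c("C17H22N4O4", "C17H24N4O3"),
    calc_mz_mh = c(347.1714, 333.1921), ppm_error = c(0.5, -1.0),
    diagnostic_ions = c("217.0608; 145.0396", "203.0815; 145.0396"),
    mar_urine = c(53.27, 48.39), stringsAsFactors = FALSE
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rows, tsv, "TSV")
  expect_true(any(grepl("347.1714", readLines(tsv), fixed = TRUE)))
  back <- read_report(tsv, "TSV")
  expect_identical(back$ID, rows$ID)
  json <- withr::local_tempfile(fileext = ".json")
  write_report(rows, json, "JSON")
  back2 <- read_report(json, "JSON")
  expect_identical(back2$ID, rows$ID)
  expect_equal(back2$calc_mz_mh, rows$calc_mz_mh, tolerance = 1e-9)
  expect_equal(back2$mar_urine, rows$mar_urine, tolerance = 1e-9)
})

test_that("an empty report writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(silascreen:::.empty_report(), path, "TSV")
  expect_identical(length(readLines(path)), 1L)
})
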