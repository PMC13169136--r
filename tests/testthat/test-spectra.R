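test_that("the fixture dialect loads the printed peak lists", {
  spectra <- read_aqa_fixtures()
  expect_length(spectra, 39)
  cmp7 <- spectra[[7]]
  expect_identical(cmp7$name, "Chlorogenic acid")
  expect_equal(nrow(cmp7$peaks), 9)
  expect_equal(base_peak(cmp7)$mz, 191.0551)
  expect_equal(cmp7$rt, 3.19)
  expect_equal(cmp7$dimer_mz, 707.1832)
  # inconsistent printed exact-mass cells are flagged on load, not reproduced
  w <- capture_warnings(read_spectra(aqa_fixture_path()))
  expect_true(any(grepl("disagrees with formula", w)))
  # the feruloylquinic rows print C17H20O8 where the ion demands C17H20O9
  expect_true(any(grepl("C17H20O8", w)))
})

test_that("normalization is idempotent, drops zeros and merges duplicates", {
  sp <- msms_spectrum("t", 400, data.frame(mz = c(100, 200, 300),
                                           abundance = c(5, 50, 25)),
                      normalize = FALSE)
  n1 <- normalize_spectrum(sp)
  n2 <- normalize_spectrum(n1)
  expect_equal(n1$peaks, n2$peaks)
  expect_equal(max(n1$peaks$abundance), 100)
  expect_equal(sum(n1$peaks$abundance == 100), 1L)
  expect_warning(
    z <- msms_spectrum("z", 400, data.frame(mz = c(100, 200),
                                            abundance = c(0, 50))),
    "zero-abundance")
  expect_equal(nrow(z$peaks), 1)
  # printed tables occasionally duplicate a fragment; first occurrence wins
  expect_warning(
    d <- msms_spectrum("d", 400, data.frame(mz = c(111.0435, 111.0435, 200),
                                            abundance = c(51.4, 3.6, 100))),
    "duplicated")
  expect_equal(d$peaks$abundance[d$peaks$mz == 111.0435], 51.4)
})

test_that("base peak ties break to the lower m/z with a flag", {
  sp <- msms_spectrum("tie", 500, data.frame(mz = c(150, 120, 300),
                                             abundance = c(100, 100, 10)))
  bp <- base_peak(sp)
  expect_equal(bp$mz, 120)
  expect_true(attr(bp, "tie"))
  one <- msms_spectrum("one", 500, data.frame(mz = 191.0551, abundance = 40))
  expect_equal(base_peak(one)$mz, 191.0551)
  expect_false(attr(base_peak(one), "tie"))
})

test_that("find_peak returns the nearest in-tolerance peak or nothing", {
  spectra <- read_aqa_fixtures()
  cmp4 <- spectra[[4]]
  expect_equal(find_peak(cmp4, 179.034, tol_mda = 10)$mz, 179.0339)
  expect_null(find_peak(cmp4, 500.0, tol_mda = 10))
  two <- msms_spectrum("two", 400,
                       data.frame(mz = c(179.030, 179.036),
                                  abundance = c(50, 100)))
  expect_equal(find_peak(two, 179.034, tol_mda = 10)$mz, 179.036)
  expect_equal(find_peak(two, 179.034, tol_ppm = 30)$mz, 179.036)
})

test_that("MSP and MGF round-trips preserve peaks", {
  spectra <- read_aqa_fixtures()[c(4, 7, 22)]
  for (fmt in c("msp", "mgf")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_spectra(spectra, path, fmt)
    back <- read_spectra(path)
    expect_length(back, 3)
    for (i in seq_along(back)) {
      expect_equal(nrow(back[[i]]$peaks), nrow(spectra[[i]]$peaks))
      expect_equal(back[[i]]$peaks$mz, spectra[[i]]$peaks$mz,
                   tolerance = 1e-4)
      expect_equal(back[[i]]$peaks$abundance, spectra[[i]]$peaks$abundance,
                   tolerance = 0.1)
      expect_equal(back[[i]]$precursor_mz, spectra[[i]]$precursor_mz,
                   tolerance = 1e-4)
    }
  }
})

test_that("a minimal MGF record reads as one spectrum", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=minimal", "PEPMASS=353.0878",
               "191.0551 100", "END IONS"), path)
  got <- read_spectra(path)
  expect_length(got, 1)
  expect_equal(got[[1]]$precursor_mz, 353.0878)
})

test_that("malformed and empty inputs error or warn informatively", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tprecursor_mz\tfragments",
               "x1\t353.1\t191.0551 (100); garbage"), bad)
  expect_error(suppressWarnings(read_spectra(bad)), "x1")
  empty <- tempfile(fileext = ".msp")
  writeLines(character(0), empty)
  expect_warning(got <- read_spectra(empty), "empty")
  expect_length(got, 0)
  expect_error(read_spectra("/no/such/file.msp"), "not found")
})
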