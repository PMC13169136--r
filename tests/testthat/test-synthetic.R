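cfg <- derep_config()

test_that("structure specifications are validated", {
  expect_error(structure_spec("quinic", c("2" = "caffeoyl")), "position")
  expect_error(structure_spec("hexaric", c("1" = "caffeoyl")), "position")
  expect_error(structure_spec("quinic",
                              stats::setNames(rep("caffeoyl", 2),
                                              c("3", "3"))),
               "one decoration per site")
  expect_error(structure_spec("quercetin", c("3" = "caffeoyl")), "backbone")
  expect_error(structure_spec("quinic", c("3" = "caffeoyl"),
                              sugar = "hexose"), "aglycone")
})

test_that("the leontopodic-A spec reproduces its fragment chain exactly", {
  sp <- structure_spec(
    "hexaric", stats::setNames(rep("caffeoyl", 3), c("2", "3", "4")),
    ester = "hydroxybutanyl")
  out <- synthesize_spectrum(sp, noise = NULL, config = cfg)
  # chain expected from formula arithmetic, independently of the generator:
  # [M-H]- of C37H34O19, then three caffeoyl (C9H6O3) losses, then the
  # hexarate anion after the hydroxybutanyl residue departs
  caf <- monoisotopic_mass("C9H6O3")
  prec <- deprotonated_mz("C37H34O19")
  expected <- c(prec, prec - caf, prec - 2 * caf, prec - 3 * caf,
                deprotonated_mz("C6H10O8"))
  expect_equal(out$spectrum$precursor_mz, prec, tolerance = 1e-3)
  for (mz in expected) {
    expect_false(is.null(find_peak(out$spectrum, mz, tol_mda = 1)))
  }
  r <- annotate(out$spectrum, cfg)
  expect_identical(r$class, "caffeoylhexaric acid")
  expect_identical(r$substituents, "hydroxybutanyl")
})

test_that("zero-noise spectra round-trip to their generating structure", {
  enum <- spec_enumeration()
  expect_gt(length(enum), 50)
  ok <- vapply(enum, function(s) {
    out <- synthesize_spectrum(s, noise = NULL, config = cfg)
    m <- matches_truth(out$truth, annotate(out$spectrum, cfg))
    isTRUE(m$class) && isTRUE(m$composition) &&
      (is.na(m$positions) || isTRUE(m$positions))
  }, logical(1))
  expect_true(all(ok))
})

test_that("seeded generation is exactly reproducible", {
  d1 <- generate_dataset(12, noise = noise_model(), seed = 31, config = cfg)
  d2 <- generate_dataset(12, noise = noise_model(), seed = 31, config = cfg)
  expect_identical(d1$truth, d2$truth)
  for (i in seq_along(d1$spectra)) {
    expect_identical(d1$spectra[[i]]$peaks, d2$spectra[[i]]$peaks)
  }
  d3 <- generate_dataset(12, noise = noise_model(), seed = 32, config = cfg)
  expect_false(identical(d1$spectra[[1]]$peaks, d3$spectra[[1]]$peaks))
})

test_that("recovery does not improve as abundance jitter grows", {
  rates <- vapply(c(0, 0.4, 1.2), function(sd) {
    ds <- generate_dataset(40, noise = noise_model(jitter_sd = sd),
                           seed = 77, config = cfg)
    recovery_stats(ds, cfg)$position_pct
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("decoy-only spectra stay unannotated", {
  ds <- generate_dataset(30, mix = c(decoy = 1), noise = noise_model(),
                         seed = 13, config = cfg)
  st <- recovery_stats(ds, cfg)
  expect_gte(st$decoy_unannotated_pct, 90)
})

test_that("degenerate generator inputs are rejected", {
  expect_error(generate_dataset(0), "positive")
  expect_error(generate_dataset(5, mix = c(acylquinic = 0.5)), "sum to 1")
})
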