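test_that("monoisotopic masses reproduce printed and hand-derived values", {
  # caffeoyl neutral loss prints as 162.03 Da
  expect_equal(round(monoisotopic_mass("C9H6O3"), 2), 162.03)
  expect_equal(round(monoisotopic_mass("C9H6O3"), 4), 162.0317)
  # anhydrohexose, hand-summed from atomic masses
  expect_equal(monoisotopic_mass("C6H10O5"), 162.0528, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(""), 0)
  # typeset underscores are tolerated
  expect_equal(monoisotopic_mass("C_16_H_18_O_9_"),
               monoisotopic_mass("C16H18O9"))
})

test_that("formula parsing rejects unknown symbols and names them", {
  expect_error(parse_formula("C6H12Xx2"), "Xx")
  expect_error(monoisotopic_mass("C2Zz"), "Zz")
})

test_that("deprotonated and dimer adduct m/z match published windows", {
  expect_equal(round(deprotonated_mz("C37H34O19"), 4), 781.1622)
  expect_equal(round(deprotonated_mz("C33H28O17"), 4), 695.1254)
  expect_equal(round(dimer_mz("C16H18O9"), 3), 707.183)
  # hand-derived brute-force value; printed dimers for this species are
  # measured and scatter around it
  expect_equal(round(dimer_mz("C25H24O12"), 4), 1031.2463)
  # definitional identities
  for (f in c("C16H18O9", "C6H12O6", "C10H8O3")) {
    expect_equal(deprotonated_mz(f) + proton_mass(), monoisotopic_mass(f))
    expect_equal(dimer_mz(f) - deprotonated_mz(f), monoisotopic_mass(f))
  }
  expect_error(deprotonated_mz("C6O6"), "hydrogen")
  expect_error(dimer_mz("C2O4"), "hydrogen")
})

test_that("ppm windows reproduce the published 5-ppm EIC bounds", {
  w1 <- ppm_window(353.0867, 5)
  expect_equal(round(unname(w1[["lower"]]), 4), 353.0849)
  expect_equal(round(unname(w1[["upper"]]), 4), 353.0885)
  w2 <- ppm_window(515.1189, 5)
  expect_equal(round(unname(w2[["lower"]]), 4), 515.1163)
  expect_equal(round(unname(w2[["upper"]]), 4), 515.1215)
  w0 <- ppm_window(200.1, 0)
  expect_equal(unname(w0[["lower"]]), unname(w0[["upper"]]))
  expect_error(ppm_window(-1, 5), "positive")
})

test_that("ppm error is signed and exact on the window edges", {
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(round(ppm_error(353.0880, 353.0878), 2), 0.57)
  expect_equal(round(ppm_error(781.1583, 781.1622), 2), -4.99)
  expect_error(ppm_error(100, 0), "positive")
  # window edge maps back to +/- tol exactly
  for (c0 in c(100.05, 353.0867, 857.1571)) {
    w <- ppm_window(c0, 5)
    expect_equal(ppm_error(unname(w[["upper"]]), c0), 5, tolerance = 1e-9)
    expect_equal(ppm_error(unname(w[["lower"]]), c0), -5, tolerance = 1e-9)
    expect_equal((w[["upper"]] - c0) / c0, (c0 - w[["lower"]]) / c0,
                 tolerance = 1e-12)
  }
})

test_that("neutral losses identify registry residues with tie-breaking", {
  expect_equal(neutral_loss(515.1196, 353.0879), 162.0317, tolerance = 1e-4)
  acyls <- acyl_registry()
  expect_identical(identify_loss(515.1196 - 353.0879, acyls), "caffeoyl")
  sugars <- sugar_registry()$sugars
  expect_identical(identify_loss(324.106, sugars), "di-hexose")
  esters <- ester_registry()
  expect_identical(identify_loss(86.037, esters), "hydroxybutanyl")
  expect_true(is.na(identify_loss(55.5, acyls)))
  # tie broken by smallest absolute error
  reg <- data.frame(name = c("a", "b"), loss_mass = c(100.000, 100.004))
  expect_identical(identify_loss(100.003, reg), "b")
  expect_error(neutral_loss(100, 200), "smaller")
})

test_that("masses agree with an independent per-atom summation oracle", {
  set.seed(42)
  for (i in 1:100) {
    f <- random_formula()
    expect_equal(monoisotopic_mass(f), oracle_mass(f), tolerance = 1e-6)
  }
})

test_that("mass is additive over disjoint element-count union", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_formula()
    b <- random_formula()
    expect_equal(monoisotopic_mass(formula_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
  }
  expect_equal(monoisotopic_mass(formula_subtract("C16H18O9", "C9H6O3")),
               monoisotopic_mass("C7H12O6"), tolerance = 1e-9)
  expect_error(formula_subtract("C2H4", "C3H4"), "negative")
})
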