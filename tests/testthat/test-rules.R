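cfg <- derep_config()

test_that("backbone recognition separates quinic from hexaric series", {
  spectra <- read_aqa_fixtures()
  bb <- detect_backbone(spectra[[7]], cfg)
  expect_identical(bb$name, "quinic")
  expect_gte(nrow(bb$matches), 3)
  hx <- detect_backbone(mono_cha_spectrum(), cfg)
  expect_identical(hx$name, "hexaric")
  expect_null(detect_backbone(white_noise_spectrum(), cfg))
})

test_that("acyl markers identify candidate residues", {
  spectra <- read_aqa_fixtures()
  expect_true("caffeoyl" %in% detect_acyls(spectra[[4]], cfg)$name)
  cand6 <- detect_acyls(spectra[[6]], cfg)
  expect_true("p-coumaroyl" %in% cand6$name)
  expect_true(any(cand6$marker_role == "acid anion" &
                    cand6$name == "p-coumaroyl"))
  expect_equal(nrow(detect_acyls(white_noise_spectrum(), cfg)), 0)
})

test_that("loss ladders count sequential residue departures", {
  tetra <- count_acyl_losses(tetra_cha_spectrum(), "caffeoyl", cfg)
  expect_equal(tetra$count, 4)
  expect_equal(tetra$chain$mz,
               c(857.1571, 695.1254, 533.0937, 371.0620, 209.0303),
               tolerance = 1e-3)
  leo <- count_acyl_losses(leontopodic_a_spectrum(), "caffeoyl", cfg)
  expect_equal(leo$count, 3)
  single <- msms_spectrum("s", 353.0878,
                          data.frame(mz = 353.0878, abundance = 100))
  expect_equal(count_acyl_losses(single, "caffeoyl", cfg)$count, 0)
})

test_that("monoacyl base-peak key assigns 3/4/5 as in the worked examples", {
  spectra <- read_aqa_fixtures()
  # neochlorogenic pattern: base 191.055 with prominent caffeic acid ions
  r4 <- assign_quinic_regiochemistry(spectra[[4]], "caffeoyl", cfg)
  expect_length(r4$assignments, 1)
  expect_identical(r4$assignments[[1]]$position, "3")
  # chlorogenic pattern: base 191.055 with negligible acid ions
  r7 <- assign_quinic_regiochemistry(spectra[[7]], "caffeoyl", cfg)
  expect_identical(r7$assignments[[1]]$position, "5")
  # 4-substitution: base at the dehydrated quinate 173.044
  r5 <- assign_quinic_regiochemistry(spectra[[5]], "caffeoyl", cfg)
  expect_identical(r5$assignments[[1]]$position, "4")
})

test_that("diacyl order follows the loss-ion abundances with a ratio gate", {
  spectra <- read_aqa_fixtures()
  # compound 34: [M-H-caffeoyl]- 68.1% vs [M-H-p-coumaroyl]- 2.4%
  o34 <- assign_diacyl_order(spectra[[34]], c("caffeoyl", "p-coumaroyl"), cfg)
  expect_false(o34$ambiguous)
  expect_identical(o34$orders[[1]][["first"]], "caffeoyl")
  o28 <- assign_diacyl_order(spectra[[28]], c("caffeoyl", "p-coumaroyl"), cfg)
  expect_false(o28$ambiguous)
  expect_identical(o28$orders[[1]][["first"]], "caffeoyl")
  # equal loss-ion abundances cannot be ordered
  eq <- msms_spectrum("eq", 499.1246, data.frame(
    mz = c(499.1246, 353.0883, 337.0934, 191.0561, 173.0455, 179.0350,
           163.0401, 135.0452, 119.0503),
    abundance = c(30, 40, 40, 100, 10, 30, 30, 20, 15)))
  oe <- assign_diacyl_order(eq, c("caffeoyl", "p-coumaroyl"), cfg)
  expect_true(oe$ambiguous)
  expect_length(oe$orders, 2)
})

test_that("full diacyl assignments reproduce the published calls", {
  spectra <- read_aqa_fixtures()
  r34 <- annotate(spectra[[34]], cfg)
  expect_identical(r34$name, "4-p-coumaroyl-5-caffeoylquinic acid")
  r28 <- annotate(spectra[[28]], cfg)
  expect_identical(r28$name, "3-p-coumaroyl-5-caffeoylquinic acid")
  r22 <- annotate(spectra[[22]], cfg)
  expect_identical(r22$class, "acylquinic acid")
  expect_identical(r22$acyls, c("caffeoyl", "caffeoyl"))
  expect_true(assignment_contains(
    r22, expected_assignment(c(3, 5), c("caffeoyl", "caffeoyl"))))
})

test_that("hexaric substituents resolve the leontopodic-type esters", {
  leo <- assign_hexaric_substituents(leontopodic_a_spectrum(), cfg)
  expect_equal(leo$caffeoyl_count, 3)
  expect_identical(leo$substituents, "hydroxybutanyl")
  expect_identical(leo$name, "hydroxybutanyl-tricaffeoylhexaric acid")
  hb <- assign_hexaric_substituents(hydroxybenzoyl_cha_spectrum(), cfg)
  expect_equal(hb$caffeoyl_count, 3)
  expect_identical(hb$substituents, "hydroxybenzoyl")
  expect_true(any(hb$evidence$rule == "hexaric/ester-marker"))
  tet <- assign_hexaric_substituents(tetra_cha_spectrum(), cfg)
  expect_equal(tet$caffeoyl_count, 4)
  expect_length(tet$substituents, 0)
  # unmatched residual is reported, not guessed
  odd <- msms_spectrum("odd", 209.0303 + 162.0317 + 55.5, data.frame(
    mz = c(209.0303 + 162.0317 + 55.5, 209.0303, 191.0197, 173.0092,
           147.0299, 179.0350),
    abundance = c(20, 70, 100, 18, 25, 30)))
  ro <- assign_hexaric_substituents(odd, cfg)
  expect_false(ro$resolved)
  expect_match(ro$substituents, "^unknown\\(")
})

test_that("glycoside logic resolves aglycone, sugar and linkage", {
  q <- spectrum_from("qh", 463.0882, c(463.0882, 301.0354), c(15, 100))
  g <- assign_glycoside(q, cfg)
  expect_identical(g$aglycone, "quercetin")
  expect_identical(g$sugar, "hexose")
  expect_identical(g$linkage, "O-glycoside")
  # myricetin acetylhexoside: concomitant hexose + acetyl loss (204.063)
  m <- spectrum_from("acet", 521.0937, c(521.0937, 317.0303), c(15, 100))
  gm <- assign_glycoside(m, cfg)
  expect_identical(gm$aglycone, "myricetin")
  expect_identical(gm$sugar, "acetylhexose")
  # sugar ester: two or more cross-ring cleavages (-60/-90/-120)
  se <- spectrum_from("ester", 299.0772,
                      c(299.0772, 239.0561, 209.0455, 179.0350, 137.0244),
                      c(20, 25, 30, 40, 100))
  gs <- assign_glycoside(se, cfg)
  expect_identical(gs$linkage, "sugar ester")
  expect_identical(gs$aglycone, "hydroxybenzoic acid")
  # isobaric flavone aglycones stay either/or without a prior
  l <- spectrum_from("lh", 447.0933, c(447.0933, 285.0405), c(15, 100))
  expect_identical(assign_glycoside(l, cfg)$aglycone, "luteolin/kaempferol")
  # caffeoyl-ester glycoside: loss of 324.085 to the apigenin anion
  a <- spectrum_from("caffgly", 593.1300,
                     c(593.1300, 431.0983, 269.0455, 179.0350, 161.0244,
                       135.0452),
                     c(15, 35, 100, 30, 10, 22))
  ga <- assign_glycoside(a, cfg)
  expect_identical(ga$aglycone, "apigenin")
  expect_identical(ga$sugar, "caffeoylhexose")
  # sugar loss without a recognisable aglycone
  u <- spectrum_from("ug", 400.10, c(400.10, 238.0472), c(20, 100))
  gu <- assign_glycoside(u, cfg)
  expect_true(is.na(gu$aglycone))
  expect_identical(gu$sugar, "hexose")
})

test_that("retention-time priors resolve isobaric aglycones when supplied", {
  pri <- data.frame(name = c("luteolin", "kaempferol"),
                    rt_min = c(10, 12), rt_max = c(11, 13))
  cfg_rt <- derep_config(rt_priors = pri)
  l <- msms_spectrum("lh", 447.0933,
                     data.frame(mz = c(447.0933, 285.0405),
                                abundance = c(15, 100)), rt = 10.5)
  expect_identical(assign_glycoside(l, cfg_rt)$aglycone, "luteolin")
})

test_that("annotate dispatches across all branches and never raises", {
  spectra <- read_aqa_fixtures()
  r22 <- annotate(spectra[[22]], cfg)
  expect_identical(r22$class, "acylquinic acid")
  r54 <- annotate(leontopodic_a_spectrum(), cfg)
  expect_identical(r54$class, "caffeoylhexaric acid")
  expect_true("leontopodic A-type" %in% r54$notes)
  rn <- annotate(white_noise_spectrum(), cfg)
  expect_identical(rn$class, "unannotated")
  expect_identical(rn$confidence, "E")
  expect_gt(length(rn$notes), 0)
})

test_that("confidence grading follows the six-level scheme", {
  spectra <- read_aqa_fixtures()
  # chlorogenic acid: standard with confirmed stereochemistry
  expect_identical(annotate(spectra[[7]], cfg)$confidence, "A2")
  # 3-feruloylquinic acid: resolved positions, no standard
  expect_identical(annotate(spectra[[10]], cfg)$confidence, "D1")
  # ambiguous 1- vs 3- hydroxydihydrocaffeoyl isomer
  expect_identical(annotate(spectra[[1]], cfg)$confidence, "D2")
  # policy B applies to standards without stereo confirmation
  r54 <- annotate(leontopodic_a_spectrum(), cfg)
  expect_identical(r54$confidence, "C")
  std <- standards_registry()
  expect_identical(assign_confidence(r54, std, policy = "B"), "B")
  expect_identical(assign_confidence(r54, std, stereo_confirmed = TRUE), "A2")
})

test_that("every positional claim is backed by evidence entries", {
  spectra <- read_aqa_fixtures()
  results <- lapply(spectra, annotate, config = cfg)
  for (r in results) {
    expect_gt(nrow(r$evidence), 0)
    if (length(r$assignments)) {
      expect_true(any(grepl("^regio/", r$evidence$rule)))
      expect_true(any(grepl("^backbone/", r$evidence$rule)))
    }
    if (length(r$acyls)) {
      expect_true(any(grepl("^acyl/", r$evidence$rule)))
    }
  }
})

test_that("removing a diagnostic peak never makes the result more specific", {
  spec_level <- function(r) {
    if (r$class %in% c("unannotated", "unknown glycoside")) return(0L)
    if (length(r$acyls) == 0L) return(1L)
    if (length(r$assignments) == 1L &&
        all(grepl("^[0-9]+$", r$assignments[[1]]$position))) return(3L)
    2L
  }
  spectra <- read_aqa_fixtures()
  for (idx in c(4, 7, 34)) {
    sp <- spectra[[idx]]
    full <- spec_level(annotate(sp, cfg))
    for (drop in seq_len(nrow(sp$peaks))) {
      reduced <- sp
      reduced$peaks <- sp$peaks[-drop, , drop = FALSE]
      if (nrow(reduced$peaks) == 0L) next
      reduced <- normalize_spectrum(reduced)
      expect_lte(spec_level(annotate(reduced, cfg)), full)
    }
  }
})

test_that("annotation is deterministic", {
  spectra <- read_aqa_fixtures()
  a <- annotate_spectra(spectra, cfg)
  b <- annotate_spectra(spectra, cfg)
  attr(a, "results") <- NULL
  attr(b, "results") <- NULL
  expect_identical(a, b)
})

test_that("literature names parse into composition and positions", {
  p <- parse_compound_name("4-p-coumaroyl-5-caffeoylquinic acid")
  expect_identical(p$acyls, c("caffeoyl", "p-coumaroyl"))
  expect_identical(p$positions, c(4L, 5L))
  p2 <- parse_compound_name("3,4,5-tricaffeoylquinic acid")
  expect_identical(p2$acyls, rep("caffeoyl", 3))
  expect_identical(p2$positions, c(3L, 4L, 5L))
  p3 <- parse_compound_name("chlorogenic acid")
  expect_identical(p3$positions, 5L)
  p4 <- parse_compound_name("4-caffeoylquinic acid 2")
  expect_identical(p4$positions, 4L)
  p5 <- parse_compound_name("5-hydroxy-dihydrocaffeoylquinic acid")
  expect_identical(p5$acyls, "hydroxydihydrocaffeoyl")
})
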