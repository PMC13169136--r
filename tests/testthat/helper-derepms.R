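# Shared fixtures: the Table-1 acylquinic peak lists ship as a TSV; the
# caffeoylhexaric and glycoside worked examples are reconstructed here from
# their published fragment ladders (synthetic abundances).

aqa_fixture_path <- function() {
  system.file("extdata", "table1_aqa.tsv", package = "derepms")
}

read_aqa_fixtures <- function() {
  suppressWarnings(read_spectra(aqa_fixture_path(), format = "tsv"))
}

spectrum_from <- function(id, precursor, mz, abundance) {
  msms_spectrum(id, precursor, data.frame(mz = mz, abundance = abundance))
}

# leontopodic acid A pattern: three sequential caffeoyl losses ending on the
# hydroxybutanyl terminus at 295.067, then the hexarate series
leontopodic_a_spectrum <- function() {
  spectrum_from(
    "leontopodicA", 781.1622,
    mz = c(781.1622, 619.1305, 457.0988, 295.0671, 209.0303, 191.0197,
           173.0092, 147.0299, 129.0193, 111.0088, 85.0295,
           179.0350, 161.0244, 135.0452),
    abundance = c(25, 30, 45, 60, 70, 100, 18, 25, 14, 9, 8, 30, 12, 25))
}

tetra_cha_spectrum <- function() {
  spectrum_from(
    "tetraCHA", 857.1571,
    mz = c(857.1571, 695.1254, 533.0937, 371.0620, 209.0303, 191.0197,
           147.0299, 129.0193, 179.0350, 135.0452),
    abundance = c(20, 30, 45, 60, 70, 100, 25, 14, 30, 25))
}

hydroxybenzoyl_cha_spectrum <- function() {
  spectrum_from(
    "hb-triCHA", 815.1465,
    mz = c(815.1465, 653.1148, 491.0831, 329.0514, 209.0303, 191.0197,
           147.0299, 137.0244, 93.0346, 179.0350, 135.0452),
    abundance = c(20, 30, 45, 60, 70, 100, 25, 35, 20, 30, 25))
}

# hexaric backbone series alone (monoCHA-style, compound-40 pattern)
mono_cha_spectrum <- function() {
  spectrum_from(
    "monoCHA", 371.0620,
    mz = c(371.0620, 209.0303, 191.0197, 173.0092, 147.0299, 129.0193,
           111.0088, 179.0350, 135.0452),
    abundance = c(30, 70, 100, 18, 25, 14, 9, 35, 25))
}

white_noise_spectrum <- function() {
  spectrum_from("noise", 441.20,
                mz = c(402.11, 350.31, 222.21, 123.41, 99.12),
                abundance = c(10, 30, 100, 20, 5))
}

# independent per-atom mass oracle: expands the formula into an atom list
# and sums one atom at a time, with its own constants table
oracle_mass <- function(formula) {
  masses <- c(C = 12.000000, H = 1.00782503, O = 15.9949146, N = 14.0030740)
  s <- gsub("_", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  total <- 0
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    for (i in seq_len(n)) total <- total + masses[[sym]]
  }
  total
}

random_formula <- function() {
  paste0("C", sample(0:60, 1), "H", sample(0:80, 1), "O", sample(0:30, 1),
         "N", sample(0:5, 1))
}

# does some candidate assignment place every expected (position, residue)
# pair, counting an ambiguous label like "3(or 1)" as any digit it contains?
assignment_contains <- function(result, expected) {
  any(vapply(result$assignments, function(a) {
    if (nrow(a) != nrow(expected)) return(FALSE)
    used <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(expected))) {
      ok <- which(!used & a$residue == expected$residue[i] &
                    vapply(a$position, function(lbl)
                      as.character(expected$position[i]) %in%
                        regmatches(lbl, gregexpr("[0-9]", lbl))[[1]],
                      logical(1)))
      if (length(ok) == 0L) return(FALSE)
      used[ok[1]] <- TRUE
    }
    TRUE
  }, logical(1)))
}

expected_assignment <- function(positions, residues) {
  data.frame(position = as.character(positions), residue = residues,
             stringsAsFactors = FALSE)
}
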