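# Exact-mass arithmetic for singly deprotonated negative-ion ESI.
#
# Convention: ion m/z = neutral monoisotopic mass - proton mass (1.00727646 Da).
# No electron-mass bookkeeping; this reproduces printed calculated values for
# [M-H]- and [2M-H]- ions of phenolic metabolites to 4 decimal places.

#' Monoisotopic atomic masses used throughout the package
#'
#' CODATA/IUPAC monoisotopic masses of the light elements found in plant
#' phenolics, plus the proton mass used for deprotonated-adduct arithmetic.
#'
#' @format Named numeric vector of atomic masses in Da, with the proton mass
#'   stored separately in `attr(, "proton")`.
#' @export
mass_constants <- local({
  m <- c(
    C = 12.000000,
    H = 1.00782503,
    O = 15.9949146,
    N = 14.0030740,
    S = 31.97207117,
    P = 30.97376200
  )
  attr(m, "proton") <- 1.00727646
  m
})

#' Proton monoisotopic mass (Da)
#' @return Numeric scalar, 1.00727646.
#' @export
proton_mass <- function() attr(mass_constants, "proton")

#' Parse a molecular formula in Hill notation
#'
#' Accepts strings such as `"C16H18O9"`. Underscores are stripped first, so
#' the typeset form `"C_16_H_18_O_9_"` found in tables is accepted as well.
#' Unknown element symbols are rejected with the offending symbol named.
#'
#' @param x Formula string, or an already-parsed `elemental_formula`.
#' @return Named integer vector of element counts, class `elemental_formula`.
#' @examples
#' parse_formula("C9H6O3")
#' parse_formula("C_16_H_18_O_9_")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("_", "", x, fixed = TRUE)
  s <- gsub("[[:space:]]", "", s)
  counts <- integer(0)
  if (nzchar(s)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    tokens <- regmatches(s, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(s)) {
      stop("cannot parse formula: '", x, "'", call. = FALSE)
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!sym %in% names(mass_constants)) {
        stop("unknown element symbol '", sym, "' in formula '", x, "'",
             call. = FALSE)
      }
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    }
  }
  structure(counts, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  ord <- c("C", "H", setdiff(sort(names(x)), c("C", "H")))
  ord <- ord[ord %in% names(x)]
  paste0(vapply(ord, function(el) {
    n <- x[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Combine two elemental formulas by element-wise count addition
#'
#' @param a,b Formula strings or `elemental_formula` objects.
#' @return An `elemental_formula` whose counts are the sums.
#' @export
formula_add <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) +
      (if (el %in% names(b)) b[[el]] else 0L)
  }, integer(1))
  structure(out, class = "elemental_formula")
}

#' Subtract one elemental formula from another
#'
#' @param a,b Formula strings or `elemental_formula` objects; `b` must be a
#'   sub-formula of `a`.
#' @return An `elemental_formula` of the difference.
#' @export
formula_subtract <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  for (el in names(b)) {
    have <- if (el %in% names(a)) a[[el]] else 0L
    if (have < b[[el]]) {
      stop("formula subtraction would give negative ", el, " count",
           call. = FALSE)
    }
    a[el] <- have - b[[el]]
  }
  out <- unclass(a)
  structure(out[out > 0L], class = "elemental_formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or `elemental_formula`.
#' @return Neutral monoisotopic mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C9H6O3")   # caffeoyl neutral loss, 162.0317
#' monoisotopic_mass("C6H10O5")  # anhydrohexose, 162.0528
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  if (length(f) == 0L) return(0)
  sum(mass_constants[names(f)] * as.numeric(f))
}

#' m/z of the deprotonated molecular ion [M-H]-
#'
#' @param formula Formula of the neutral molecule; must contain hydrogen.
#' @return m/z of the singly deprotonated anion.
#' @examples
#' deprotonated_mz("C16H18O9")  # chlorogenic acid, 353.0878
#' @export
deprotonated_mz <- function(formula) {
  f <- parse_formula(formula)
  if (!("H" %in% names(f)) || f[["H"]] < 1L) {
    stop("cannot deprotonate a hydrogen-free formula: '",
         format(f), "'", call. = FALSE)
  }
  monoisotopic_mass(f) - proton_mass()
}

#' m/z of the proton-bound dimer [2M-H]-
#'
#' @param formula Formula of the neutral molecule; must contain hydrogen.
#' @return m/z of the dimeric deprotonated adduct, 2M - proton.
#' @examples
#' dimer_mz("C16H18O9")  # 707.183 for chlorogenic acid
#' @export
dimer_mz <- function(formula) {
  f <- parse_formula(formula)
  if (!("H" %in% names(f)) || f[["H"]] < 1L) {
    stop("cannot deprotonate a hydrogen-free formula: '",
         format(f), "'", call. = FALSE)
  }
  2 * monoisotopic_mass(f) - proton_mass()
}

#' Symmetric ppm mass window around a centre m/z
#'
#' The window used for extracted-ion matching: multiplicatively symmetric,
#' `centre * (1 +/- tol * 1e-6)`.
#'
#' @param center Centre m/z (> 0).
#' @param tolerance Tolerance in ppm (>= 0).
#' @return Object of class `mass_window`: numeric `c(lower, upper)`.
#' @examples
#' ppm_window(353.0867, 5)  # 353.0849 - 353.0885
#' @export
ppm_window <- function(center, tolerance) {
  stopifnot(is.numeric(center), is.numeric(tolerance), tolerance >= 0)
  if (center <= 0) stop("window centre must be positive", call. = FALSE)
  structure(c(lower = center * (1 - tolerance * 1e-6),
              upper = center * (1 + tolerance * 1e-6)),
            center = center, ppm = tolerance, class = "mass_window")
}

#' @export
print.mass_window <- function(x, ...) {
  cat(sprintf("<mass window> %.4f - %.4f (%.4g ppm around %.4f)\n",
              x[["lower"]], x[["upper"]], attr(x, "ppm"), attr(x, "center")))
  invisible(x)
}

#' Signed relative mass error in parts per million
#'
#' @param measured Measured m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(measured - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  (measured - theoretical) / theoretical * 1e6
}

#' Neutral-loss mass between a precursor and a fragment
#'
#' @param precursor,fragment m/z values; the precursor must be the heavier.
#' @return Loss in Da.
#' @export
neutral_loss <- function(precursor, fragment) {
  if (any(fragment >= precursor)) {
    stop("fragment m/z must be smaller than the precursor m/z", call. = FALSE)
  }
  precursor - fragment
}

#' Identify a neutral-loss mass against a residue registry
#'
#' @param delta Observed loss in Da.
#' @param registry Data frame with columns `name` and `loss_mass` (Da), such
#'   as produced by [acyl_registry()] or [sugar_registry()].
#' @param tolerance_mda Absolute matching tolerance in mDa (default 10).
#' @return The matching residue name (ties broken by smallest absolute
#'   error), or `NA_character_` when nothing is in tolerance.
#' @export
identify_loss <- function(delta, registry, tolerance_mda = 10) {
  stopifnot(is.data.frame(registry),
            all(c("name", "loss_mass") %in% names(registry)))
  err <- abs(registry$loss_mass - delta)
  ok <- which(err <= tolerance_mda / 1000)
  if (length(ok) == 0L) return(NA_character_)
  registry$name[ok[which.min(err[ok])]]
}

# Round half away from zero at `digits` decimals, the convention used when
# comparing against printed values (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
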