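# Editable rule registries: acyl residues, sugars, aglycones, backbone
# signatures, hexaric ester substituents, authentic standards. Shipped as
# YAML under inst/extdata/registries/; every loader accepts an alternate
# path so the rule base can be swapped without touching code. Marker and
# loss m/z are computed from formulas at load time so a registry edit only
# has to state chemistry, never arithmetic.

registry_file <- function(name, dir = NULL) {
  if (is.null(dir)) {
    path <- system.file("extdata", "registries", name, package = "derepms")
  } else {
    path <- file.path(dir, name)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("registry file not found: ", name, call. = FALSE)
  }
  path
}

marker_mz <- function(marker) {
  if (!is.null(marker$mz)) as.numeric(marker$mz)
  else deprotonated_mz(marker$formula)
}

#' Load the acyl-residue registry
#'
#' Each residue carries its neutral-loss formula, its free-acid formula
#' (whose deprotonated anion is the primary marker) and secondary marker
#' ions, plus the backbone context in which it applies.
#'
#' @param path Optional path to an alternate YAML registry directory.
#' @return Data frame with columns `name`, `loss_formula`, `acid_formula`,
#'   `loss_mass`, `acid_anion_mz`, `context`, and a list column `markers`
#'   of data frames (`role`, `mz`).
#' @export
acyl_registry <- function(path = NULL) {
  raw <- yaml::read_yaml(registry_file("acyl_residues.yaml", path))$residues
  out <- data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    loss_formula = vapply(raw, `[[`, character(1), "loss_formula"),
    acid_formula = vapply(raw, `[[`, character(1), "acid_formula"),
    context = vapply(raw, function(r) r$context %||% "any", character(1)),
    stringsAsFactors = FALSE
  )
  out$loss_mass <- vapply(out$loss_formula, monoisotopic_mass, numeric(1))
  out$acid_anion_mz <- vapply(out$acid_formula, deprotonated_mz, numeric(1))
  out$markers <- lapply(raw, function(r) {
    ms <- r$markers %||% list()
    data.frame(
      role = vapply(ms, `[[`, character(1), "role"),
      mz = vapply(ms, marker_mz, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out
}

#' Load the sugar-loss registry
#'
#' @inheritParams acyl_registry
#' @return List with `sugars` (data frame: `name`, `loss_formula`,
#'   `loss_mass`) and `cross_ring` (same columns) for the hexose cross-ring
#'   cleavages (-60/-90/-120 Da).
#' @export
sugar_registry <- function(path = NULL) {
  raw <- yaml::read_yaml(registry_file("sugars.yaml", path))
  as_loss_df <- function(entries) {
    df <- data.frame(
      name = vapply(entries, `[[`, character(1), "name"),
      loss_formula = vapply(entries, `[[`, character(1), "loss_formula"),
      stringsAsFactors = FALSE
    )
    df$loss_mass <- vapply(df$loss_formula, monoisotopic_mass, numeric(1))
    df
  }
  list(sugars = as_loss_df(raw$sugars), cross_ring = as_loss_df(raw$cross_ring))
}

#' Load the aglycone registry
#'
#' @inheritParams acyl_registry
#' @return Data frame with `name`, `formula`, `type` ("flavonoid" or
#'   "phenolic acid") and `anion_mz` (the deprotonated aglycone).
#' @export
aglycone_registry <- function(path = NULL) {
  raw <- yaml::read_yaml(registry_file("aglycones.yaml", path))$aglycones
  out <- data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    formula = vapply(raw, `[[`, character(1), "formula"),
    type = vapply(raw, `[[`, character(1), "type"),
    stringsAsFactors = FALSE
  )
  out$anion_mz <- vapply(out$formula, deprotonated_mz, numeric(1))
  out
}

#' Load the backbone signature registry
#'
#' @inheritParams acyl_registry
#' @return Named list (by backbone) with `anion_mz` and a data frame
#'   `series` of diagnostic ions (`mz`, `role`).
#' @export
backbone_registry <- function(path = NULL) {
  raw <- yaml::read_yaml(registry_file("backbones.yaml", path))$backbones
  out <- lapply(raw, function(b) {
    series <- data.frame(
      mz = vapply(b$series, function(s) {
        if (!is.null(s$mz)) as.numeric(s$mz) else deprotonated_mz(s$formula)
      }, numeric(1)),
      role = vapply(b$series, `[[`, character(1), "role"),
      stringsAsFactors = FALSE
    )
    list(name = b$name, anion_mz = deprotonated_mz(b$anion_formula),
         series = series)
  })
  names(out) <- vapply(raw, `[[`, character(1), "name")
  out
}

#' Load the hexaric ester-substituent registry
#'
#' @inheritParams acyl_registry
#' @return Data frame with `name`, `acid_formula`, `acid_mass`,
#'   `loss_mass` (anhydro, acid - H2O) and list column `markers`.
#' @export
ester_registry <- function(path = NULL) {
  raw <- yaml::read_yaml(registry_file("hexaric_esters.yaml", path))$esters
  out <- data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    acid_formula = vapply(raw, `[[`, character(1), "acid_formula"),
    stringsAsFactors = FALSE
  )
  out$acid_mass <- vapply(out$acid_formula, monoisotopic_mass, numeric(1))
  out$loss_mass <- out$acid_mass - monoisotopic_mass("H2O")
  out$markers <- lapply(raw, function(r) {
    ms <- r$markers %||% list()
    data.frame(
      role = vapply(ms, `[[`, character(1), "role"),
      mz = vapply(ms, marker_mz, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out
}

#' Load the authentic-standards registry
#'
#' @inheritParams acyl_registry
#' @return Data frame with `name`, list column `synonyms`, and logical
#'   `stereo` (whether the standard comparison confirms stereochemistry).
#' @export
standards_registry <- function(path = NULL) {
  raw <- yaml::read_yaml(registry_file("standards.yaml", path))$standards
  data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    stereo = vapply(raw, function(s) isTRUE(s$stereo), logical(1)),
    stringsAsFactors = FALSE
  ) -> out
  out$synonyms <- lapply(raw, function(s) as.character(s$synonyms %||% character(0)))
  out
}

standards_match <- function(name, standards) {
  if (is.null(standards) || is.na(name)) return(NULL)
  for (i in seq_len(nrow(standards))) {
    if (identical(name, standards$name[i]) ||
        name %in% standards$synonyms[[i]]) {
      return(list(name = standards$name[i], stereo = standards$stereo[i]))
    }
  }
  NULL
}

`%||%` <- function(x, y) if (is.null(x)) y else x
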