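# Hierarchical dereplication keys for negative-mode MS/MS of plant phenolics.
#
# Dispatch: backbone recognition (quinic vs hexaric diagnostic-ion series)
# -> acyl detection and composition by neutral-loss arithmetic -> base-peak
# regiochemistry and diacyl ordering (quinic) or caffeoyl-loss ladders and
# ester substituents (hexaric) -> glycoside logic for everything else ->
# confidence grading. Every claim carries at least one evidence entry
# (a fired rule plus the matched peak).

#' Annotation engine configuration
#'
#' @param tol_mda MS2 fragment-matching tolerance, absolute mDa. Default 10:
#'   printed MS2 values from the modelled instrument sit a few ppm below
#'   theory, so an absolute window is more robust than ppm at low m/z.
#' @param ms1_ppm MS1 (extracted-ion) tolerance in ppm, default 5.
#' @param composition_tol_mda Tolerance for whole-composition neutral-loss
#'   arithmetic (precursor minus backbone anion against a sum of residue
#'   losses); slightly wider than `tol_mda` because precursor and theory
#'   errors accumulate.
#' @param prominence Relative abundance (% of base peak) at and above which a
#'   secondary acid marker counts as "prominent" (default 20).
#' @param negligible Relative abundance at and below which an ion counts as
#'   "negligible" (default 5).
#' @param order_ratio Minimum fold-ratio between the two [M-H-acyl]- ions
#'   required to call the acylation order of a mixed diacyl (default 3);
#'   below it both orders are reported.
#' @param standard_policy Confidence grade for a standard match without
#'   stereochemical confirmation: `"C"` (default) or `"B"`.
#' @param registry_dir Optional directory of alternate YAML registries.
#' @param rt_priors Optional data frame (`name`, `rt_min`, `rt_max`) used to
#'   resolve isobaric aglycones by retention time.
#' @return List of settings plus loaded registries, class `derep_config`.
#' @export
derep_config <- function(tol_mda = 10, ms1_ppm = 5, composition_tol_mda = 15,
                         prominence = 20, negligible = 5, order_ratio = 3,
                         standard_policy = c("C", "B"),
                         registry_dir = NULL, rt_priors = NULL) {
  stopifnot(tol_mda > 0, ms1_ppm > 0, composition_tol_mda > 0,
            prominence > 0, prominence < 100,
            negligible >= 0, negligible < 100, order_ratio >= 1)
  structure(list(
    tol_mda = tol_mda, ms1_ppm = ms1_ppm,
    composition_tol_mda = composition_tol_mda,
    prominence = prominence, negligible = negligible,
    order_ratio = order_ratio,
    standard_policy = match.arg(standard_policy),
    rt_priors = rt_priors,
    registries = list(
      acyls = acyl_registry(registry_dir),
      sugars = sugar_registry(registry_dir),
      aglycones = aglycone_registry(registry_dir),
      backbones = backbone_registry(registry_dir),
      esters = ester_registry(registry_dir),
      standards = standards_registry(registry_dir)
    )
  ), class = "derep_config")
}

evidence_row <- function(rule, detail, mz = NA_real_, abundance = NA_real_) {
  data.frame(rule = rule, detail = detail, mz = mz, abundance = abundance,
             stringsAsFactors = FALSE)
}

caffeoyl_loss_mass <- function() monoisotopic_mass("C9H6O3")

# ------------------------------------------------------------- backbone ----

#' Recognise the backbone from its diagnostic-ion series
#'
#' A backbone is called when at least three ions of its signature series
#' match at the MS2 tolerance; quinic vs hexaric is separated by 191.056 vs
#' 191.020 (36 mDa apart, unambiguous at the 10 mDa default).
#'
#' @param x An `msms_spectrum`.
#' @param config A [derep_config()].
#' @return List (`name`, `anion_mz`, `matches` data frame) or `NULL`.
#' @export
detect_backbone <- function(x, config = derep_config()) {
  x <- if (x$normalized) x else normalize_spectrum(x)
  best <- NULL
  for (bb in config$registries$backbones) {
    hits <- lapply(seq_len(nrow(bb$series)), function(i) {
      pk <- find_peak(x, bb$series$mz[i], tol_mda = config$tol_mda)
      if (is.null(pk)) return(NULL)
      data.frame(role = bb$series$role[i], target_mz = bb$series$mz[i],
                 mz = pk$mz, abundance = pk$abundance,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
    n <- if (is.null(hits)) 0L else nrow(hits)
    if (n >= 3L) {
      anion_hit <- !is.null(find_peak(x, bb$anion_mz,
                                      tol_mda = config$tol_mda))
      cand <- list(name = bb$name, anion_mz = bb$anion_mz, matches = hits,
                   n = n, anion_hit = anion_hit)
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && cand$anion_hit && !best$anion_hit)) {
        best <- cand
      }
    }
  }
  best
}

# ----------------------------------------------------------------- acyls ----

acyls_for_context <- function(registry, context) {
  registry[registry$context %in% c("any", context), , drop = FALSE]
}

#' Detect candidate acyl residues from their marker ions
#'
#' A residue is a candidate when its acid anion (primary marker) or any
#' secondary marker (decarboxylated, demethylated, ...) is present at the
#' MS2 tolerance. Multiplicity is settled later by loss arithmetic and
#' ladders, not here.
#'
#' @inheritParams detect_backbone
#' @param context Backbone context, `"quinic"` by default (the registry's
#'   context field resolves isobaric markers such as m/z 197.045).
#' @return Data frame (`name`, `marker_role`, `mz`, `abundance`), one row
#'   per matched marker; zero rows when nothing matches.
#' @export
detect_acyls <- function(x, config = derep_config(), context = "quinic") {
  x <- if (x$normalized) x else normalize_spectrum(x)
  reg <- acyls_for_context(config$registries$acyls, context)
  rows <- list()
  for (i in seq_len(nrow(reg))) {
    targets <- rbind(
      data.frame(role = "acid anion", mz = reg$acid_anion_mz[i]),
      reg$markers[[i]][, c("role", "mz")]
    )
    for (j in seq_len(nrow(targets))) {
      pk <- find_peak(x, targets$mz[j], tol_mda = config$tol_mda)
      if (!is.null(pk)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = reg$name[i], marker_role = targets$role[j],
          mz = pk$mz, abundance = pk$abundance, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), marker_role = character(0),
                      mz = numeric(0), abundance = numeric(0)))
  }
  do.call(rbind, rows)
}

# Enumerate multisets of residue losses (sizes 1..max_n) explaining
# `target` Da; returns the best multiset (smallest error, then fewest
# residues) or NULL.
compose_losses <- function(target, losses, tol, max_n = 4L) {
  nms <- names(losses)
  best <- NULL
  recurse <- function(start, chosen, total) {
    if (length(chosen) > 0L) {
      err <- abs(total - target)
      if (err <= tol &&
          (is.null(best) || err < best$err - 1e-12 ||
           (abs(err - best$err) <= 1e-12 && length(chosen) < length(best$set)))) {
        best <<- list(set = chosen, err = err)
      }
    }
    if (length(chosen) >= max_n) return()
    for (i in seq(start, length(losses))) {
      if (total + losses[i] > target + tol) next
      recurse(i, c(chosen, nms[i]), total + losses[i])
    }
  }
  if (length(losses) > 0L) recurse(1L, character(0), 0)
  best
}

compose_acyls <- function(x, anion_mz, candidates, config, context = "quinic") {
  reg <- acyls_for_context(config$registries$acyls, context)
  target <- x$precursor_mz - anion_mz
  tol <- config$composition_tol_mda / 1000
  pick <- function(regsub) {
    losses <- regsub$loss_mass
    names(losses) <- regsub$name
    compose_losses(target, losses, tol)
  }
  cand_names <- unique(candidates$name)
  best <- pick(reg[reg$name %in% cand_names, , drop = FALSE])
  marker_supported <- !is.null(best)
  if (is.null(best)) best <- pick(reg)
  if (is.null(best)) return(NULL)
  list(acyls = sort(best$set), err = best$err,
       marker_supported = marker_supported)
}

#' Count sequential losses of one residue from the precursor
#'
#' Walks the longest chain starting at the precursor in which consecutive
#' members differ by the residue's neutral-loss mass within tolerance; each
#' step re-anchors on the matched peak so measurement errors do not
#' accumulate.
#'
#' @inheritParams detect_backbone
#' @param loss_mass Residue neutral-loss mass in Da (or a residue name
#'   found in the acyl registry).
#' @return List with `count` (chain length minus one) and `chain` (data
#'   frame of the matched fragments, precursor first).
#' @export
count_acyl_losses <- function(x, loss_mass, config = derep_config()) {
  x <- if (x$normalized) x else normalize_spectrum(x)
  if (is.character(loss_mass)) {
    reg <- config$registries$acyls
    i <- match(loss_mass, reg$name)
    if (is.na(i)) stop("unknown residue: ", loss_mass, call. = FALSE)
    loss_mass <- reg$loss_mass[i]
  }
  chain <- data.frame(mz = x$precursor_mz, abundance = NA_real_)
  cur <- x$precursor_mz
  repeat {
    pk <- find_peak(x, cur - loss_mass, tol_mda = config$tol_mda)
    if (is.null(pk)) break
    chain <- rbind(chain, pk)
    cur <- pk$mz
  }
  list(count = nrow(chain) - 1L, chain = chain)
}

# ------------------------------------------------------ quinic regiochem ----

# Diagnostic-ion table for the regio key: quinic backbone ions plus the
# composition residues' acid anions and secondary markers. The regio "base
# peak" is read over this set (the global base peak may be the surviving
# precursor ion, which carries no positional information).
quinic_diagnostics <- function(x, acyls, config) {
  reg <- config$registries$acyls
  rows <- list(
    data.frame(kind = "backbone-anion", residue = NA_character_,
               target_mz = 191.0561, stringsAsFactors = FALSE),
    data.frame(kind = "backbone-dehydrated", residue = NA_character_,
               target_mz = 173.0455, stringsAsFactors = FALSE)
  )
  for (r in unique(acyls)) {
    i <- match(r, reg$name)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "acid anion", residue = r, target_mz = reg$acid_anion_mz[i],
      stringsAsFactors = FALSE)
    mk <- reg$markers[[i]]
    if (nrow(mk)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "secondary", residue = r, target_mz = mk$mz,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  d$abundance <- vapply(d$target_mz, function(m)
    peak_abundance(x, m, tol_mda = config$tol_mda), numeric(1))
  d$mz <- vapply(d$target_mz, function(m) {
    pk <- find_peak(x, m, tol_mda = config$tol_mda)
    if (is.null(pk)) NA_real_ else pk$mz
  }, numeric(1))
  d
}

one_assignment <- function(positions, residues) {
  data.frame(position = positions, residue = residues,
             stringsAsFactors = FALSE)
}

#' Order the two residues of a mixed diacyl by their loss-ion abundances
#'
#' The residue whose `[M-H-residue]-` ion is the more abundant was lost
#' first in fragmentation and is assigned the position lost first (C-5 in
#' the quinic key). Calling the order requires the two loss ions to differ
#' by at least the configured fold-ratio; otherwise both orders are
#' reported.
#'
#' @inheritParams detect_backbone
#' @param residues Character vector of the two distinct residue names.
#' @return List with `orders` (list of `c(first, second)` vectors; length 2
#'   when ambiguous), `loss_ions` (data frame) and `ambiguous` flag.
#' @export
assign_diacyl_order <- function(x, residues, config = derep_config()) {
  stopifnot(length(residues) == 2L, residues[1] != residues[2])
  reg <- config$registries$acyls
  li <- do.call(rbind, lapply(residues, function(r) {
    i <- match(r, reg$name)
    target <- x$precursor_mz - reg$loss_mass[i]
    pk <- find_peak(x, target, tol_mda = config$tol_mda)
    data.frame(residue = r, target_mz = target,
               mz = if (is.null(pk)) NA_real_ else pk$mz,
               abundance = if (is.null(pk)) 0 else pk$abundance,
               stringsAsFactors = FALSE)
  }))
  a <- li$abundance
  if (max(a) > 0 && (min(a) == 0 || max(a) / min(a) >= config$order_ratio)) {
    first <- li$residue[which.max(a)]
    orders <- list(c(first = first, second = setdiff(residues, first)))
    ambiguous <- FALSE
  } else {
    orders <- list(c(first = residues[1], second = residues[2]),
                   c(first = residues[2], second = residues[1]))
    ambiguous <- TRUE
  }
  list(orders = orders, loss_ions = li, ambiguous = ambiguous)
}

#' Assign acylation positions on a quinic backbone
#'
#' Implements the base-peak key over the diagnostic-ion set: base 173.045
#' ("dehydrated" quinate) marks C-4; base at the residue's acid anion marks
#' C-3; base 191.055 marks C-3 when the residue's acid ions are prominent,
#' else C-5. A decarboxylated marker as diagnostic base peak cannot separate
#' C-1 from C-3 and yields the label `"3(or 1)"`. Diacyls combine the key
#' with the loss-ion order (first-lost residue at C-5); vicinal diacyls are
#' marked by base 173.045.
#'
#' @inheritParams detect_backbone
#' @param acyls Character vector (multiset) of residue names.
#' @return List with `assignments` (list of position/residue data frames;
#'   more than one entry means the key cannot separate the candidates),
#'   `diagnostics` (the ion table used) and `evidence`.
#' @export
assign_quinic_regiochemistry <- function(x, acyls, config = derep_config()) {
  stopifnot(length(acyls) >= 1L)
  x <- if (x$normalized) x else normalize_spectrum(x)
  d <- quinic_diagnostics(x, acyls, config)
  present <- d[d$abundance > 0, , drop = FALSE]
  ev <- list()
  if (nrow(present) == 0L) {
    return(list(assignments = list(), diagnostics = d,
                evidence = evidence_row("regio", "no diagnostic ions present")))
  }
  base <- present[which.max(present$abundance), ]
  ev[[1]] <- evidence_row(
    "regio/base-peak",
    sprintf("diagnostic base peak %s (%s)", base$kind,
            if (is.na(base$residue)) "backbone" else base$residue),
    base$mz, base$abundance)

  marker_prom <- function(residue) {
    m <- d[!is.na(d$residue) & d$residue == residue, "abundance"]
    if (length(m) == 0L) 0 else max(m)
  }
  # Position of the single (or remaining) residue given the diagnostic base.
  # For monoacyls a 191.055 base with prominent acid ions marks C-3 (the
  # neochlorogenic pattern) and with negligible ones C-5; for diacyls a
  # 191.055 base cannot separate C-1 from C-3 and stays ambiguous.
  position_of <- function(residue, mono = TRUE) {
    if (base$kind == "backbone-dehydrated") return("4")
    if (base$kind %in% c("acid anion", "secondary")) {
      if (identical(base$residue, residue)) {
        return(if (base$kind == "acid anion") "3" else "3(or 1)")
      }
      return("3(or 1)")
    }
    # base = 191.055 backbone anion
    if (!mono) return("3(or 1)")
    if (marker_prom(residue) >= config$prominence) "3" else "5"
  }

  n <- length(acyls)
  assignments <- list()
  if (n == 1L) {
    pos <- position_of(acyls[1])
    assignments <- list(one_assignment(pos, acyls[1]))
    ev[[length(ev) + 1L]] <- evidence_row(
      "regio/monoacyl", sprintf("position %s for %s (marker prominence %.1f%%)",
                                pos, acyls[1], marker_prom(acyls[1])))
  } else if (n == 2L && acyls[1] == acyls[2]) {
    r <- acyls[1]
    if (base$kind == "backbone-dehydrated") {
      assignments <- list(one_assignment(c("4", "1, 3 or 5"), c(r, r)))
    } else {
      assignments <- list(one_assignment(c("3(or 1)", "5"), c(r, r)))
    }
    ev[[length(ev) + 1L]] <- evidence_row(
      "regio/diacyl-symmetric",
      paste("positions", paste(assignments[[1]]$position, collapse = ",")))
  } else if (n == 2L) {
    ord <- assign_diacyl_order(x, acyls, config)
    for (i in seq_len(nrow(ord$loss_ions))) {
      li <- ord$loss_ions[i, ]
      ev[[length(ev) + 1L]] <- evidence_row(
        "regio/loss-ion", sprintf("[M-H-%s]-", li$residue), li$mz,
        li$abundance)
    }
    for (o in ord$orders) {
      second_pos <- position_of(o[["second"]], mono = FALSE)
      if (second_pos == "5") second_pos <- "3(or 1)"  # C-5 is taken
      assignments[[length(assignments) + 1L]] <-
        one_assignment(c(second_pos, "5"), c(o[["second"]], o[["first"]]))
    }
    if (ord$ambiguous) {
      ev[[length(ev) + 1L]] <- evidence_row(
        "regio/diacyl-order",
        sprintf("loss-ion ratio below %gx; both orders retained",
                config$order_ratio))
    }
  } else if (n == 3L && length(unique(acyls)) == 1L) {
    if (base$kind == "backbone-dehydrated") {
      assignments <- list(one_assignment(c("3", "4", "5"), acyls))
      ev[[length(ev) + 1L]] <- evidence_row(
        "regio/triacyl", "vicinal key: base 173.045 with three identical acyls")
    }
  }
  # dedupe identical assignments (ambiguous orders can coincide)
  if (length(assignments) > 1L) {
    keys <- vapply(assignments, function(a)
      paste(a$position, a$residue, collapse = "|"), character(1))
    assignments <- assignments[!duplicated(keys)]
  }
  list(assignments = assignments, diagnostics = d,
       evidence = do.call(rbind, ev))
}

# ------------------------------------------------------- hexaric branch ----

#' Resolve caffeoyl count and ester substituents on a hexaric backbone
#'
#' The caffeoyl multiplicity and any residual ester are found by matching
#' `precursor - [HA-H]-` against `k x caffeoyl + ester` neutral-loss sums;
#' the sequential caffeoyl-loss ladder and any ester marker ions are
#' recorded as evidence. An unmatched residual is reported as
#' `"unknown(<delta m>)"`.
#'
#' @inheritParams detect_backbone
#' @return List: `caffeoyl_count`, `substituents` (character), `name`,
#'   `ladder` (data frame), `evidence`, `resolved` (logical).
#' @export
assign_hexaric_substituents <- function(x, config = derep_config()) {
  x <- if (x$normalized) x else normalize_spectrum(x)
  ha_anion <- deprotonated_mz("C6H10O8")       # 209.0303
  caf <- caffeoyl_loss_mass()
  esters <- config$registries$esters
  target <- x$precursor_mz - ha_anion
  tol <- config$composition_tol_mda / 1000

  best <- NULL
  for (k in 0:4) {
    resid <- target - k * caf
    # pure k-caffeoyl
    if (abs(resid) <= tol &&
        (is.null(best) || abs(resid) < best$err)) {
      best <- list(k = k, ester = NULL, err = abs(resid))
    }
    for (i in seq_len(nrow(esters))) {
      err <- abs(resid - esters$loss_mass[i])
      if (err <= tol && (is.null(best) || err < best$err)) {
        best <- list(k = k, ester = esters$name[i], err = err)
      }
    }
  }
  ladder <- count_acyl_losses(x, caf, config)
  ev <- list(evidence_row(
    "hexaric/ladder",
    sprintf("%d sequential caffeoyl losses: %s", ladder$count,
            paste(sprintf("%.3f", ladder$chain$mz), collapse = " -> "))))
  if (is.null(best)) {
    k <- ladder$count
    resid <- target - k * caf
    sub <- sprintf("unknown(%.3f)", resid)
    ev[[2]] <- evidence_row("hexaric/residual",
                            sprintf("residual loss %.3f Da unmatched", resid))
    return(list(caffeoyl_count = k, substituents = sub,
                name = NA_character_, ladder = ladder$chain,
                evidence = do.call(rbind, ev), resolved = FALSE))
  }
  subst <- character(0)
  if (!is.null(best$ester)) {
    subst <- best$ester
    i <- match(best$ester, esters$name)
    mk <- esters$markers[[i]]
    for (j in seq_len(nrow(mk))) {
      pk <- find_peak(x, mk$mz[j], tol_mda = config$tol_mda)
      if (!is.null(pk)) {
        ev[[length(ev) + 1L]] <- evidence_row(
          "hexaric/ester-marker", paste(best$ester, mk$role[j]),
          pk$mz, pk$abundance)
      }
    }
    # ester-terminus ion [M-H-kCA]- (e.g. 295.067 for the leontopodic A type)
    pk <- find_peak(x, ha_anion + esters$loss_mass[i],
                    tol_mda = config$tol_mda)
    if (!is.null(pk)) {
      ev[[length(ev) + 1L]] <- evidence_row(
        "hexaric/ester-terminus", sprintf("[HA-H+%s]-", best$ester),
        pk$mz, pk$abundance)
    }
  }
  counts <- c("1" = "mono", "2" = "di", "3" = "tri", "4" = "tetra")
  nm <- if (best$k >= 1) {
    core <- paste0(if (best$k > 1) counts[[as.character(best$k)]] else "",
                   "caffeoylhexaric acid")
    if (length(subst)) paste0(subst, "-", core) else core
  } else NA_character_
  ev[[length(ev) + 1L]] <- evidence_row(
    "hexaric/composition",
    sprintf("%d caffeoyl%s explain the precursor within %.1f mDa", best$k,
            if (length(subst)) paste0(" + ", subst) else "",
            best$err * 1000))
  list(caffeoyl_count = best$k, substituents = subst, name = nm,
       ladder = ladder$chain, evidence = do.call(rbind, ev), resolved = TRUE)
}

# ------------------------------------------------------ glycoside branch ----

#' Resolve aglycone, sugar and linkage for glycosides and sugar esters
#'
#' Matches precursor neutral losses against the sugar registry, looks the
#' residual fragment up in the aglycone registry, and calls the linkage
#' "sugar ester" when at least two hexose cross-ring cleavages (-60/-90/
#' -120 Da) are present, else "O-glycoside". Isobaric aglycones are
#' reported as either/or unless a retention-time prior resolves them.
#'
#' @inheritParams detect_backbone
#' @return `NULL` when no sugar loss or bare aglycone is recognised;
#'   otherwise a list with `aglycone` (possibly `"a/b"`), `aglycone_type`,
#'   `sugar`, `linkage`, `name` and `evidence`.
#' @export
assign_glycoside <- function(x, config = derep_config()) {
  x <- if (x$normalized) x else normalize_spectrum(x)
  sugars <- config$registries$sugars$sugars
  cross <- config$registries$sugars$cross_ring
  agl <- config$registries$aglycones
  tol <- config$tol_mda

  aglycone_group <- function(mz) {
    hit <- agl[abs(agl$anion_mz - mz) <= tol / 1000, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    if (nrow(hit) > 1L && !is.null(config$rt_priors) && !is.na(x$rt)) {
      pri <- config$rt_priors
      sel <- vapply(hit$name, function(nm) {
        i <- match(nm, pri$name)
        !is.na(i) && x$rt >= pri$rt_min[i] && x$rt <= pri$rt_max[i]
      }, logical(1))
      if (any(sel)) hit <- hit[sel, , drop = FALSE]
    }
    hit
  }

  ev <- list()
  # cross-ring cleavages, diagnostic of ester-bound sugars
  xr <- 0L
  for (i in seq_len(nrow(cross))) {
    pk <- find_peak(x, x$precursor_mz - cross$loss_mass[i], tol_mda = tol)
    if (!is.null(pk)) {
      xr <- xr + 1L
      ev[[length(ev) + 1L]] <- evidence_row(
        "glycoside/cross-ring", sprintf("%s (-%.0f Da)", cross$name[i],
                                        cross$loss_mass[i]),
        pk$mz, pk$abundance)
    }
  }
  linkage <- if (xr >= 2L) "sugar ester" else "O-glycoside"

  best <- NULL
  for (i in seq_len(nrow(sugars))) {
    pk <- find_peak(x, x$precursor_mz - sugars$loss_mass[i], tol_mda = tol)
    if (is.null(pk)) next
    grp <- aglycone_group(pk$mz)
    cand <- list(sugar = sugars$name[i], loss = sugars$loss_mass[i],
                 frag = pk, group = grp)
    if (is.null(best) ||
        (!is.null(grp) && is.null(best$group)) ||
        (!is.null(grp) && !is.null(best$group) && cand$loss > best$loss)) {
      best <- cand
    }
  }

  if (is.null(best)) {
    grp <- aglycone_group(x$precursor_mz)
    if (is.null(grp)) return(NULL)
    nm <- paste(grp$name, collapse = "/")
    ev[[length(ev) + 1L]] <- evidence_row(
      "glycoside/bare-aglycone", nm, x$precursor_mz, NA_real_)
    return(list(aglycone = nm, aglycone_type = grp$type[1],
                sugar = NA_character_, linkage = NA_character_, name = nm,
                evidence = do.call(rbind, ev)))
  }
  ev[[length(ev) + 1L]] <- evidence_row(
    "glycoside/sugar-loss",
    sprintf("loss of %s (%.4f Da)", best$sugar, best$loss),
    best$frag$mz, best$frag$abundance)
  if (is.null(best$group)) {
    return(list(aglycone = NA_character_, aglycone_type = NA_character_,
                sugar = best$sugar, linkage = linkage,
                name = NA_character_, evidence = do.call(rbind, ev)))
  }
  nm_agl <- paste(best$group$name, collapse = "/")
  ev[[length(ev) + 1L]] <- evidence_row(
    "glycoside/aglycone", nm_agl, best$frag$mz, best$frag$abundance)
  sugar_word <- sub("^rutinosyl$", "rutinoside",
                    sub("hexose$", "hexoside", best$sugar))
  nm <- paste0(nm_agl, " ", sugar_word,
               if (linkage == "sugar ester") " (sugar ester)" else "")
  list(aglycone = nm_agl, aglycone_type = best$group$type[1],
       sugar = best$sugar, linkage = linkage, name = nm,
       evidence = do.call(rbind, ev))
}

# ------------------------------------------------------------- annotate ----

quinic_name <- function(assignments, acyls) {
  if (length(assignments) != 1L) return(NA_character_)
  a <- assignments[[1]]
  if (!all(grepl("^[0-9]+$", a$position))) return(NA_character_)
  ord <- order(a$position)
  a <- a[ord, , drop = FALSE]
  if (length(unique(a$residue)) == 1L && nrow(a) > 1L) {
    prefix <- c("2" = "di", "3" = "tri", "4" = "tetra")[[as.character(nrow(a))]]
    paste0(paste(a$position, collapse = ","), "-", prefix, a$residue[1],
           "quinic acid")
  } else {
    paste0(paste(paste0(a$position, "-", a$residue), collapse = "-"),
           "quinic acid")
  }
}

specificity_level <- function(result) {
  # 0 unannotated < 1 class < 2 class+composition < 3 +positions
  if (result$class %in% c("unannotated", "unknown glycoside")) return(0L)
  has_comp <- length(result$acyls) > 0L || length(result$substituents) > 0L ||
    (!is.na(result$aglycone) && nzchar(result$aglycone))
  if (!has_comp) return(1L)
  full <- FALSE
  if (result$class == "acylquinic acid") {
    full <- length(result$assignments) == 1L &&
      all(grepl("^[0-9]+$", result$assignments[[1]]$position))
  } else if (result$class == "caffeoylhexaric acid") {
    full <- !any(grepl("^unknown", result$substituents))
  } else {
    full <- !is.na(result$aglycone) && !grepl("/", result$aglycone,
                                              fixed = TRUE)
  }
  if (full) 3L else 2L
}

#' Grade identification confidence
#'
#' Six-level scheme: `A2` standard-confirmed structure including
#' stereochemistry; `B`/`C` standard-matched without stereochemical
#' confirmation (which of the two is policy, default `C`); `D1` no standard
#' but fully resolved positions/structure; `D2` composition resolved but
#' positions or isobaric identity ambiguous; `E` class-level only.
#'
#' @param result An `annotation_result`.
#' @param standards Standards registry data frame
#'   (default the shipped [standards_registry()]).
#' @param stereo_confirmed Optional logical overriding the registry's
#'   stereo flag (stereochemistry is never inferred from MS2; it must be
#'   asserted externally).
#' @param policy `"C"` (default) or `"B"` for a standard match without
#'   stereo confirmation.
#' @return Single character, one of `"A2" "B" "C" "D1" "D2" "E"`.
#' @export
assign_confidence <- function(result, standards = standards_registry(),
                              stereo_confirmed = NULL, policy = "C") {
  lvl <- specificity_level(result)
  if (lvl == 0L) return("E")
  std <- standards_match(result$name, standards)
  if (!is.null(std)) {
    stereo <- if (is.null(stereo_confirmed)) std$stereo else
      isTRUE(stereo_confirmed)
    return(if (stereo) "A2" else policy)
  }
  c("E", "E", "D2", "D1")[lvl + 1L]
}

new_annotation_result <- function(id) {
  structure(list(
    id = id, class = "unannotated", backbone = NA_character_,
    acyls = character(0), assignments = list(), substituents = character(0),
    aglycone = NA_character_, sugar = NA_character_, linkage = NA_character_,
    name = NA_character_, confidence = "E",
    evidence = evidence_row("none", "no rule fired")[0, ],
    notes = character(0)
  ), class = "annotation_result")
}

#' Annotate one MS/MS spectrum with the full hierarchical key
#'
#' Never raises on spectrum content: spectra that fire no rule come back
#' with class `"unannotated"` and the reasons in `notes`.
#'
#' @inheritParams detect_backbone
#' @param standards Standards registry for confidence grading (default the
#'   config's).
#' @return An `annotation_result`: chemical class, backbone, acyl multiset,
#'   candidate position assignments, substituents, aglycone/sugar/linkage,
#'   canonical name, confidence grade and the full evidence trail.
#' @export
annotate <- function(x, config = derep_config(), standards = NULL) {
  stopifnot(inherits(x, "msms_spectrum"))
  x <- if (x$normalized) x else normalize_spectrum(x)
  if (is.null(standards)) standards <- config$registries$standards
  res <- new_annotation_result(x$id)
  ev <- list()

  bb <- detect_backbone(x, config)
  if (!is.null(bb)) {
    res$backbone <- bb$name
    ev[[length(ev) + 1L]] <- do.call(rbind, lapply(
      seq_len(nrow(bb$matches)), function(i)
        evidence_row("backbone/series",
                     paste(bb$name, bb$matches$role[i]),
                     bb$matches$mz[i], bb$matches$abundance[i])))
  }

  if (!is.null(bb) && bb$name == "quinic") {
    cand <- detect_acyls(x, config, context = "quinic")
    comp <- compose_acyls(x, bb$anion_mz, cand, config, context = "quinic")
    if (!is.null(comp) && length(comp$acyls) >= 1L) {
      res$class <- "acylquinic acid"
      res$acyls <- comp$acyls
      for (r in unique(comp$acyls)) {
        hit <- cand[cand$name == r, , drop = FALSE]
        if (nrow(hit)) {
          ev[[length(ev) + 1L]] <- evidence_row(
            "acyl/marker", paste(r, hit$marker_role[1]),
            hit$mz[1], hit$abundance[1])
        } else {
          ev[[length(ev) + 1L]] <- evidence_row(
            "acyl/loss-arithmetic",
            paste(r, "inferred from neutral-loss sum only"))
        }
      }
      if (!comp$marker_supported) {
        res$notes <- c(res$notes,
                       "acyl composition from loss arithmetic without marker support")
      }
      regio <- assign_quinic_regiochemistry(x, comp$acyls, config)
      res$assignments <- regio$assignments
      ev[[length(ev) + 1L]] <- regio$evidence
      res$name <- quinic_name(regio$assignments, comp$acyls)
      if (is.na(res$name)) {
        res$notes <- c(res$notes, "acyl positions ambiguous")
      }
    } else {
      res$notes <- c(res$notes,
                     "quinic backbone without an explicable acyl loss")
    }
  } else if (!is.null(bb) && bb$name == "hexaric") {
    hx <- assign_hexaric_substituents(x, config)
    ev[[length(ev) + 1L]] <- hx$evidence
    if (hx$caffeoyl_count >= 1L) {
      res$class <- "caffeoylhexaric acid"
      res$acyls <- rep("caffeoyl", hx$caffeoyl_count)
      res$substituents <- hx$substituents
      res$name <- hx$name
      if (identical(hx$substituents, "hydroxybutanyl") &&
          hx$caffeoyl_count == 3L) {
        res$notes <- c(res$notes, "leontopodic A-type")
      } else if (length(hx$substituents) == 0L && hx$caffeoyl_count == 3L) {
        res$notes <- c(res$notes, "leontopodic B-type")
      }
    } else {
      res$notes <- c(res$notes, "hexaric backbone without caffeoyl losses")
    }
  } else {
    gl <- assign_glycoside(x, config)
    if (!is.null(gl)) {
      ev[[length(ev) + 1L]] <- gl$evidence
      if (!is.na(gl$aglycone)) {
        res$class <- if (gl$aglycone_type == "flavonoid") {
          if (is.na(gl$sugar)) "flavonoid aglycone" else "flavonoid glycoside"
        } else "phenolic-acid glycoside/ester"
        res$aglycone <- gl$aglycone
        res$sugar <- gl$sugar
        res$linkage <- gl$linkage
        res$name <- gl$name
      } else {
        res$class <- "unknown glycoside"
        res$sugar <- gl$sugar
        res$linkage <- gl$linkage
        res$notes <- c(res$notes,
                       "sugar loss without a recognisable aglycone")
      }
    } else {
      res$notes <- c(res$notes, "no backbone series, sugar loss or aglycone matched")
    }
  }

  res$evidence <- do.call(rbind, c(list(res$evidence), ev))
  res$confidence <- assign_confidence(res, standards,
                                      policy = config$standard_policy)
  res
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation> %s: %s", x$id, x$class))
  if (!is.na(x$name)) cat(" -- ", x$name, sep = "")
  cat(sprintf("  [%s]\n", x$confidence))
  if (length(x$acyls)) {
    cat("  acyls:", paste(x$acyls, collapse = " + "), "\n")
  }
  if (length(x$assignments)) {
    for (a in x$assignments) {
      cat("  positions:",
          paste(paste0(a$position, "-", a$residue), collapse = ", "), "\n")
    }
  }
  if (length(x$substituents)) {
    cat("  substituents:", paste(x$substituents, collapse = ", "), "\n")
  }
  if (!is.na(x$aglycone)) {
    cat("  aglycone:", x$aglycone,
        if (!is.na(x$sugar)) paste0(" + ", x$sugar, " (", x$linkage, ")"),
        "\n")
  }
  cat("  evidence:", nrow(x$evidence), "entries\n")
  invisible(x)
}

positions_string <- function(res) {
  if (length(res$assignments) == 0L) return(NA_character_)
  paste(vapply(res$assignments, function(a)
    paste(paste0(a$position, "-", a$residue), collapse = "+"),
    character(1)), collapse = " | ")
}

#' Annotate a list of spectra into a flat table
#'
#' @param spectra List of `msms_spectrum` objects.
#' @inheritParams annotate
#' @return Data frame, one row per spectrum, with the annotation summary;
#'   the full `annotation_result` objects are attached as
#'   `attr(, "results")`.
#' @export
annotate_spectra <- function(spectra, config = derep_config()) {
  results <- lapply(spectra, annotate, config = config)
  out <- data.frame(
    id = vapply(results, `[[`, character(1), "id"),
    input_name = vapply(spectra, function(s) s$name %||% NA_character_,
                        character(1)),
    class = vapply(results, `[[`, character(1), "class"),
    composition = vapply(results, function(r)
      if (length(r$acyls)) paste(r$acyls, collapse = "+") else
        NA_character_, character(1)),
    positions = vapply(results, positions_string, character(1)),
    substituents = vapply(results, function(r)
      if (length(r$substituents)) paste(r$substituents, collapse = "+") else
        NA_character_, character(1)),
    aglycone = vapply(results, `[[`, character(1), "aglycone"),
    sugar = vapply(results, `[[`, character(1), "sugar"),
    linkage = vapply(results, `[[`, character(1), "linkage"),
    annotation = vapply(results, `[[`, character(1), "name"),
    confidence = vapply(results, `[[`, character(1), "confidence"),
    n_evidence = vapply(results, function(r) nrow(r$evidence), integer(1)),
    notes = vapply(results, function(r)
      if (length(r$notes)) paste(r$notes, collapse = "; ") else
        NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "results") <- results
  out
}

#' Parse a literature compound name into expected composition and positions
#'
#' Utility for comparing engine output against printed compound names such
#' as `"3-p-coumaroyl-5-caffeoylquinic acid"` or `"chlorogenic acid"`
#' (= 5-caffeoylquinic acid in the numbering convention used here; the
#' alternative convention exists in the older literature).
#'
#' @param name Compound name.
#' @return List with `acyls` (sorted character multiset) and `positions`
#'   (integer vector, possibly empty when the name carries none).
#' @export
parse_compound_name <- function(name) {
  n <- tolower(name)
  n <- gsub("‐|‑|‒|–", "-", n)   # unicode hyphens
  n <- gsub("caffeyl", "caffeoyl", n)                # printed variant
  if (grepl("neochlorogenic", n)) return(list(acyls = "caffeoyl", positions = 3L))
  if (grepl("chlorogenic", n)) return(list(acyls = "caffeoyl", positions = 5L))
  residues <- c("hydroxy-dihydrocaffeoyl" = "hydroxydihydrocaffeoyl",
                "hydroxydihydrocaffeoyl" = "hydroxydihydrocaffeoyl",
                "dihydrocaffeoyl" = "dihydrocaffeoyl",
                "caffeoyl" = "caffeoyl",
                "p-coumaroyl" = "p-coumaroyl",
                "coumaroyl" = "p-coumaroyl",
                "feruloyl" = "feruloyl")
  mult <- c(di = 2L, tri = 3L, tetra = 4L)
  acyls <- character(0)
  work <- n
  # tokens like "3-caffeoyl", "4-p-coumaroyl", "dicaffeoyl", "tricaffeoyl"
  for (key in names(residues)) {
    pat <- gsub("-", "[- ]?", key, fixed = TRUE)
    while (grepl(pat, work)) {
      pre <- regmatches(work, regexpr(paste0("(di|tri|tetra)(?=", pat, ")"),
                                      work, perl = TRUE))
      k <- if (length(pre) && pre %in% names(mult)) mult[[pre]] else 1L
      acyls <- c(acyls, rep(residues[[key]], k))
      work <- sub(paste0("(di|tri|tetra)?", pat), "", work)
    }
  }
  n2 <- sub("[[:space:]]+[0-9]$", "", n)  # trailing isomer counter ("... acid 2")
  pos <- as.integer(regmatches(n2, gregexpr("(?<![0-9.])[1-5](?![0-9.])", n2,
                                            perl = TRUE))[[1]])
  list(acyls = sort(acyls), positions = sort(unique(pos)))
}
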