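# Data model and I/O for MS/MS spectra: construction, normalisation, peak
# matching, and readers/writers for MSP, MGF and the tabular fixture dialect
# (one compound per row, fragment list as "m/z (abundance); ...").

#' Construct an MS/MS spectrum
#'
#' @param id Spectrum identifier.
#' @param precursor_mz m/z of the deprotonated molecular ion [M-H]-.
#' @param peaks Data frame (or 2-column matrix) with columns `mz` and
#'   `abundance` (relative, percent of base peak).
#' @param dimer_mz Optional m/z of the [2M-H]- adduct.
#' @param dimer_abundance Optional relative abundance of the dimer ion.
#' @param rt Optional retention time in minutes (>= 0).
#' @param formula Optional molecular formula string for the neutral.
#' @param name Optional compound name (fixtures carry the printed name).
#' @param normalize Normalise abundances on construction (default TRUE).
#' @return Object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(id, precursor_mz, peaks, dimer_mz = NA_real_,
                          dimer_abundance = NA_real_, rt = NA_real_,
                          formula = NA_character_, name = NA_character_,
                          normalize = TRUE) {
  peaks <- as.data.frame(peaks)
  if (!all(c("mz", "abundance") %in% names(peaks))) {
    names(peaks)[1:2] <- c("mz", "abundance")
  }
  peaks <- peaks[, c("mz", "abundance")]
  stopifnot(is.numeric(peaks$mz), is.numeric(peaks$abundance))
  if (nrow(peaks) < 1L) stop("a spectrum needs at least one fragment peak",
                             call. = FALSE)
  if (any(peaks$mz <= 0)) stop("fragment m/z must be positive", call. = FALSE)
  if (!is.na(precursor_mz) && any(peaks$mz > precursor_mz + 0.05)) {
    stop("fragment m/z above the precursor m/z (beyond matching tolerance)",
         call. = FALSE)
  }
  if (!is.na(rt) && rt < 0) stop("retention time must be >= 0", call. = FALSE)
  x <- structure(
    list(id = as.character(id), precursor_mz = as.numeric(precursor_mz),
         peaks = peaks, dimer_mz = as.numeric(dimer_mz),
         dimer_abundance = as.numeric(dimer_abundance), rt = as.numeric(rt),
         formula = as.character(formula), name = as.character(name),
         normalized = FALSE),
    class = "msms_spectrum"
  )
  if (normalize) normalize_spectrum(x) else x
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %s  [M-H]- %.4f  %d peaks%s\n",
              x$id, x$precursor_mz, nrow(x$peaks),
              if (!is.na(x$rt)) sprintf("  tR %.2f min", x$rt) else ""))
  invisible(x)
}

#' Normalise a spectrum's fragment abundances
#'
#' Drops zero-abundance peaks (with a warning), merges duplicated entries
#' closer than 1 mDa keeping the first occurrence (transcribed tables
#' occasionally duplicate a fragment), and rescales so the base peak is
#' exactly 100. Idempotent.
#'
#' @param x An `msms_spectrum`.
#' @return The normalised spectrum.
#' @export
normalize_spectrum <- function(x) {
  stopifnot(inherits(x, "msms_spectrum"))
  p <- x$peaks
  if (any(p$abundance == 0)) {
    warning("dropping ", sum(p$abundance == 0),
            " zero-abundance peak(s) in spectrum ", x$id, call. = FALSE)
    p <- p[p$abundance != 0, , drop = FALSE]
  }
  if (nrow(p) == 0L) stop("spectrum ", x$id, " has no nonzero peaks",
                          call. = FALSE)
  if (any(p$abundance < 0)) stop("negative abundances in spectrum ", x$id,
                                 call. = FALSE)
  keep <- rep(TRUE, nrow(p))
  for (i in seq_len(nrow(p))[-1]) {
    if (any(abs(p$mz[seq_len(i - 1)][keep[seq_len(i - 1)]] - p$mz[i]) < 1e-3)) {
      keep[i] <- FALSE
    }
  }
  if (!all(keep)) {
    warning("spectrum ", x$id, ": ", sum(!keep),
            " duplicated fragment(s) within 1 mDa; keeping first occurrence",
            call. = FALSE)
    p <- p[keep, , drop = FALSE]
  }
  p$abundance <- p$abundance / max(p$abundance) * 100
  rownames(p) <- NULL
  x$peaks <- p
  x$normalized <- TRUE
  x
}

#' Base peak of a spectrum
#'
#' @param x An `msms_spectrum` with at least one fragment.
#' @return One-row data frame (`mz`, `abundance`); on an exact abundance tie
#'   the lower m/z wins and the result carries `attr(, "tie") = TRUE`.
#' @export
base_peak <- function(x) {
  stopifnot(inherits(x, "msms_spectrum"))
  p <- x$peaks
  if (nrow(p) == 0L) stop("empty peak list", call. = FALSE)
  top <- which(p$abundance == max(p$abundance))
  tie <- length(top) > 1L
  i <- top[which.min(p$mz[top])]
  out <- p[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tie") <- tie
  out
}

#' Find the nearest in-tolerance fragment peak
#'
#' @param x An `msms_spectrum`.
#' @param mz Target m/z.
#' @param tol_mda Absolute tolerance in mDa (default 10; the MS2 axis of
#'   the instrument class modelled here reads a few ppm low against theory,
#'   so an absolute tolerance is the robust default).
#' @param tol_ppm Optional ppm tolerance; overrides `tol_mda` when given.
#' @return One-row data frame (`mz`, `abundance`) of the nearest
#'   in-tolerance peak, or `NULL` when none qualifies.
#' @export
find_peak <- function(x, mz, tol_mda = 10, tol_ppm = NULL) {
  stopifnot(inherits(x, "msms_spectrum"))
  tol <- if (!is.null(tol_ppm)) mz * tol_ppm * 1e-6 else tol_mda / 1000
  d <- abs(x$peaks$mz - mz)
  ok <- which(d <= tol)
  if (length(ok) == 0L) return(NULL)
  out <- x$peaks[ok[which.min(d[ok])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

peak_abundance <- function(x, mz, tol_mda = 10) {
  pk <- find_peak(x, mz, tol_mda = tol_mda)
  if (is.null(pk)) 0 else pk$abundance
}

# ---------------------------------------------------------------- readers --

parse_fragment_list <- function(s, id = "?") {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty fragment list for ", id, call. = FALSE)
  items <- strsplit(s, ";", fixed = TRUE)[[1]]
  items <- trimws(items[nzchar(trimws(items))])
  m <- regmatches(items, regexec(
    "^([0-9]+\\.?[0-9]*)[[:space:]]*\\(([0-9]+\\.?[0-9]*)\\)$", items))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) {
    stop("malformed fragment entry '", items[bad[1]], "' in record ", id,
         call. = FALSE)
  }
  data.frame(
    mz = vapply(m, function(g) as.numeric(g[2]), numeric(1)),
    abundance = vapply(m, function(g) as.numeric(g[3]), numeric(1))
  )
}

read_fixture_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#",
                           quote = "")
  required <- c("id", "precursor_mz", "fragments")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("fixture file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  getcol <- function(col, default = NA) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    frm <- as.character(getcol("formula", NA_character_)[i])
    sp <- msms_spectrum(
      id = tab$id[i],
      precursor_mz = as.numeric(tab$precursor_mz[i]),
      peaks = parse_fragment_list(tab$fragments[i], id = tab$id[i]),
      dimer_mz = suppressWarnings(as.numeric(getcol("dimer_mz")[i])),
      rt = suppressWarnings(as.numeric(getcol("rt_min")[i])),
      formula = frm,
      name = as.character(getcol("name", NA_character_)[i])
    )
    # Printed "exact mass" cells are occasionally inconsistent with the
    # printed formula; flag rather than reproduce them.
    em <- suppressWarnings(as.numeric(getcol("exact_mass")[i]))
    if (!is.na(em) && !is.na(frm) && nzchar(frm)) {
      theo <- tryCatch(deprotonated_mz(frm), error = function(e) NA_real_)
      if (!is.na(theo) && abs(theo - em) > 2e-3) {
        warning(sprintf(
          "record %s: printed exact mass %.4f disagrees with formula %s (calc. %.4f); using measured peaks",
          tab$id[i], em, frm, theo), call. = FALSE)
        attr(sp, "exact_mass_flag") <- TRUE
      }
    }
    out[[i]] <- sp
  }
  out
}

read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); i <- 1L; n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^Name:", lines[i], ignore.case = TRUE)) i <- i + 1L
    if (i > n) break
    meta <- list(); npeaks <- NA_integer_
    while (i <= n && grepl(":", lines[i], fixed = TRUE)) {
      key <- tolower(trimws(sub(":.*$", "", lines[i])))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      meta[[key]] <- val
      i <- i + 1L
      if (key == "num peaks") { npeaks <- as.integer(val); break }
    }
    if (is.na(npeaks)) stop("MSP record without 'Num Peaks' near line ", i,
                            call. = FALSE)
    pk <- lines[seq(i, length.out = npeaks)]
    i <- i + npeaks
    fields <- strsplit(trimws(pk), "[[:space:]]+")
    peaks <- data.frame(
      mz = vapply(fields, function(f) as.numeric(f[1]), numeric(1)),
      abundance = vapply(fields, function(f) as.numeric(f[2]), numeric(1))
    )
    out[[length(out) + 1L]] <- msms_spectrum(
      id = meta[["name"]] %||% paste0("msp_", length(out) + 1L),
      precursor_mz = as.numeric(meta[["precursormz"]] %||% NA),
      peaks = peaks,
      rt = as.numeric(meta[["retentiontime"]] %||% NA),
      formula = meta[["formula"]] %||% NA_character_,
      name = meta[["comments"]] %||% NA_character_
    )
  }
  out
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); inside <- FALSE; meta <- list(); peaks <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (identical(ln, "BEGIN IONS")) {
      inside <- TRUE; meta <- list(); peaks <- list(); next
    }
    if (identical(ln, "END IONS")) {
      pk <- do.call(rbind, peaks)
      out[[length(out) + 1L]] <- msms_spectrum(
        id = meta[["TITLE"]] %||% paste0("mgf_", length(out) + 1L),
        precursor_mz = as.numeric(meta[["PEPMASS"]] %||% NA),
        peaks = data.frame(mz = pk[, 1], abundance = pk[, 2]),
        rt = if (!is.null(meta[["RTINSECONDS"]]))
          as.numeric(meta[["RTINSECONDS"]]) / 60 else NA_real_,
        formula = meta[["FORMULA"]] %||% NA_character_
      )
      inside <- FALSE; next
    }
    if (!inside) next
    if (grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") val <- strsplit(val, "[[:space:]]+")[[1]][1]
      meta[[key]] <- val
    } else {
      f <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]])
      if (length(f) < 2 || anyNA(f[1:2])) {
        stop("malformed MGF peak line: '", ln, "'", call. = FALSE)
      }
      peaks[[length(peaks) + 1L]] <- f[1:2]
    }
  }
  if (inside) stop("MGF record without END IONS", call. = FALSE)
  out
}

#' Read MS/MS spectra from MSP, MGF or the tabular fixture dialect
#'
#' The fixture dialect is a UTF-8 TSV with one compound per row and columns
#' `id`, `precursor_mz`, `fragments` (mandatory) plus optional `name`,
#' `formula`, `exact_mass`, `dimer_mz`, `rt_min`. The fragment list mirrors
#' the typography of printed tables: `"191.0551 (100); 179.0339 (59.5)"`.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"msp"`, `"mgf"`, `"tsv"`; `"auto"` keys
#'   on the file extension.
#' @return List of [msms_spectrum()] objects (abundances normalised).
#'   An empty file yields an empty list with a warning.
#' @export
read_spectra <- function(path, format = c("auto", "msp", "mgf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     msp = "msp", mgf = "mgf", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  nonblank <- function(p) any(nzchar(trimws(readLines(p, warn = FALSE))))
  if (!nonblank(path)) {
    warning("input file is empty: ", path, call. = FALSE)
    return(list())
  }
  switch(format,
         msp = read_msp(path),
         mgf = read_mgf(path),
         tsv = read_fixture_tsv(path))
}

# ---------------------------------------------------------------- writers --

#' Write spectra to MSP or MGF
#'
#' @param spectra List of `msms_spectrum` objects.
#' @param path Output file.
#' @param format `"msp"` or `"mgf"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("msp", "mgf")) {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    if (format == "msp") {
      writeLines(c(
        paste0("Name: ", sp$id),
        if (!is.na(sp$precursor_mz))
          sprintf("PrecursorMZ: %.5f", sp$precursor_mz),
        if (!is.na(sp$formula) && nzchar(sp$formula))
          paste0("Formula: ", sp$formula),
        if (!is.na(sp$rt)) sprintf("RetentionTime: %.3f", sp$rt),
        sprintf("Num Peaks: %d", nrow(sp$peaks)),
        sprintf("%.5f %.4f", sp$peaks$mz, sp$peaks$abundance),
        ""
      ), con)
    } else {
      writeLines(c(
        "BEGIN IONS",
        paste0("TITLE=", sp$id),
        if (!is.na(sp$precursor_mz))
          sprintf("PEPMASS=%.5f", sp$precursor_mz),
        "CHARGE=1-",
        if (!is.na(sp$rt)) sprintf("RTINSECONDS=%.2f", sp$rt * 60),
        sprintf("%.5f %.4f", sp$peaks$mz, sp$peaks$abundance),
        "END IONS",
        ""
      ), con)
    }
  }
  invisible(path)
}
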