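# Semi-quantitation by percent peak area: each compound as a percentage of
# its class total, and each class as a percentage of the grand total. Areas
# are arbitrary AUC units from full-scan extracted-ion integration; only
# ratios are meaningful, so every output is scale-invariant.

#' Percent-peak-area semi-quantitation
#'
#' @param areas Data frame with columns `compound`, `class`, `area`
#'   (AUC, arbitrary units, >= 0).
#' @return List with `per_compound` (adds `pct_of_class`) and `per_class`
#'   (`class`, `total_area`, `pct_of_total`). Within every class the
#'   compound percentages sum to 100, as do the class shares (class shares
#'   are area-weighted). A class whose areas are all zero gets `NA`
#'   percentages and a message.
#' @examples
#' class_percentages(data.frame(
#'   compound = c("a", "b"), class = "AQA", area = c(3, 1)))
#' @export
class_percentages <- function(areas) {
  stopifnot(is.data.frame(areas),
            all(c("compound", "class", "area") %in% names(areas)))
  if (any(areas$area < 0)) stop("areas must be >= 0", call. = FALSE)
  if (anyDuplicated(areas$compound)) {
    stop("duplicated compound ids in area table", call. = FALSE)
  }
  per_compound <- areas
  per_compound$pct_of_class <- NA_real_
  class_totals <- tapply(areas$area, areas$class, sum)
  for (cl in names(class_totals)) {
    idx <- areas$class == cl
    tot <- class_totals[[cl]]
    if (tot > 0) {
      per_compound$pct_of_class[idx] <- areas$area[idx] / tot * 100
    } else {
      message("class '", cl, "' has zero total area; percentages undefined")
    }
  }
  grand <- sum(areas$area)
  per_class <- data.frame(
    class = names(class_totals),
    total_area = as.numeric(class_totals),
    pct_of_total = if (grand > 0) as.numeric(class_totals) / grand * 100
    else NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(per_class) <- NULL
  list(per_compound = per_compound, per_class = per_class)
}

#' Read an area table from TSV
#'
#' @param path TSV with columns `compound`, `class`, `area`.
#' @return Data frame suitable for [class_percentages()].
#' @export
read_area_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("compound", "class", "area")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("area table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab$area <- as.numeric(tab$area)
  tab
}
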