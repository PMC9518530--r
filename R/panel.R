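#' Indicator scheme
#'
#' An indicator scheme declares, for every column of a region-by-indicator
#' panel, its short code, which of the four resilience dimensions it belongs
#' to (resistance, restore, adaptability, collaborative), and whether it is a
#' positive indicator (larger raw value means better status) or a negative
#' one (larger means worse).  The attribute drives the orientation branch of
#' min-max standardization.
#'
#' @param code character vector of unique short indicator codes (e.g. "V11").
#' @param dimension character vector, one of `"resistance"`, `"restore"`,
#'   `"adaptability"`, `"collaborative"` per indicator.
#' @param attribute character vector, `"positive"` or `"negative"` per
#'   indicator.
#' @param description optional free-text description per indicator.
#' @param units optional free-text units per indicator.
#' @return A data frame of class `"indicator_scheme"` with one row per
#'   indicator and columns `code`, `dimension`, `attribute`, `description`,
#'   `units`.
#' @examples
#' indicator_scheme(c("A", "B"), c("resistance", "restore"),
#'                  c("positive", "negative"))
#' @export
indicator_scheme <- function(code, dimension, attribute,
                             description = "", units = "") {
  code <- as.character(code)
  dimension <- match.arg(as.character(dimension), resilience_dimensions(),
                         several.ok = TRUE)
  dimension <- rep_len(dimension, length(code))
  attribute <- match.arg(as.character(attribute), c("positive", "negative"),
                         several.ok = TRUE)
  attribute <- rep_len(attribute, length(code))
  if (anyDuplicated(code)) {
    stop_resilpp("duplicate indicator code(s): %s",
                 paste(unique(code[duplicated(code)]), collapse = ", "),
                 class = "resilpp_scheme_error")
  }
  out <- data.frame(code = code, dimension = dimension, attribute = attribute,
                    description = rep_len(as.character(description), length(code)),
                    units = rep_len(as.character(units), length(code)),
                    stringsAsFactors = FALSE)
  class(out) <- c("indicator_scheme", "data.frame")
  out
}

#' The four resilience dimensions
#'
#' @return Character vector of the four dimension names in canonical order.
#' @export
resilience_dimensions <- function() {
  c("resistance", "restore", "adaptability", "collaborative")
}

#' Region-by-indicator panel
#'
#' Bundles a numeric `m x n` matrix of raw indicator values with its region
#' labels, indicator scheme, and a missing-cell mask.  Row order (regions)
#' and column order (indicators) are significant and preserved by every
#' operation in the package.
#'
#' @param values numeric matrix, regions in rows, indicators in columns.
#'   `NA` cells are taken as missing and recorded in the mask.
#' @param region_labels character vector of unique region labels, one per row.
#' @param scheme an [indicator_scheme()] whose length equals `ncol(values)`.
#' @return An object of class `"indicator_panel"`: a list with elements
#'   `values` (matrix with dimnames), `region_labels`, `scheme`,
#'   `missing_mask` (logical matrix).
#' @examples
#' sch <- indicator_scheme(c("A", "B"), "resistance", "positive")
#' indicator_panel(matrix(1:6, 3, 2), c("r1", "r2", "r3"), sch)
#' @export
indicator_panel <- function(values, region_labels, scheme) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  missing_mask <- is.na(values)
  dimnames(values) <- list(region_labels, scheme$code)
  dimnames(missing_mask) <- dimnames(values)
  out <- structure(list(values = values,
                        region_labels = as.character(region_labels),
                        scheme = scheme,
                        missing_mask = missing_mask),
                   class = "indicator_panel")
  issues <- validate_panel(out)
  if (length(issues)) {
    stop_resilpp("invalid panel: %s", paste(vapply(issues, `[[`, "", "message"),
                                            collapse = "; "),
                 class = "resilpp_panel_error")
  }
  out
}

#' Validate a panel and report structural issues
#'
#' Checks the panel invariants (at least two regions, unique labels, scheme
#' length equal to the column count, observed cells finite, mask consistent
#' with `NA` placement) and returns a list of issues rather than raising.
#'
#' @param panel an object shaped like an `indicator_panel` (the constructor
#'   calls this itself; it can also be applied to hand-built lists).
#' @return A list, empty when all invariants hold.  Each issue is a list with
#'   a `message` and, where applicable, `row`/`col` coordinates.
#' @export
validate_panel <- function(panel) {
  issues <- list()
  add <- function(message, row = NA_integer_, col = NA_integer_) {
    issues[[length(issues) + 1L]] <<- list(message = message, row = row, col = col)
  }
  v <- panel$values
  if (!is.matrix(v) || !is.numeric(v)) {
    add("values must be a numeric matrix")
    return(issues)
  }
  m <- nrow(v); n <- ncol(v)
  if (m < 2L) add(sprintf("need at least 2 regions, got %d", m))
  if (n < 1L) add("need at least 1 indicator")
  if (length(panel$region_labels) != m) {
    add("region label count does not match row count")
  }
  dup <- unique(panel$region_labels[duplicated(panel$region_labels)])
  for (d in dup) add(sprintf("duplicate region label '%s'", d))
  if (nrow(panel$scheme) != n) add("scheme length does not match column count")
  if (!identical(dim(panel$missing_mask), dim(v))) {
    add("missing mask shape does not match values")
  } else {
    bad <- which((!is.finite(v)) & !panel$missing_mask, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      add(sprintf("non-finite observed cell at region %d, indicator %d",
                  bad[k, 1L], bad[k, 2L]),
          row = bad[k, 1L], col = bad[k, 2L])
    }
    masked_but_present <- which(panel$missing_mask & !is.na(v), arr.ind = TRUE)
    for (k in seq_len(nrow(masked_but_present))) {
      add(sprintf("cell at region %d, indicator %d masked missing but has a value",
                  masked_but_present[k, 1L], masked_but_present[k, 2L]),
          row = masked_but_present[k, 1L], col = masked_but_present[k, 2L])
    }
  }
  issues
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("indicator_panel: %d regions x %d indicators, %d missing cell(s)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  dims <- table(factor(x$scheme$dimension, levels = resilience_dimensions()))
  cat("dimensions:", paste(sprintf("%s=%d", names(dims), dims), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.indicator_scheme <- function(x, ...) {
  cat(sprintf("indicator_scheme: %d indicators (%d negative)\n",
              nrow(x), sum(x$attribute == "negative")))
  NextMethod()
}

# Internal: error if the panel still has missing cells.
assert_complete <- function(panel, what = "operation") {
  if (any(panel$missing_mask)) {
    stop_resilpp("%s requires a complete panel; %d missing cell(s) present",
                 what, sum(panel$missing_mask),
                 class = "resilpp_incomplete_error")
  }
  invisible(panel)
}
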