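#' Read an indicator scheme table
#'
#' The scheme file is a delimited table with columns `code`, `dimension`,
#' `attribute` (either the full words or the single letters `P`/`N`), and
#' optional `description` and `units`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return An [indicator_scheme()].
#' @export
read_scheme <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("code", "dimension", "attribute")
  if (!all(need %in% names(tab))) {
    stop_resilpp("scheme file must have columns: %s", paste(need, collapse = ", "),
                 class = "resilpp_io_error")
  }
  attr_full <- ifelse(toupper(tab$attribute) %in% c("P", "POSITIVE"),
                      "positive",
               ifelse(toupper(tab$attribute) %in% c("N", "NEGATIVE"),
                      "negative", NA))
  if (anyNA(attr_full)) {
    stop_resilpp("unknown attribute value(s): %s",
                 paste(unique(tab$attribute[is.na(attr_full)]), collapse = ", "),
                 class = "resilpp_io_error")
  }
  indicator_scheme(tab$code, tab$dimension, attr_full,
                   description = tab$description %||% "",
                   units = tab$units %||% "")
}

#' Read a region-by-indicator panel
#'
#' The panel file is a delimited table whose header row carries the
#' indicator codes, whose first column holds the region labels, and whose
#' empty cells mark missing values.  Header codes must match the scheme
#' exactly and in order.
#'
#' @param path panel file path.
#' @param scheme an [indicator_scheme()] or the path of a scheme file.
#' @param sep field separator.
#' @return An [indicator_panel()].
#' @export
read_panel <- function(path, scheme, sep = ",") {
  if (is.character(scheme)) scheme <- read_scheme(scheme, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  labels <- as.character(tab[[1L]])
  codes <- names(tab)[-1L]
  if (!identical(codes, scheme$code)) {
    stop_resilpp("header codes do not match scheme: file has [%s], scheme has [%s]",
                 paste(codes, collapse = ", "),
                 paste(scheme$code, collapse = ", "),
                 class = "resilpp_io_error")
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) {
    coerced <- suppressWarnings(apply(values, 2L, as.numeric))
    bad <- which(is.na(coerced) & !is.na(values), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_resilpp("non-numeric cell(s), first at row %d column %d",
                   bad[1L, 1L], bad[1L, 2L], class = "resilpp_io_error")
    }
    values <- coerced
  }
  indicator_panel(values, labels, scheme)
}

#' Write a panel to delimited text
#'
#' @param panel an [indicator_panel()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = ",") {
  v <- panel$values
  v[panel$missing_mask] <- NA
  out <- data.frame(region = panel$region_labels, v, check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read region coordinates
#'
#' Accepts either a delimited table with columns `label`, `x`, `y`, or a
#' GeoJSON file of point features (a `FeatureCollection` whose features have
#' point geometry and a label-like property).
#'
#' @param path file path; `.geojson`/`.json` files are parsed as GeoJSON.
#' @param sep field separator for delimited input.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
read_coordinates <- function(path, sep = ",") {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features %||% stop_resilpp("GeoJSON has no features",
                                           class = "resilpp_io_error")
    rows <- lapply(feats, function(f) {
      geom <- f$geometry
      if (!identical(geom$type, "Point")) {
        stop_resilpp("GeoJSON feature is not a Point", class = "resilpp_io_error")
      }
      props <- f$properties %||% list()
      label <- props$label %||% props$name %||% props$region %||%
        stop_resilpp("GeoJSON point lacks a label/name/region property",
                     class = "resilpp_io_error")
      data.frame(label = as.character(label),
                 x = as.numeric(geom$coordinates[[1L]]),
                 y = as.numeric(geom$coordinates[[2L]]))
    })
    do.call(rbind, rows)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!all(c("label", "x", "y") %in% names(tab))) {
      stop_resilpp("coordinate file must have columns label, x, y",
                   class = "resilpp_io_error")
    }
    tab[, c("label", "x", "y")]
  }
}

#' Run the full measurement pipeline
#'
#' Chains imputation, standardization, projection-pursuit weighting and
#' scoring (with per-dimension runs), Jenks classification, the
#' entropy-TOPSIS comparator, and — when coordinates are supplied — global
#' and local Moran analysis of the region scores.  All randomness fans out
#' from one root seed via per-stage derived seeds, so any stage can be rerun
#' in isolation and two runs with the same inputs are identical.
#'
#' @param panel an [indicator_panel()] (may contain missing cells).
#' @param coords optional coordinates (data frame `label`, `x`, `y`); when
#'   `NULL` the spatial stage is skipped with a notice in the manifest.
#' @param seed root integer seed.
#' @param config a [ga_config()] template for the optimizer stages.
#' @param imputation an [imputation_config()] template (its seed is
#'   overridden by the derived stage seed).
#' @param k Jenks class count.
#' @param variance_method Moran variance null, see [global_moran()].
#' @param n_perm permutation count for Moran inference.
#' @return A list of class `"pipeline_result"`: `measure` (a
#'   `measure_report`), `moran`, `local`, `weights_matrix`, `panel`
#'   (completed), `standardized`, `manifest`.
#' @export
run_pipeline <- function(panel, coords = NULL, seed = 1L,
                         config = ga_config(),
                         imputation = imputation_config(),
                         k = 5L,
                         variance_method = "randomization",
                         n_perm = 999L) {
  stages <- list()
  imputation$seed <- derive_seed(seed, "impute")
  complete <- impute(panel, imputation)
  stages$impute <- list(seed = imputation$seed,
                        n_imputed = sum(panel$missing_mask))
  std <- standardize(complete)
  config$seed <- derive_seed(seed, "measure")
  measure <- measure_resilience(std, config, k = k)
  stages$measure <- list(seed = config$seed)

  moran <- NULL; local <- NULL; W <- NULL
  if (is.null(coords)) {
    stages$spatial <- list(skipped = TRUE,
                           notice = "no coordinates supplied; spatial stage skipped")
  } else {
    idx <- match(panel$region_labels, coords$label)
    if (anyNA(idx)) {
      stop_resilpp("coordinates missing for region(s): %s",
                   paste(panel$region_labels[is.na(idx)], collapse = ", "),
                   class = "resilpp_io_error")
    }
    coords <- coords[idx, , drop = FALSE]
    W <- spatial_weights(coords, "inverse_distance")
    sc <- measure$scores$scores
    moran <- global_moran(sc, W, variance_method)
    perm <- moran_permutation_test(sc, W, n_perm,
                                   seed = derive_seed(seed, "perm"))
    moran$p_permutation <- perm$pseudo_p
    local <- local_moran(sc, W, n_perm, seed = derive_seed(seed, "lisa"))
    stages$spatial <- list(seed_perm = derive_seed(seed, "perm"),
                           seed_lisa = derive_seed(seed, "lisa"),
                           n_perm = n_perm)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("resilpp")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   root_seed = as.integer(seed),
                   stages = stages,
                   config = unclass(config),
                   imputation = unclass(imputation))
  structure(list(measure = measure, moran = moran, local = local,
                 weights_matrix = W, panel = complete, standardized = std,
                 manifest = manifest),
            class = "pipeline_result")
}

#' Write a pipeline result to disk
#'
#' Emits delimited tables (scores, weights, dimension scores, LISA table)
#' and a JSON report (classification, Moran report, manifest, including
#' md5 hashes of the written tables).
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- result$measure
  wtab <- data.frame(code = names(m$weights$projection_values),
                     projection_value = unname(m$weights$projection_values),
                     weight = unname(m$weights$weights))
  utils::write.table(wtab, file.path(dir, "weights.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  stab <- data.frame(region = names(m$scores$scores),
                     score = unname(m$scores$scores),
                     level = if (!is.null(m$classification)) m$classification$levels
                             else NA_integer_,
                     m$dimension_scores, check.names = FALSE)
  utils::write.table(stab, file.path(dir, "scores.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$local)) {
    utils::write.table(result$local$table, file.path(dir, "lisa.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(names(hashes))
  report <- list(
    classification = if (!is.null(m$classification)) {
      list(k = m$classification$k, breaks = m$classification$breaks,
           gvf = m$classification$gvf)
    },
    moran = if (!is.null(result$moran)) {
      r <- result$moran
      list(I = r$I, expected = r$expected, variance = r$variance,
           variance_method = r$variance_method, z = r$z,
           p_two_sided = r$p_two_sided, p_permutation = r$p_permutation)
    },
    objective_trace = m$scores$optimizer$trace,
    manifest = c(result$manifest, list(output_hashes = as.list(hashes))))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
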