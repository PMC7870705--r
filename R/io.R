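#' Read a genotype-counts table (TSV)
#'
#' Reads a tab-separated table of selfed-family genotype counts: required
#' columns `population`, `n_TT`, `n_TG`, `n_GG` (a header row is
#' mandatory; further columns such as a group label are carried through).
#' Malformed rows are reported with their line number and column.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A tibble of class `counts_table`.
#' @examples
#' path <- system.file("extdata", "rm7033_t1_counts.tsv", package = "gametx")
#' read_counts_tsv(path)
#' @export
read_counts_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("population", "n_TT", "n_TG", "n_GG")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("n_TT", "n_TG", "n_GG")) {
    vals <- raw[[col]]
    bad <- which(is.na(vals) | !grepl("^[0-9]+$", vals))
    if (length(bad) > 0) {
      abort(sprintf(
        "Line %d, column %s: \"%s\" is not a nonnegative integer.",
        bad[1] + 1L, col, vals[bad[1]] %||% "NA"))
    }
    raw[[col]] <- as.integer(vals)
  }
  dup <- raw$population[duplicated(raw$population)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate population id(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  out <- as_tibble(raw)
  class(out) <- c("counts_table", class(out))
  out
}

#' Write a genotype-counts table (TSV)
#'
#' @param data A counts table (columns `population`, `n_TT`, `n_TG`,
#'   `n_GG`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a per-plant marker-genotype table (TSV)
#'
#' Reads a tab-separated table with one row per plant: a `plant_id`
#' column, one column per marker in the same order as `map` (codes `T`,
#' `H`, `G`, or `-` for missing), and a `phenotype` column (`N` or `SS`,
#' or a sterile-pollen morphology label treated as SS). Marker columns
#' must match the map exactly, in order.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param map A [marker_map()].
#' @return A tibble of plant records suitable for [delimit_locus()].
#' @export
read_marker_tsv <- function(path, map) {
  stopifnot(inherits(map, "marker_map"))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"phenotype" %in% names(raw)) {
    abort("Missing required `phenotype` column.")
  }
  marker_cols <- setdiff(names(raw), c("plant_id", "phenotype"))
  if (!identical(marker_cols, map$marker)) {
    abort(sprintf(
      "Marker columns (%s) do not match the map order (%s).",
      paste(marker_cols, collapse = ", "),
      paste(map$marker, collapse = ", ")))
  }
  for (col in map$marker) {
    raw[[col]] <- normalize_calls(raw[[col]], context = col)
  }
  bad <- !raw$phenotype %in% c("N", PHENOTYPE_SS)
  if (any(bad)) {
    abort(sprintf("Line %d: unknown phenotype \"%s\" (expected N or SS).",
                  which(bad)[1] + 1L, raw$phenotype[which(bad)[1]]))
  }
  as_tibble(raw)
}

#' Read a marker map (TSV)
#'
#' Reads a tab-separated marker map: required column `marker`, optional
#' `bp` (physical position) and `cm` (genetic position), rows in map
#' order.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A [marker_map()].
#' @examples
#' path <- system.file("extdata", "marker_map_synthetic.tsv",
#'                     package = "gametx")
#' read_map_tsv(path)
#' @export
read_map_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"marker" %in% names(raw)) {
    abort("Missing required `marker` column.")
  }
  marker_map(raw$marker,
             bp = if ("bp" %in% names(raw)) as.numeric(raw$bp) else NULL,
             cm = if ("cm" %in% names(raw)) as.numeric(raw$cm) else NULL)
}

#' Write a per-plant marker-genotype table (TSV)
#'
#' Missing genotype calls are written with the conventional `-` token.
#'
#' @param records A plant-record tibble (as from
#'   [simulate_marker_population()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_tsv <- function(records, path) {
  out <- as_tibble(records)
  for (col in names(out)) {
    if (is.character(out[[col]])) {
      out[[col]][is.na(out[[col]])] <- "-"
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Bundle analysis results with run metadata
#'
#' Collects estimation/test/mapping results with the package version,
#' seed, and a content hash so a run is self-describing. Serialization
#' through [write_result_json()] / [read_result_json()] is lossless, and
#' the byte stream is deterministic for identical inputs (include a
#' `timestamp` only if you want one).
#'
#' @param ... Named result objects (tibbles, lists, or package result
#'   objects; coerced to plain lists for serialization).
#' @param seed The seed governing any randomness in the run.
#' @param timestamp Optional timestamp string; omitted by default to keep
#'   outputs byte-deterministic.
#' @return A list of class `result_bundle`.
#' @export
result_bundle <- function(..., seed = NULL, timestamp = NULL) {
  results <- list(...)
  if (length(results) > 0 && (is.null(names(results)) ||
                              any(names(results) == ""))) {
    abort("All results must be named.")
  }
  structure(list(
    metadata = list(
      package = "gametx",
      version = as.character(utils::packageVersion("gametx")),
      seed = seed,
      timestamp = timestamp
    ),
    results = results
  ), class = "result_bundle")
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    return(as.data.frame(x))
  }
  if (is.list(x)) {
    return(lapply(unclass(x), unclass_deep))
  }
  if (!is.null(attr(x, "class"))) {
    return(unclass(x))
  }
  x
}

#' Write results as JSON
#'
#' Canonical machine-readable output: scalars are unboxed and numbers are
#' written at full precision.
#'
#' @param x A [result_bundle()] or any list/tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Plain-text graphical genotypes
#'
#' Renders plant records as aligned text, one line per plant, the
#' conventional "graphical genotype" view of a recombinant screen.
#'
#' @param records A plant-record tibble.
#' @param map A [marker_map()].
#' @return A character vector of lines, invisibly; printed as a side
#'   effect.
#' @export
format_graphical_genotypes <- function(records, map) {
  stopifnot(inherits(map, "marker_map"))
  records <- as_tibble(records)
  ids <- if ("plant_id" %in% names(records)) {
    as.character(records$plant_id)
  } else {
    as.character(seq_len(nrow(records)))
  }
  idw <- max(nchar(c("plant", ids)))
  mw <- pmax(nchar(map$marker), 1L)
  pad <- function(x, w) mapply(formatC, x, width = w, USE.NAMES = FALSE)
  header <- paste(c(formatC("plant", width = idw),
                    pad(map$marker, mw),
                    "phenotype"), collapse = " ")
  lines <- vapply(seq_len(nrow(records)), function(i) {
    calls <- record_calls(records[i, , drop = FALSE], map)
    calls[is.na(calls)] <- "-"
    paste(c(formatC(ids[i], width = idw),
            pad(calls, mw),
            records$phenotype[i] %||% ""), collapse = " ")
  }, character(1))
  out <- c(header, lines)
  cat(out, sep = "\n")
  invisible(out)
}
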