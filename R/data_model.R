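#' Validate a data frame of candidate countries
#'
#' A country table holds one row per candidate country: a unique identifier,
#' the sovereign debt-to-GDP ratio, the conservation benefit fields (areas in
#' km2), and optional probability-of-success and cost columns. Additional
#' columns (governance indices, sovereignty flags, extra benefit metrics, ...)
#' are carried through untouched and can be referenced by screening rules or
#' used as alternative benefit fields.
#'
#' @param df A data frame with at least the columns `country_id`,
#'   `debt_to_gdp`, `eez_area_km2` and `coral_area_km2`. Optional columns
#'   `name`, `p_success` and `cost`; missing `p_success`/`cost` are filled
#'   with 1 (and the fill reported via [message()]).
#' @param percent If `TRUE`, `debt_to_gdp` is given in percent (60 = 60%) and
#'   is divided by 100 on input. The stored representation is always a ratio.
#' @return The validated data frame with class `country_table`.
#' @examples
#' ct <- country_table(data.frame(
#'   country_id = c("AAA", "BBB"), debt_to_gdp = c(0.5, 0.7),
#'   eez_area_km2 = c(1e5, 2e5), coral_area_km2 = c(100, 0)))
#' @export
country_table <- function(df, percent = FALSE) {
  if (!is.data.frame(df)) stop_validation("country table must be a data frame")
  required <- c("country_id", "debt_to_gdp", "eez_area_km2", "coral_area_km2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation("country table: missing required column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  df$country_id <- as.character(df$country_id)
  dup <- unique(df$country_id[duplicated(df$country_id)])
  if (length(dup) > 0L) {
    stop_validation("country table: duplicate country_id: %s",
                    paste(dup, collapse = ", "))
  }
  if (!"name" %in% names(df)) df$name <- df$country_id

  for (col in c("debt_to_gdp", "eez_area_km2", "coral_area_km2")) {
    df[[col]] <- coerce_numeric(df[[col]], col, "country table")
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0L) {
      stop_validation("country table: column '%s' must be finite and >= 0 (row %d, country %s)",
                      col, bad[1L], df$country_id[bad[1L]])
    }
  }
  if (isTRUE(percent)) df$debt_to_gdp <- df$debt_to_gdp / 100

  if (!"p_success" %in% names(df)) {
    df$p_success <- 1
    message("country table: 'p_success' absent; filled with default 1")
  } else {
    df$p_success <- coerce_numeric(df$p_success, "p_success", "country table")
    bad <- which(!is.finite(df$p_success) | df$p_success < 0 | df$p_success > 1)
    if (length(bad) > 0L) {
      stop_validation("country table: p_success must be in [0,1] (row %d, country %s)",
                      bad[1L], df$country_id[bad[1L]])
    }
  }
  if (!"cost" %in% names(df)) {
    df$cost <- 1
    message("country table: 'cost' absent; filled with default 1")
  } else {
    df$cost <- coerce_numeric(df$cost, "cost", "country table")
    bad <- which(!is.finite(df$cost) | df$cost <= 0)
    if (length(bad) > 0L) {
      stop_validation("country table: cost must be > 0 (row %d, country %s)",
                      bad[1L], df$country_id[bad[1L]])
    }
  }
  rownames(df) <- NULL
  class(df) <- c("country_table", "data.frame")
  df
}

#' Read a candidate-country table from CSV
#'
#' @param path Path to a CSV file (header row, `.` decimal separator, UTF-8).
#' @inheritParams country_table
#' @return A [country_table].
#' @export
load_country_table <- function(path, percent = FALSE) {
  if (!file.exists(path)) stop_validation("country table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  country_table(df, percent = percent)
}

#' Write a country table to CSV at full precision
#'
#' The writer is the inverse of [load_country_table()]: a write/read
#' round-trip preserves every numeric field to full double precision.
#'
#' @param countries A [country_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(countries, path) {
  stopifnot(inherits(countries, "country_table"))
  df <- as.data.frame(countries)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a per-country threat-layer table
#'
#' Holds the mean normalized human-impact value of each threat layer within
#' each country's EEZ (each in \[0, 1\], as in cumulative human-impact
#' mapping). Every country must have a value for every layer: a missing cell
#' is a validation error, never imputed as zero, since a silent zero would
#' masquerade as "no threat".
#'
#' @param values A numeric matrix (countries x layers) with rownames =
#'   country ids and colnames = layer names, or a data frame with a
#'   `country_id` column followed by one numeric column per layer.
#' @return An object of class `threat_table`: a list with elements
#'   `layer_names`, `country_ids` and `values` (the matrix).
#' @export
threat_table <- function(values) {
  if (is.data.frame(values)) {
    if (!"country_id" %in% names(values)) {
      stop_validation("threat table data frame needs a 'country_id' column")
    }
    ids <- as.character(values$country_id)
    m <- as.matrix(values[setdiff(names(values), "country_id")])
    rownames(m) <- ids
    values <- m
  }
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("threat table needs a matrix with country rownames and layer colnames")
  }
  storage.mode(values) <- "double"
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0L) {
    stop_validation("threat table: duplicate country_id: %s", paste(dup, collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_validation("threat table: value %s out of [0,1] at (country %s, layer %s)",
                    format(values[bad[1L, 1L], bad[1L, 2L]]),
                    rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  }
  structure(
    list(layer_names = colnames(values), country_ids = rownames(values),
         values = values),
    class = "threat_table")
}

#' Read a threat-layer table from CSV
#'
#' Two layouts are accepted. `wide`: one row per country, a `country_id`
#' column, one column per layer (layer order = file column order). `long`:
#' columns `country_id`, `layer_name`, `value` (layer order = first
#' appearance). Both layouts of the same content load to identical tables.
#'
#' @param path Path to the CSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @return A [threat_table].
#' @export
load_threat_layers <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_validation("threat layer file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "wide") {
    if (!"country_id" %in% names(df)) {
      stop_validation("wide threat file needs a 'country_id' column")
    }
    layer_cols <- setdiff(names(df), "country_id")
    for (col in layer_cols) df[[col]] <- coerce_numeric(df[[col]], col, "threat table")
    miss <- which(is.na(as.matrix(df[layer_cols])), arr.ind = TRUE)
    if (nrow(miss) > 0L) {
      stop_validation("threat table: missing cell (country %s, layer %s); cells must be complete",
                      df$country_id[miss[1L, 1L]], layer_cols[miss[1L, 2L]])
    }
    threat_table(df)
  } else {
    need <- c("country_id", "layer_name", "value")
    if (!all(need %in% names(df))) {
      stop_validation("long threat file needs columns: %s", paste(need, collapse = ", "))
    }
    df$value <- coerce_numeric(df$value, "value", "threat table")
    ids <- unique(as.character(df$country_id))
    layers <- unique(as.character(df$layer_name))
    key <- paste(df$country_id, df$layer_name, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE]
      stop_validation("threat table: duplicate cell (country %s, layer %s)",
                      d$country_id[1L], d$layer_name[1L])
    }
    m <- matrix(NA_real_, length(ids), length(layers), dimnames = list(ids, layers))
    m[cbind(match(df$country_id, ids), match(df$layer_name, layers))] <- df$value
    miss <- which(is.na(m), arr.ind = TRUE)
    if (nrow(miss) > 0L) {
      stop_validation("threat table: missing cell (country %s, layer %s); cells must be complete",
                      ids[miss[1L, 1L]], layers[miss[1L, 2L]])
    }
    threat_table(m)
  }
}

#' Define a threat-classification scheme
#'
#' A scheme partitions threat layers into those a marine protected area can
#' abate (fishing pressure, benthic structures, direct human impacts) and
#' those it cannot (e.g. climate-driven heat stress or acidification).
#' Whether shipping is treated as abatable is the canonical sensitivity
#' variant: two schemes differing only in shipping's class are both valid.
#'
#' @param scheme_id Short identifier for the scheme.
#' @param assignment Named character vector or list mapping each layer name
#'   to `"abatable"` or `"unabatable"`. Both classes must be non-empty.
#' @return An object of class `classification_scheme`.
#' @export
classification_scheme <- function(scheme_id, assignment) {
  if (!is_string(scheme_id)) stop_validation("scheme_id must be a single string")
  assignment <- unlist(assignment)
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop_validation("scheme '%s': assignment must be named by layer", scheme_id)
  }
  dup <- unique(names(assignment)[duplicated(names(assignment))])
  if (length(dup) > 0L) {
    stop_validation("scheme '%s': layer assigned more than once: %s",
                    scheme_id, paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(assignment), c("abatable", "unabatable"))
  if (length(bad) > 0L) {
    stop_validation("scheme '%s': unknown class label(s): %s (must be abatable/unabatable)",
                    scheme_id, paste(bad, collapse = ", "))
  }
  if (!all(c("abatable", "unabatable") %in% assignment)) {
    stop_validation("scheme '%s': needs at least one abatable and one unabatable layer",
                    scheme_id)
  }
  structure(list(scheme_id = scheme_id,
                 assignment = stats::setNames(as.character(assignment), names(assignment))),
            class = "classification_scheme")
}

#' Read a classification scheme from JSON or CSV
#'
#' JSON layout: `{"scheme_id": "...", "assignment": {"layer": "abatable", ...}}`.
#' CSV layout: columns `layer_name`, `class` (the scheme id defaults to the
#' file name without extension).
#'
#' @param path Path to the scheme file.
#' @param scheme_id Optional override of the scheme id.
#' @return A [classification_scheme].
#' @export
load_classification <- function(path, scheme_id = NULL) {
  if (!file.exists(path)) stop_validation("scheme file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$assignment)) stop_validation("scheme file %s: no 'assignment' field", path)
    id <- scheme_id %||% obj$scheme_id %||% sub("\\.[^.]*$", "", basename(path))
    classification_scheme(id, obj$assignment)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("layer_name", "class") %in% names(df))) {
      stop_validation("scheme CSV %s needs columns layer_name, class", path)
    }
    id <- scheme_id %||% sub("\\.[^.]*$", "", basename(path))
    classification_scheme(id, stats::setNames(df$class, df$layer_name))
  }
}

#' Write a classification scheme to JSON
#' @param scheme A [classification_scheme].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(scheme, path) {
  stopifnot(inherits(scheme, "classification_scheme"))
  jsonlite::write_json(list(scheme_id = scheme$scheme_id,
                            assignment = as.list(scheme$assignment)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write scenario results and the comparison report to disk
#'
#' Writes one ranked CSV per scenario (columns `rank`, `country_id`, `b`,
#' `i_abatable`, `i_unabatable`, `discount`, `expected_benefit`, `p_success`,
#' `cost`, `ce_score`), the comparison report as `report.json`, and a
#' `manifest.json` recording scheme ids, the alpha used per scenario, the
#' seed and the configuration. Benefit-scale columns are rounded to 2
#' decimals and dimensionless columns to 4; scores are carried at full
#' precision internally and rounded only here. Re-running on identical
#' inputs reproduces byte-identical files (no timestamps).
#'
#' @param results List of `scenario_result` objects (see [run_scenario()]).
#' @param report Optional `comparison_report` (see [compare_topk()]).
#' @param out_dir Output directory, created if needed.
#' @param config Optional run configuration echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @return Invisibly, the manifest list (with element `files`).
#' @export
write_results <- function(results, report = NULL, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  if (length(results) == 0L) {
    warning("write_results: empty scenario list; writing manifest only")
  }
  files <- character(0)
  scenario_meta <- list()
  for (res in results) {
    stopifnot(inherits(res, "scenario_result"))
    fn <- paste0("scenario_", sanitize_filename(res$scenario_id), ".csv")
    df <- res$scored
    out <- data.frame(
      rank = df$rank,
      country_id = df$country_id,
      b = round(df$b, 2),
      i_abatable = round(df$i_abatable, 4),
      i_unabatable = round(df$i_unabatable, 4),
      discount = round(df$discount, 4),
      expected_benefit = round(df$expected_benefit, 2),
      p_success = round(df$p_success, 4),
      cost = round(df$cost, 4),
      ce_score = round(df$ce_score, 2),
      stringsAsFactors = FALSE)
    utils::write.csv(out, file.path(out_dir, fn), row.names = FALSE, quote = FALSE)
    files <- c(files, fn)
    scenario_meta[[res$scenario_id]] <- list(
      file = fn, alpha = res$alpha_used, pool_size = res$pool_size,
      top_k = res$top_k, scheme_id = res$scheme_id, benefit_field = res$benefit_field)
  }
  if (!is.null(report)) {
    stopifnot(inherits(report, "comparison_report"))
    jsonlite::write_json(unclass_report(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "report.json")
  }
  manifest <- list(scenarios = scenario_meta, seed = seed, config = config,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- c(files, "manifest.json")
  invisible(manifest)
}

# JSON-friendly view of a comparison report (matrix as labelled nested arrays).
unclass_report <- function(report) {
  list(
    compared_scenarios = report$compared_scenarios,
    excluded_scenarios = report$excluded_scenarios,
    k = report$k,
    jaccard = list(scenario_ids = report$compared_scenarios,
                   matrix = apply(report$jaccard, 1L, as.list, simplify = FALSE)),
    jaccard_min = report$jaccard_min,
    jaccard_max = report$jaccard_max,
    jaccard_mean = report$jaccard_mean,
    union_set = report$union_set,
    membership = report$membership)
}
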