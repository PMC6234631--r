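# Element mappings and coding-inconsistency harmonization.
#
# An element mapping links one source variable (dataset, visit, short_name)
# to one canonical element (m:1 — many source variables may serve one
# element, but a source variable never maps to two elements). A coding map
# translates a source dataset's categorical codes onto the uniform coding of
# the canonical element; it is the machine form of a code-harmonization
# table with one row per (dataset, variable, source code).

MAPPING_COLUMNS <- c("dataset", "visit", "source_short_name", "element_id")
CODING_MAP_COLUMNS <- c("dataset", "source_short_name", "source_code",
                        "source_label", "uniform_code", "uniform_label")

#' Read an element-mapping CSV
#'
#' @param path CSV with columns dataset, visit, source_short_name, element_id.
#' @return An `xs_mappings` data frame.
#' @export
read_mappings <- function(path) {
  raw <- read_csv_chr(path)
  require_columns(raw, MAPPING_COLUMNS, sprintf("mapping file '%s'", path),
                  path = path)
  as_mappings(raw[MAPPING_COLUMNS])
}

#' Construct an element-mapping table
#' @param df Data frame with columns dataset, visit, source_short_name,
#'   element_id.
#' @return An `xs_mappings` data frame.
#' @export
as_mappings <- function(df) {
  require_columns(df, MAPPING_COLUMNS, "mapping table")
  key <- paste(df$dataset, df$visit, df$source_short_name, sep = "\r")
  multi <- tapply(df$element_id, key, function(e) length(unique(e)) > 1)
  if (any(multi)) {
    offenders <- gsub("\r", "/", names(multi)[multi])
    xs_validation_error(sprintf(
      "source variable(s) mapped to more than one canonical element: %s",
      paste(offenders, collapse = ", ")), offenders = offenders)
  }
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("xs_mappings", "data.frame"))
}

#' Validate mappings against the dictionaries they reference
#'
#' Checks that every mapped source variable exists in its dataset's
#' dictionary and every target element exists in the canonical dictionary.
#'
#' @param mappings An `xs_mappings` table.
#' @param canon An `xs_canonical_dictionary`.
#' @param dicts List of `xs_data_dictionary`, one per mapped dataset.
#' @return `mappings`, invisibly.
#' @export
validate_mappings <- function(mappings, canon, dicts) {
  names(dicts) <- vapply(dicts, function(d) d$dataset_id, character(1))
  for (i in seq_len(nrow(mappings))) {
    m <- mappings[i, ]
    if (!m$element_id %in% canon$elements$element_id) {
      xs_validation_error(sprintf(
        "mapping references unknown canonical element '%s'", m$element_id))
    }
    d <- dicts[[m$dataset]]
    if (is.null(d)) {
      xs_validation_error(sprintf(
        "mapping references unknown dataset '%s'", m$dataset))
    }
    if (is.null(dict_variable(d, m$visit, m$source_short_name))) {
      xs_validation_error(sprintf(
        "mapping references unknown source variable %s/%s/%s",
        m$dataset, m$visit, m$source_short_name))
    }
  }
  invisible(mappings)
}

#' Construct a coding map
#'
#' @param df Data frame with columns dataset, source_short_name, source_code,
#'   source_label, uniform_code, uniform_label. Within one
#'   (dataset, variable), source codes must be unique.
#' @return An `xs_coding_map` data frame.
#' @export
as_coding_map <- function(df) {
  require_columns(df, CODING_MAP_COLUMNS, "coding map")
  key <- paste(df$dataset, df$source_short_name, df$source_code, sep = "\r")
  if (anyDuplicated(key)) {
    xs_validation_error("duplicate source codes within one (dataset, variable) in coding map")
  }
  df <- df[CODING_MAP_COLUMNS]
  rownames(df) <- NULL
  structure(df, class = c("xs_coding_map", "data.frame"))
}

#' Read a coding-map CSV
#' @param path CSV path.
#' @return An `xs_coding_map`.
#' @export
read_coding_map <- function(path) {
  raw <- read_csv_chr(path)
  require_columns(raw, CODING_MAP_COLUMNS, sprintf("coding map '%s'", path),
                  path = path)
  as_coding_map(raw)
}

#' Write a coding map to CSV
#' @param map An `xs_coding_map`.
#' @param path Output path.
#' @export
write_coding_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, na = "")
  invisible(path)
}

empty_coding_map <- function() {
  as_coding_map(as.data.frame(
    setNames(rep(list(character(0)), length(CODING_MAP_COLUMNS)),
             CODING_MAP_COLUMNS), stringsAsFactors = FALSE))
}

# A source domain is compared as a *set* of (code, case-folded label) pairs:
# this flags both code shifts (0/1 vs 1/2) and label permutations
# (1=Female vs 1=Male) while ignoring label case and display order.
normalize_domain <- function(dom) {
  sort(paste(dom$code, tolower(dom$label), sep = "\r"))
}

#' Detect coding inconsistencies across datasets
#'
#' For every categorical canonical element with at least one mapped source
#' variable, compares the value domains of all mapped sources. The element
#' is inconsistent when any two sources disagree on the set of
#' (code, case-folded label) pairs. Numeric elements are never flagged.
#'
#' @param canon An `xs_canonical_dictionary`.
#' @param dicts List of `xs_data_dictionary`.
#' @param mappings An `xs_mappings` table (validated against both sides).
#' @return A list of `xs_inconsistency_report`s, one per categorical element
#'   with mapped sources. Each report holds `element_id`, `sources` (named
#'   list of domain data frames, names `dataset/visit/short_name`) and
#'   `is_inconsistent`.
#' @export
detect_inconsistencies <- function(canon, dicts, mappings) {
  validate_mappings(mappings, canon, dicts)
  names(dicts) <- vapply(dicts, function(d) d$dataset_id, character(1))
  el <- canon$elements
  reports <- list()
  for (i in seq_len(nrow(el))) {
    if (el$var_type[i] != "categorical") next
    eid <- el$element_id[i]
    rows <- mappings[mappings$element_id == eid, , drop = FALSE]
    if (nrow(rows) == 0) next
    sources <- list()
    for (j in seq_len(nrow(rows))) {
      m <- rows[j, ]
      var <- dict_variable(dicts[[m$dataset]], m$visit, m$source_short_name)
      sources[[paste(m$dataset, m$visit, m$source_short_name, sep = "/")]] <-
        var$domain[[1]]
    }
    norm <- unique(vapply(sources, function(d) paste(normalize_domain(d),
                                                     collapse = ";"),
                          character(1)))
    reports[[eid]] <- structure(
      list(element_id = eid, sources = sources,
           is_inconsistent = length(norm) > 1),
      class = "xs_inconsistency_report")
  }
  structure(unname(reports), class = "xs_inconsistency_reports")
}

#' Build a coding map from an inconsistency report
#'
#' Joins each source (code, label) pair through a reviewer-supplied label
#' correspondence onto the uniform domain: source label -> uniform label ->
#' uniform code. The label correspondence is explicit input — semantic label
#' equivalence (e.g. "M" vs "Male") is a human judgement the engine refuses
#' to guess; an unmatched label is an error listing the offenders.
#'
#' @param report One `xs_inconsistency_report`.
#' @param uniform_domain Data frame (code, label): the element's uniform
#'   coding, in display order.
#' @param label_match Named character vector or list mapping each (case-folded)
#'   source label to its uniform label.
#' @return An `xs_coding_map` with one row per (dataset, variable, source
#'   code) across the report's sources.
#' @export
build_coding_map <- function(report, uniform_domain, label_match) {
  label_match <- unlist(label_match)
  names(label_match) <- tolower(names(label_match))
  rows <- list()
  unmatched <- character(0)
  for (src in names(report$sources)) {
    parts <- strsplit(src, "/", fixed = TRUE)[[1]]
    dom <- report$sources[[src]]
    for (k in seq_len(nrow(dom))) {
      ul <- unname(label_match[tolower(dom$label[k])])
      if (is.na(ul)) {
        unmatched <- c(unmatched, dom$label[k])
        next
      }
      uc <- uniform_domain$code[tolower(uniform_domain$label) == tolower(ul)]
      if (length(uc) != 1) {
        xs_validation_error(sprintf(
          "uniform label '%s' not present exactly once in the uniform domain", ul))
      }
      rows[[length(rows) + 1]] <- data.frame(
        dataset = parts[1], source_short_name = parts[3],
        source_code = dom$code[k], source_label = dom$label[k],
        uniform_code = uc,
        uniform_label = uniform_domain$label[uniform_domain$code == uc],
        stringsAsFactors = FALSE)
    }
  }
  if (length(unmatched)) {
    xs_unmapped_label_error(sprintf(
      "source label(s) with no uniform correspondence (manual review needed): %s",
      paste(unique(unmatched), collapse = ", ")), labels = unique(unmatched))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$dataset, out$source_short_name,
                               out$source_code, sep = "\r")), , drop = FALSE]
  as_coding_map(out)
}

#' Translate a source code to its uniform code
#'
#' Vectorised over `raw_code`. A variable with no rows in the coding map was
#' never flagged as inconsistent and its codes pass through untouched;
#' missing values (NA or empty string) pass through as missing. A variable
#' that *does* have map rows but receives a code not among them signals an
#' unknown-code error: a data/dictionary mismatch must surface, never be
#' silently passed along.
#'
#' @param map An `xs_coding_map` (may be empty).
#' @param dataset_id,source_short_name Which variable the codes belong to.
#' @param raw_code Character vector of source codes.
#' @return Character vector of uniform codes, same length as `raw_code`.
#' @export
harmonize_value <- function(map, dataset_id, source_short_name, raw_code) {
  raw_code <- as.character(raw_code)
  rows <- map[map$dataset == dataset_id &
                map$source_short_name == source_short_name, , drop = FALSE]
  if (nrow(rows) == 0) return(raw_code)
  missing <- is.na(raw_code) | !nzchar(raw_code)
  out <- raw_code
  idx <- match(raw_code[!missing], rows$source_code)
  if (anyNA(idx)) {
    bad <- unique(raw_code[!missing][is.na(idx)])
    xs_unknown_code_error(sprintf(
      "code(s) %s of %s/%s not present in the coding map (known codes: %s)",
      paste(bad, collapse = ", "), dataset_id, source_short_name,
      paste(rows$source_code, collapse = ", ")), codes = bad)
  }
  out[!missing] <- rows$uniform_code[idx]
  out[missing] <- NA_character_
  out
}

#' The domain a source variable exposes after harmonization
#' @keywords internal
harmonized_domain <- function(map, dataset_id, source_short_name, dom) {
  rows <- map[map$dataset == dataset_id &
                map$source_short_name == source_short_name, , drop = FALSE]
  if (nrow(rows) == 0) return(dom)
  data.frame(code = rows$uniform_code, label = rows$uniform_label,
             stringsAsFactors = FALSE)
}

#' Rewrite a dictionary's value domains through a coding map
#'
#' Produces the dictionary as it stands after load-time harmonization:
#' every variable with coding-map rows gets its domain replaced by the
#' mapped uniform (code, label) pairs; unmapped variables are untouched.
#' Re-running [detect_inconsistencies()] on dictionaries rewritten with a
#' complete coding map reports no inconsistency.
#'
#' @param dict An `xs_data_dictionary`.
#' @param map An `xs_coding_map`.
#' @return The rewritten `xs_data_dictionary`.
#' @export
apply_coding_map_to_dictionary <- function(dict, map) {
  v <- dict$variables
  v$domain <- lapply(seq_len(nrow(v)), function(i)
    harmonized_domain(map, dict$dataset_id, v$short_name[i], v$domain[[i]]))
  dict$variables <- v
  dict
}

#' Write inconsistency reports as CSV
#'
#' One row per (element, source, code): the long form of the per-dataset
#' domain comparison.
#'
#' @param reports An `xs_inconsistency_reports` list.
#' @param path Output CSV path.
#' @export
write_inconsistency_report <- function(reports, path) {
  rows <- list()
  for (r in reports) {
    for (src in names(r$sources)) {
      dom <- r$sources[[src]]
      parts <- strsplit(src, "/", fixed = TRUE)[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        element_id = r$element_id, dataset = parts[1], visit = parts[2],
        source_short_name = parts[3],
        domain = format_domain(dom),
        is_inconsistent = r$is_inconsistent, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(0), dataset = character(0),
               visit = character(0), source_short_name = character(0),
               domain = character(0), is_inconsistent = logical(0))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.xs_inconsistency_reports <- function(x, ...) {
  n_bad <- sum(vapply(x, function(r) r$is_inconsistent, logical(1)))
  cat(sprintf("<inconsistency reports> %d categorical element(s) checked, %d inconsistent\n",
              length(x), n_bad))
  for (r in x) {
    if (!r$is_inconsistent) next
    cat(sprintf("  %s:\n", r$element_id))
    for (src in names(r$sources)) {
      cat(sprintf("    %-30s %s\n", src, format_domain(r$sources[[src]])))
    }
  }
  invisible(x)
}
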