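# Per-dataset data dictionaries: parsing, validation, serialization.
#
# A data dictionary CSV has one row per variable with columns
#   dataset, visit, short_name, display_name, description, type, unit,
#   domain, labels
# where `domain` encodes the value domain of a categorical variable as
# "code=label;code=label" pairs in display order, and `labels` holds
# "|"-separated synonyms. Codes are opaque tokens: the same numeral can mean
# different things in different datasets, so codes are never interpreted
# numerically anywhere in the package.

VAR_TYPES <- c("identifier", "numeric", "categorical", "text", "date")
DICT_COLUMNS <- c("dataset", "visit", "short_name", "display_name",
                  "description", "type", "unit", "domain", "labels")

#' Parse a "code=label;code=label" value-domain string
#'
#' @param x A single character string (may be empty).
#' @return A data frame with character columns `code` and `label`, in the
#'   order the pairs appear in `x`.
#' @keywords internal
parse_domain <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(code = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regexpr("=", parts, fixed = TRUE)
  if (any(m < 0)) {
    xs_format_error(sprintf("malformed domain entry (expected code=label): %s",
                            paste(parts[m < 0], collapse = ", ")))
  }
  data.frame(code  = trimws(substr(parts, 1, m - 1)),
             label = trimws(substr(parts, m + 1, nchar(parts))),
             stringsAsFactors = FALSE)
}

format_domain <- function(dom) {
  if (is.null(dom) || nrow(dom) == 0) return("")
  paste(paste(dom$code, dom$label, sep = "="), collapse = ";")
}

parse_synonyms <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' Read and validate a per-dataset data dictionary
#'
#' Parses a dictionary CSV (one row per variable) into a `xs_data_dictionary`
#' object and enforces the structural invariants: unique `short_name` within
#' each visit, a non-empty duplicate-free domain exactly for categorical
#' variables, units only on numeric variables, and exactly one
#' identifier-typed variable per visit (the subject key).
#'
#' @param path Path to the dictionary CSV.
#' @return An object of class `xs_data_dictionary`: a list with
#'   `dataset_id`, `visits` (in first-seen order) and `variables`, a data
#'   frame with list-columns `domain` (code/label data frame) and `labels`
#'   (character vector of synonyms).
#' @export
parse_data_dictionary <- function(path) {
  raw <- read_csv_chr(path)
  require_columns(raw, DICT_COLUMNS, sprintf("data dictionary '%s'", path),
                  path = path)
  if (nrow(raw) == 0) {
    xs_validation_error(sprintf("data dictionary '%s' defines no variables", path))
  }
  ids <- unique(raw$dataset)
  if (length(ids) != 1 || !is_token(ids)) {
    xs_validation_error(sprintf(
      "data dictionary '%s' must name exactly one dataset (found: %s)",
      path, paste(ids, collapse = ", ")))
  }
  bad_type <- setdiff(unique(raw$type), VAR_TYPES)
  if (length(bad_type)) {
    xs_validation_error(sprintf("unknown variable type(s): %s",
                                paste(bad_type, collapse = ", ")))
  }
  vars <- data.frame(visit = raw$visit,
                     short_name = raw$short_name,
                     display_name = raw$display_name,
                     description = raw$description,
                     var_type = raw$type,
                     unit = raw$unit,
                     stringsAsFactors = FALSE)
  vars$domain <- lapply(raw$domain, parse_domain)
  vars$labels <- lapply(raw$labels, parse_synonyms)
  dict <- structure(list(dataset_id = ids,
                         visits = unique(raw$visit),
                         variables = vars),
                    class = "xs_data_dictionary")
  validate_data_dictionary(dict)
  dict
}

#' Validate a data dictionary object
#'
#' @param dict An `xs_data_dictionary`.
#' @return `dict`, invisibly; signals a validation error otherwise.
#' @export
validate_data_dictionary <- function(dict) {
  v <- dict$variables
  if (any(!is_token(v$short_name))) {
    xs_validation_error("empty short_name in data dictionary")
  }
  for (visit in dict$visits) {
    vv <- v[v$visit == visit, , drop = FALSE]
    dup <- unique(vv$short_name[duplicated(vv$short_name)])
    if (length(dup)) {
      xs_validation_error(sprintf(
        "duplicate short_name(s) within visit '%s': %s",
        visit, paste(dup, collapse = ", ")), duplicates = dup)
    }
    n_id <- sum(vv$var_type == "identifier")
    if (n_id != 1) {
      xs_validation_error(sprintf(
        "visit '%s' must have exactly one identifier variable (found %d)",
        visit, n_id))
    }
  }
  if (!all(v$visit %in% dict$visits)) {
    xs_validation_error("variable references a visit not in the visit list")
  }
  for (i in seq_len(nrow(v))) {
    dom <- v$domain[[i]]
    if (v$var_type[i] == "categorical") {
      if (nrow(dom) == 0) {
        xs_validation_error(sprintf(
          "categorical variable '%s' (visit %s) has an empty domain",
          v$short_name[i], v$visit[i]))
      }
      if (anyDuplicated(dom$code)) {
        xs_validation_error(sprintf(
          "duplicate codes in domain of '%s': %s", v$short_name[i],
          paste(unique(dom$code[duplicated(dom$code)]), collapse = ", ")))
      }
    } else if (nrow(dom) > 0) {
      xs_validation_error(sprintf(
        "non-categorical variable '%s' must not declare a domain",
        v$short_name[i]))
    }
    if (nzchar(v$unit[i]) && v$var_type[i] != "numeric") {
      xs_validation_error(sprintf(
        "unit is only allowed on numeric variables ('%s')", v$short_name[i]))
    }
  }
  invisible(dict)
}

#' Serialize a data dictionary back to its CSV layout
#'
#' Inverse of [parse_data_dictionary()]: `parse(write(parse(f)))` reproduces
#' the parsed structure field for field.
#'
#' @param dict An `xs_data_dictionary`.
#' @param path Output CSV path.
#' @export
write_data_dictionary <- function(dict, path) {
  v <- dict$variables
  out <- data.frame(dataset = dict$dataset_id,
                    visit = v$visit,
                    short_name = v$short_name,
                    display_name = v$display_name,
                    description = v$description,
                    type = v$var_type,
                    unit = v$unit,
                    domain = vapply(v$domain, format_domain, character(1)),
                    labels = vapply(v$labels, paste, character(1), collapse = "|"),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up one variable definition
#' @keywords internal
dict_variable <- function(dict, visit, short_name) {
  v <- dict$variables
  hit <- which(v$visit == visit & v$short_name == short_name)
  if (length(hit) != 1) return(NULL)
  v[hit, , drop = FALSE]
}

identifier_variable <- function(dict, visit) {
  v <- dict$variables
  v$short_name[v$visit == visit & v$var_type == "identifier"][1]
}

#' @export
print.xs_data_dictionary <- function(x, ...) {
  cat(sprintf("<data dictionary> dataset '%s': %d variable(s) across %d visit(s) (%s)\n",
              x$dataset_id, nrow(x$variables), length(x$visits),
              paste(x$visits, collapse = ", ")))
  invisible(x)
}
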