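# Relational store: dictionary-driven schema generation and CSV loading.
#
# The store is a single embedded SQLite file (or in-memory database) holding
# one table per (dataset, visit, part). Wide visits are split into parts of
# at most `max_columns` columns with the subject identifier replicated into
# every part, so any part can answer a distinct-subject count on its own and
# parts combine on the identifier. Coding harmonization is applied at load
# time — stored categorical codes are already uniform, so query translation
# uses one uniform coding for every dataset.

# Abstract storage types; the dialect layer maps them to SQL column types.
STORAGE_TYPES <- c(identifier = "text_key", numeric = "double",
                   categorical = "token", text = "text", date = "date_text")

SQL_DIALECTS <- list(
  sqlite = c(text_key = "TEXT", double = "REAL", token = "TEXT",
             text = "TEXT", date_text = "TEXT"),
  mysql  = c(text_key = "VARCHAR(255)", double = "DOUBLE",
             token = "VARCHAR(64)", text = "TEXT", date_text = "VARCHAR(10)"))

#' Storage type for a variable type
#'
#' Deterministic map from dictionary variable types to abstract storage
#' types: a declared decimal/numeric becomes a double-precision real column,
#' identifiers become text keys, categorical codes are stored as opaque text
#' tokens, dates as ISO-8601 text.
#'
#' @param var_type One of identifier, numeric, categorical, text, date.
#' @return The storage type token.
#' @export
storage_type_for <- function(var_type) {
  st <- STORAGE_TYPES[var_type]
  if (anyNA(st)) {
    xs_abort(sprintf("unknown variable type '%s'",
                     paste(var_type[is.na(st)], collapse = ", ")),
             "xs_config_error")
  }
  unname(st)
}

sql_column_type <- function(storage_type, dialect = "sqlite") {
  map <- SQL_DIALECTS[[dialect]]
  if (is.null(map)) xs_abort(sprintf("unknown SQL dialect '%s'", dialect),
                             "xs_config_error")
  unname(map[storage_type])
}

#' Generate table specs and DDL for a dataset
#'
#' One table per (visit, part): variables are packed into parts in
#' dictionary order, at most `max_columns` columns per part, with the
#' visit's identifier column replicated into every part. Physical names are
#' `<dataset>_<visit>_part<N>`.
#'
#' @param dict An `xs_data_dictionary`.
#' @param max_columns Maximum columns per physical table (>= 2).
#' @param dialect SQL dialect for the emitted DDL ("sqlite" or "mysql").
#' @return A list with `specs` (list of `xs_table_spec`) and `ddl`
#'   (character vector of CREATE TABLE statements).
#' @export
create_schema <- function(dict, max_columns = 900, dialect = "sqlite") {
  if (max_columns < 2) {
    xs_schema_error("max_columns must be at least 2")
  }
  specs <- list()
  ddl <- character(0)
  for (visit in dict$visits) {
    vv <- dict$variables[dict$variables$visit == visit, , drop = FALSE]
    id_col <- vv$short_name[vv$var_type == "identifier"]
    if (length(id_col) != 1) {
      xs_schema_error(sprintf(
        "visit '%s' of dataset '%s' has no identifier variable",
        visit, dict$dataset_id))
    }
    others <- vv[vv$var_type != "identifier", , drop = FALSE]
    per_part <- max_columns - 1L
    n_parts <- max(1L, ceiling(nrow(others) / per_part))
    for (p in seq_len(n_parts) - 1L) {
      take <- others[seq_len(nrow(others)) > p * per_part &
                       seq_len(nrow(others)) <= (p + 1) * per_part, ,
                     drop = FALSE]
      cols <- data.frame(
        short_name = c(id_col, take$short_name),
        storage_type = c(storage_type_for("identifier"),
                         if (nrow(take)) storage_type_for(take$var_type)),
        stringsAsFactors = FALSE)
      name <- sprintf("%s_%s_part%d", dict$dataset_id, visit, p)
      spec <- structure(list(dataset_id = dict$dataset_id, visit = visit,
                             part_index = p, physical_name = name,
                             columns = cols, identifier_column = id_col),
                        class = "xs_table_spec")
      specs[[length(specs) + 1]] <- spec
      ddl <- c(ddl, sprintf(
        "CREATE TABLE %s (%s)", name,
        paste(sprintf("\"%s\" %s", cols$short_name,
                      sql_column_type(cols$storage_type, dialect)),
              collapse = ", ")))
    }
  }
  list(specs = specs, ddl = ddl)
}

#' Open an embedded store
#'
#' @param path SQLite database file, or ":memory:" (default) for an
#'   in-memory store.
#' @return An `xs_store`: an environment holding the connection plus the
#'   registered dictionaries, table specs, mappings and coding map.
#' @export
open_store <- function(path = ":memory:") {
  st <- new.env(parent = emptyenv())
  st$con <- DBI::dbConnect(RSQLite::SQLite(), path)
  st$dicts <- list()
  st$specs <- list()
  st$canon <- NULL
  st$mappings <- NULL
  st$coding_map <- empty_coding_map()
  st$ddl_log <- character(0)
  class(st) <- "xs_store"
  st
}

#' Close a store's database connection
#' @param store An `xs_store`.
#' @export
close_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' Register the canonical dictionary with a store
#' @param store An `xs_store`.
#' @param canon An `xs_canonical_dictionary`.
#' @export
set_canonical <- function(store, canon) {
  store$canon <- canon
  invisible(store)
}

#' Register element mappings with a store
#' @param store An `xs_store`.
#' @param mappings An `xs_mappings` table.
#' @export
set_mappings <- function(store, mappings) {
  if (!is.null(store$canon) && length(store$dicts)) {
    validate_mappings(mappings, store$canon, store$dicts)
  }
  store$mappings <- mappings
  invisible(store)
}

#' Register a coding map with a store
#' @param store An `xs_store`.
#' @param map An `xs_coding_map`.
#' @export
set_coding_map <- function(store, map) {
  store$coding_map <- map
  invisible(store)
}

#' Register a dataset: create its tables from the dictionary
#'
#' Generates the schema with [create_schema()], drops any previous tables
#' for the dataset (replace semantics) and executes the DDL.
#'
#' @param store An `xs_store`.
#' @param dict The dataset's `xs_data_dictionary`.
#' @param max_columns Maximum columns per physical table.
#' @return The list of `xs_table_spec`s created, invisibly.
#' @export
add_dataset <- function(store, dict, max_columns = 900) {
  validate_data_dictionary(dict)
  sch <- create_schema(dict, max_columns, dialect = "sqlite")
  for (spec in sch$specs) {
    DBI::dbExecute(store$con,
                   sprintf("DROP TABLE IF EXISTS %s", spec$physical_name))
  }
  for (stmt in sch$ddl) DBI::dbExecute(store$con, stmt)
  store$dicts[[dict$dataset_id]] <- dict
  store$specs[[dict$dataset_id]] <- sch$specs
  store$ddl_log <- c(store$ddl_log, sch$ddl)
  invisible(sch$specs)
}

dataset_specs <- function(store, dataset_id, visit = NULL) {
  specs <- store$specs[[dataset_id]]
  if (is.null(specs)) {
    xs_abort(sprintf("unknown dataset '%s'", dataset_id), "xs_unknown_dataset")
  }
  if (!is.null(visit)) {
    specs <- Filter(function(s) s$visit == visit, specs)
  }
  specs
}

# Physical location of one source variable: (table, column, identifier).
locate_column <- function(store, dataset_id, visit, short_name) {
  for (spec in dataset_specs(store, dataset_id, visit)) {
    if (short_name %in% spec$columns$short_name) {
      return(list(table = spec$physical_name, column = short_name,
                  identifier = spec$identifier_column))
    }
  }
  NULL
}

#' Load one visit's CSV into the store
#'
#' Reads the per-visit record file (one row per subject), validates it
#' against the dictionary (every CSV column must be declared; the identifier
#' column must be present), harmonizes every cell of a coding-mapped
#' categorical variable, parses numeric cells, and inserts the surviving
#' rows into the visit's part tables. Rows with an unparseable numeric cell,
#' an unknown categorical code, a missing identifier, or a duplicate
#' identifier (later row loses) are rejected and logged, the rest loaded.
#' Empty cells are stored as SQL NULL.
#'
#' @param store An `xs_store` with the dataset registered.
#' @param csv_path Path to the `<dataset>-<visit>.csv` record file.
#' @param dataset_id,visit Which dataset/visit the file belongs to.
#' @return An `xs_load_report`: counts of rows loaded/rejected, number of
#'   harmonized cells, and a per-row rejection log.
#' @export
load_visit <- function(store, csv_path, dataset_id, visit) {
  dict <- store$dicts[[dataset_id]]
  if (is.null(dict)) {
    xs_load_error(sprintf("dataset '%s' is not registered", dataset_id))
  }
  if (!visit %in% dict$visits) {
    xs_load_error(sprintf("unknown visit '%s' for dataset '%s'", visit, dataset_id))
  }
  raw <- read_csv_chr(csv_path)
  vv <- dict$variables[dict$variables$visit == visit, , drop = FALSE]
  extra <- setdiff(names(raw), vv$short_name)
  if (length(extra)) {
    xs_load_error(sprintf(
      "CSV column(s) not in the dictionary for %s/%s: %s (the dictionary is the contract)",
      dataset_id, visit, paste(extra, collapse = ", ")), columns = extra)
  }
  id_col <- identifier_variable(dict, visit)
  if (!id_col %in% names(raw)) {
    xs_load_error(sprintf("identifier column '%s' missing from %s", id_col, csv_path))
  }

  n <- nrow(raw)
  reject_reason <- rep(NA_character_, n)
  harmonized_cells <- 0L
  cooked <- list()
  for (col in names(raw)) {
    var <- dict_variable(dict, visit, col)
    cells <- raw[[col]]
    blank <- is.na(cells) | !nzchar(trimws(cells))
    if (var$var_type == "numeric") {
      vals <- suppressWarnings(as.numeric(cells))
      bad <- !blank & is.na(vals)
      reject_reason[bad & is.na(reject_reason)] <-
        sprintf("unparseable numeric value in '%s'", col)
      vals[blank] <- NA_real_
      cooked[[col]] <- vals
    } else if (var$var_type == "categorical") {
      vals <- rep(NA_character_, n)
      map_rows <- store$coding_map[
        store$coding_map$dataset == dataset_id &
          store$coding_map$source_short_name == col, , drop = FALSE]
      if (nrow(map_rows) == 0) {
        vals[!blank] <- cells[!blank]
      } else {
        idx <- match(cells[!blank], map_rows$source_code)
        bad_rows <- which(!blank)[is.na(idx)]
        reject_reason[bad_rows[is.na(reject_reason[bad_rows])]] <-
          sprintf("unknown code in '%s'", col)
        ok <- which(!blank)[!is.na(idx)]
        vals[ok] <- map_rows$uniform_code[idx[!is.na(idx)]]
        harmonized_cells <- harmonized_cells + length(ok)
      }
      cooked[[col]] <- vals
    } else {
      vals <- cells
      vals[blank] <- NA_character_
      cooked[[col]] <- vals
    }
  }
  ids <- cooked[[id_col]]
  reject_reason[is.na(ids) & is.na(reject_reason)] <- "missing identifier"
  dup <- duplicated(ids) & !is.na(ids)
  reject_reason[dup & is.na(reject_reason)] <- "duplicate identifier"

  keep <- is.na(reject_reason)
  frame <- as.data.frame(cooked, stringsAsFactors = FALSE, optional = TRUE)
  names(frame) <- names(cooked)
  frame <- frame[keep, , drop = FALSE]

  # Replace semantics: recreate the visit's part tables, then append.
  for (spec in dataset_specs(store, dataset_id, visit)) {
    DBI::dbExecute(store$con,
                   sprintf("DROP TABLE IF EXISTS %s", spec$physical_name))
    cols <- spec$columns
    DBI::dbExecute(store$con, sprintf(
      "CREATE TABLE %s (%s)", spec$physical_name,
      paste(sprintf("\"%s\" %s", cols$short_name,
                    sql_column_type(cols$storage_type, "sqlite")),
            collapse = ", ")))
    present <- intersect(cols$short_name, names(frame))
    part <- frame[, present, drop = FALSE]
    # columns declared in the dictionary but absent from this CSV load as NULL
    for (missing_col in setdiff(cols$short_name, present)) {
      part[[missing_col]] <-
        if (cols$storage_type[cols$short_name == missing_col] == "double")
          NA_real_ else NA_character_
    }
    part <- part[, cols$short_name, drop = FALSE]
    if (nrow(part)) {
      DBI::dbWriteTable(store$con, spec$physical_name, part, append = TRUE)
    }
  }

  log <- data.frame(row = which(!keep),
                    reason = reject_reason[!keep],
                    stringsAsFactors = FALSE)
  structure(list(dataset_id = dataset_id, visit = visit,
                 rows_loaded = sum(keep), rows_rejected = sum(!keep),
                 harmonized_cells = harmonized_cells,
                 rejected_row_log = log),
            class = "xs_load_report")
}

#' Count distinct subjects in a dataset
#'
#' Union of distinct identifier values over every visit of the dataset.
#'
#' @param store An `xs_store`.
#' @param dataset_id Dataset to count.
#' @return Integer count.
#' @export
subject_universe <- function(store, dataset_id) {
  specs <- dataset_specs(store, dataset_id)
  part0 <- Filter(function(s) s$part_index == 0, specs)
  selects <- vapply(part0, function(s) {
    sprintf("SELECT \"%s\" AS subj FROM %s WHERE \"%s\" IS NOT NULL",
            s$identifier_column, s$physical_name, s$identifier_column)
  }, character(1))
  sql <- sprintf("SELECT COUNT(DISTINCT subj) FROM (%s)",
                 paste(selects, collapse = " UNION "))
  as.integer(DBI::dbGetQuery(store$con, sql)[[1]])
}

#' @export
print.xs_load_report <- function(x, ...) {
  cat(sprintf("<load report> %s/%s: %d loaded, %d rejected, %d harmonized cell(s)\n",
              x$dataset_id, x$visit, x$rows_loaded, x$rows_rejected,
              x$harmonized_cells))
  if (nrow(x$rejected_row_log)) {
    for (i in seq_len(nrow(x$rejected_row_log))) {
      cat(sprintf("  row %d: %s\n", x$rejected_row_log$row[i],
                  x$rejected_row_log$reason[i]))
    }
  }
  invisible(x)
}

#' @export
print.xs_store <- function(x, ...) {
  cat(sprintf("<xcohort store> %d dataset(s): %s\n", length(x$dicts),
              paste(names(x$dicts), collapse = ", ")))
  invisible(x)
}
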