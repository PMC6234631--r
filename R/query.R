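# Cross-cohort count queries.
#
# A cohort query selects datasets and constrains canonical elements:
# numeric elements by an inclusive range (slider semantics), categorical
# elements by a set of uniform codes (checkbox semantics). Translation
# instantiates, per dataset, the distinct-subject count template
#
#   SELECT COUNT(DISTINCT <identifier>) FROM <table>
#    WHERE <column> BETWEEN <min> AND <max>
#
# generalised to several criteria and several mapped source variables:
# criteria combine with AND; the source variables mapped to one element
# (across visits and split-table parts) combine with OR, so a subject
# qualifies on a criterion if ANY of their visits' values satisfies it.
# Because every split part carries the identifier, parts meet on the
# identifier through the same set algebra. Values travel as bound
# parameters, never pasted into the SQL.

#' Build a query criterion
#'
#' @param element_id Canonical element the criterion constrains.
#' @param min,max Inclusive bounds for a numeric-range criterion.
#' @param codes Character vector of allowed uniform codes for a
#'   categorical criterion.
#' @return An `xs_criterion`.
#' @export
criterion <- function(element_id, min = NULL, max = NULL, codes = NULL) {
  if (!is.null(codes)) {
    if (!is.null(min) || !is.null(max)) {
      xs_spec_error("a criterion is either a numeric range or a code set, not both")
    }
    codes <- as.character(codes)
    if (length(codes) == 0) xs_spec_error("allowed code set must be non-empty")
    return(structure(list(element_id = element_id, kind = "categorical_in",
                          allowed_codes = codes), class = "xs_criterion"))
  }
  if (is.null(min) || is.null(max)) {
    xs_spec_error("a numeric-range criterion needs both min and max")
  }
  if (min > max) xs_spec_error("criterion min must not exceed max")
  structure(list(element_id = element_id, kind = "numeric_range",
                 min = as.numeric(min), max = as.numeric(max)),
            class = "xs_criterion")
}

#' Build a cohort query
#'
#' @param dataset_ids Non-empty character vector of datasets to query.
#' @param criteria List of [criterion()]s, at most one per element.
#' @return An `xs_cohort_query`.
#' @export
cohort_query <- function(dataset_ids, criteria = list()) {
  if (length(dataset_ids) == 0) xs_spec_error("select at least one dataset")
  if (inherits(criteria, "xs_criterion")) criteria <- list(criteria)
  els <- vapply(criteria, function(c) c$element_id, character(1))
  if (anyDuplicated(els)) {
    xs_spec_error(sprintf("more than one criterion for element(s): %s",
                          paste(unique(els[duplicated(els)]), collapse = ", ")))
  }
  structure(list(dataset_ids = unique(dataset_ids), criteria = criteria),
            class = "xs_cohort_query")
}

# Check criteria against the canonical dictionary: queryable type, codes
# within the uniform domain, element known.
validate_criteria <- function(canon, criteria) {
  for (cr in criteria) {
    el <- canonical_element(canon, cr$element_id)
    if (cr$kind == "categorical_in") {
      if (el$var_type != "categorical") {
        xs_spec_error(sprintf("element '%s' is not categorical", cr$element_id))
      }
      dom <- el$uniform_domain[[1]]
      bad <- setdiff(cr$allowed_codes, dom$code)
      if (length(bad)) {
        xs_spec_error(sprintf(
          "code(s) %s not in the uniform domain of '%s'",
          paste(bad, collapse = ", "), cr$element_id))
      }
    } else if (el$var_type != "numeric") {
      xs_spec_error(sprintf("element '%s' is not numeric", cr$element_id))
    }
  }
  invisible(criteria)
}

#' Resolve criteria elements to physical columns
#'
#' For each selected dataset and each queried element, lists the physical
#' (visit, table, column) targets the element maps to. A dataset with no
#' target for some queried element is recorded as non-covering: "the
#' element is not collected there" is data, not an error, and is kept
#' distinct from a zero count.
#'
#' @param store An `xs_store` with mappings registered.
#' @param query An `xs_cohort_query`.
#' @return A list with `targets` (data frame dataset, element_id, visit,
#'   table, column, identifier) and `non_covering` (data frame dataset,
#'   element_id).
#' @export
resolve_mappings <- function(store, query) {
  if (is.null(store$mappings)) xs_spec_error("no element mappings registered")
  targets <- list()
  nc <- list()
  for (ds in query$dataset_ids) {
    if (is.null(store$dicts[[ds]])) {
      xs_abort(sprintf("unknown dataset '%s'", ds), "xs_unknown_dataset")
    }
    for (cr in query$criteria) {
      rows <- store$mappings[store$mappings$dataset == ds &
                               store$mappings$element_id == cr$element_id, ,
                             drop = FALSE]
      found <- FALSE
      for (j in seq_len(nrow(rows))) {
        loc <- locate_column(store, ds, rows$visit[j], rows$source_short_name[j])
        if (is.null(loc)) next
        found <- TRUE
        targets[[length(targets) + 1]] <- data.frame(
          dataset = ds, element_id = cr$element_id, visit = rows$visit[j],
          table = loc$table, column = loc$column, identifier = loc$identifier,
          stringsAsFactors = FALSE)
      }
      if (!found) {
        nc[[length(nc) + 1]] <- data.frame(dataset = ds,
                                           element_id = cr$element_id,
                                           stringsAsFactors = FALSE)
      }
    }
  }
  empty <- function(cols) as.data.frame(setNames(
    rep(list(character(0)), length(cols)), cols), stringsAsFactors = FALSE)
  list(targets = if (length(targets)) do.call(rbind, targets) else
         empty(c("dataset", "element_id", "visit", "table", "column", "identifier")),
       non_covering = if (length(nc)) do.call(rbind, nc) else
         empty(c("dataset", "element_id")))
}

# One criterion against one dataset: a compound SELECT of qualifying
# subject identifiers, OR (UNION) over the mapped targets.
criterion_select <- function(cr, tg) {
  pieces <- character(0)
  binds <- list()
  for (j in seq_len(nrow(tg))) {
    if (cr$kind == "numeric_range") {
      pieces <- c(pieces, sprintf(
        "SELECT \"%s\" AS subj FROM %s WHERE \"%s\" BETWEEN ? AND ?",
        tg$identifier[j], tg$table[j], tg$column[j]))
      binds <- c(binds, list(cr$min, cr$max))
    } else {
      ph <- paste(rep("?", length(cr$allowed_codes)), collapse = ", ")
      pieces <- c(pieces, sprintf(
        "SELECT \"%s\" AS subj FROM %s WHERE \"%s\" IN (%s)",
        tg$identifier[j], tg$table[j], tg$column[j], ph))
      binds <- c(binds, as.list(cr$allowed_codes))
    }
  }
  list(sql = sprintf("SELECT subj FROM (%s)", paste(pieces, collapse = " UNION ")),
       bindings = binds)
}

# The full subject-set select for one dataset: INTERSECT across criteria;
# with no criteria, the dataset's whole subject universe.
subject_set_select <- function(store, dataset_id, criteria, resolution) {
  if (length(criteria) == 0) {
    part0 <- Filter(function(s) s$part_index == 0,
                    dataset_specs(store, dataset_id))
    sel <- vapply(part0, function(s) sprintf(
      "SELECT \"%s\" AS subj FROM %s WHERE \"%s\" IS NOT NULL",
      s$identifier_column, s$physical_name, s$identifier_column), character(1))
    return(list(sql = sprintf("SELECT subj FROM (%s)",
                              paste(sel, collapse = " UNION ")),
                bindings = list()))
  }
  sqls <- character(0)
  binds <- list()
  for (cr in criteria) {
    tg <- resolution$targets[resolution$targets$dataset == dataset_id &
                               resolution$targets$element_id == cr$element_id, ,
                             drop = FALSE]
    cs <- criterion_select(cr, tg)
    sqls <- c(sqls, cs$sql)
    binds <- c(binds, cs$bindings)
  }
  list(sql = paste(sqls, collapse = " INTERSECT "), bindings = binds)
}

#' Translate a cohort query to per-dataset SQL
#'
#' @param store An `xs_store`.
#' @param query An `xs_cohort_query`.
#' @param resolution Optional precomputed [resolve_mappings()] result.
#' @return A list of `xs_translated_query` (dataset_id, sql, bindings,
#'   applicable). Datasets that do not cover every queried element carry
#'   `applicable = FALSE` and no SQL.
#' @export
translate <- function(store, query, resolution = NULL) {
  if (!is.null(store$canon)) validate_criteria(store$canon, query$criteria)
  if (is.null(resolution)) resolution <- resolve_mappings(store, query)
  lapply(query$dataset_ids, function(ds) {
    if (ds %in% resolution$non_covering$dataset) {
      return(structure(list(dataset_id = ds, sql = character(0),
                            bindings = list(), applicable = FALSE),
                       class = "xs_translated_query"))
    }
    ss <- subject_set_select(store, ds, query$criteria, resolution)
    structure(list(
      dataset_id = ds,
      sql = sprintf("SELECT COUNT(DISTINCT subj) FROM (%s)", ss$sql),
      bindings = ss$bindings, applicable = TRUE),
      class = "xs_translated_query")
  })
}

#' Execute translated queries and aggregate counts
#'
#' @param store An `xs_store`.
#' @param tqs List of `xs_translated_query` from [translate()].
#' @return An `xs_query_result`: `per_dataset` (named counts, `NA` for
#'   datasets that do not cover the queried elements) and `total`, the sum
#'   over applicable datasets. Subjects are never linked across datasets.
#' @export
execute <- function(store, tqs) {
  per <- vapply(tqs, function(tq) {
    if (!tq$applicable) return(NA_integer_)
    n <- tryCatch(
      DBI::dbGetQuery(store$con, tq$sql,
                      params = if (length(tq$bindings)) tq$bindings)[[1]],
      error = function(e) xs_execution_error(sprintf(
        "query failed for dataset '%s': %s [%s]", tq$dataset_id,
        conditionMessage(e), tq$sql)))
    as.integer(n)
  }, integer(1))
  names(per) <- vapply(tqs, function(tq) tq$dataset_id, character(1))
  structure(list(per_dataset = per, total = sum(per, na.rm = TRUE)),
            class = "xs_query_result")
}

#' Count subjects matching a cohort query
#'
#' Convenience wrapper: resolve, translate, execute.
#'
#' @param store An `xs_store`.
#' @param query An `xs_cohort_query`.
#' @return An `xs_query_result`.
#' @export
count_subjects <- function(store, query) {
  execute(store, translate(store, query))
}

# Identifiers of subjects in one dataset satisfying all criteria; NULL when
# the dataset does not cover some element.
eligible_ids <- function(store, dataset_id, criteria) {
  q <- cohort_query(dataset_id, criteria)
  if (!is.null(store$canon)) validate_criteria(store$canon, criteria)
  resolution <- resolve_mappings(store, q)
  if (nrow(resolution$non_covering)) return(NULL)
  ss <- subject_set_select(store, dataset_id, criteria, resolution)
  DBI::dbGetQuery(store$con, sprintf("SELECT DISTINCT subj FROM (%s)", ss$sql),
                  params = if (length(ss$bindings)) ss$bindings)[[1]]
}

#' Fetch harmonized element values for eligible subjects
#'
#' Returns, for every source variable mapped to `element_id` in the
#' requested datasets, the non-missing stored (harmonized) values: uniform
#' codes for categorical elements, reals for numeric ones. With a
#' `subject_filter`, only subjects satisfying the filter in their dataset
#' contribute; a dataset that does not cover the filter contributes nobody.
#'
#' @param store An `xs_store`.
#' @param dataset_ids Datasets to pull from.
#' @param element_id Canonical element to fetch.
#' @param subject_filter Optional `xs_cohort_query`-style criteria list
#'   restricting subjects.
#' @return Data frame (dataset, identifier, visit, value).
#' @export
fetch_values <- function(store, dataset_ids, element_id,
                         subject_filter = NULL) {
  el <- canonical_element(store$canon, element_id)
  q <- cohort_query(dataset_ids, list(
    if (el$var_type == "numeric") criterion(element_id, min = -Inf, max = Inf)
    else criterion(element_id, codes = el$uniform_domain[[1]]$code)))
  resolution <- resolve_mappings(store, q)
  if (nrow(resolution$targets) == 0) {
    xs_spec_error(sprintf(
      "element '%s' is not covered in any requested dataset", element_id))
  }
  out <- list()
  for (ds in dataset_ids) {
    keep_ids <- NULL
    if (!is.null(subject_filter)) {
      keep_ids <- eligible_ids(store, ds, subject_filter)
      if (is.null(keep_ids) || length(keep_ids) == 0) next
    }
    tg <- resolution$targets[resolution$targets$dataset == ds, , drop = FALSE]
    for (j in seq_len(nrow(tg))) {
      df <- DBI::dbGetQuery(store$con, sprintf(
        "SELECT \"%s\" AS identifier, \"%s\" AS value FROM %s WHERE \"%s\" IS NOT NULL",
        tg$identifier[j], tg$column[j], tg$table[j], tg$column[j]))
      if (!is.null(keep_ids)) df <- df[df$identifier %in% keep_ids, , drop = FALSE]
      if (nrow(df) == 0) next
      df$dataset <- ds
      df$visit <- tg$visit[j]
      df$column <- tg$column[j]
      out[[length(out) + 1]] <- df
    }
  }
  if (length(out) == 0) {
    return(data.frame(dataset = character(0), identifier = character(0),
                      visit = character(0), column = character(0),
                      value = if (el$var_type == "numeric") numeric(0) else character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (el$var_type == "numeric") res$value <- as.numeric(res$value)
  else res$value <- as.character(res$value)
  res[c("dataset", "identifier", "visit", "column", "value")]
}

#' Read a cohort query from JSON
#'
#' Expected shape:
#' `{"datasets": [...], "criteria": [{"element": "age", "min": 20, "max": 50},
#' {"element": "gender", "codes": ["2"]}]}`.
#'
#' @param path JSON file path.
#' @return An `xs_cohort_query`.
#' @export
read_query_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  crits <- lapply(j$criteria, function(c) {
    if (!is.null(c$codes)) criterion(c$element, codes = unlist(c$codes))
    else criterion(c$element, min = c$min, max = c$max)
  })
  cohort_query(unlist(j$datasets), crits)
}

#' @export
print.xs_query_result <- function(x, ...) {
  cat("<query result>\n")
  for (ds in names(x$per_dataset)) {
    v <- x$per_dataset[[ds]]
    cat(sprintf("  %-12s %s\n", ds, if (is.na(v)) "n/a" else v))
  }
  cat(sprintf("  %-12s %d\n", "total", x$total))
  invisible(x)
}

#' @export
print.xs_translated_query <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<translated query> %s: not applicable (element not covered)\n",
                x$dataset_id))
  } else {
    cat(sprintf("<translated query> %s:\n  %s\n  bindings: %s\n", x$dataset_id,
                x$sql, paste(unlist(x$bindings), collapse = ", ")))
  }
  invisible(x)
}
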