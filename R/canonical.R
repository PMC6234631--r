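# The canonical data dictionary: the unified catalogue of common data
# elements that drives term search, hierarchical browsing and query
# translation. Only numeric and categorical elements are queryable.

CANON_COLUMNS <- c("element_id", "display_name", "category_path", "type",
                   "unit", "uniform_domain", "synonyms")

#' Read and validate a canonical data dictionary
#'
#' The canonical dictionary lists one common data element per row:
#' `element_id, display_name, category_path, type, unit, uniform_domain,
#' synonyms`, with `category_path` slash-separated (e.g.
#' `demographics/gender`), `uniform_domain` in the same `code=label;...`
#' encoding as source dictionaries, and `synonyms` separated by `|`.
#'
#' @param path Path to the canonical dictionary CSV.
#' @return An `xs_canonical_dictionary`: a list with one element `elements`,
#'   a data frame with list-columns `category_path`, `uniform_domain`, and
#'   `synonyms`.
#' @export
parse_canonical_dictionary <- function(path) {
  raw <- read_csv_chr(path)
  require_columns(raw, CANON_COLUMNS,
                  sprintf("canonical dictionary '%s'", path), path = path)
  dup <- unique(raw$element_id[duplicated(raw$element_id)])
  if (length(dup)) {
    xs_validation_error(sprintf("duplicate element_id(s): %s",
                                paste(dup, collapse = ", ")), duplicates = dup)
  }
  bad <- setdiff(unique(raw$type), c("numeric", "categorical"))
  if (nrow(raw) > 0 && length(bad)) {
    xs_validation_error(sprintf(
      "canonical element types must be numeric or categorical (found: %s)",
      paste(bad, collapse = ", ")))
  }
  el <- data.frame(element_id = raw$element_id,
                   display_name = raw$display_name,
                   var_type = raw$type,
                   unit = raw$unit,
                   stringsAsFactors = FALSE)
  el$category_path <- lapply(raw$category_path, function(p) {
    if (is.na(p) || !nzchar(p)) character(0) else strsplit(p, "/", fixed = TRUE)[[1]]
  })
  el$uniform_domain <- lapply(raw$uniform_domain, parse_domain)
  el$synonyms <- lapply(raw$synonyms, parse_synonyms)
  for (i in seq_len(nrow(el))) {
    dom <- el$uniform_domain[[i]]
    if (el$var_type[i] == "categorical" && nrow(dom) == 0) {
      xs_validation_error(sprintf(
        "categorical element '%s' has an empty uniform domain", el$element_id[i]))
    }
    if (el$var_type[i] != "categorical" && nrow(dom) > 0) {
      xs_validation_error(sprintf(
        "numeric element '%s' must not declare a uniform domain", el$element_id[i]))
    }
  }
  structure(list(elements = el), class = "xs_canonical_dictionary")
}

#' Serialize a canonical dictionary to CSV
#' @param canon An `xs_canonical_dictionary`.
#' @param path Output CSV path.
#' @export
write_canonical_dictionary <- function(canon, path) {
  el <- canon$elements
  out <- data.frame(
    element_id = el$element_id,
    display_name = el$display_name,
    category_path = vapply(el$category_path, paste, character(1), collapse = "/"),
    type = el$var_type,
    unit = el$unit,
    uniform_domain = vapply(el$uniform_domain, format_domain, character(1)),
    synonyms = vapply(el$synonyms, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

canonical_element <- function(canon, element_id) {
  hit <- which(canon$elements$element_id == element_id)
  if (length(hit) != 1) {
    xs_validation_error(sprintf("unknown canonical element '%s'", element_id))
  }
  canon$elements[hit, , drop = FALSE]
}

#' Search canonical query terms
#'
#' Case-insensitive containment search over display names, element ids and
#' synonyms, ranked exact match first, then prefix matches, then substring
#' matches; ties broken by display name. An empty query returns every
#' element in dictionary order.
#'
#' @param canon An `xs_canonical_dictionary`.
#' @param query Search string.
#' @return The matching rows of `canon$elements`, best match first.
#' @export
search_terms <- function(canon, query) {
  el <- canon$elements
  if (!nzchar(query)) return(el)
  q <- tolower(query)
  score_one <- function(i) {
    keys <- tolower(c(el$display_name[i], el$element_id[i], el$synonyms[[i]]))
    s <- vapply(keys, function(k) {
      if (k == q) 1L
      else if (startsWith(k, q)) 2L
      else if (grepl(q, k, fixed = TRUE)) 3L
      else 4L
    }, integer(1))
    min(s)
  }
  score <- vapply(seq_len(nrow(el)), score_one, integer(1))
  keep <- score < 4L
  out <- el[keep, , drop = FALSE]
  out[order(score[keep], out$display_name), , drop = FALSE]
}

#' Hierarchical browse tree of canonical elements
#'
#' Builds the level-by-level browsing hierarchy: internal nodes are
#' `category_path` components in first-seen order and leaves are exactly the
#' canonical elements. Elements with an empty path sit at the root.
#'
#' @param canon An `xs_canonical_dictionary`.
#' @return A nested node list: `list(name, children, elements)` where
#'   `children` is a named list of child nodes and `elements` a character
#'   vector of element ids attached at this node.
#' @export
browse_tree <- function(canon) {
  new_node <- function(name) list(name = name, children = list(),
                                  elements = character(0))
  root <- new_node("")
  insert <- function(node, path, id) {
    if (length(path) == 0) {
      node$elements <- c(node$elements, id)
      return(node)
    }
    head <- path[[1]]
    if (is.null(node$children[[head]])) node$children[[head]] <- new_node(head)
    node$children[[head]] <- insert(node$children[[head]], path[-1], id)
    node
  }
  el <- canon$elements
  for (i in seq_len(nrow(el))) {
    root <- insert(root, el$category_path[[i]], el$element_id[i])
  }
  structure(root, class = "xs_browse_tree")
}

#' Count leaves of a browse tree
#' @param tree An `xs_browse_tree` (or internal node).
#' @return Number of element leaves in the subtree.
#' @export
tree_leaf_count <- function(tree) {
  length(tree$elements) +
    sum(vapply(tree$children, tree_leaf_count, numeric(1)))
}

tree_leaf_ids <- function(tree) {
  c(tree$elements,
    unlist(lapply(tree$children, tree_leaf_ids), use.names = FALSE))
}

#' @export
print.xs_canonical_dictionary <- function(x, ...) {
  cat(sprintf("<canonical dictionary> %d common data element(s)\n",
              nrow(x$elements)))
  invisible(x)
}
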