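# Graphical exploration and case-control exploration.
#
# Graphical exploration summarises one element (y) against a categorical
# grouping element (x): bar-plot counts when y is categorical, box-plot
# statistics when y is numeric. Because several source variables in a
# dataset may map to x or to y, one series is produced per
# (dataset, x-variable, y-variable) pair; a subject contributes one
# observation per pair of visits with both values present.
#
# Case-control exploration is a five-part count procedure: base-population
# criteria, a case condition, a control condition, categorical match
# (stratification) elements, and outcome elements, yielding case/control
# count tables. All subject selection reuses the query engine's semantics
# (AND across criteria, any-visit OR within one), so the same subject sets
# appear in counts and in explorations.

# Box statistics: quartiles by linear interpolation between order
# statistics (quantile type 7); Tukey whiskers at the most extreme observed
# values within 1.5 * IQR of the quartiles.
box_stats <- function(v) {
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  list(n = length(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3],
       max = max(v), whisker_lo = min(v[v >= lo_fence]),
       whisker_hi = max(v[v <= hi_fence]))
}

#' Plot-ready statistics for one element against a categorical grouping
#'
#' @param store An `xs_store`.
#' @param x_element Categorical canonical element used as the x-axis
#'   grouping; a numeric x is unsupported.
#' @param y_element Canonical element summarised on the y-axis: categorical
#'   y yields bar counts, numeric y yields box statistics.
#' @param dataset_ids Datasets to generate series for.
#' @return A list of `xs_plot_series`; one per (dataset, mapped x-variable,
#'   mapped y-variable) pair with at least one complete observation. Each
#'   series has `groups`: per observed x code (in uniform-domain order),
#'   either a named count vector over y codes (bar) or the box statistics
#'   list (box).
#' @export
plot_data <- function(store, x_element, y_element, dataset_ids) {
  xe <- canonical_element(store$canon, x_element)
  ye <- canonical_element(store$canon, y_element)
  if (xe$var_type != "categorical") {
    xs_spec_error(sprintf(
      "x-axis element '%s' must be categorical (it is the grouping variable)",
      x_element))
  }
  plot_kind <- if (ye$var_type == "categorical") "bar" else "box"
  xv <- fetch_values(store, dataset_ids, x_element)
  yv <- fetch_values(store, dataset_ids, y_element)
  x_order <- xe$uniform_domain[[1]]$code
  series <- list()
  for (ds in dataset_ids) {
    xds <- xv[xv$dataset == ds, , drop = FALSE]
    yds <- yv[yv$dataset == ds, , drop = FALSE]
    for (xcol in unique(xds$column)) {
      for (ycol in unique(yds$column)) {
        a <- xds[xds$column == xcol, c("identifier", "value")]
        b <- yds[yds$column == ycol, c("identifier", "value")]
        obs <- merge(a, b, by = "identifier", suffixes = c("_x", "_y"))
        if (nrow(obs) == 0) next
        codes <- intersect(x_order, unique(obs$value_x))
        groups <- lapply(codes, function(code) {
          yy <- obs$value_y[obs$value_x == code]
          if (plot_kind == "bar") {
            y_codes <- intersect(ye$uniform_domain[[1]]$code, unique(yy))
            vapply(setNames(y_codes, y_codes),
                   function(yc) sum(yy == yc), numeric(1))
          } else {
            box_stats(as.numeric(yy))
          }
        })
        names(groups) <- codes
        series[[length(series) + 1]] <- structure(
          list(dataset_id = ds, x_variable = xcol, y_variable = ycol,
               plot_kind = plot_kind, groups = groups),
          class = "xs_plot_series")
      }
    }
  }
  series
}

#' Specify an outcome element for case-control exploration
#'
#' Numeric outcomes must be dichotomised explicitly: a threshold plus a
#' direction (there is no default threshold). Categorical outcomes are
#' tabulated per uniform code.
#'
#' @param element_id Canonical element.
#' @param threshold Numeric threshold (numeric elements only).
#' @param direction `"ge"` (value >= threshold) or `"le"` (value <= threshold).
#' @return An outcome specification list.
#' @export
cc_outcome <- function(element_id, threshold = NULL, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  list(element_id = element_id, threshold = threshold, direction = direction)
}

#' Build a case-control specification
#'
#' The five parts of a case-control exploration: base-population criteria,
#' a case condition, a control condition, categorical match elements for
#' stratification, and outcome elements.
#'
#' @param base_criteria List of [criterion()]s defining the base population.
#' @param case_condition [criterion()] selecting cases within the base.
#' @param control_condition [criterion()] selecting controls within the base.
#' @param match_elements Character vector of categorical element ids.
#' @param outcomes List of [cc_outcome()]s.
#' @return An `xs_case_control_spec`.
#' @export
case_control_spec <- function(base_criteria, case_condition, control_condition,
                              match_elements = character(0), outcomes = list()) {
  structure(list(base_criteria = base_criteria,
                 case_condition = case_condition,
                 control_condition = control_condition,
                 match_elements = match_elements,
                 outcomes = outcomes),
            class = "xs_case_control_spec")
}

#' Read a case-control specification from JSON
#'
#' Expected shape: an object with `base` (array of criteria), `case` and
#' `control` (single criteria), `match` (array of element ids) and
#' `outcomes` (array of `{element, threshold, direction}`), criteria encoded
#' as in [read_query_json()].
#'
#' @param path JSON file path.
#' @return An `xs_case_control_spec`.
#' @export
read_case_control_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_crit <- function(c) {
    if (!is.null(c$codes)) criterion(c$element, codes = unlist(c$codes))
    else criterion(c$element, min = c$min, max = c$max)
  }
  case_control_spec(
    base_criteria = lapply(j$base, as_crit),
    case_condition = as_crit(j$case),
    control_condition = as_crit(j$control),
    match_elements = unlist(j$match) %||% character(0),
    outcomes = lapply(j$outcomes, function(o)
      cc_outcome(o$element, o$threshold %||% NULL, o$direction %||% "ge")))
}

# A subject's single match value: the value at the earliest visit (in
# dictionary visit order) with a non-missing value for the element.
match_value_per_subject <- function(store, ds, element_id, ids) {
  vals <- fetch_values(store, ds, element_id)
  vals <- vals[vals$identifier %in% ids, , drop = FALSE]
  if (nrow(vals) == 0) {
    return(setNames(character(0), character(0)))
  }
  visit_rank <- match(vals$visit, store$dicts[[ds]]$visits)
  vals <- vals[order(vals$identifier, visit_rank), , drop = FALSE]
  first <- !duplicated(vals$identifier)
  setNames(vals$value[first], vals$identifier[first])
}

count_meeting_outcome <- function(store, ds, outcome, el_type, ids) {
  if (length(ids) == 0) return(0L)
  vals <- fetch_values(store, ds, outcome$element_id)
  vals <- vals[vals$identifier %in% ids, , drop = FALSE]
  if (el_type == "numeric") {
    hit <- if (outcome$direction == "ge") vals$value >= outcome$threshold
           else vals$value <= outcome$threshold
    length(unique(vals$identifier[hit]))
  } else {
    vals  # handled per code by the caller
  }
}

#' Run a case-control exploration
#'
#' Per dataset: the base population is the subjects satisfying every base
#' criterion; cases are base subjects additionally satisfying the case
#' condition, controls those satisfying the control condition. Case and
#' control sets must be disjoint — an overlap is a specification error
#' reporting the overlapping count. Strata cross-tabulate the match-element
#' codes (one value per subject: earliest visit wins) over cases and
#' controls; subjects missing a match value are left out of the strata.
#' Outcomes count, among cases and controls, subjects meeting a numeric
#' threshold at any visit, or carrying each code for categorical outcomes.
#' Counts are computed per dataset and summed; subjects are never linked
#' across datasets. Datasets that do not cover all the specification's
#' elements are skipped and reported.
#'
#' @param store An `xs_store`.
#' @param spec An `xs_case_control_spec`.
#' @param dataset_ids Datasets to explore.
#' @return An `xs_case_control_table`: `strata` (data frame of match-code
#'   combinations with case/control counts), `outcomes` (data frame label /
#'   cases / controls), `totals`, and `skipped_datasets`.
#' @export
run_case_control <- function(store, spec, dataset_ids) {
  for (m in spec$match_elements) {
    el <- canonical_element(store$canon, m)
    if (el$var_type != "categorical") {
      xs_spec_error(sprintf("match element '%s' must be categorical", m))
    }
  }
  per_ds <- list()
  skipped <- character(0)
  for (ds in dataset_ids) {
    case_ids <- eligible_ids(store, ds, c(spec$base_criteria,
                                          list(spec$case_condition)))
    control_ids <- eligible_ids(store, ds, c(spec$base_criteria,
                                             list(spec$control_condition)))
    if (is.null(case_ids) || is.null(control_ids)) {
      skipped <- c(skipped, ds)
      next
    }
    overlap <- intersect(case_ids, control_ids)
    if (length(overlap)) {
      xs_spec_error(sprintf(
        "case and control conditions overlap: %d subject(s) in dataset '%s' satisfy both",
        length(overlap), ds), overlap_count = length(overlap))
    }
    per_ds[[ds]] <- list(cases = case_ids, controls = control_ids)
  }

  # Strata: cross-tabulate match values per dataset, then sum across.
  strata_acc <- list()
  add_stratum <- function(key, is_case, n) {
    cur <- strata_acc[[key]] %||% c(cases = 0, controls = 0)
    cur[if (is_case) "cases" else "controls"] <-
      cur[if (is_case) "cases" else "controls"] + n
    strata_acc[[key]] <<- cur
  }
  if (length(spec$match_elements)) {
    for (ds in names(per_ds)) {
      both <- c(per_ds[[ds]]$cases, per_ds[[ds]]$controls)
      mv <- lapply(spec$match_elements, function(m)
        match_value_per_subject(store, ds, m, both))
      tab_group <- function(ids, is_case) {
        if (length(ids) == 0) return()
        vals <- vapply(mv, function(v) unname(v[ids]), character(length(ids)))
        vals <- matrix(vals, nrow = length(ids))
        complete <- rowSums(is.na(vals)) == 0
        keys <- apply(vals[complete, , drop = FALSE], 1, paste, collapse = "|")
        for (k in names(table(keys))) add_stratum(k, is_case, sum(keys == k))
      }
      tab_group(per_ds[[ds]]$cases, TRUE)
      tab_group(per_ds[[ds]]$controls, FALSE)
    }
  }
  strata <- if (length(strata_acc)) {
    keys <- sort(names(strata_acc))
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    df <- as.data.frame(parts, stringsAsFactors = FALSE)
    names(df) <- spec$match_elements
    df$cases <- vapply(keys, function(k) strata_acc[[k]][["cases"]], numeric(1))
    df$controls <- vapply(keys, function(k) strata_acc[[k]][["controls"]], numeric(1))
    rownames(df) <- NULL
    df
  } else {
    data.frame(cases = numeric(0), controls = numeric(0))
  }

  # Outcomes.
  out_rows <- list()
  for (o in spec$outcomes) {
    el <- canonical_element(store$canon, o$element_id)
    if (el$var_type == "numeric") {
      if (is.null(o$threshold)) {
        xs_spec_error(sprintf(
          "numeric outcome '%s' needs an explicit threshold", o$element_id))
      }
      lab <- sprintf("%s %s %s", o$element_id,
                     if (o$direction == "ge") ">=" else "<=", o$threshold)
      n_case <- 0L; n_ctrl <- 0L
      for (ds in names(per_ds)) {
        n_case <- n_case + count_meeting_outcome(store, ds, o, "numeric",
                                                 per_ds[[ds]]$cases)
        n_ctrl <- n_ctrl + count_meeting_outcome(store, ds, o, "numeric",
                                                 per_ds[[ds]]$controls)
      }
      out_rows[[length(out_rows) + 1]] <- data.frame(
        label = lab, cases = n_case, controls = n_ctrl,
        stringsAsFactors = FALSE)
    } else {
      dom <- el$uniform_domain[[1]]
      acc <- matrix(0, nrow = nrow(dom), ncol = 2,
                    dimnames = list(dom$code, c("cases", "controls")))
      for (ds in names(per_ds)) {
        vals <- fetch_values(store, ds, o$element_id)
        for (grp in c("cases", "controls")) {
          vg <- vals[vals$identifier %in% per_ds[[ds]][[grp]], , drop = FALSE]
          for (code in dom$code) {
            acc[code, grp] <- acc[code, grp] +
              length(unique(vg$identifier[vg$value == code]))
          }
        }
      }
      for (k in seq_len(nrow(dom))) {
        out_rows[[length(out_rows) + 1]] <- data.frame(
          label = sprintf("%s = %s", o$element_id, dom$label[k]),
          cases = acc[dom$code[k], "cases"],
          controls = acc[dom$code[k], "controls"], stringsAsFactors = FALSE)
      }
    }
  }
  outcomes <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(label = character(0), cases = numeric(0), controls = numeric(0))

  totals <- c(cases = sum(vapply(per_ds, function(x) length(x$cases), numeric(1))),
              controls = sum(vapply(per_ds, function(x) length(x$controls),
                                    numeric(1))))
  structure(list(strata = strata, outcomes = outcomes, totals = totals,
                 skipped_datasets = skipped),
            class = "xs_case_control_table")
}

#' Prevalence table from per-dataset counts
#'
#' Each label pairs a condition count with a joint (condition-and-target)
#' count per dataset; entries are summed across datasets (a missing / `NA`
#' entry contributes 0) and the prevalence is
#' `100 * joint / condition`, rounded half-up to one decimal.
#'
#' @param condition_counts Named list: label -> numeric vector of
#'   per-dataset condition counts (`NA` where the dataset lacks the data).
#' @param joint_counts Named list with the same labels: per-dataset counts
#'   of subjects with the condition and the target.
#' @return Data frame with columns label, condition_count,
#'   condition_and_target_count, prevalence_pct.
#' @export
prevalence_table <- function(condition_counts, joint_counts) {
  if (!identical(names(condition_counts), names(joint_counts))) {
    xs_spec_error("condition and joint count labels must align")
  }
  rows <- lapply(names(condition_counts), function(lab) {
    cond <- sum(condition_counts[[lab]], na.rm = TRUE)
    joint <- sum(joint_counts[[lab]], na.rm = TRUE)
    if (joint > cond) {
      xs_abort(sprintf(
        "joint count (%d) exceeds condition count (%d) for '%s'",
        joint, cond, lab), "xs_data_error")
    }
    data.frame(label = lab, condition_count = cond,
               condition_and_target_count = joint,
               prevalence_pct = if (cond > 0) round_half_up(100 * joint / cond, 1)
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.xs_case_control_table <- function(x, ...) {
  cat(sprintf("<case-control table> %d case(s), %d control(s)\n",
              x$totals[["cases"]], x$totals[["controls"]]))
  if (nrow(x$strata)) {
    cat("strata:\n"); print(x$strata)
  }
  if (nrow(x$outcomes)) {
    cat("outcomes:\n"); print(x$outcomes)
  }
  if (length(x$skipped_datasets)) {
    cat("skipped (elements not covered):",
        paste(x$skipped_datasets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.xs_plot_series <- function(x, ...) {
  cat(sprintf("<plot series> %s: %s of %s by %s, %d group(s)\n",
              x$dataset_id, x$plot_kind, x$y_variable, x$x_variable,
              length(x$groups)))
  invisible(x)
}
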