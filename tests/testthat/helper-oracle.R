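# Independent brute-force oracle for distinct-subject counts: reads the raw
# corpus CSVs straight from disk, applies the coding map and the criteria
# in memory (per-criterion any-visit semantics, AND across criteria), and
# counts subjects. No package query code is involved beyond the criterion
# field names.

oracle_read_corpus <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  list(
    cfg = cfg,
    coding_map = read.csv(file.path(dir, "coding_map.csv"),
                          colClasses = "character"),
    mappings = read.csv(file.path(dir, "mappings.csv"),
                        colClasses = "character"),
    visits = lapply(cfg$datasets, function(d) {
      v <- lapply(d$visits, function(p)
        read.csv(file.path(dir, p), colClasses = "character",
                 na.strings = character(0)))
      names(v) <- names(d$visits)
      v
    }) |> setNames(vapply(cfg$datasets, function(d) d$id, character(1))))
}

# Subject ids in one dataset satisfying one criterion at any visit.
oracle_criterion_ids <- function(corpus, ds, cr) {
  rows <- corpus$mappings[corpus$mappings$dataset == ds &
                            corpus$mappings$element_id == cr$element_id, ,
                          drop = FALSE]
  ids <- character(0)
  for (j in seq_len(nrow(rows))) {
    tab <- corpus$visits[[ds]][[rows$visit[j]]]
    col <- rows$source_short_name[j]
    if (is.null(tab[[col]])) next
    vals <- tab[[col]]
    nonmiss <- !is.na(vals) & nzchar(vals)
    if (cr$kind == "numeric_range") {
      num <- suppressWarnings(as.numeric(vals))
      hit <- nonmiss & !is.na(num) & num >= cr$min & num <= cr$max
    } else {
      m <- corpus$coding_map[corpus$coding_map$dataset == ds &
                               corpus$coding_map$source_short_name == col, ,
                             drop = FALSE]
      v2 <- vals
      if (nrow(m)) v2[nonmiss] <- m$uniform_code[match(vals[nonmiss],
                                                       m$source_code)]
      hit <- nonmiss & v2 %in% cr$allowed_codes
    }
    ids <- union(ids, tab$pid[hit])
  }
  ids
}

oracle_counts <- function(corpus, datasets, criteria) {
  vapply(datasets, function(ds) {
    sets <- lapply(criteria, function(cr) oracle_criterion_ids(corpus, ds, cr))
    if (length(sets) == 0) {
      all_ids <- unique(unlist(lapply(corpus$visits[[ds]],
                                      function(t) t$pid)))
      return(length(all_ids))
    }
    length(Reduce(intersect, sets))
  }, numeric(1))
}

# Ground-truth-based eligibility (a second, generator-side oracle): uses the
# uniform attribute table the generator retained.
gt_eligible <- function(gt, ds, criteria) {
  g <- gt[gt$dataset == ds, , drop = FALSE]
  col_of <- c(gender = "gender", age = "age", body_mass_index = "bmi",
              diabetes_history = "diabetes", osa_events_per_hour = "ahi")
  sets <- lapply(criteria, function(cr) {
    v <- g[[col_of[[cr$element_id]]]]
    hit <- if (cr$kind == "numeric_range") {
      !is.na(v) & v >= cr$min & v <= cr$max
    } else {
      !is.na(v) & v %in% cr$allowed_codes
    }
    unique(g$pid[hit])
  })
  if (length(sets) == 0) unique(g$pid) else Reduce(intersect, sets)
}
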