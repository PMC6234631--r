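# Synthetic multi-cohort fixture generation.
#
# The generator emulates the structural heterogeneity of a multi-study
# sleep-cohort repository: several datasets with their own dictionaries,
# visit-suffixed short names for shared elements (bmi_v1 / bmi_v2 style),
# heterogeneous gender codings per dataset (the three styles seen in the
# field: uniform 1=Male/2=Female, shifted 0=Female/1=Male, permuted
# 1=Female/2=Male), overlapping-but-unequal variable coverage, and missing
# cells. It writes a complete, loadable corpus (dictionaries, visit CSVs,
# element mappings, coding map, YAML config) and keeps the pre-coding
# ground truth, so tests can compare engine output against the attributes
# the corpus was generated from.
#
# Randomness is drawn from streams keyed by (seed, dataset, variable):
# adding a variable to the generator never perturbs the draws of existing
# variables, so fixtures stay stable as the generator grows.

GENDER_STYLES <- list(
  uniform  = data.frame(code = c("1", "2"), label = c("Male", "Female"),
                        stringsAsFactors = FALSE),
  shifted  = data.frame(code = c("0", "1"), label = c("Female", "Male"),
                        stringsAsFactors = FALSE),
  permuted = data.frame(code = c("1", "2"), label = c("Female", "Male"),
                        stringsAsFactors = FALSE))

UNIFORM_GENDER <- data.frame(code = c("1", "2"), label = c("Male", "Female"),
                             stringsAsFactors = FALSE)
UNIFORM_YESNO <- data.frame(code = c("1", "2"), label = c("Yes", "No"),
                            stringsAsFactors = FALSE)

#' Fixture generator configuration
#'
#' Defaults describe the reference synthetic corpus: three datasets with
#' the three gender coding styles, 200 subjects each, the first dataset
#' longitudinal with two visits, 5% missing cells, ages uniform on
#' 20–90 years, BMI normal(28, 5) kg/m2 with a +4 shift for diabetics,
#' diabetes prevalence 0.2, and an apnea-hypopnea-like event rate
#' lognormal(log 8, 0.9) events/hour.
#'
#' @param n_datasets Number of datasets (1–3 use the three coding styles in
#'   order; more recycle).
#' @param n_subjects Subjects per dataset (recycled to `n_datasets`).
#' @param n_visits Visits per dataset (recycled).
#' @param coding_styles Gender coding style per dataset: uniform, shifted or
#'   permuted (recycled).
#' @param seed Integer seed; fully determines the corpus.
#' @param missingness_rate Probability that a non-identifier cell is missing.
#' @param age_range Uniform age range, years.
#' @param bmi_mean,bmi_sd BMI distribution, kg/m2.
#' @param bmi_diabetes_shift Added to mean BMI for diabetic subjects.
#' @param diabetes_prev Probability of a diabetes history.
#' @param retention Fraction of subjects retained at each later visit.
#' @return A validated `xs_fixture_config` list.
#' @export
fixture_config <- function(n_datasets = 3,
                           n_subjects = 200,
                           n_visits = c(2, 1, 1),
                           coding_styles = c("uniform", "shifted", "permuted"),
                           seed = 1,
                           missingness_rate = 0.05,
                           age_range = c(20, 90),
                           bmi_mean = 28, bmi_sd = 5,
                           bmi_diabetes_shift = 4,
                           diabetes_prev = 0.2,
                           retention = 0.8) {
  if (missingness_rate < 0 || missingness_rate >= 1) {
    xs_abort("missingness_rate must be in [0, 1)", "xs_config_error")
  }
  bad <- setdiff(coding_styles, names(GENDER_STYLES))
  if (length(bad)) {
    xs_abort(sprintf("unknown coding style(s): %s", paste(bad, collapse = ", ")),
             "xs_config_error")
  }
  structure(list(
    n_datasets = n_datasets,
    n_subjects = rep_len(n_subjects, n_datasets),
    n_visits = rep_len(n_visits, n_datasets),
    coding_styles = rep_len(coding_styles, n_datasets),
    seed = as.integer(seed),
    missingness_rate = missingness_rate,
    age_range = age_range, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    bmi_diabetes_shift = bmi_diabetes_shift, diabetes_prev = diabetes_prev,
    retention = retention), class = "xs_fixture_config")
}

# Keyed pseudo-random stream: a deterministic sub-seed per
# (seed, dataset, variable) string key, kept inside 32-bit integer range.
keyed_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483647)
}

keyed_draw <- function(seed, key, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(keyed_seed(seed, key))
  fn()
}

fixture_canonical <- function() {
  el <- data.frame(
    element_id = c("gender", "age", "body_mass_index", "diabetes_history",
                   "osa_events_per_hour"),
    display_name = c("gender", "age", "body mass index",
                     "diabetes mellitus - history",
                     "obstructive sleep apneas/hour"),
    var_type = c("categorical", "numeric", "numeric", "categorical", "numeric"),
    unit = c("", "years", "kilograms per square meter", "", "events/hour"),
    stringsAsFactors = FALSE)
  el$category_path <- list(c("demographics"), c("demographics"),
                           c("anthropometry"), c("medical history"),
                           c("sleep"))
  el$uniform_domain <- list(UNIFORM_GENDER,
                            parse_domain(""), parse_domain(""),
                            UNIFORM_YESNO, parse_domain(""))
  el$synonyms <- list(c("sex"), character(0), c("BMI"),
                      c("diabetes"), c("OSA", "obstructive sleep apnea"))
  structure(list(elements = el), class = "xs_canonical_dictionary")
}

fixture_dictionary <- function(ds, visits, style) {
  dom <- GENDER_STYLES[[style]]
  rows <- list()
  for (v in visits) {
    sfx <- paste0("_", v)
    rows[[length(rows) + 1]] <- data.frame(
      visit = v,
      short_name = c("pid", paste0(c("gender", "age", "bmi", "diab", "ahi"), sfx)),
      display_name = c("subject identifier", "gender", "age",
                       "body mass index", "diabetes mellitus - history",
                       "obstructive sleep apneas/hour"),
      description = "synthetic fixture variable",
      var_type = c("identifier", "categorical", "numeric", "numeric",
                   "categorical", "numeric"),
      unit = c("", "", "years", "kilograms per square meter", "", "events/hour"),
      stringsAsFactors = FALSE)
  }
  vars <- do.call(rbind, rows)
  vars$domain <- lapply(seq_len(nrow(vars)), function(i) {
    if (vars$var_type[i] != "categorical") return(parse_domain(""))
    if (startsWith(vars$short_name[i], "gender")) dom else UNIFORM_YESNO
  })
  vars$labels <- lapply(seq_len(nrow(vars)), function(i) {
    if (startsWith(vars$short_name[i], "bmi")) "BMI" else character(0)
  })
  structure(list(dataset_id = ds, visits = visits, variables = vars),
            class = "xs_data_dictionary")
}

#' Generate a synthetic multi-cohort fixture corpus
#'
#' Writes a complete, loadable corpus under `dir`: `canonical.csv`,
#' `dictionaries/<dataset>.csv`, `data/<dataset>-<visit>.csv`,
#' `mappings.csv`, `coding_map.csv` and `config.yaml` (which records the
#' generator's distribution settings so tests and docs read expected
#' effects from the same source the generator used). The same seed always
#' produces a byte-identical corpus.
#'
#' @param cfg An [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `config`, and `ground_truth` — the
#'   per-(dataset, subject, visit) attribute table in uniform coding, before
#'   the per-dataset gender recoding was applied. Applying the emitted
#'   coding map to the raw CSVs reproduces these uniform attributes exactly.
#' @export
generate_fixture <- function(cfg = fixture_config(), dir) {
  dir.create(file.path(dir, "dictionaries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  canon <- fixture_canonical()
  write_canonical_dictionary(canon, file.path(dir, "canonical.csv"))

  datasets <- paste0("DS", seq_len(cfg$n_datasets))
  gt_rows <- list()
  map_rows <- list()
  coding_rows <- list()
  for (d in seq_len(cfg$n_datasets)) {
    ds <- datasets[d]
    style <- cfg$coding_styles[d]
    visits <- paste0("v", seq_len(cfg$n_visits[d]))
    dict <- fixture_dictionary(ds, visits, style)
    write_data_dictionary(dict, file.path(dir, "dictionaries",
                                          paste0(ds, ".csv")))
    n <- cfg$n_subjects[d]
    pid <- sprintf("%s_S%04d", ds, seq_len(n))

    # Subject-level attributes (visit 1 values), keyed draws.
    gender_u <- keyed_draw(cfg$seed, paste(ds, "gender"), function()
      sample(UNIFORM_GENDER$code, n, replace = TRUE))
    diab_u <- keyed_draw(cfg$seed, paste(ds, "diab"), function()
      ifelse(runif(n) < cfg$diabetes_prev, "1", "2"))
    age1 <- keyed_draw(cfg$seed, paste(ds, "age"), function()
      round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1))
    bmi1 <- keyed_draw(cfg$seed, paste(ds, "bmi"), function()
      round(rnorm(n, cfg$bmi_mean, cfg$bmi_sd) +
              ifelse(diab_u == "1", cfg$bmi_diabetes_shift, 0), 1))
    ahi1 <- keyed_draw(cfg$seed, paste(ds, "ahi"), function()
      round(rlnorm(n, log(8), 0.9), 1))

    per_visit <- list(list(age = age1, bmi = bmi1, ahi = ahi1,
                           present = rep(TRUE, n)))
    for (v in seq_along(visits)[-1]) {
      present <- keyed_draw(cfg$seed, paste(ds, "present", v), function()
        runif(n) < cfg$retention) & per_visit[[v - 1]]$present
      bmi_d <- keyed_draw(cfg$seed, paste(ds, "bmi_delta", v), function()
        round(rnorm(n, 0, 1), 1))
      ahi_v <- keyed_draw(cfg$seed, paste(ds, "ahi", v), function()
        round(rlnorm(n, log(8), 0.9), 1))
      per_visit[[v]] <- list(age = round(per_visit[[v - 1]]$age + 2, 1),
                             bmi = round(per_visit[[v - 1]]$bmi + bmi_d, 1),
                             ahi = ahi_v, present = present)
    }

    # Gender recoding for this dataset's style: uniform code -> source code
    # via the shared label.
    dom <- GENDER_STYLES[[style]]
    to_source <- setNames(dom$code, dom$label)
    gender_src <- unname(to_source[UNIFORM_GENDER$label[
      match(gender_u, UNIFORM_GENDER$code)]])

    for (v in seq_along(visits)) {
      visit <- visits[v]
      sfx <- paste0("_", visit)
      present <- per_visit[[v]]$present
      vals <- data.frame(pid = pid,
                         gender = gender_src, age = per_visit[[v]]$age,
                         bmi = per_visit[[v]]$bmi, diab = diab_u,
                         ahi = per_visit[[v]]$ahi, stringsAsFactors = FALSE)
      # missingness per cell, keyed so each variable has its own stream
      miss <- list()
      for (var in c("gender", "age", "bmi", "diab", "ahi")) {
        miss[[var]] <- keyed_draw(cfg$seed, paste(ds, "miss", var, v), function()
          runif(n) < cfg$missingness_rate)
        vals[[var]][miss[[var]]] <- NA
      }
      out <- data.frame(pid = vals$pid, stringsAsFactors = FALSE)
      names(out) <- "pid"
      for (var in c("gender", "age", "bmi", "diab", "ahi")) {
        out[[paste0(var, sfx)]] <- vals[[var]]
      }
      out <- out[present, , drop = FALSE]
      csv <- file.path(dir, "data", sprintf("%s-%s.csv", ds, visit))
      write.csv(out, csv, row.names = FALSE, na = "")

      gt <- data.frame(dataset = ds, pid = pid, visit = visit,
                       gender = gender_u, age = per_visit[[v]]$age,
                       bmi = per_visit[[v]]$bmi, diabetes = diab_u,
                       ahi = per_visit[[v]]$ahi, stringsAsFactors = FALSE)
      for (var in c("gender", "age", "bmi", "diab", "ahi")) {
        col <- c(gender = "gender", age = "age", bmi = "bmi",
                 diab = "diabetes", ahi = "ahi")[[var]]
        gt[[col]][miss[[var]]] <- NA
      }
      gt_rows[[length(gt_rows) + 1]] <- gt[present, , drop = FALSE]

      map_rows[[length(map_rows) + 1]] <- data.frame(
        dataset = ds, visit = visit,
        source_short_name = paste0(c("gender", "age", "bmi", "diab", "ahi"), sfx),
        element_id = c("gender", "age", "body_mass_index", "diabetes_history",
                       "osa_events_per_hour"),
        stringsAsFactors = FALSE)

      if (style != "uniform") {
        coding_rows[[length(coding_rows) + 1]] <- data.frame(
          dataset = ds, source_short_name = paste0("gender", sfx),
          source_code = dom$code, source_label = dom$label,
          uniform_code = UNIFORM_GENDER$code[
            match(dom$label, UNIFORM_GENDER$label)],
          uniform_label = dom$label,
          stringsAsFactors = FALSE)
      }
    }
  }
  mappings <- as_mappings(do.call(rbind, map_rows))
  write.csv(as.data.frame(mappings), file.path(dir, "mappings.csv"),
            row.names = FALSE)
  coding_map <- if (length(coding_rows)) as_coding_map(do.call(rbind, coding_rows))
                else empty_coding_map()
  write_coding_map(coding_map, file.path(dir, "coding_map.csv"))

  config <- list(
    datasets = lapply(seq_len(cfg$n_datasets), function(d) list(
      id = datasets[d],
      dictionary = file.path("dictionaries", paste0(datasets[d], ".csv")),
      visits = as.list(setNames(
        file.path("data", sprintf("%s-v%d.csv", datasets[d],
                                  seq_len(cfg$n_visits[d]))),
        paste0("v", seq_len(cfg$n_visits[d])))),
      coding_style = cfg$coding_styles[d])),
    canonical = "canonical.csv", mappings = "mappings.csv",
    coding_map = "coding_map.csv",
    max_columns = 900, dialect = "sqlite",
    generator = list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                     missingness_rate = cfg$missingness_rate,
                     age_range = cfg$age_range,
                     bmi = list(mean = cfg$bmi_mean, sd = cfg$bmi_sd,
                                diabetes_shift = cfg$bmi_diabetes_shift),
                     diabetes_prev = cfg$diabetes_prev,
                     ahi = list(meanlog = log(8), sdlog = 0.9),
                     retention = cfg$retention))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))

  invisible(list(dir = dir, config = config,
                 ground_truth = do.call(rbind, gt_rows)))
}

#' Build and load a store from a corpus directory
#'
#' Reads a corpus laid out as written by [generate_fixture()] (driven by its
#' `config.yaml`), registers dictionaries, mappings and coding map, creates
#' the schemas and loads every visit CSV with harmonization applied.
#'
#' @param dir Corpus directory containing `config.yaml`.
#' @param db_path SQLite path for the store (default in-memory).
#' @return An `xs_store`, loaded. The per-visit `xs_load_report`s are
#'   attached as attribute `"load_reports"`.
#' @export
build_store <- function(dir, db_path = ":memory:") {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  store <- open_store(db_path)
  set_canonical(store, parse_canonical_dictionary(file.path(dir, cfg$canonical)))
  set_coding_map(store, read_coding_map(file.path(dir, cfg$coding_map)))
  reports <- list()
  for (d in cfg$datasets) {
    dict <- parse_data_dictionary(file.path(dir, d$dictionary))
    add_dataset(store, dict, max_columns = cfg$max_columns %||% 900)
    for (visit in names(d$visits)) {
      reports[[length(reports) + 1]] <-
        load_visit(store, file.path(dir, d$visits[[visit]]), d$id, visit)
    }
  }
  set_mappings(store, read_mappings(file.path(dir, cfg$mappings)))
  attr(store, "load_reports") <- reports
  store
}
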