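# Small in-code fixture builders shared across test files.

# Write a dictionary CSV from a compact row spec and parse it back.
write_dict_csv <- function(path, dataset, rows) {
  df <- do.call(rbind, lapply(rows, function(r) data.frame(
    dataset = dataset,
    visit = r$visit %||% "v1",
    short_name = r$short_name,
    display_name = r$display_name %||% r$short_name,
    description = r$description %||% "",
    type = r$type,
    unit = r$unit %||% "",
    domain = r$domain %||% "",
    labels = r$labels %||% "",
    stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal one-visit dictionary: identifier + gender + age.
toy_dictionary <- function(dataset = "TOY", gender_domain = "1=Male;2=Female",
                           dir = withr::local_tempdir()) {
  path <- file.path(dir, paste0(dataset, ".csv"))
  write_dict_csv(path, dataset, list(
    list(short_name = "pid", type = "identifier",
         display_name = "subject id"),
    list(short_name = "gender", type = "categorical", domain = gender_domain),
    list(short_name = "age", type = "numeric", unit = "years")))
  parse_data_dictionary(path)
}

# Canonical dictionary with gender / age / body_mass_index, written + parsed.
toy_canonical <- function(dir = withr::local_tempdir()) {
  path <- file.path(dir, "canonical.csv")
  df <- data.frame(
    element_id = c("gender", "age", "body_mass_index"),
    display_name = c("gender", "age", "body mass index"),
    category_path = c("demographics", "demographics", "anthropometry"),
    type = c("categorical", "numeric", "numeric"),
    unit = c("", "years", "kilograms per square meter"),
    uniform_domain = c("1=Male;2=Female", "", ""),
    synonyms = c("sex", "", "BMI"),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  parse_canonical_dictionary(path)
}

# A corpus of toy datasets carrying the eight published gender codings, a
# handful of subjects each, plus the uniform canonical gender element.
# Returns a loaded store plus the pieces needed to re-detect.
table1_corpus <- function(n_per = 6) {
  fx <- in_paper_fixtures()
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  canon <- toy_canonical(dir)
  store <- open_store()
  set_canonical(store, canon)
  set_coding_map(store, fx$gender_coding_map)
  dicts <- list()
  map_rows <- list()
  for (ds in names(fx$source_gender_domains)) {
    dom <- fx$source_gender_domains[[ds]]
    dict_path <- write_dict_csv(file.path(dir, paste0(ds, ".csv")), ds, list(
      list(short_name = "pid", type = "identifier"),
      list(short_name = "gender", type = "categorical",
           domain = paste(paste(dom$code, dom$label, sep = "="), collapse = ";"))))
    dict <- parse_data_dictionary(dict_path)
    dicts[[ds]] <- dict
    add_dataset(store, dict)
    codes <- rep(dom$code, length.out = n_per)
    csv <- file.path(dir, paste0(ds, "-v1.csv"))
    write.csv(data.frame(pid = sprintf("%s%02d", ds, seq_len(n_per)),
                         gender = codes, stringsAsFactors = FALSE),
              csv, row.names = FALSE, na = "")
    load_visit(store, csv, ds, "v1")
    map_rows[[ds]] <- data.frame(dataset = ds, visit = "v1",
                                 source_short_name = "gender",
                                 element_id = "gender",
                                 stringsAsFactors = FALSE)
  }
  mappings <- as_mappings(do.call(rbind, map_rows))
  set_mappings(store, mappings)
  list(store = store, dicts = dicts, canon = canon, mappings = mappings,
       coding_map = fx$gender_coding_map)
}

# Random fixture configuration within small problem sizes.
random_fixture_config <- function(seed) {
  set.seed(seed)
  fixture_config(
    n_datasets = sample(2:3, 1),
    n_subjects = sample(30:150, 1),
    n_visits = sample(1:3, 3, replace = TRUE),
    coding_styles = sample(c("uniform", "shifted", "permuted")),
    seed = seed,
    missingness_rate = runif(1, 0, 0.15))
}

# Random criteria over the generated fixture's canonical elements
# (uses the RNG state of the caller).
random_criteria <- function(n = sample(1:5, 1)) {
  pool <- list(
    function() criterion("age", min = min(r <- runif(2, 15, 95)), max = max(r)),
    function() criterion("body_mass_index",
                         min = min(r <- runif(2, 12, 50)), max = max(r)),
    function() criterion("osa_events_per_hour",
                         min = min(r <- runif(2, 0, 60)), max = max(r)),
    function() criterion("gender", codes = sample(c("1", "2"), sample(1:2, 1))),
    function() criterion("diabetes_history",
                         codes = sample(c("1", "2"), sample(1:2, 1))))
  lapply(sample(seq_along(pool), min(n, length(pool))), function(i) pool[[i]]())
}
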