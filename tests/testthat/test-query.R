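# A small hand-built two-visit store in the style of a longitudinal cohort:
# bmi recorded under visit-suffixed short names, gender and age at baseline.
make_cohort_store <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  dict_p <- write_dict_csv(file.path(dir, "shhs.csv"), "SHHS", list(
    list(short_name = "pid", type = "identifier", visit = "shhs1"),
    list(short_name = "gender", type = "categorical", visit = "shhs1",
         domain = "1=Male;2=Female"),
    list(short_name = "age_s1", type = "numeric", visit = "shhs1"),
    list(short_name = "bmi_s1", type = "numeric", visit = "shhs1",
         display_name = "body mass index"),
    list(short_name = "pid", type = "identifier", visit = "shhs2"),
    list(short_name = "bmi_s2", type = "numeric", visit = "shhs2",
         display_name = "body mass index")))
  dict <- parse_data_dictionary(dict_p)
  store <- open_store()
  set_canonical(store, toy_canonical(dir))
  add_dataset(store, dict)
  v1 <- file.path(dir, "shhs-shhs1.csv")
  writeLines(c("pid,gender,age_s1,bmi_s1",
               "p1,2,25,31.0",
               "p2,2,45,24.0",
               "p3,1,30,28.0",
               "p4,2,60,22.0",
               "p5,1,48,35.0",
               "p6,2,33,"), v1)
  v2 <- file.path(dir, "shhs-shhs2.csv")
  writeLines(c("pid,bmi_s2",
               "p2,31.0",
               "p4,29.5",
               "p6,27.0"), v2)
  load_visit(store, v1, "SHHS", "shhs1")
  load_visit(store, v2, "SHHS", "shhs2")
  set_mappings(store, as_mappings(data.frame(
    dataset = "SHHS",
    visit = c("shhs1", "shhs1", "shhs1", "shhs2"),
    source_short_name = c("gender", "age_s1", "bmi_s1", "bmi_s2"),
    element_id = c("gender", "age", "body_mass_index", "body_mass_index"),
    stringsAsFactors = FALSE)))
  store
}

test_that("one element resolves to every mapped variable across visits", {
  store <- make_cohort_store()
  q <- cohort_query("SHHS", list(criterion("body_mass_index", min = 0, max = 99)))
  res <- resolve_mappings(store, q)
  expect_equal(nrow(res$targets), 2)
  expect_setequal(res$targets$column, c("bmi_s1", "bmi_s2"))
  expect_setequal(res$targets$visit, c("shhs1", "shhs2"))
  expect_equal(nrow(res$non_covering), 0)
  close_store(store)
})

test_that("several variables in one visit can serve one element", {
  dir <- withr::local_tempdir()
  dict <- parse_data_dictionary(write_dict_csv(
    file.path(dir, "hb.csv"), "HeartBEAT", list(
      list(short_name = "pid", type = "identifier", visit = "baseline"),
      list(short_name = "bmi_scrn", type = "numeric", visit = "baseline"),
      list(short_name = "calc_bmi", type = "numeric", visit = "baseline"))))
  store <- open_store()
  set_canonical(store, toy_canonical(dir))
  add_dataset(store, dict)
  set_mappings(store, as_mappings(data.frame(
    dataset = "HeartBEAT", visit = "baseline",
    source_short_name = c("bmi_scrn", "calc_bmi"),
    element_id = "body_mass_index", stringsAsFactors = FALSE)))
  q <- cohort_query("HeartBEAT",
                    list(criterion("body_mass_index", min = 0, max = 99)))
  res <- resolve_mappings(store, q)
  expect_equal(nrow(res$targets), 2)
  expect_setequal(res$targets$column, c("bmi_scrn", "calc_bmi"))
  expect_equal(unique(res$targets$visit), "baseline")
  # an element mapped nowhere marks the dataset non-covering, not an error
  q2 <- cohort_query("HeartBEAT", list(criterion("age", min = 0, max = 99)))
  res2 <- resolve_mappings(store, q2)
  expect_equal(nrow(res2$targets), 0)
  expect_equal(res2$non_covering$dataset, "HeartBEAT")
  close_store(store)
})

test_that("translation instantiates the distinct-count template with bound values", {
  store <- make_cohort_store()
  q <- cohort_query("SHHS", list(criterion("age", min = 20, max = 50)))
  tq <- translate(store, q)[[1]]
  expect_true(tq$applicable)
  expect_match(tq$sql, "COUNT\\(DISTINCT subj\\)")
  expect_match(tq$sql, "\"age_s1\" BETWEEN \\? AND \\?")
  expect_equal(unlist(tq$bindings), c(20, 50))
  # values travel as parameters, never pasted into the statement
  expect_no_match(tq$sql, "20")
  close_store(store)
})

test_that("counts intersect criteria and OR across a criterion's visits", {
  store <- make_cohort_store()
  # females aged 20..50: p1 (25), p2 (45); p6 is 33 but female too
  r <- count_subjects(store, cohort_query("SHHS", list(
    criterion("gender", codes = "2"), criterion("age", min = 20, max = 50))))
  expect_equal(unname(r$per_dataset["SHHS"]), 3L)
  expect_equal(r$total, 3L)
  # bmi >= 29 at ANY visit: p1 (31.0 s1), p5 (35.0 s1), p2 (31.0 s2), p4 (29.5 s2)
  r2 <- count_subjects(store, cohort_query("SHHS", list(
    criterion("body_mass_index", min = 29, max = 99))))
  expect_equal(r2$total, 4L)
  # AND of both: females with any-visit bmi >= 29 and age 20..50: p1, p2
  r3 <- count_subjects(store, cohort_query("SHHS", list(
    criterion("gender", codes = "2"),
    criterion("age", min = 20, max = 50),
    criterion("body_mass_index", min = 29, max = 99))))
  expect_equal(r3$total, 2L)
  close_store(store)
})

test_that("a full-range criterion counts subjects with a non-missing value", {
  store <- make_cohort_store()
  # p6 has bmi missing at shhs1 but present at shhs2; all 6 have some bmi
  r <- count_subjects(store, cohort_query("SHHS", list(
    criterion("body_mass_index", min = -1e9, max = 1e9))))
  expect_equal(r$total, 6L)
  # age is missing for nobody, present only at shhs1
  r2 <- count_subjects(store, cohort_query("SHHS", list(
    criterion("age", min = -1e9, max = 1e9))))
  expect_equal(r2$total, 6L)
  close_store(store)
})

test_that("impossible ranges count zero; empty criteria count the universe", {
  store <- make_cohort_store()
  r <- count_subjects(store, cohort_query("SHHS", list(
    criterion("age", min = 1001, max = 1001))))
  expect_equal(r$total, 0L)
  r2 <- count_subjects(store, cohort_query("SHHS", list()))
  expect_equal(r2$total, subject_universe(store, "SHHS"))
  close_store(store)
})

test_that("non-covering datasets report n/a, never zero", {
  store <- make_cohort_store()
  dir <- withr::local_tempdir()
  d2 <- parse_data_dictionary(write_dict_csv(
    file.path(dir, "other.csv"), "OTHER", list(
      list(short_name = "pid", type = "identifier"),
      list(short_name = "age", type = "numeric"))))
  add_dataset(store, d2)
  csv <- file.path(dir, "other-v1.csv")
  writeLines(c("pid,age", "x1,40"), csv)
  load_visit(store, csv, "OTHER", "v1")
  store$mappings <- as_mappings(rbind(
    as.data.frame(store$mappings),
    data.frame(dataset = "OTHER", visit = "v1", source_short_name = "age",
               element_id = "age", stringsAsFactors = FALSE)))
  r <- count_subjects(store, cohort_query(c("SHHS", "OTHER"), list(
    criterion("body_mass_index", min = 0, max = 99))))
  expect_true(is.na(r$per_dataset[["OTHER"]]))
  expect_equal(r$per_dataset[["SHHS"]], 6L)
  expect_equal(r$total, 6L)  # total sums applicable datasets only
  close_store(store)
})

test_that("criteria are validated against the canonical dictionary", {
  store <- make_cohort_store()
  expect_error(count_subjects(store, cohort_query("SHHS", list(
    criterion("gender", codes = "9")))), class = "xs_spec_error")
  expect_error(count_subjects(store, cohort_query("SHHS", list(
    criterion("gender", min = 0, max = 1)))), class = "xs_spec_error")
  expect_error(cohort_query("SHHS", list(
    criterion("age", min = 50, max = 20))), class = "xs_spec_error")
  expect_error(cohort_query(character(0), list()), class = "xs_spec_error")
  expect_error(cohort_query("SHHS", list(
    criterion("age", min = 0, max = 9), criterion("age", min = 1, max = 2))),
    class = "xs_spec_error")
  close_store(store)
})

test_that("fetched values are harmonized and filterable", {
  d <- withr::local_tempdir()
  generate_fixture(fixture_config(seed = 5), d)
  store <- build_store(d)
  ds <- c("DS1", "DS2", "DS3")
  g <- fetch_values(store, ds, "gender")
  expect_true(all(g$value %in% c("1", "2")))   # only uniform codes remain
  # a filter matching nobody yields an empty frame
  none <- fetch_values(store, ds, "gender",
                       subject_filter = list(criterion("age", min = 900, max = 901)))
  expect_equal(nrow(none), 0)
  # the value multiset matches a raw-CSV oracle extraction after recoding
  corpus <- oracle_read_corpus(d)
  for (dsx in ds) {
    raw <- corpus$visits[[dsx]][["v1"]]$gender_v1
    raw <- raw[!is.na(raw) & nzchar(raw)]
    m <- corpus$coding_map[corpus$coding_map$dataset == dsx &
                             corpus$coding_map$source_short_name == "gender_v1", ]
    if (nrow(m)) raw <- m$uniform_code[match(raw, m$source_code)]
    got <- g$value[g$dataset == dsx & g$visit == "v1"]
    expect_equal(sort(got), sort(raw))
  }
  expect_error(fetch_values(store, ds, "no_such_element"),
               class = "xs_validation_error")
  close_store(store)
})

test_that("SQL counts agree with the brute-force oracle on random fixtures", {
  for (seed in c(101, 202, 303)) {
    d <- withr::local_tempdir()
    generate_fixture(random_fixture_config(seed), d)
    store <- build_store(d)
    corpus <- oracle_read_corpus(d)
    ds <- vapply(corpus$cfg$datasets, function(x) x$id, character(1))
    set.seed(seed + 1)
    for (k in 1:5) {
      crits <- random_criteria()
      got <- count_subjects(store, cohort_query(ds, crits))
      want <- oracle_counts(corpus, ds, crits)
      expect_equal(unname(got$per_dataset[ds]), unname(want),
                   info = sprintf("seed %d query %d", seed, k))
    }
    close_store(store)
  }
})
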