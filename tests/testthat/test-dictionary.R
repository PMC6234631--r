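test_that("a minimal dictionary parses with types, domains and identifier", {
  dir <- withr::local_tempdir()
  path <- write_dict_csv(file.path(dir, "toy.csv"), "TOY", list(
    list(short_name = "id", type = "identifier"),
    list(short_name = "gender", type = "categorical",
         domain = "1=Male;2=Female"),
    list(short_name = "age", type = "numeric", unit = "years")))
  d <- parse_data_dictionary(path)
  expect_s3_class(d, "xs_data_dictionary")
  expect_equal(d$dataset_id, "TOY")
  expect_equal(nrow(d$variables), 3)
  expect_equal(sum(d$variables$var_type == "identifier"), 1)
  expect_equal(d$variables$domain[[2]],
               data.frame(code = c("1", "2"), label = c("Male", "Female"),
                          stringsAsFactors = FALSE))
})

test_that("the same element can recur across visits with distinct short names", {
  dir <- withr::local_tempdir()
  path <- write_dict_csv(file.path(dir, "shhs.csv"), "SHHS", list(
    list(short_name = "subjid", type = "identifier", visit = "shhs1"),
    list(short_name = "bmi_s1", type = "numeric", visit = "shhs1",
         display_name = "body mass index", unit = "kilograms per square meter"),
    list(short_name = "subjid", type = "identifier", visit = "shhs2"),
    list(short_name = "bmi_s2", type = "numeric", visit = "shhs2",
         display_name = "body mass index", unit = "kilograms per square meter")))
  d <- parse_data_dictionary(path)
  bmi <- d$variables[startsWith(d$variables$short_name, "bmi"), ]
  expect_equal(nrow(bmi), 2)
  expect_equal(unique(bmi$display_name), "body mass index")
  expect_setequal(bmi$visit, c("shhs1", "shhs2"))
})

test_that("domain order follows the file, codes stay opaque tokens", {
  dir <- withr::local_tempdir()
  path <- write_dict_csv(file.path(dir, "hb.csv"), "HeartBEAT", list(
    list(short_name = "pid", type = "identifier"),
    list(short_name = "gender", type = "categorical",
         domain = "0=Female;1=Male")))
  d <- parse_data_dictionary(path)
  dom <- d$variables$domain[[2]]
  expect_identical(dom$code, c("0", "1"))
  expect_identical(dom$label, c("Female", "Male"))
  expect_type(dom$code, "character")
})

test_that("malformed dictionaries are rejected with classed errors", {
  dir <- withr::local_tempdir()
  # missing required column
  df <- data.frame(dataset = "X", visit = "v1", short_name = "id",
                   display_name = "", description = "", type = "identifier",
                   unit = "", domain = "")  # no labels column
  p1 <- file.path(dir, "m.csv"); write.csv(df, p1, row.names = FALSE)
  err <- expect_error(parse_data_dictionary(p1), class = "xs_format_error")
  expect_match(conditionMessage(err), "labels")
  # duplicate short_name within a visit
  p2 <- write_dict_csv(file.path(dir, "d.csv"), "X", list(
    list(short_name = "pid", type = "identifier"),
    list(short_name = "age", type = "numeric"),
    list(short_name = "age", type = "numeric")))
  err <- expect_error(parse_data_dictionary(p2), class = "xs_validation_error")
  expect_match(conditionMessage(err), "age")
  # categorical with empty domain
  p3 <- write_dict_csv(file.path(dir, "e.csv"), "X", list(
    list(short_name = "pid", type = "identifier"),
    list(short_name = "gender", type = "categorical")))
  expect_error(parse_data_dictionary(p3), class = "xs_validation_error")
  # no identifier in a visit
  p4 <- write_dict_csv(file.path(dir, "n.csv"), "X", list(
    list(short_name = "age", type = "numeric")))
  expect_error(parse_data_dictionary(p4), class = "xs_validation_error")
  # unit on a non-numeric variable
  p5 <- write_dict_csv(file.path(dir, "u.csv"), "X", list(
    list(short_name = "pid", type = "identifier"),
    list(short_name = "note", type = "text", unit = "years")))
  expect_error(parse_data_dictionary(p5), class = "xs_validation_error")
})

test_that("serialize-parse round trip reproduces the structure exactly", {
  dir <- withr::local_tempdir()
  path <- write_dict_csv(file.path(dir, "rt.csv"), "RT", list(
    list(short_name = "pid", type = "identifier", visit = "v1"),
    list(short_name = "gender", type = "categorical", visit = "v1",
         domain = "0=Female;1=Male", labels = "sex|sex at birth"),
    list(short_name = "bmi", type = "numeric", visit = "v1",
         unit = "kilograms per square meter", labels = "BMI"),
    list(short_name = "pid", type = "identifier", visit = "v2"),
    list(short_name = "visitdate", type = "date", visit = "v2")))
  d1 <- parse_data_dictionary(path)
  out <- file.path(dir, "rt2.csv")
  write_data_dictionary(d1, out)
  d2 <- parse_data_dictionary(out)
  expect_identical(d1, d2)
})

test_that("canonical dictionary parses, rejects duplicates, allows empty", {
  canon <- toy_canonical()
  expect_equal(nrow(canon$elements), 3)
  gd <- canon$elements$uniform_domain[[1]]
  expect_identical(gd, data.frame(code = c("1", "2"),
                                  label = c("Male", "Female"),
                                  stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  # duplicate element_id
  df <- data.frame(element_id = c("age", "age"), display_name = "age",
                   category_path = "demographics", type = "numeric",
                   unit = "years", uniform_domain = "", synonyms = "")
  p <- file.path(dir, "dup.csv"); write.csv(df, p, row.names = FALSE)
  expect_error(parse_canonical_dictionary(p), class = "xs_validation_error")
  # header-only file
  p2 <- file.path(dir, "empty.csv")
  write.csv(df[0, ], p2, row.names = FALSE)
  empty <- parse_canonical_dictionary(p2)
  expect_equal(nrow(empty$elements), 0)
  # round trip
  out <- file.path(dir, "canon2.csv")
  write_canonical_dictionary(canon, out)
  expect_identical(canon, parse_canonical_dictionary(out))
})

test_that("term search ranks exact, prefix, then substring; synonyms count", {
  canon <- toy_canonical()
  expect_equal(search_terms(canon, "body mass")$element_id, "body_mass_index")
  expect_equal(search_terms(canon, "BMI")$element_id, "body_mass_index")
  expect_equal(nrow(search_terms(canon, "zzz-no-such-term")), 0)
  expect_equal(search_terms(canon, "")$element_id, canon$elements$element_id)
  # exact beats prefix beats substring
  dir <- withr::local_tempdir()
  df <- data.frame(
    element_id = c("age", "age_at_diagnosis", "stage"),
    display_name = c("age", "age at diagnosis", "stage"),
    category_path = "demographics", type = "numeric", unit = "",
    uniform_domain = "", synonyms = "")
  p <- file.path(dir, "c.csv"); write.csv(df, p, row.names = FALSE)
  res <- search_terms(parse_canonical_dictionary(p), "age")
  expect_equal(res$element_id, c("age", "age_at_diagnosis", "stage"))
})

test_that("browse tree mirrors category paths and its leaves are the elements", {
  canon <- toy_canonical()
  tree <- browse_tree(canon)
  expect_named(tree$children, c("demographics", "anthropometry"))
  expect_setequal(tree$children$demographics$elements, c("gender", "age"))
  expect_equal(tree_leaf_count(tree), nrow(canon$elements))

  # an element with an empty path sits at the root
  dir <- withr::local_tempdir()
  df <- data.frame(element_id = "x", display_name = "x", category_path = "",
                   type = "numeric", unit = "", uniform_domain = "",
                   synonyms = "")
  p <- file.path(dir, "r.csv"); write.csv(df, p, row.names = FALSE, na = "")
  t2 <- browse_tree(parse_canonical_dictionary(p))
  expect_equal(t2$elements, "x")
  expect_length(t2$children, 0)
})

test_that("leaf count equals element count on random dictionaries", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(1:20, 1)
    paths <- vapply(seq_len(n), function(i) {
      depth <- sample(0:3, 1)
      paste(sample(letters[1:4], depth, replace = TRUE), collapse = "/")
    }, character(1))
    el <- data.frame(element_id = sprintf("e%02d", seq_len(n)),
                     display_name = sprintf("element %02d", seq_len(n)),
                     var_type = "numeric", unit = "", stringsAsFactors = FALSE)
    el$category_path <- lapply(paths, function(p)
      if (nzchar(p)) strsplit(p, "/")[[1]] else character(0))
    el$uniform_domain <- rep(list(data.frame(code = character(0),
                                             label = character(0))), n)
    el$synonyms <- rep(list(character(0)), n)
    canon <- structure(list(elements = el), class = "xs_canonical_dictionary")
    tree <- browse_tree(canon)
    expect_equal(tree_leaf_count(tree), n)
    expect_setequal(xcohort:::tree_leaf_ids(tree), el$element_id)
  }
})
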