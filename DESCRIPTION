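Package: xcohort
Title: Cross-Cohort Query and Exploration of Harmonized Clinical Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A metadata-driven engine for exploring heterogeneous cohort
    datasets. Per-dataset data dictionaries are harmonized against a canonical
    dictionary of common data elements via explicit element mappings and
    coding maps; data are loaded into an embedded relational store with
    coding inconsistencies resolved at load time; distinct-subject count
    queries, graphical-exploration summaries (bar and box plot statistics),
    case-control count tables, and prevalence tables are computed across the
    datasets through dictionary-driven SQL translation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
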