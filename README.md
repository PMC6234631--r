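# xcohort

Cross-cohort query and exploration of heterogeneous clinical datasets.

Epidemiological data repositories host datasets from independently designed
cohort studies: per-visit CSV record files described by per-dataset data
dictionaries. The same concept goes by different variable names in every
study (`bmi_s1`/`bmi_s2` here, `bmi_scrn`/`calc_bmi` there), and categorical
codings contradict each other — "gender" may be 1=Male/2=Female,
0=Female/1=Male, or 1=Female/2=Male depending on the study. `xcohort` is a
metadata-driven engine that makes subject-level questions answerable across
such a repository *before* anyone requests full data access: it harmonizes
the datasets against a canonical dictionary of common data elements, loads
them into an embedded SQL store with codings unified, and answers
distinct-subject count queries, graphical-exploration summaries, and
case-control count tables.

## The model

Three pieces of metadata drive everything:

* **Canonical dictionary** — one row per common data element (CDE): id,
  display name, category path for hierarchical browsing, type
  (numeric/categorical), unit, uniform value domain, synonyms.
* **Element mappings** — m:1 links `(dataset, visit, source variable) →
  canonical element`.
* **Coding maps** — per-dataset rows `source code → uniform code` for the
  categorical elements whose codings disagree across datasets. Detection of
  disagreement is automatic (set comparison of (code, case-folded label)
  pairs across mapped sources); the resolution is explicit reviewer input —
  the engine refuses to guess label semantics.

Harmonization is applied at **load time**, so stored codes are already
uniform and one SQL statement works for every dataset. A cohort query —
datasets plus criteria over canonical elements — is translated per dataset
from the distinct-subject count template

```sql
SELECT COUNT(DISTINCT <identifier>) FROM <table>
 WHERE <column> BETWEEN <min> AND <max>
```

with AND across criteria and OR across the source variables mapped to one
element (any-visit semantics), `IN (codes)` for categorical criteria, and
bound parameters throughout. Datasets that do not collect a queried element
report `n/a`, never 0.

## Worked example

The package ships a synthetic-corpus generator that emulates the
heterogeneity above (three datasets, three gender coding styles, a
longitudinal first dataset, missing cells):

```r
library(xcohort)
dir <- tempfile("corpus-")
generate_fixture(fixture_config(seed = 7), dir)
store <- build_store(dir)

canon <- parse_canonical_dictionary(file.path(dir, "canonical.csv"))
dicts <- lapply(paste0("DS", 1:3), function(d)
  parse_data_dictionary(file.path(dir, "dictionaries", paste0(d, ".csv"))))
detect_inconsistencies(canon, dicts, read_mappings(file.path(dir, "mappings.csv")))
#> <inconsistency reports> 2 categorical element(s) checked, 1 inconsistent
#>   gender:
#>     DS1/v1/gender_v1               1=Male;2=Female
#>     DS1/v2/gender_v2               1=Male;2=Female
#>     DS2/v1/gender_v1               0=Female;1=Male
#>     DS3/v1/gender_v1               1=Female;2=Male

count_subjects(store, cohort_query(paste0("DS", 1:3), list(
  criterion("gender", codes = "2"),          # uniform code 2 = Female
  criterion("age", min = 20, max = 50))))
#> <query result>
#>   DS1          41
#>   DS2          39
#>   DS3          34
#>   total        114
close_store(store)
```

The three per-dataset numbers are distinct-subject counts of women aged
20–50 (any visit) in each dataset — correct across the three contradictory
gender codings because the store holds harmonized codes — and the total is
their sum (subjects are never linked across datasets).

Beyond counts: `plot_data()` returns bar counts or box statistics of one
element against a categorical grouping element, `run_case_control()`
produces stratified case/control count tables from a five-part
specification (base criteria, case condition, control condition, match
elements, outcomes), and `prevalence_table()` turns per-dataset condition
and joint counts into summed counts with prevalences. A thin CLI wraps the
same functions: see `inst/scripts/xcohort` (`generate-fixture`,
`validate-dict`, `detect-inconsistencies`, `load`, `query`, `explore`,
`case-control`).

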