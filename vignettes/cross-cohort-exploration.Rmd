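---
title: "Cross-cohort exploration of harmonized clinical datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort exploration of harmonized clinical datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcohort)
```

## The problem

Epidemiological data repositories accumulate datasets from independently
designed cohort studies. Each study ships its clinical variables as per-visit
CSV files plus a data dictionary (short name, display name, type, unit, value
domain, synonyms), and no two studies agree on how to name or code anything:
body mass index may be `bmi_s1` at baseline and `bmi_s2` at follow-up in one
study and `bmi_scrn`/`calc_bmi` in another, and "gender" may be coded
1=Male/2=Female, 0=Female/1=Male, or 1=Female/2=Male depending on the study.
A researcher asking "how many female subjects aged 20–50 exist across these
cohorts?" needs all of that heterogeneity resolved before the count means
anything.

`xcohort` is a metadata-driven engine for that job. Its moving parts are:

1. a **canonical dictionary** of common data elements (CDEs) that drives
   search, hierarchical browsing and query translation;
2. **element mappings**, m:1 links from source variables (per dataset and
   visit) to canonical elements;
3. **coding-inconsistency detection and harmonization**: an automatic
   comparison of the value domains of all sources mapped to one categorical
   element, plus reviewer-built coding maps onto one uniform coding;
4. a **dictionary-driven loader** into an embedded SQL store; and
5. **count queries, graphical-exploration summaries, and case-control
   tables** over the harmonized store.

## The count-query model

A cohort query selects datasets and constrains canonical elements: numeric
elements by an inclusive range, categorical elements by a set of uniform
codes. Per dataset the engine instantiates the distinct-subject count
template

```sql
SELECT COUNT(DISTINCT <identifier>) FROM <table>
 WHERE <column> BETWEEN <min> AND <max>
```

generalised in two directions. Criteria combine with **AND**. Within one
criterion, the source variables mapped to its element — across visits and
across split table parts — combine with **OR**, so a subject qualifies if
*any* of their visits' values satisfies the criterion ("any-visit"
semantics). The any-visit choice is anchored by the typical eligibility
phrasing of cohort re-use studies ("≥ 5 events per hour recorded during any
visit"); requiring all criteria within the *same* visit is a defensible
alternative we did not implement, and the two differ for longitudinal
datasets (a subject may be in range for age at one visit and for BMI at
another). Missing values never satisfy a criterion — SQL `BETWEEN`/`IN`
exclude `NULL` — so a full-range criterion counts exactly the subjects with
a non-missing value.

A dataset in which some queried element is mapped to nothing is reported as
**n/a**, never 0: "the element is not collected here" and "queried and
empty" are different answers. The total is the sum over applicable datasets;
subjects are never linked across datasets (the repository has no
cross-study identifier), so the total can in principle count one person
twice if they enrolled in two studies.

## Harmonization happens at load time

Two designs were possible: keep source codes as stored and rewrite each
dataset's SQL at query time, or recode the data once while loading. We load
harmonized ("the first option"): each cell of a coding-mapped categorical
variable passes through the coding map before insertion, so one uniform SQL
statement works for every dataset, at the cost of reloading if a map
changes. The loader records how many cells it harmonized.

Two deliberate refusals are part of the contract:

* **The engine never guesses label semantics.** Inconsistency *detection* is
  automatic — an element is flagged when two mapped sources disagree on the
  set of (code, case-folded label) pairs, which catches both code shifts
  (0/1 vs 1/2) and label permutations (1=Female vs 1=Male) — but the
  *resolution* (which source label means which uniform label) is an explicit
  reviewer input to `build_coding_map()`. A source label absent from that
  input is an error listing the offenders, not a fuzzy match.
* **Unknown codes surface, they are not passed through.** If a variable has
  coding-map rows, a data cell whose code is not among them indicates a
  data/dictionary mismatch; the loader rejects that row and logs it.
  Variables with no map rows (never flagged) pass through untouched.

Codes are opaque text tokens everywhere: the same numeral carries different
meanings in different studies, so numeric interpretation of codes is never
safe.

## The store

The store is a single embedded SQLite database; the schema generator also
emits MySQL-flavoured DDL through a small dialect layer, since the SQL
template itself is dialect-portable. One table is created per
(dataset, visit, part): relational engines cap the column count of a table,
and clinical visits can exceed it, so a visit's variables are packed into
parts (default cap 900 columns) in dictionary order with the subject
identifier replicated into every part. Replication makes each part
self-sufficient for distinct-subject counting, and parts recombine through
the identifier via the same set algebra (`UNION`/`INTERSECT`) used across
visits — no explicit join is needed.

Loading is batch, replace-on-load: tables are dropped and recreated per
load, so reloading a file is idempotent. Empty cells become SQL `NULL`;
sentinel missing codes (e.g. `-9`) are not special-cased and must either be
declared in the domain or cleaned upstream. A row is rejected (and logged
with a reason) for an unparseable numeric cell, an unknown mapped code, a
missing identifier, or a duplicate identifier (the later row loses);
rejecting rows rather than cells keeps a subject's record internally
consistent.

## Exploration

`plot_data()` summarises element *y* against categorical element *x*: bar
counts when *y* is categorical, box statistics when *y* is numeric, one
series per (dataset, mapped x-variable, mapped y-variable) pair, each
subject contributing when both values are present. Box statistics use
quartiles by linear interpolation between order statistics (`quantile`
type 7) and Tukey whiskers — the most extreme observations within 1.5 × IQR
of the quartiles. These are the dominant conventions; nothing downstream
depends on the choice beyond the plotted shape.

`run_case_control()` implements a five-part count procedure: base-population
criteria, a case condition, a control condition, categorical match elements,
and outcome elements. Cases and controls are base subjects additionally
satisfying the respective condition; an overlap between the two sets is a
specification error (reported with the overlapping count), not silently
resolved. Match elements produce a stratified cross-tabulation of case and
control counts — not matched-pair sampling; the output is a count table.
When visits disagree on a subject's match value, the earliest visit with a
non-missing value wins (a subject's stratum should be stable, and baseline
is the natural anchor); subjects missing a match value are omitted from the
strata but kept in the totals. Numeric outcomes require an explicit
threshold and direction (e.g. ≥ 15 events/hour) — there is no default
dichotomisation a tool should pick for you.

`prevalence_table()` does the arithmetic of a comorbidity table: per
condition label, per-dataset condition counts and condition-and-target
counts are summed (an `NA` entry contributes 0, for datasets lacking the
variable) and the prevalence is `100 × joint / condition`, rounded half-up
to one decimal to match conventional display precision.

## The synthetic corpus

Real multi-study repositories are access-controlled, so the package carries
a generator that emulates the *structure* of one: 3 datasets with the three
gender coding styles (uniform 1=Male/2=Female, shifted 0=Female/1=Male,
permuted 1=Female/2=Male), 200 subjects each, the first dataset
longitudinal with two visits (80% retention), visit-suffixed short names
(`bmi_v1`-style), 5% missing cells, ages uniform on 20–90 years, BMI
normal(28, 5) kg/m², diabetes prevalence 0.2 with a +4 kg/m² BMI shift for
diabetics (so the box-plot example has a visible signal in a realistic
direction), and an apnea-hypopnea-like rate lognormal(log 8, 0.9)
events/hour. These settings are written into the corpus's `config.yaml`, so
tests and documentation read the expected effects from the same source the
generator used.

Randomness is drawn from streams keyed by (seed, dataset, variable), so the
same seed is byte-identical and adding a variable to the generator never
perturbs existing draws. The generator retains the pre-recoding ground
truth; applying its own coding map to its raw CSVs reproduces the uniform
attributes exactly, which is what makes it usable as an oracle.

What the fixtures do *not* emulate: real marginal distributions and
correlations, informative missingness, measurement drift across visits, or
study-specific eligibility. Passing tests therefore demonstrate the
*mechanics* — harmonization, translation, counting, set algebra — not
epidemiological fidelity.

## Numerical and scale choices

Test and verification problem sizes are kept desk-scale: random corpora of
2–3 datasets with 30–150 subjects and 1–3 visits, 100 random queries for
the SQL-vs-brute-force comparison, and 200 trials for the property suites
(monotonicity, box ordering, case/control disjointness, ground-truth
recovery). Counts are integers and comparisons exact; the only rounding
anywhere is the half-up display rounding of prevalences. Criterion bounds
travel as bound SQL parameters, so R and SQLite compare the same IEEE
doubles.

## Known limitations

* No statistical testing (odds ratios, χ², confidence intervals) — the
  engine reports counts and prevalences only.
* No cross-dataset subject de-duplication.
* Any-visit semantics only (see above).
* Synonym search is string containment, not ontology-aware.
* No streaming or incremental loads; a corpus is loaded as a batch.

## A worked example

```{r example}
dir <- tempfile("corpus-")
fx <- generate_fixture(fixture_config(seed = 7), dir)
store <- build_store(dir)

# which elements are inconsistently coded across the three datasets?
canon <- parse_canonical_dictionary(file.path(dir, "canonical.csv"))
dicts <- lapply(paste0("DS", 1:3), function(d)
  parse_data_dictionary(file.path(dir, "dictionaries", paste0(d, ".csv"))))
detect_inconsistencies(canon, dicts, read_mappings(file.path(dir, "mappings.csv")))

# females aged 20-50, counted per dataset over the harmonized store
count_subjects(store, cohort_query(paste0("DS", 1:3), list(
  criterion("gender", codes = "2"),
  criterion("age", min = 20, max = 50))))

close_store(store)
```
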