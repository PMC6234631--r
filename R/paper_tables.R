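# In-built reference constants: the published gender coding-harmonization
# table for the nine-study sleep repository the engine was designed around,
# and the published OSA use-case count tables. These are inputs (printed
# tables), used as fixtures for harmonization round-trips and prevalence
# arithmetic; the full repository data is access-controlled and not
# reproduced here.

#' Reference tables from the sleep-repository use case
#'
#' Returns, as structured constants:
#' \describe{
#'   \item{gender_coding_map}{An `xs_coding_map` with the published
#'     per-dataset gender codings of eight cohort studies (SHHS, CHAT,
#'     HeartBEAT, CFS, MrOS, CCSHS, HCHS, MESA) mapped onto the uniform
#'     coding 1=Male, 2=Female.}
#'   \item{uniform_gender_domain}{The uniform gender domain (code/label).}
#'   \item{source_gender_domains}{Named list of each dataset's source
#'     (code, label) domain.}
#'   \item{osa_counts}{Per-dataset counts of subjects meeting the OSA
#'     criterion (>= 5 obstructive apnea events/hour at any visit) in the
#'     four datasets of the published use case.}
#'   \item{demographics}{Matrix of OSA-subject counts by gender and race per
#'     dataset (`NA` where race was unavailable).}
#'   \item{condition_counts, joint_counts}{Per-dataset counts of subjects
#'     with a history of each medical condition, and with the condition and
#'     OSA jointly, for the prevalence table. The published diabetes
#'     prevalence cell is internally inconsistent with its counts and is
#'     carried as data only, never asserted.}
#' }
#'
#' @return A named list of constants.
#' @export
in_paper_fixtures <- function() {
  styles <- list(
    SHHS      = list(code = c("1", "2"), label = c("Male", "Female")),
    CHAT      = list(code = c("1", "2"), label = c("Male", "Female")),
    HeartBEAT = list(code = c("0", "1"), label = c("Female", "Male")),
    CFS       = list(code = c("0", "1"), label = c("Female", "Male")),
    MrOS      = list(code = c("1", "2"), label = c("Female", "Male")),
    CCSHS     = list(code = c("0", "1"), label = c("Female", "Male")),
    HCHS      = list(code = c("0", "1"), label = c("Female", "Male")),
    MESA      = list(code = c("0", "1"), label = c("Female", "Male")))
  uniform <- data.frame(code = c("1", "2"), label = c("Male", "Female"),
                        stringsAsFactors = FALSE)
  rows <- lapply(names(styles), function(ds) {
    s <- styles[[ds]]
    data.frame(dataset = ds, source_short_name = "gender",
               source_code = s$code, source_label = s$label,
               uniform_code = uniform$code[match(s$label, uniform$label)],
               uniform_label = s$label, stringsAsFactors = FALSE)
  })
  gender_map <- as_coding_map(do.call(rbind, rows))
  source_domains <- lapply(styles, function(s)
    data.frame(code = s$code, label = s$label, stringsAsFactors = FALSE))

  ds4 <- c("SHHS", "CHAT", "HeartBEAT", "CFS")
  osa <- setNames(c(2071, 214, 300, 189), ds4)
  demographics <- rbind(
    Male   = c(1117,  96, 221, 107),
    Female = c( 954, 118,  79,  82),
    White  = c(1838,  55,  NA,  70),
    Black  = c( 141, 139,  NA, 118),
    Other  = c(  92,  20,  NA,   1))
  colnames(demographics) <- ds4

  condition_counts <- list(
    hypertension = setNames(c(2441,   2, 298, 285), ds4),
    diabetes     = setNames(c( 405,   0, 153, 153), ds4),
    depression   = setNames(c(  NA,   6, 100, 120), ds4),
    anxiety      = setNames(c(  NA,   9,  64,  60), ds4))
  joint_counts <- list(
    hypertension = setNames(c(1330,   1, 281, 105), ds4),
    diabetes     = setNames(c( 153,   0, 144,  48), ds4),
    depression   = setNames(c(  NA,   3,  94,  38), ds4),
    anxiety      = setNames(c(  NA,   5,  59,  16), ds4))

  list(gender_coding_map = gender_map,
       uniform_gender_domain = uniform,
       source_gender_domains = source_domains,
       osa_counts = osa,
       demographics = demographics,
       condition_counts = condition_counts,
       joint_counts = joint_counts)
}
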