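#' @import methods
#' @importFrom stats pnorm qnorm rbinom runif sd setNames rnorm aggregate
#' @importFrom utils head
NULL

#' Cohort of baseline inpatient records
#'
#' One record per patient: demographic fields plus the deduplicated set of
#' 3-character ICD-10 codes diagnosed at the baseline (first) admission.
#' Disease-free patients (empty code sets) are permitted so that synthetic
#' cohorts can carry the full screening denominator; the record-reading path
#' ([applyFilters()]) excludes them as the inclusion flow requires.
#'
#' @slot patients data.frame with columns `patient_id`, `age`, `sex`
#'   (`"male"`/`"female"`).
#' @slot codes list of character vectors, parallel to `patients`; each a
#'   sorted set of unique 3-character codes.
#' @slot label population/stratum name.
#' @slot report named list of parse/filter counts accumulated upstream.
#' @export
setClass("Cohort",
  representation(
    patients = "data.frame",
    codes = "list",
    label = "character",
    report = "list"
  ),
  prototype(
    patients = data.frame(patient_id = character(0), age = integer(0),
                          sex = character(0), stringsAsFactors = FALSE),
    codes = list(), label = "cohort", report = list()
  )
)

setValidity("Cohort", function(object) {
  p <- object@patients
  msgs <- character(0)
  need <- c("patient_id", "age", "sex")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, "patients must have columns patient_id, age, sex")
  else {
    if (nrow(p) != length(object@codes))
      msgs <- c(msgs, "codes list length must equal number of patients")
    if (anyDuplicated(p$patient_id))
      msgs <- c(msgs, "patient ids must be unique")
    if (any(p$age < 0, na.rm = TRUE))
      msgs <- c(msgs, "ages must be non-negative")
    if (!all(p$sex %in% c("male", "female")))
      msgs <- c(msgs, "sex must be 'male' or 'female'")
    if (!all(vapply(object@codes, is.character, logical(1))))
      msgs <- c(msgs, "codes must be character vectors")
  }
  if (length(object@label) != 1L)
    msgs <- c(msgs, "label must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Cohort
#'
#' @param patients data.frame with `patient_id`, `age`, `sex`.
#' @param codes list of character code vectors, one per patient; each is
#'   deduplicated and sorted.
#' @param label cohort name.
#' @param report optional list of upstream parse/filter counts.
#' @return A [Cohort-class] object.
#' @export
Cohort <- function(patients, codes, label = "cohort", report = list()) {
  patients$patient_id <- as.character(patients$patient_id)
  patients$age <- as.integer(patients$age)
  patients$sex <- as.character(patients$sex)
  rownames(patients) <- NULL
  codes <- lapply(codes, function(x) sort(unique(as.character(x))))
  new("Cohort", patients = patients[, c("patient_id", "age", "sex")],
      codes = codes, label = label, report = report)
}

#' Undirected multimorbidity network
#'
#' Nodes are 3-character ICD-10 disease categories with chapter, prevalence
#' and patient count attributes; edges are selected comorbidity patterns
#' carrying odds ratio, p-value and co-occurrence frequency. All edge odds
#' ratios exceed 1 by construction (the first selection criterion).
#'
#' @slot graph an undirected, simple `igraph` object.
#' @slot label population/stratum name.
#' @export
setClass("MultimorbidityNetwork",
  representation(graph = "ANY", label = "character"),
  prototype(label = "network")
)

setValidity("MultimorbidityNetwork", function(object) {
  g <- object@graph
  msgs <- character(0)
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (!igraph::is_simple(g))
    msgs <- c(msgs, "graph must be simple (no loops or multi-edges)")
  if (is.null(igraph::V(g)$name) && igraph::vcount(g) > 0)
    msgs <- c(msgs, "nodes must be named by disease code")
  if (igraph::ecount(g) > 0) {
    or <- igraph::E(g)$odds_ratio
    if (is.null(or) || any(!is.finite(or)) || any(or <= 1))
      msgs <- c(msgs, "all edge odds ratios must be finite and > 1")
  }
  if (length(msgs)) msgs else TRUE
})
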