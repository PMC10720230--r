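#' Number of inpatients in a cohort
#' @param x a [Cohort-class].
#' @return integer count of baseline records (one per patient).
#' @export
setGeneric("nInpatients", function(x) standardGeneric("nInpatients"))

#' @rdname nInpatients
#' @export
setMethod("nInpatients", "Cohort", function(x) nrow(x@patients))

#' Patient demographics table
#' @param x a [Cohort-class].
#' @return data.frame with `patient_id`, `age`, `sex`.
#' @export
setGeneric("patientData", function(x) standardGeneric("patientData"))

#' @rdname patientData
#' @export
setMethod("patientData", "Cohort", function(x) x@patients)

#' Per-patient diagnosis code sets
#' @param x a [Cohort-class].
#' @return list of sorted character vectors of 3-character ICD-10 codes.
#' @export
setGeneric("diseaseCodes", function(x) standardGeneric("diseaseCodes"))

#' @rdname diseaseCodes
#' @export
setMethod("diseaseCodes", "Cohort", function(x) x@codes)

#' Label of a cohort or network
#' @param x a [Cohort-class] or [MultimorbidityNetwork-class].
#' @return single character label.
#' @export
setGeneric("objectLabel", function(x) standardGeneric("objectLabel"))

#' @rdname objectLabel
#' @export
setMethod("objectLabel", "Cohort", function(x) x@label)

#' @rdname objectLabel
#' @export
setMethod("objectLabel", "MultimorbidityNetwork", function(x) x@label)

#' Parse/filter report accumulated while building a cohort
#' @param x a [Cohort-class].
#' @return named list of exclusion counts by reason.
#' @export
setGeneric("cohortReport", function(x) standardGeneric("cohortReport"))

#' @rdname cohortReport
#' @export
setMethod("cohortReport", "Cohort", function(x) x@report)

#' Sparse patient-by-disease indicator matrix
#'
#' Rows are patients (in cohort order), columns are disease codes in
#' lexicographic order; entry is `TRUE` when the code appears in the
#' patient's baseline record. This is the workhorse representation for
#' pairwise pattern counting via a single sparse cross-product.
#'
#' @param x a [Cohort-class].
#' @return a `Matrix::sparseMatrix` (pattern/logical) with dimnames.
#' @export
setGeneric("diseaseIndicators", function(x) standardGeneric("diseaseIndicators"))

#' @rdname diseaseIndicators
#' @export
setMethod("diseaseIndicators", "Cohort", function(x) {
  all_codes <- sort(unique(unlist(x@codes, use.names = FALSE)))
  n <- nInpatients(x)
  k <- lengths(x@codes)
  i <- rep.int(seq_len(n), k)
  j <- match(unlist(x@codes, use.names = FALSE), all_codes)
  Matrix::sparseMatrix(i = i, j = j, dims = c(n, length(all_codes)),
                       dimnames = list(x@patients$patient_id, all_codes))
})

#' Underlying igraph of a multimorbidity network
#' @param x a [MultimorbidityNetwork-class].
#' @return the `igraph` object with node and edge attributes.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "MultimorbidityNetwork", function(x) x@graph)

#' Node and edge counts of a network
#' @param x a [MultimorbidityNetwork-class].
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "MultimorbidityNetwork",
          function(x) igraph::vcount(x@graph))

#' @rdname nNodes
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname nNodes
#' @export
setMethod("nEdges", "MultimorbidityNetwork",
          function(x) igraph::ecount(x@graph))

#' Node attribute table of a network
#' @param x a [MultimorbidityNetwork-class].
#' @return data.frame with `code`, `chapter`, `prevalence`, `count`, sorted
#'   by code.
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "MultimorbidityNetwork", function(x) {
  g <- x@graph
  if (igraph::vcount(g) == 0L)
    return(data.frame(code = character(0), chapter = integer(0),
                      prevalence = numeric(0), count = numeric(0)))
  df <- data.frame(
    code = igraph::V(g)$name,
    chapter = if (is.null(igraph::V(g)$chapter)) NA_integer_ else igraph::V(g)$chapter,
    prevalence = if (is.null(igraph::V(g)$prevalence)) NA_real_ else igraph::V(g)$prevalence,
    count = if (is.null(igraph::V(g)$count)) NA_real_ else igraph::V(g)$count,
    stringsAsFactors = FALSE
  )
  df[order(df$code), , drop = FALSE]
})

#' Edge attribute table of a network
#' @param x a [MultimorbidityNetwork-class].
#' @return data.frame with canonical `code_i < code_j` pairs, `odds_ratio`,
#'   `p_value`, `frequency`, sorted by pair.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "MultimorbidityNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(code_i = character(0), code_j = character(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      frequency = numeric(0)))
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  ci <- pmin(ends[, 1], ends[, 2])
  cj <- pmax(ends[, 1], ends[, 2])
  df <- data.frame(
    code_i = ci, code_j = cj,
    odds_ratio = igraph::E(g)$odds_ratio,
    p_value = if (is.null(igraph::E(g)$p_value)) NA_real_ else igraph::E(g)$p_value,
    frequency = if (is.null(igraph::E(g)$frequency)) NA_real_ else igraph::E(g)$frequency,
    stringsAsFactors = FALSE
  )
  df[order(df$code_i, df$code_j), , drop = FALSE]
})

setMethod("show", "Cohort", function(object) {
  p <- object@patients
  cat("Cohort '", object@label, "': ", nrow(p), " inpatients\n", sep = "")
  if (nrow(p)) {
    cat("  ages ", min(p$age), "-", max(p$age),
        "; female ", sum(p$sex == "female"),
        ", male ", sum(p$sex == "male"), "\n", sep = "")
    cat("  distinct diseases: ",
        length(unique(unlist(object@codes, use.names = FALSE))),
        "; diagnoses per capita: ",
        round(sum(lengths(object@codes)) / nrow(p), 2), "\n", sep = "")
  }
  invisible(object)
})

setMethod("show", "MultimorbidityNetwork", function(object) {
  cat("MultimorbidityNetwork '", object@label, "': ",
      igraph::vcount(object@graph), " nodes, ",
      igraph::ecount(object@graph), " edges\n", sep = "")
  invisible(object)
})
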