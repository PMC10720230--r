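#' Descriptive summary of a cohort
#'
#' Counts diagnoses as distinct 3-character codes per baseline record (the
#' same definition used by pattern enumeration), and summarizes per-capita
#' diagnoses overall and by single year of age and ICD-10 chapter, the
#' single-disease vs multimorbidity (>= 2 diseases) split overall, by sex
#' and by age, and the age distribution.
#'
#' @param cohort a non-empty [Cohort-class].
#' @return list of class `"PopulationSummary"`: `label`, `n_inpatients`,
#'   `n_diseases`, `n_diagnoses`, `per_capita`, `per_capita_by_age_chapter`
#'   (data.frame `age`, `chapter`, `diagnoses`, `per_capita`),
#'   `per_capita_by_age` (rowsum over chapters), `single_count`,
#'   `single_pct`, `multimorbidity_count`, `multimorbidity_pct`,
#'   `multimorbidity_by_sex`, `multimorbidity_by_age`, `mean_age`, `sd_age`.
#'   Percentages are exact (unrounded); print rounds to 2 decimals.
#' @export
summarizePopulation <- function(cohort) {
  n <- nInpatients(cohort)
  if (n == 0L) stop("empty cohort")
  codes <- diseaseCodes(cohort)
  p <- patientData(cohort)
  k <- lengths(codes)
  n_diag <- sum(k)

  all_codes <- unlist(codes, use.names = FALSE)
  age_rep <- rep.int(p$age, k)
  ch <- icdChapter(all_codes)
  byac <- as.data.frame(table(age = age_rep, chapter = ch),
                        stringsAsFactors = FALSE)
  byac <- byac[byac$Freq > 0, , drop = FALSE]
  names(byac)[3] <- "diagnoses"
  byac$age <- as.integer(byac$age)
  byac$chapter <- as.integer(byac$chapter)
  n_by_age <- table(p$age)
  byac$per_capita <- byac$diagnoses /
    as.integer(n_by_age[as.character(byac$age)])
  byac <- byac[order(byac$age, byac$chapter), , drop = FALSE]
  rownames(byac) <- NULL
  by_age <- aggregate(diagnoses ~ age, data = byac, FUN = sum)
  by_age$per_capita <- by_age$diagnoses /
    as.integer(n_by_age[as.character(by_age$age)])

  multi <- k >= 2L
  multi_by_sex <- vapply(c(male = "male", female = "female"), function(s) {
    sel <- p$sex == s
    if (!any(sel)) NA_real_ else 100 * sum(multi[sel]) / sum(sel)
  }, numeric(1))
  multi_by_age <- vapply(sort(unique(p$age)), function(a) {
    sel <- p$age == a
    100 * sum(multi[sel]) / sum(sel)
  }, numeric(1))
  names(multi_by_age) <- sort(unique(p$age))

  structure(list(
    label = objectLabel(cohort),
    n_inpatients = n,
    n_diseases = length(unique(all_codes)),
    n_diagnoses = n_diag,
    per_capita = n_diag / n,
    per_capita_by_age_chapter = byac,
    per_capita_by_age = by_age,
    single_count = sum(k == 1L),
    single_pct = 100 * sum(k == 1L) / n,
    multimorbidity_count = sum(multi),
    multimorbidity_pct = 100 * sum(multi) / n,
    multimorbidity_by_sex = multi_by_sex,
    multimorbidity_by_age = multi_by_age,
    mean_age = mean(p$age),
    sd_age = sd(p$age)
  ), class = "PopulationSummary")
}

#' @export
print.PopulationSummary <- function(x, ...) {
  cat("PopulationSummary '", x$label, "': ", x$n_inpatients,
      " inpatients, ", x$n_diseases, " diseases, ", x$n_diagnoses,
      " diagnoses (", round(x$per_capita, 2), "/person)\n", sep = "")
  cat("  single disease: ", x$single_count, " (",
      round(x$single_pct, 2), "%); multimorbidity: ",
      x$multimorbidity_count, " (", round(x$multimorbidity_pct, 2),
      "%)\n", sep = "")
  cat("  age ", round(x$mean_age, 2), " ± ", round(x$sd_age, 2),
      "\n", sep = "")
  invisible(x)
}

#' Network complexity ratio
#'
#' Ratio of edge counts of two multimorbidity networks; the usual
#' "A is r times more complex than B" population comparison.
#'
#' @param network_a,network_b non-empty [MultimorbidityNetwork-class]
#'   objects; `network_b` must have at least one edge.
#' @return unrounded ratio `edges(a) / edges(b)` (reports round to 2 dp).
#' @export
complexityRatio <- function(network_a, network_b) {
  if (nNodes(network_a) == 0L || nNodes(network_b) == 0L)
    stop("both networks must be non-empty")
  if (nEdges(network_b) == 0L)
    stop("reference network has no edges")
  nEdges(network_a) / nEdges(network_b)
}

#' Top-k comorbidity patterns by frequency
#'
#' Ranks patterns by co-occurrence frequency descending, ties by odds ratio
#' descending, residual ties by canonical pair order.
#'
#' @param patterns pattern table with `frequency` and `odds_ratio`.
#' @param k number of patterns (default 10); fewer available rows are all
#'   returned with a warning.
#' @return the top rows, ranked.
#' @export
topKComorbidities <- function(patterns, k = 10L) {
  if (k == 0L) return(patterns[0, , drop = FALSE])
  if (nrow(patterns) < k) {
    warning("only ", nrow(patterns), " patterns available (k = ", k, ")")
    k <- nrow(patterns)
  }
  ord <- order(-patterns$frequency, -patterns$odds_ratio,
               patterns$code_i, patterns$code_j)
  out <- patterns[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

pairKey <- function(df) paste(pmin(df$code_i, df$code_j),
                              pmax(df$code_i, df$code_j), sep = "+")

#' Overlap between two ranked sets (patterns or hubs)
#'
#' @param top_a,top_b either pattern tables (compared on the canonical
#'   `code_i + code_j` pair key) or character vectors (e.g. hub codes).
#' @return list with `shared`, `specific_a`, `specific_b` (sorted keys).
#' @export
overlapAnalysis <- function(top_a, top_b) {
  keys <- function(x) if (is.data.frame(x)) pairKey(x) else as.character(x)
  a <- keys(top_a); b <- keys(top_b)
  list(shared = sort(intersect(a, b)),
       specific_a = sort(setdiff(a, b)),
       specific_b = sort(setdiff(b, a)))
}

#' Full two-population comparison
#'
#' Runs the complete pipeline per population and per sex stratum (six
#' networks: overall/male/female for each population, screened and selected
#' independently), then assembles the comparison: complexity ratios,
#' top-k comorbidity overlap, and hub overlap. Optionally writes every
#' artifact (cohort CSVs, pattern tables, GraphML networks, node/edge and
#' metric tables, hub reports, and a machine-readable comparison JSON).
#'
#' @param cohort_a,cohort_b two [Cohort-class] objects (e.g. two
#'   populations).
#' @param k_hubs hubs per network (default 10).
#' @param k_top top-k comorbidities for the overlap analysis (default 10).
#' @param alpha unadjusted significance level (default 0.05).
#' @param prevalence_floor pattern prevalence floor (default 1e-4).
#' @param out_dir optional directory; when given, all artifacts are written.
#' @return list of class `"ComparisonReport"`: `summaries` (per stratum),
#'   `reports` (HubReports per stratum), `complexity_ratios`
#'   (overall/male/female), `top_overlap`, `hub_overlap`.
#' @export
runFullComparison <- function(cohort_a, cohort_b, k_hubs = 10L, k_top = 10L,
                              alpha = 0.05, prevalence_floor = 1e-4,
                              out_dir = NULL) {
  strata <- function(cohort) {
    c(list(overall = cohort), stratifyBySex(cohort))
  }
  sa <- strata(cohort_a)
  sb <- strata(cohort_b)
  run <- function(cohorts, tag) {
    out <- lapply(cohorts, hubPipeline, k = k_hubs, alpha = alpha,
                  prevalence_floor = prevalence_floor)
    names(out) <- paste(tag, names(cohorts), sep = "_")
    out
  }
  reports <- c(run(sa, objectLabel(cohort_a)), run(sb, objectLabel(cohort_b)))
  summaries <- lapply(c(sa, sb), summarizePopulation)
  names(summaries) <- names(reports)

  la <- objectLabel(cohort_a); lb <- objectLabel(cohort_b)
  ratio_for <- function(stratum) {
    a <- reports[[paste(la, stratum, sep = "_")]]$network
    b <- reports[[paste(lb, stratum, sep = "_")]]$network
    if (nNodes(a) == 0L || nNodes(b) == 0L || nEdges(b) == 0L) NA_real_
    else complexityRatio(a, b)
  }
  ratios <- vapply(c(overall = "overall", male = "male", female = "female"),
                   ratio_for, numeric(1))

  topk <- lapply(reports, function(r) {
    sel <- r$patterns[r$patterns$selected, , drop = FALSE]
    if (nrow(sel) == 0L) sel else suppressWarnings(topKComorbidities(sel, k_top))
  })
  ov <- lapply(c(overall = "overall", male = "male", female = "female"),
               function(s) overlapAnalysis(
                 topk[[paste(la, s, sep = "_")]],
                 topk[[paste(lb, s, sep = "_")]]))
  hub_ov <- lapply(c(overall = "overall", male = "male", female = "female"),
                   function(s) overlapAnalysis(
                     reports[[paste(la, s, sep = "_")]]$hubs$code,
                     reports[[paste(lb, s, sep = "_")]]$hubs$code))

  result <- structure(list(
    labels = c(a = la, b = lb),
    summaries = summaries,
    reports = reports,
    top_k = topk,
    complexity_ratios = ratios,
    top_overlap = ov,
    hub_overlap = hub_ov
  ), class = "ComparisonReport")

  if (!is.null(out_dir)) writeComparisonArtifacts(result, out_dir)
  result
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport: ", x$labels[["a"]], " vs ", x$labels[["b"]], "\n",
      sep = "")
  for (s in c("overall", "male", "female"))
    cat("  ", s, ": complexity ratio ",
        round(x$complexity_ratios[[s]], 2), "; shared top-k patterns ",
        length(x$top_overlap[[s]]$shared), "; shared hubs ",
        length(x$hub_overlap[[s]]$shared), "\n", sep = "")
  invisible(x)
}

writeComparisonArtifacts <- function(x, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    writePatternTable(r$patterns, file.path(out_dir, paste0(nm, "_patterns.csv")))
    exportNetwork(r$network, out_dir, prefix = nm)
    exportNetwork(r$associated, out_dir, prefix = paste0(nm, "_hub_associated"))
    writeHubReport(r, file.path(out_dir, paste0(nm, "_hubs.json")))
  }
  comp <- list(
    labels = as.list(x$labels),
    complexity_ratios = lapply(x$complexity_ratios, round, 2),
    top_overlap = x$top_overlap,
    hub_overlap = x$hub_overlap,
    summaries = lapply(x$summaries, function(s)
      list(n_inpatients = s$n_inpatients, n_diseases = s$n_diseases,
           n_diagnoses = s$n_diagnoses,
           per_capita = round(s$per_capita, 2),
           single_pct = round(s$single_pct, 2),
           multimorbidity_pct = round(s$multimorbidity_pct, 2),
           mean_age = round(s$mean_age, 2), sd_age = round(s$sd_age, 2)))
  )
  jsonlite::write_json(comp, file.path(out_dir, "comparison_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Quick-look plots of a population summary
#'
#' Stacked per-capita diagnoses by age and chapter, or the multimorbidity
#' proportion by age. Requires ggplot2.
#'
#' @param summary a `"PopulationSummary"`.
#' @param type `"per_capita"` (stacked bars by chapter) or
#'   `"multimorbidity"` (proportion by age).
#' @return a ggplot object.
#' @export
plotSummary <- function(summary, type = c("per_capita", "multimorbidity")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  type <- match.arg(type)
  if (type == "per_capita") {
    df <- summary$per_capita_by_age_chapter
    df$chapter <- factor(df$chapter, levels = 1:14)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$per_capita,
                                     fill = .data$chapter)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Age (years)", y = "Per-capita disease diagnoses",
                    fill = "ICD-10 chapter", title = summary$label)
  } else {
    df <- data.frame(age = as.integer(names(summary$multimorbidity_by_age)),
                     pct = unname(summary$multimorbidity_by_age))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$pct)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Age (years)", y = "Multimorbidity (%)",
                    title = summary$label)
  }
}
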