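#' Per-disease counts and prevalences in a cohort
#'
#' @param cohort a [Cohort-class].
#' @return data.frame with `code`, `chapter`, `count` (number of baseline
#'   records containing the code) and `prevalence` (`count / n_inpatients`),
#'   sorted by code.
#' @export
diseasePrevalence <- function(cohort) {
  n <- nInpatients(cohort)
  tab <- table(unlist(diseaseCodes(cohort), use.names = FALSE))
  codes <- sort(names(tab))
  data.frame(code = codes,
             chapter = icdChapter(codes),
             count = as.integer(tab[codes]),
             prevalence = as.integer(tab[codes]) / n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enumerate all comorbidity patterns of a cohort
#'
#' A comorbidity pattern is an unordered pair of distinct diseases present
#' together in at least one patient's baseline record. For each pattern the
#' full patient-level 2x2 table is returned: `n11` patients with both,
#' `n10`/`n01` with exactly one, `n00` with neither (patients with no
#' disease at all count in `n00`). Computed with one sparse cross-product of
#' the patient-by-disease indicator matrix.
#'
#' @param cohort a [Cohort-class].
#' @return data.frame with canonical (`code_i` < `code_j`) pairs, the four
#'   cells, `frequency` (= `n11`) and `prevalence`
#'   (= `frequency / n_inpatients`), sorted by pair.
#' @export
enumeratePatterns <- function(cohort) {
  n <- nInpatients(cohort)
  empty <- data.frame(code_i = character(0), code_j = character(0),
                      n11 = integer(0), n10 = integer(0), n01 = integer(0),
                      n00 = integer(0), frequency = integer(0),
                      prevalence = numeric(0))
  if (n == 0L) return(empty)
  M <- diseaseIndicators(cohort)
  if (ncol(M) < 2L) return(empty)
  X <- M * 1                            # numeric sparse
  CO <- Matrix::crossprod(X)            # n11 for every ordered pair
  counts <- Matrix::diag(CO)
  TT <- as(as(Matrix::triu(CO, k = 1L), "generalMatrix"), "TsparseMatrix")
  keep <- TT@x > 0
  if (!any(keep)) return(empty)
  codes <- colnames(M)
  n11 <- as.integer(TT@x[keep])
  ii <- TT@i[keep] + 1L
  jj <- TT@j[keep] + 1L
  ci <- codes[ii]
  cj <- codes[jj]
  n10 <- as.integer(counts[ii]) - n11
  n01 <- as.integer(counts[jj]) - n11
  out <- data.frame(code_i = ci, code_j = cj, n11 = n11, n10 = n10,
                    n01 = n01, n00 = n - n11 - n10 - n01,
                    frequency = n11, prevalence = n11 / n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$code_i, out$code_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Odds ratio and Wald p-value of a 2x2 comorbidity table
#'
#' For an unadjusted logistic regression of one binary disease indicator on
#' the other, the exponentiated slope equals the contingency cross-product
#' ratio `(n11 * n00) / (n10 * n01)`; the closed form is used here (the
#' regression fit serves only as an independent cross-check in the test
#' suite). The two-sided p-value is the Wald test of the log odds ratio
#' with standard error `sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)`. If any cell
#' is zero, the Haldane-Anscombe correction (+0.5 to all four cells) keeps
#' the estimate finite; such patterns are flagged via `zero_cell`.
#'
#' @param n11,n10,n01,n00 vectors of non-negative cell counts
#'   (`n11` = both diseases, `n00` = neither).
#' @return data.frame with `odds_ratio`, `p_value`, `zero_cell`.
#' @examples
#' estimateOR(10, 20, 30, 40)   # OR 0.667, p ~0.374
#' @export
estimateOR <- function(n11, n10, n01, n00) {
  stopifnot(length(n11) == length(n10), length(n10) == length(n01),
            length(n01) == length(n00))
  if (any(c(n11, n10, n01, n00) < 0)) stop("cell counts must be >= 0")
  ntot <- n11 + n10 + n01 + n00
  if (any(ntot == 0)) stop("empty 2x2 table (n = 0)")
  zero <- n11 == 0 | n10 == 0 | n01 == 0 | n00 == 0
  a <- n11 + 0.5 * zero; b <- n10 + 0.5 * zero
  c_ <- n01 + 0.5 * zero; d <- n00 + 0.5 * zero
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- log(or) / se
  data.frame(odds_ratio = or, p_value = 2 * pnorm(-abs(z)),
             zero_cell = zero)
}

#' Bonferroni family size for edge selection
#'
#' The number of enumerated patterns with odds ratio strictly greater than
#' 1, computed per cohort/stratum; the adjusted significance threshold is
#' `alpha / N`.
#'
#' @param odds_ratio numeric vector of pattern odds ratios.
#' @return integer `N >= 0`.
#' @export
bonferroniN <- function(odds_ratio) sum(odds_ratio > 1)

#' Apply the three edge-selection criteria to a pattern table
#'
#' A pattern becomes a network edge iff (1) odds ratio > 1, (2) two-sided
#' p-value < `alpha / N` with `N` the number of patterns with OR > 1 in the
#' same table (Bonferroni), and (3) pattern prevalence > the floor
#' (default 1/10,000). All inequalities are strict.
#'
#' @param patterns data.frame from [enumeratePatterns()], with or without
#'   the OR columns ([estimateOR()] is applied if absent).
#' @param alpha unadjusted significance level (default 0.05).
#' @param prevalence_floor minimum pattern prevalence (default 1e-4).
#' @return the pattern table with added columns `odds_ratio`, `p_value`,
#'   `zero_cell`, `bonferroni_n`, `alpha_adjusted`, `selected`; a selection
#'   report (counts failing each criterion) is attached as attribute
#'   `"selection_report"`.
#' @export
selectEdges <- function(patterns, alpha = 0.05, prevalence_floor = 1e-4) {
  if (!all(c("odds_ratio", "p_value", "zero_cell") %in% names(patterns))) {
    est <- estimateOR(patterns$n11, patterns$n10, patterns$n01, patterns$n00)
    patterns <- cbind(patterns, est)
  }
  N <- bonferroniN(patterns$odds_ratio)
  patterns$bonferroni_n <- N
  patterns$alpha_adjusted <- if (N > 0) alpha / N else NA_real_
  if (N == 0L && nrow(patterns) > 0L) {
    warning("no pattern has OR > 1; no edge can be selected")
    patterns$selected <- rep(FALSE, nrow(patterns))
  } else {
    patterns$selected <- patterns$odds_ratio > 1 &
      patterns$p_value < alpha / N &
      patterns$prevalence > prevalence_floor
  }
  attr(patterns, "selection_report") <- list(
    n_patterns = nrow(patterns),
    bonferroni_n = N,
    alpha_adjusted = if (N > 0) alpha / N else NA_real_,
    fail_or = sum(patterns$odds_ratio <= 1),
    fail_p = if (N > 0) sum(!(patterns$p_value < alpha / N)) else nrow(patterns),
    fail_prevalence = sum(!(patterns$prevalence > prevalence_floor)),
    n_selected = sum(patterns$selected),
    n_zero_cell = sum(patterns$zero_cell)
  )
  patterns
}

#' Screen a cohort: enumerate, estimate, and select in one call
#'
#' @param cohort a [Cohort-class].
#' @inheritParams selectEdges
#' @return pattern table as from [selectEdges()].
#' @export
screenPatterns <- function(cohort, alpha = 0.05, prevalence_floor = 1e-4) {
  pat <- enumeratePatterns(cohort)
  if (nrow(pat) == 0L) {
    pat$odds_ratio <- numeric(0); pat$p_value <- numeric(0)
    pat$zero_cell <- logical(0); pat$bonferroni_n <- integer(0)
    pat$alpha_adjusted <- numeric(0); pat$selected <- logical(0)
    return(pat)
  }
  selectEdges(pat, alpha = alpha, prevalence_floor = prevalence_floor)
}

#' Write a pattern table as CSV
#' @param patterns pattern table from [screenPatterns()]/[selectEdges()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePatternTable <- function(patterns, path) {
  data.table::fwrite(patterns, path)
  invisible(path)
}
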