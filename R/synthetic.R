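#' Joint prevalence of a bivariate Bernoulli pair with a given odds ratio
#'
#' For two binary diseases with marginal prevalences `p_i`, `p_j` and target
#' odds ratio `psi`, returns the unique joint prevalence
#' `p11 = P(both present)` compatible with the marginals, i.e. the admissible
#' root of `(psi - 1) p11^2 - S p11 + psi p_i p_j = 0` with
#' `S = 1 + (p_i + p_j)(psi - 1)` (the Plackett construction); for
#' `psi = 1` this is the independence product `p_i * p_j`. The result always
#' lies within the Frechet bounds
#' `[max(0, p_i + p_j - 1), min(p_i, p_j)]`.
#'
#' @param p_i,p_j marginal prevalences in (0, 1); vectorized.
#' @param psi target odds ratio, > 0.
#' @return joint prevalence `p11`.
#' @examples
#' solveJointPrevalence(0.5, 0.5, 1)  # 0.25
#' solveJointPrevalence(0.3, 0.2, 4)  # ~0.1107
#' @export
solveJointPrevalence <- function(p_i, p_j, psi) {
  stopifnot(all(p_i > 0 & p_i < 1), all(p_j > 0 & p_j < 1))
  if (any(psi <= 0)) stop("odds ratio psi must be > 0")
  n <- max(length(p_i), length(p_j), length(psi))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n); psi <- rep_len(psi, n)
  p11 <- p_i * p_j
  idx <- which(abs(psi - 1) > 1e-12)
  if (length(idx)) {
    a <- psi[idx] - 1
    S <- 1 + (p_i[idx] + p_j[idx]) * a
    disc <- S^2 - 4 * a * psi[idx] * p_i[idx] * p_j[idx]
    p11[idx] <- (S - sqrt(pmax(disc, 0))) / (2 * a)
  }
  lo <- pmax(0, p_i + p_j - 1)
  hi <- pmin(p_i, p_j)
  pmin(pmax(p11, lo), hi)
}

#' Configuration for a synthetic inpatient cohort
#'
#' Defines a cohort of `n_patients` baseline records with known marginal
#' disease prevalences and, for a set of vertex-disjoint planted pairs,
#' known pairwise odds ratios; every non-planted disease is sampled
#' independently. Vertex-disjointness keeps the joint law exactly specified
#' without a full multivariate dependence model.
#'
#' @param n_patients number of patients.
#' @param diseases named numeric vector: names are 3-character ICD-10 codes,
#'   values are marginal prevalences in (0, 1).
#' @param planted_pairs data.frame with columns `code_i`, `code_j`, `psi`
#'   (odds ratio > 0), or `NULL` for a fully independent cohort.
#' @param sex_fraction_female proportion of females (default 0.5).
#' @param age_range inclusive integer age bounds, default `c(40, 59)`.
#' @param seed integer RNG seed; generation is a pure function of the config.
#' @return validated config (list with class `"SyntheticCohortConfig"`).
#' @export
syntheticCohortConfig <- function(n_patients, diseases, planted_pairs = NULL,
                                  sex_fraction_female = 0.5,
                                  age_range = c(40L, 59L), seed = 1L) {
  stopifnot(n_patients >= 1, length(diseases) >= 1)
  codes <- names(diseases)
  if (is.null(codes) || anyDuplicated(codes))
    stop("diseases must be a named vector with unique codes")
  codes <- normalizeCode(codes)
  names(diseases) <- codes
  if (any(diseases <= 0 | diseases >= 1))
    stop("all marginal prevalences must lie in (0, 1)")
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
    planted_pairs$code_i <- normalizeCode(planted_pairs$code_i)
    planted_pairs$code_j <- normalizeCode(planted_pairs$code_j)
    planted_pairs$psi <- as.numeric(planted_pairs$psi)
    members <- c(planted_pairs$code_i, planted_pairs$code_j)
    if (!all(members %in% codes))
      stop("planted pair codes must appear in the disease catalog")
    if (anyDuplicated(members))
      stop("planted pairs must be vertex-disjoint")
    if (any(planted_pairs$psi <= 0))
      stop("planted odds ratios must be > 0")
    p11 <- solveJointPrevalence(diseases[planted_pairs$code_i],
                                diseases[planted_pairs$code_j],
                                planted_pairs$psi)
    cells_ok <- p11 >= 0 &
      diseases[planted_pairs$code_i] - p11 >= 0 &
      diseases[planted_pairs$code_j] - p11 >= 0 &
      1 - diseases[planted_pairs$code_i] - diseases[planted_pairs$code_j] + p11 >= 0
    if (any(!cells_ok))
      stop("infeasible planted pair(s): ",
           paste(planted_pairs$code_i[!cells_ok],
                 planted_pairs$code_j[!cells_ok], sep = "-", collapse = ", "))
  } else {
    planted_pairs <- data.frame(code_i = character(0), code_j = character(0),
                                psi = numeric(0))
  }
  stopifnot(sex_fraction_female >= 0, sex_fraction_female <= 1,
            length(age_range) == 2, age_range[1] <= age_range[2])
  structure(list(n_patients = as.integer(n_patients),
                 diseases = diseases,
                 planted_pairs = planted_pairs,
                 sex_fraction_female = sex_fraction_female,
                 age_range = as.integer(age_range),
                 seed = as.integer(seed)),
            class = "SyntheticCohortConfig")
}

#' Read a synthetic-cohort config from YAML or JSON
#'
#' Expected fields mirror [syntheticCohortConfig()]: `n_patients`,
#' `diseases` (code -> prevalence mapping), optional `planted_pairs` (list of
#' `{code_i, code_j, psi}`), `sex_fraction_female`, `age_range`, `seed`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return validated config.
#' @export
readCohortConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- raw$planted_pairs
  if (!is.null(pp) && !is.data.frame(pp))
    pp <- do.call(rbind, lapply(pp, as.data.frame))
  syntheticCohortConfig(
    n_patients = raw$n_patients,
    diseases = unlist(raw$diseases),
    planted_pairs = pp,
    sex_fraction_female = raw$sex_fraction_female %||% 0.5,
    age_range = raw$age_range %||% c(40L, 59L),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logical patient x disease matrix -> per-patient sorted code sets
presenceToCodes <- function(pres) {
  idx <- which(pres, arr.ind = TRUE)
  split(colnames(pres)[idx[, 2]],
        factor(idx[, 1], levels = seq_len(nrow(pres))))
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort with planted pairwise odds ratios
#'
#' Samples `n_patients` baseline records: ages uniform over the configured
#' range, sex by the configured fraction, each planted pair from the 2x2
#' cell distribution implied by [solveJointPrevalence()], and every
#' remaining disease independently at its marginal prevalence. The random
#' stream order is fixed (sex, age, planted pairs in config order, remaining
#' diseases in catalog order) so a seed fully determines the cohort.
#' Patients with no sampled disease are kept: they belong to the screening
#' denominator (they contribute to the `n00` cell of every pattern).
#'
#' @param config a [syntheticCohortConfig()].
#' @return list with `cohort` (a [Cohort-class]) and `truth` (data.frame
#'   `code_i`, `code_j`, `psi`, `p11`, one row per planted pair).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  n <- config$n_patients
  dis <- config$diseases
  pp <- config$planted_pairs
  withSeed(config$seed, {
    sex <- ifelse(runif(n) < config$sex_fraction_female, "female", "male")
    age <- config$age_range[1] +
      floor(runif(n) * (config$age_range[2] - config$age_range[1] + 1L))
    pres <- matrix(FALSE, nrow = n, ncol = length(dis),
                   dimnames = list(NULL, names(dis)))
    truth <- data.frame(code_i = character(0), code_j = character(0),
                        psi = numeric(0), p11 = numeric(0))
    if (nrow(pp)) {
      p11 <- solveJointPrevalence(dis[pp$code_i], dis[pp$code_j], pp$psi)
      for (r in seq_len(nrow(pp))) {
        pi_ <- dis[[pp$code_i[r]]]; pj_ <- dis[[pp$code_j[r]]]
        cells <- c(p11[r], pi_ - p11[r], pj_ - p11[r], 1 - pi_ - pj_ + p11[r])
        draw <- sample.int(4L, n, replace = TRUE, prob = cells)
        pres[, pp$code_i[r]] <- draw %in% c(1L, 2L)
        pres[, pp$code_j[r]] <- draw %in% c(1L, 3L)
      }
      truth <- data.frame(code_i = pp$code_i, code_j = pp$code_j,
                          psi = pp$psi, p11 = unname(p11))
    }
    free <- setdiff(names(dis), c(pp$code_i, pp$code_j))
    for (code in free) pres[, code] <- runif(n) < dis[[code]]
  })
  codes <- presenceToCodes(pres)
  patients <- data.frame(
    patient_id = sprintf("S%0*d", nchar(n), seq_len(n)),
    age = as.integer(age), sex = sex, stringsAsFactors = FALSE)
  list(cohort = Cohort(patients, codes, label = "synthetic"),
       truth = truth)
}

#' Generate a fully independent (null) cohort
#'
#' Convenience wrapper around [generateCohort()] with no planted pairs; used
#' for family-wise error-rate checks of the Bonferroni selection rule.
#'
#' @param n_patients number of patients.
#' @param diseases named prevalence vector as in [syntheticCohortConfig()].
#' @param seed integer RNG seed.
#' @return a [Cohort-class].
#' @export
nullCohort <- function(n_patients, diseases, seed = 1L) {
  cfg <- syntheticCohortConfig(n_patients, diseases, NULL, seed = seed)
  generateCohort(cfg)$cohort
}

#' Latent-factor cohort (positive dependence, no exact odds ratios)
#'
#' An optional, more "realistic" generator: one shared standard-normal
#' factor per patient, thresholded per disease so that marginal prevalences
#' are exact while all disease pairs are positively dependent. Unlike
#' [generateCohort()] the pairwise odds ratios are not specified exactly, so
#' this mode is excluded from exact parameter-recovery checks.
#'
#' @param n_patients number of patients.
#' @param diseases named prevalence vector.
#' @param loading common factor loading in `[0, 1)`; 0 gives independence.
#' @param seed integer RNG seed.
#' @return a [Cohort-class].
#' @export
latentFactorCohort <- function(n_patients, diseases, loading = 0.4,
                               seed = 1L) {
  stopifnot(loading >= 0, loading < 1)
  cfg <- syntheticCohortConfig(n_patients, diseases, NULL, seed = seed)
  n <- cfg$n_patients
  dis <- cfg$diseases
  withSeed(cfg$seed, {
    sex <- ifelse(runif(n) < cfg$sex_fraction_female, "female", "male")
    age <- cfg$age_range[1] +
      floor(runif(n) * (cfg$age_range[2] - cfg$age_range[1] + 1L))
    z <- rnorm(n)
    pres <- matrix(FALSE, nrow = n, ncol = length(dis),
                   dimnames = list(NULL, names(dis)))
    for (code in names(dis)) {
      liab <- loading * z + sqrt(1 - loading^2) * rnorm(n)
      pres[, code] <- liab < qnorm(dis[[code]])
    }
  })
  codes <- presenceToCodes(pres)
  patients <- data.frame(
    patient_id = sprintf("S%0*d", nchar(n), seq_len(n)),
    age = as.integer(age), sex = sex, stringsAsFactors = FALSE)
  Cohort(patients, codes, label = "synthetic_latent")
}

#' Write the planted truth table as CSV
#' @param truth data.frame from [generateCohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePlantedTruth <- function(truth, path) {
  data.table::fwrite(truth, path)
  invisible(path)
}
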